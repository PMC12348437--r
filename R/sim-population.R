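#' @include sim-expression.R
NULL

# Map a genomic position to its 1-based CDS coordinate (NA when intronic),
# given the gene's exons in genomic order and its strand.
cdsIndexOf <- function(exons, strand, pos) {
  st <- IRanges::start(exons); en <- IRanges::end(exons)
  w <- IRanges::width(exons)
  hit <- which(pos >= st & pos <= en)
  if (!length(hit)) return(NA_integer_)
  hit <- hit[1L]
  if (strand == "+") {
    sum(w[seq_len(hit - 1L)]) + (pos - st[hit] + 1L)
  } else {
    offset <- if (hit < length(w)) sum(w[(hit + 1L):length(w)]) else 0L
    offset + (en[hit] - pos + 1L)
  }
}

complementBase <- function(x) chartr("ACGT", "TACG", x)

# Reference trait means for the panel (units: cm, cm^2, cm^3, mm, count, count).
traitBaselines <- function() {
  c(TRL = 25, RSA = 8, RV = 0.3, RD = 0.5, RTN = 120, RBN = 80)
}

#' Simulate panel genotypes and root phenotypes
#'
#' Generates inbred biallelic SNP calls over every family gene region (start
#' codon - 2000 bp to stop codon + 500 bp) and a control/NaCl root-phenotype
#' table. Gene regions of members listed in \code{two_haplotype_members}
#' (which always includes causal members) are simulated as one tightly
#' linked block on the member's designated gene, so the region carries
#' exactly two haplotypes. Each row of \code{causal_spec} plants one causal
#' SNP whose dosage reduces the NaCl value of the named trait
#' multiplicatively, calibrated so the relative salt-injury rate carries the
#' requested fraction of variance; control values are effect-free.
#'
#' @param catalog a \linkS4class{NacCatalog}.
#' @param config the \linkS4class{SimConfig}.
#' @param truth the \linkS4class{TruthSet} to fill in.
#' @return list(panel = \linkS4class{GenotypePanel}, pheno = long-format
#'   phenotype data.frame (accession, trait, condition, replicate, plant,
#'   value), truth = updated TruthSet).
#' @export
simulatePopulation <- function(catalog, config, truth) {
  stopifnot(methods::is(config, "SimConfig"), methods::is(truth, "TruthSet"))
  withSeed(config@seed + 2L, {
    gr <- geneRanges(catalog)
    ids <- gr$gene_id
    fam <- ids[!is.na(memberOf(truth)[ids])]
    acc <- sprintf("ACC%03d", seq_len(config@n_accessions))
    nacc <- length(acc)

    # designated gene per member: first copy in chromosome order
    mem <- memberOf(truth)[fam]
    ord <- order(as.integer(factor(as.character(GenomicRanges::seqnames(gr)),
                                   levels = wheatChromosomes()))[match(fam, ids)],
                 GenomicRanges::start(gr)[match(fam, ids)])
    famo <- fam[ord]
    designated <- vapply(split(famo, memberOf(truth)[famo]), `[`, character(1), 1L)

    snp_rows <- list(); call_rows <- list(); hap_of <- list()
    causal <- config@causal_spec
    causal_rows <- list()

    for (g in fam) {
      i <- match(g, ids)
      m <- memberOf(truth)[[g]]
      strand <- as.character(GenomicRanges::strand(gr))[i]
      lo <- GenomicRanges::start(gr)[i]; hi <- GenomicRanges::end(gr)[i]
      win <- if (strand == "+") c(lo - 2000L, hi + 500L) else c(lo - 500L, hi + 2000L)
      win[1] <- max(win[1], 1L)
      pos <- sort(sample(seq(win[1], win[2]), config@snps_per_gene_region))
      exons <- gr$exons[[i]]
      cdsseq <- as.character(cdsSequences(catalog)[[g]])
      ref <- vapply(pos, function(p) {
        ci <- cdsIndexOf(exons, strand, p)
        if (is.na(ci)) sample(c("A", "C", "G", "T"), 1L)
        else {
          b <- substr(cdsseq, ci, ci)
          if (strand == "+") b else complementBase(b)
        }
      }, character(1))
      alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))

      two_hap <- m %in% config@two_haplotype_members && g == designated[[as.character(m)]]
      if (two_hap) {
        block <- rbinom(nacc, 1L, 0.3) + 1L       # haplotype 1 (major) or 2
        names(block) <- acc
        hap_of[[g]] <- block
        dose <- matrix(rep(2L * (block - 1L), each = length(pos)),
                       nrow = length(pos))
      } else {
        maf <- runif(length(pos), 0.1, 0.5)
        dose <- t(vapply(maf, function(f) 2L * rbinom(nacc, 1L, f),
                         integer(nacc)))
      }
      if (config@het_rate > 0) {
        flip <- matrix(runif(length(dose)) < config@het_rate, nrow(dose))
        dose[flip] <- 1L
      }
      calls <- matrix("0/0", nrow(dose), ncol(dose))
      calls[dose == 1L] <- "0/1"
      calls[dose == 2L] <- "1/1"
      calls[matrix(runif(length(dose)) < config@missing_rate, nrow(dose))] <- "./."
      snp_id <- sprintf("%s_s%02d", g, seq_along(pos))
      rownames(calls) <- snp_id; colnames(calls) <- acc
      snp_rows[[g]] <- data.frame(
        snp_id = snp_id, chrom = as.character(GenomicRanges::seqnames(gr))[i],
        pos = pos, ref = ref, alt = alt, gene_id = g,
        stringsAsFactors = FALSE)
      call_rows[[g]] <- calls

      if (two_hap && nrow(causal)) {
        hitr <- which(causal$member == m)
        for (r in hitr) {
          j <- ceiling(length(pos) / 2)
          causal_rows[[length(causal_rows) + 1L]] <- data.frame(
            snp_id = snp_id[j], member = m, gene_id = g,
            trait = causal$trait[r], effect = NA_real_,
            variance_explained = causal$variance_explained[r],
            stringsAsFactors = FALSE)
        }
      }
    }

    snp_tab <- do.call(rbind, snp_rows)
    calls <- do.call(rbind, call_rows)
    snps <- GenomicRanges::GRanges(
      seqnames = factor(snp_tab$chrom, levels = wheatChromosomes()),
      ranges = IRanges::IRanges(snp_tab$pos, width = 1L),
      snp_id = snp_tab$snp_id, ref = snp_tab$ref, alt = snp_tab$alt,
      display_id = sprintf("%04d[%s/%s]", snp_tab$pos %% 10000L,
                           snp_tab$ref, snp_tab$alt),
      gene_id = snp_tab$gene_id)
    panel <- new("GenotypePanel", snps = snps, calls = calls)

    # --- phenotypes ---------------------------------------------------------
    mu_inj <- 0.30; sigma_g <- 0.08
    sigma_m <- (1 - mu_inj) * config@plant_cv *
      sqrt(2 / (config@n_plants * config@n_phenotype_reps))
    causal_df <- if (length(causal_rows)) do.call(rbind, causal_rows) else
      data.frame(snp_id = character(), member = integer(), gene_id = character(),
                 trait = character(), effect = numeric(),
                 variance_explained = numeric())

    base <- traitBaselines()
    rows <- vector("list", length(rootTraits()))
    names(rows) <- rootTraits()
    for (tr in rootTraits()) {
      acc_mean <- base[[tr]] * exp(rnorm(nacc, 0, 0.15))
      injury <- mu_inj + rnorm(nacc, 0, sigma_g)
      hitr <- which(causal_df$trait == tr)
      for (r in hitr) {
        blk <- hap_of[[causal_df$gene_id[r]]]
        z <- as.numeric(scale(2 * (blk[acc] - 1)))
        ve <- causal_df$variance_explained[r]
        b <- sqrt(ve / (1 - ve) * (sigma_g^2 + sigma_m^2))
        if (mu_inj + b * max(abs(z)) + 3 * sigma_g > 0.95) {
          warning("variance_explained infeasible given plant_cv; effect truncated")
          b <- max((0.95 - mu_inj - 3 * sigma_g) / max(abs(z)), 0)
        }
        # the minor (Hap2) block is the tolerant one: alt dosage lowers injury
        causal_df$effect[r] <- -b
        injury <- injury - b * z
      }
      injury <- pmin(pmax(injury, -0.5), 0.95)
      out <- list()
      for (rep in seq_len(config@n_phenotype_reps)) {
        for (cond in c("CK", "NaCl")) {
          mult <- if (cond == "CK") rep(1, nacc) else 1 - injury
          vals <- t(vapply(seq_len(nacc), function(a)
            rlnormCV(config@n_plants, acc_mean[a] * mult[a], config@plant_cv),
            numeric(config@n_plants)))
          out[[paste(rep, cond)]] <- data.frame(
            accession = rep(acc, each = config@n_plants),
            trait = tr, condition = cond, replicate = rep,
            plant = rep(seq_len(config@n_plants), times = nacc),
            value = as.vector(t(vals)), stringsAsFactors = FALSE)
        }
      }
      rows[[tr]] <- do.call(rbind, out)
    }
    pheno <- do.call(rbind, rows)
    rownames(pheno) <- NULL

    truth@causal_snps <- causal_df
    truth@haplotype_of <- hap_of
    list(panel = panel, pheno = pheno, truth = truth)
  })
}
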