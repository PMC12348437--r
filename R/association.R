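#' @include expression.R
NULL

#' Relative salt-injury rates from root phenotypes
#'
#' Per accession, trait and replicate the plant values are averaged into
#' X_CK and X_NaCl; the replicate's injury rate is
#' (X_CK - X_NaCl) / X_CK x 100 (percent, negative when the trait increases
#' under NaCl), and the reported RSIR is the mean over replicates. Records
#' with X_CK = 0 in any replicate are flagged and excluded. Invariant to
#' plant and replicate ordering.
#'
#' @param pheno long-format data.frame with columns accession, trait,
#'   condition (CK / NaCl), replicate, plant, value.
#' @return data.frame(accession, trait, rsir); excluded accession x trait
#'   pairs are reported in attr(, "excluded").
#' @export
computeRSIR <- function(pheno) {
  need <- c("accession", "trait", "condition", "replicate", "value")
  if (!all(need %in% names(pheno)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(value ~ accession + trait + condition + replicate,
                          pheno, mean)
  wide <- merge(agg[agg$condition == "CK", ],
                agg[agg$condition == "NaCl", ],
                by = c("accession", "trait", "replicate"),
                suffixes = c("_ck", "_na"))
  if (!nrow(wide)) stop("both CK and NaCl conditions are required")
  wide$rsir_rep <- ifelse(wide$value_ck == 0, NA_real_,
                          (wide$value_ck - wide$value_na) / wide$value_ck * 100)
  res <- stats::aggregate(cbind(rsir = rsir_rep) ~ accession + trait, wide,
                          mean, na.action = stats::na.pass)
  bad <- is.na(res$rsir)
  excluded <- res[bad, c("accession", "trait")]
  res <- res[!bad, ]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Genotype quality control
#'
#' Minor-allele frequency is computed over non-missing alleles and folded to
#' at most 0.5; a SNP passes when MAF is strictly above \code{maf_min} and
#' the missing rate strictly below \code{missing_max} (the thresholds are
#' exclusive on both sides).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param maf_min,missing_max QC thresholds (defaults 0.10 and 0.05).
#' @return data.frame(snp_id, maf, missing_rate, qc_pass).
#' @export
qcSnps <- function(panel, maf_min = 0.10, missing_max = 0.05) {
  calls <- genotypeCalls(panel)
  dose <- dosageMatrix(panel)
  n_obs <- rowSums(!is.na(dose))
  alt_freq <- rowSums(dose, na.rm = TRUE) / (2 * n_obs)
  alt_freq[n_obs == 0] <- 0
  maf <- pmin(alt_freq, 1 - alt_freq)
  maf[n_obs == 0] <- 0
  missing_rate <- rowMeans(calls == "./.")
  data.frame(snp_id = rownames(calls), maf = maf,
             missing_rate = missing_rate,
             qc_pass = maf > maf_min & missing_rate < missing_max,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-SNP association scan against RSIR
#'
#' For each SNP, least-squares regression of the trait's RSIR on alt-allele
#' dosage (0/1/2) plus the top \code{n_pcs} genotype principal components
#' (computed on the mean-imputed dosage matrix of scan SNPs). Accessions
#' with a missing genotype are dropped per SNP and \code{n_used} recorded;
#' SNPs with no dosage variance after dropping are skipped. The p-value is
#' the dosage coefficient's t-test, q-values are Benjamini--Hochberg over
#' the scan, and a SNP is significant when -log10 p exceeds
#' \code{neg_log10_threshold} strictly.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param rsir output of [computeRSIR()].
#' @param trait one of [rootTraits()].
#' @param n_pcs number of principal-component covariates (default 3; 0
#'   reproduces the simple correlation test).
#' @param qc optional output of [qcSnps()]; computed when NULL.
#' @param qc_pass_only restrict the scan to QC-passing SNPs.
#' @param neg_log10_threshold significance threshold on -log10 p.
#' @return data.frame(snp_id, trait, n_used, beta, p_value, q_value,
#'   neg_log10_p, significant); skipped SNPs are listed in
#'   attr(, "skipped").
#' @export
associateRSIR <- function(panel, rsir, trait, n_pcs = 3, qc = NULL,
                          qc_pass_only = TRUE, neg_log10_threshold = 4) {
  stopifnot(trait %in% rsir$trait)
  y_all <- rsir$rsir[rsir$trait == trait]
  names(y_all) <- rsir$accession[rsir$trait == trait]
  if (sd(y_all) == 0) stop("constant phenotype: association scan undefined")
  if (is.null(qc)) qc <- qcSnps(panel)
  dose <- dosageMatrix(panel)
  keep_snps <- if (qc_pass_only) qc$snp_id[qc$qc_pass] else qc$snp_id
  dose <- dose[rownames(dose) %in% keep_snps, , drop = FALSE]
  acc <- intersect(colnames(dose), names(y_all))
  if (length(acc) < 3L)
    stop("need at least 3 accessions with genotype and phenotype")
  dose <- dose[, acc, drop = FALSE]
  y <- y_all[acc]

  pcs <- NULL
  if (n_pcs > 0) {
    imp <- dose
    mu <- rowMeans(imp, na.rm = TRUE)
    idx <- which(is.na(imp), arr.ind = TRUE)
    if (nrow(idx)) imp[idx] <- mu[idx[, 1L]]
    keep <- which(apply(imp, 1L, sd) > 0)
    # LD-prune before PCA: tightly linked candidate-region blocks would
    # otherwise dominate the top components and absorb local signals
    if (length(keep) > 1L) {
      cc <- abs(stats::cor(t(imp[keep, , drop = FALSE])))
      rownames(cc) <- colnames(cc) <- as.character(keep)
      pruned <- keep[1L]
      for (k in keep[-1L])
        if (all(cc[as.character(k), as.character(pruned)] < 0.9, na.rm = TRUE))
          pruned <- c(pruned, k)
      keep <- pruned
    }
    pr <- prcomp(t(imp[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
    n_pcs <- min(n_pcs, ncol(pr$x))
    pcs <- pr$x[, seq_len(n_pcs), drop = FALSE]
  }

  rows <- vector("list", nrow(dose))
  skipped <- character()
  for (i in seq_len(nrow(dose))) {
    d <- dose[i, ]
    ok <- !is.na(d)
    if (sd(d[ok]) == 0) {
      skipped <- c(skipped, rownames(dose)[i])
      next
    }
    X <- if (is.null(pcs)) d[ok] else cbind(dosage = d[ok], pcs[ok, , drop = FALSE])
    fit <- stats::lm(y[ok] ~ X)
    cf <- summary(fit)$coefficients
    rows[[i]] <- data.frame(snp_id = rownames(dose)[i], trait = trait,
                            n_used = sum(ok),
                            beta = cf[2L, 1L], p_value = cf[2L, 4L],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(snp_id = character(), trait = character(),
                      n_used = integer(), beta = numeric(),
                      p_value = numeric())
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$neg_log10_p <- -log10(res$p_value)
  res$significant <- res$neg_log10_p > neg_log10_threshold
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Locate a SNP relative to a gene model and call its coding effect
#'
#' Strand-aware classification: \code{promoter} within 2000 bp 5' of the
#' start codon, \code{utr3} within 500 bp 3' of the stop codon, otherwise
#' \code{exon} or \code{intron} by the exon intervals. For exonic positions
#' with a CDS available, the reference and alternative codons are compared
#' under the standard genetic code (\code{nonsense} when the alternative
#' codon is a stop).
#'
#' @param catalog a \linkS4class{NacCatalog} with CDS sequences.
#' @param gene_id catalogue gene.
#' @param position 1-based genomic position on the gene's chromosome.
#' @param alt alternative allele (plus-strand base).
#' @return list(context, coding_effect).
#' @export
annotateSnpContext <- function(catalog, gene_id, position, alt = NULL) {
  gr <- geneRanges(catalog)
  i <- match(gene_id, gr$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  strand <- as.character(GenomicRanges::strand(gr))[i]
  lo <- GenomicRanges::start(gr)[i]; hi <- GenomicRanges::end(gr)[i]
  promoter <- if (strand == "+") c(lo - 2000L, lo - 1L) else c(hi + 1L, hi + 2000L)
  utr3 <- if (strand == "+") c(hi + 1L, hi + 500L) else c(lo - 500L, lo - 1L)
  inWin <- function(w) position >= w[1] && position <= w[2]
  if (inWin(promoter)) return(list(context = "promoter", coding_effect = "na"))
  if (inWin(utr3)) return(list(context = "utr3", coding_effect = "na"))
  if (position < lo || position > hi)
    stop("SNP at ", position, " is outside the window of ", gene_id)
  exons <- gr$exons[[i]]
  ci <- cdsIndexOf(exons, strand, position)
  if (is.na(ci)) return(list(context = "intron", coding_effect = "na"))
  cds <- cdsSequences(catalog)
  if (!gene_id %in% names(cds) || is.null(alt))
    return(list(context = "exon", coding_effect = "na"))
  seqc <- as.character(cds[[gene_id]])
  codon_i <- (ci - 1L) %/% 3L
  codon <- substr(seqc, codon_i * 3L + 1L, codon_i * 3L + 3L)
  off <- ci - codon_i * 3L
  alt_cds <- if (strand == "+") toupper(alt) else complementBase(toupper(alt))
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_cds
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[codon]]; aa_alt <- code[[alt_codon]]
  effect <- if (aa_alt == aa_ref) "synonymous"
            else if (aa_alt == "*") "nonsense" else "missense"
  list(context = "exon", coding_effect = effect)
}

#' Manhattan-ready association table
#'
#' Orders results along the genome (chromosomes 1A..7D, then position, then
#' snp_id for ties) and adds a cumulative plotting coordinate.
#'
#' @param results output of [associateRSIR()].
#' @param snps the panel's SNP \code{GRanges} (provides chromosome and
#'   position per snp_id).
#' @return data.frame(snp_id, chromosome, position, cumulative_pos,
#'   neg_log10_p, trait, significant).
#' @export
manhattanTable <- function(results, snps) {
  if (!nrow(results))
    return(data.frame(snp_id = character(), chromosome = character(),
                      position = integer(), cumulative_pos = numeric(),
                      neg_log10_p = numeric(), trait = character(),
                      significant = logical()))
  i <- match(results$snp_id, snps$snp_id)
  chrom <- as.character(GenomicRanges::seqnames(snps))[i]
  pos <- GenomicRanges::start(snps)[i]
  lv <- wheatChromosomes()
  span <- tapply(pos, factor(chrom, lv), function(p) max(p, na.rm = TRUE))
  span[is.na(span)] <- 0
  offset <- setNames(c(0, cumsum(as.numeric(span)))[seq_along(lv)], lv)
  out <- data.frame(snp_id = results$snp_id, chromosome = chrom,
                    position = pos,
                    cumulative_pos = offset[chrom] + pos,
                    neg_log10_p = results$neg_log10_p,
                    trait = results$trait,
                    significant = results$significant,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chromosome, lv), out$position, out$snp_id), ]
  rownames(out) <- NULL
  out
}
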