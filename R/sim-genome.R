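#' @include sim-config.R
NULL

#' Consensus of the planted domain motif
#'
#' A fixed 30-residue consensus standing in for the conserved N-terminal
#' DNA-binding (NAM) domain that defines the family. The simulator plants it
#' in every family protein (and not in decoys); [scanNamDomain()] screens
#' for it.
#'
#' @return A 30-character amino-acid string.
#' @export
namMotifConsensus <- function() "WKATGKDKEVLSGGSTNLIGVKKALVFYAG"

aaAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

randomProtein <- function(n) {
  paste(sample(aaAlphabet(), n, replace = TRUE), collapse = "")
}

# Substitute a fraction of residues, never touching [protect_start, protect_end]
# (the planted motif must survive in every family copy).
mutateProtein <- function(protein, rate, protect_start, protect_end) {
  chars <- strsplit(protein, "")[[1]]
  idx <- seq_along(chars)
  idx <- idx[idx < protect_start | idx > protect_end]
  hit <- idx[runif(length(idx)) < rate]
  if (length(hit))
    chars[hit] <- sample(aaAlphabet(), length(hit), replace = TRUE)
  paste(chars, collapse = "")
}

# Back-translate a protein with uniformly chosen synonymous codons; appends a
# stop codon so the CDS is the full open reading frame.
backTranslate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  byAA <- split(names(code), code)
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- byAA[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""),
         byAA[["*"]][sample.int(3L, 1L)])
}

# Lay a CDS out over 2-4 exons with 100-800 bp introns. Exons are returned in
# genomic order; on the minus strand the first coding exon is the rightmost.
buildGeneStructure <- function(cds_nt, start, strand) {
  n_ex <- sample(2:4, 1L)
  cuts <- sort(sample(seq(30L, cds_nt - 30L), n_ex - 1L))
  lens <- diff(c(0L, cuts, cds_nt))
  introns <- sample(100:800, n_ex - 1L, replace = TRUE)
  exon_w <- if (strand == "+") lens else rev(lens)
  intr_w <- if (strand == "+") introns else rev(introns)
  starts <- start + cumsum(c(0L, head(exon_w, -1L) + intr_w))
  IRanges::IRanges(start = starts, end = starts + exon_w - 1L)
}

#' Simulate an annotated hexaploid genome with a planted gene family
#'
#' Places homoeolog members on the 21 chromosomes (1A..7D): each member has a
#' copy on the same-numbered chromosome of one to three subgenomes, all
#' derived from one consensus protein carrying the planted domain motif, so
#' copies of a member share well over 95\% protein identity. A configurable
#' fraction of members additionally carries a tandem cluster (consecutive
#' copies within 10 Mb on one chromosome). Motif-free decoy genes are added
#' so domain screening has something to reject. Deterministic for a fixed
#' seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A list with elements \code{catalog} (a \linkS4class{NacCatalog}
#'   whose member table is still empty) and \code{truth} (a
#'   \linkS4class{TruthSet} with the member partition and tandem clusters).
#' @examples
#' sim <- simulateGenome(SimConfig(seed = 1, n_members = 4))
#' sim$catalog
#' @export
simulateGenome <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  validObject(config)
  chrlen <- config@chromosome_length
  if (chrlen < 1e6)
    stop("chromosome_length too small to place the requested genes")
  motif <- namMotifConsensus()

  withSeed(config@seed, {
    rows <- list()
    proteins <- character()
    cdss <- character()
    exon_list <- list()
    member_of <- integer()
    cluster_of <- character()
    gidx <- 0L

    newGene <- function(chrom, start, protein, member, cluster) {
      gidx <<- gidx + 1L
      id <- sprintf("SYNG%04d", gidx)
      strand <- sample(c("+", "-"), 1L)
      cds <- backTranslate(protein)
      ex <- buildGeneStructure(nchar(cds), as.integer(start), strand)
      if (max(IRanges::end(ex)) > chrlen)
        stop("chromosome_length too small to place the requested genes")
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = id, chrom = chrom,
        start = min(IRanges::start(ex)), end = max(IRanges::end(ex)),
        strand = strand, stringsAsFactors = FALSE)
      proteins[id] <<- protein
      cdss[id] <<- cds
      exon_list[[id]] <<- ex
      member_of[id] <<- member
      cluster_of[id] <<- cluster
      id
    }

    for (m in seq_len(config@n_members)) {
      grp <- sample(1:7, 1L)
      present <- runif(3) < config@subgenome_presence
      if (!any(present)) present[sample.int(3L, 1L)] <- TRUE
      subg <- c("A", "B", "D")[present]
      has_tandem <- runif(1) < config@tandem_fraction
      k <- if (has_tandem)
        sample(seq(config@tandem_cluster_size_range[1],
                   config@tandem_cluster_size_range[2]), 1L) else 1L
      tandem_sub <- if (has_tandem) sample(subg, 1L) else NA_character_

      L <- sample(250:350, 1L)
      mstart <- sample(5:(L - nchar(motif) - 5L), 1L)
      consensus <- randomProtein(L)
      substr(consensus, mstart, mstart + nchar(motif) - 1L) <- motif

      basefrac <- if (has_tandem) runif(1, 0.02, 0.25) else runif(1, 0.05, 0.7)
      for (s in subg) {
        chrom <- paste0(grp, s)
        n_here <- if (identical(s, tandem_sub)) k else 1L
        base <- basefrac * chrlen + rnorm(1, 0, 2e5)
        gaps <- if (n_here > 1L) runif(n_here - 1L, 5e5, 6e6) else numeric()
        span <- sum(gaps) + 1e5
        base <- max(1e4, min(base, chrlen - span))
        if (chrlen - span < 1e4)
          stop("chromosome_length too small to place the requested genes")
        starts <- round(base + cumsum(c(0, gaps)))
        clab <- if (n_here > 1L) sprintf("M%03d_%s", m, chrom) else NA_character_
        for (p in starts) {
          copy <- mutateProtein(consensus, 0.01, mstart,
                                mstart + nchar(motif) - 1L)
          newGene(chrom, p, copy, m, clab)
        }
      }
    }

    n_decoys <- round(config@decoy_fraction * gidx)
    for (d in seq_len(n_decoys)) {
      chrom <- sample(wheatChromosomes(), 1L)
      start <- round(runif(1, 1e4, chrlen * 0.9))
      newGene(chrom, start, randomProtein(sample(250:350, 1L)),
              NA_integer_, NA_character_)
    }

    tab <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
      seqnames = factor(tab$chrom, levels = wheatChromosomes()),
      ranges = IRanges::IRanges(tab$start, tab$end),
      strand = tab$strand)
    GenomeInfoDb::seqlengths(gr) <-
      setNames(rep(chrlen, 21L), wheatChromosomes())
    pc <- parseChromosome(tab$chrom)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = tab$gene_id,
      subgenome = pc$subgenome,
      group_number = pc$group,
      exons = IRanges::IRangesList(exon_list[tab$gene_id]))

    catalog <- new("NacCatalog",
                   genes = gr,
                   proteins = Biostrings::AAStringSet(proteins),
                   cds = Biostrings::DNAStringSet(cdss),
                   members = S4Vectors::DataFrame(gene_id = character(),
                                                  member = integer(),
                                                  name = character(),
                                                  cluster_id = character()))
    truth <- new("TruthSet",
                 member_of = member_of,
                 cluster_of = cluster_of,
                 trajectory_of = setNames(rep(NA_character_, gidx),
                                          names(member_of)),
                 causal_snps = data.frame(snp_id = character(),
                                          member = integer(),
                                          trait = character(),
                                          effect = numeric(),
                                          variance_explained = numeric()),
                 haplotype_of = list())
    list(catalog = catalog, truth = truth)
  })
}
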