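# Hand-built fixture objects used across test files.

# A NacCatalog from explicit gene rows. `genes` is a data.frame with
# gene_id, chrom, start, end, strand; exons defaults to one exon spanning
# the gene.
makeTestCatalog <- function(genes, proteins = NULL, cds = NULL,
                            exons = NULL) {
  pc <- saltNAC:::parseChromosome(genes$chrom)
  if (is.null(exons))
    exons <- lapply(seq_len(nrow(genes)), function(i)
      IRanges::IRanges(genes$start[i], genes$end[i]))
  names(exons) <- genes$gene_id
  gr <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = wheatChromosomes()),
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = genes$gene_id, subgenome = pc$subgenome,
    group_number = pc$group,
    exons = IRanges::IRangesList(exons[genes$gene_id]))
  if (is.null(proteins))
    proteins <- setNames(rep(namMotifConsensus(), nrow(genes)),
                         genes$gene_id)
  new("NacCatalog", genes = gr,
      proteins = Biostrings::AAStringSet(proteins),
      cds = if (is.null(cds)) Biostrings::DNAStringSet()
            else Biostrings::DNAStringSet(cds),
      members = S4Vectors::DataFrame(gene_id = character(),
                                     member = integer(),
                                     name = character(),
                                     cluster_id = character()))
}

# A GenotypePanel from an explicit call matrix (rows snp, cols accession).
makeTestPanel <- function(calls, chrom = "2D", pos = NULL,
                          ref = NULL, alt = NULL) {
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq(1000L, by = 100L, length.out = n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("s%02d", seq_len(n))
  snps <- GenomicRanges::GRanges(
    seqnames = rep(chrom, n), ranges = IRanges::IRanges(pos, width = 1L),
    snp_id = rownames(calls), ref = ref, alt = alt,
    display_id = sprintf("%04d[%s/%s]", pos %% 10000L, ref, alt))
  new("GenotypePanel", snps = snps, calls = calls)
}

# One moderately sized simulated study, built once per test run.
.studyCache <- new.env(parent = emptyenv())
sharedStudy <- function() {
  if (is.null(.studyCache$study)) {
    cfg <- SimConfig(seed = 42, n_members = 10,
                     causal_spec = data.frame(member = c(2L, 6L),
                                              trait = c("TRL", "RV"),
                                              variance_explained = 0.25))
    g <- simulateGenome(cfg)
    e <- simulateExpression(g$catalog, cfg, g$truth)
    p <- simulatePopulation(g$catalog, cfg, e$truth)
    .studyCache$study <- list(cfg = cfg, catalog = g$catalog, expr = e$expr,
                              panel = p$panel, pheno = p$pheno,
                              truth = p$truth)
  }
  .studyCache$study
}

# Independently coded oracles -------------------------------------------

# Benjamini-Hochberg by explicit sort-and-cummin.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  q[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(q, 1)
}

# Welch t statistic written out by hand.
welchStat <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# Two-sided permutation p-value for the Welch statistic.
permPValue <- function(x, y, B = 20000, seed = 99) {
  obs <- abs(welchStat(x, y))
  pool <- c(x, y)
  n <- length(x)
  hits <- withr::with_seed(seed, {
    sum(replicate(B, {
      i <- sample(length(pool), n)
      abs(welchStat(pool[i], pool[-i])) >= obs
    }))
  })
  (hits + 1) / (B + 1)
}

# Transitive closure of the pairwise <=gap relation by breadth-first
# search over the full adjacency matrix.
closureOracle <- function(pos, gap = 1e7) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= gap
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}
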