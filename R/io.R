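#' @include sim-population.R
NULL

#' Write and read study files
#'
#' Plain-text interchange for every stage: GFF3 + protein/CDS FASTA for the
#' annotated genome, TSV for expression and phenotypes, VCF v4.2 for
#' genotypes, JSON for the simulation truth labels. All writers are
#' deterministic so a fixed seed yields byte-identical files.
#'
#' @name study-io
NULL

#' @rdname study-io
#' @param catalog a \linkS4class{NacCatalog}.
#' @param path output file path.
#' @export
writeCatalogGff3 <- function(catalog, path) {
  gr <- geneRanges(catalog)
  feats <- list()
  for (i in seq_along(gr)) {
    g <- gr[i]
    gene <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                   IRanges::ranges(g),
                                   GenomicRanges::strand(g))
    gene$type <- "gene"; gene$ID <- g$gene_id
    ex <- GenomicRanges::GRanges(rep(GenomicRanges::seqnames(g),
                                     length(g$exons[[1]])),
                                 g$exons[[1]],
                                 rep(GenomicRanges::strand(g),
                                     length(g$exons[[1]])))
    ex$type <- "exon"
    ex$ID <- paste0(g$gene_id, ".e", seq_along(ex))
    ex$Parent <- g$gene_id
    feats[[i]] <- c(gene, ex)
  }
  all <- suppressWarnings(do.call(c, feats))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' @rdname study-io
#' @param gff3,protein_fasta,cds_fasta file paths written by the catalogue
#'   writers.
#' @export
readCatalogFiles <- function(gff3, protein_fasta, cds_fasta = NULL) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  parent <- as.character(unlist(exons$Parent))
  exl <- split(IRanges::ranges(exons), factor(parent, levels = genes$ID))
  pc <- parseChromosome(as.character(GenomicRanges::seqnames(genes)))
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::ranges(genes),
                                GenomicRanges::strand(genes))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = genes$ID, subgenome = pc$subgenome, group_number = pc$group,
    exons = methods::as(exl, "IRangesList"))
  prot <- Biostrings::readAAStringSet(protein_fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))
  cds <- if (!is.null(cds_fasta)) {
    x <- Biostrings::readDNAStringSet(cds_fasta)
    names(x) <- sub("\\s.*$", "", names(x))
    x
  } else Biostrings::DNAStringSet()
  new("NacCatalog", genes = out, proteins = prot, cds = cds,
      members = S4Vectors::DataFrame(gene_id = character(), member = integer(),
                                     name = character(), cluster_id = character()))
}

#' @rdname study-io
#' @param panel a \linkS4class{GenotypePanel}.
#' @export
writeGenotypesVcf <- function(panel, path) {
  snps <- snpRanges(panel)
  calls <- genotypeCalls(panel)
  chroms <- unique(as.character(GenomicRanges::seqnames(snps)))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##contig=<ID=", chroms, ">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(calls)), collapse = "\t"))
  body <- paste(as.character(GenomicRanges::seqnames(snps)),
                GenomicRanges::start(snps), snps$snp_id, snps$ref, snps$alt,
                ".", ".", ".", "GT",
                apply(calls, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname study-io
#' @export
readGenotypesVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(VariantAnnotation::alt(vcf), function(a)
    as.character(a)[1], character(1))
  ref <- as.character(VariantAnnotation::ref(vcf))
  pos <- GenomicRanges::start(rr)
  snps <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(rr)),
    ranges = IRanges::IRanges(pos, width = 1L),
    snp_id = names(rr), ref = ref, alt = alt,
    display_id = sprintf("%04d[%s/%s]", pos %% 10000L, ref, alt))
  calls <- VariantAnnotation::geno(vcf)$GT
  rownames(calls) <- names(rr)
  new("GenotypePanel", snps = snps, calls = calls)
}

#' @rdname study-io
#' @param expr a \linkS4class{SaltExpressionSet}.
#' @param assay assay to write ("fpkm" or "counts").
#' @export
writeExpressionTsv <- function(expr, path, assay = "fpkm") {
  m <- SummarizedExperiment::assay(expr, assay)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname study-io
#' @export
readExpressionTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  sm <- regmatches(colnames(m), regexec("^T(\\d+)_R(\\d+)$", colnames(m)))
  if (any(lengths(sm) != 3L))
    stop("sample names must look like T06_R2 (time then replicate)")
  time <- as.numeric(vapply(sm, `[`, character(1), 2L))
  repl <- as.integer(vapply(sm, `[`, character(1), 3L))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = m),
    colData = S4Vectors::DataFrame(sample = colnames(m), time = time,
                                   replicate = repl, row.names = colnames(m)))
  new("SaltExpressionSet", se)
}

#' @rdname study-io
#' @param pheno long-format phenotype data.frame.
#' @export
writePhenotypeTsv <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname study-io
#' @export
readPhenotypeTsv <- function(path) {
  df <- read.delim(path)
  need <- c("accession", "trait", "condition", "replicate", "plant", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname study-io
#' @param truth a \linkS4class{TruthSet}.
#' @export
writeTruthJson <- function(truth, path) {
  x <- list(member_of = as.list(memberOf(truth)),
            cluster_of = as.list(clusterOf(truth)),
            trajectory_of = as.list(trajectoryOf(truth)),
            causal_snps = causalSnps(truth),
            haplotype_of = lapply(haplotypeBlocks(truth), as.list))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname study-io
#' @export
readTruthJson <- function(path) {
  x <- jsonlite::read_json(path)
  toNamed <- function(l, fun) {
    v <- vapply(l, function(e) if (is.null(e)) fun(NA) else fun(e), fun(NA))
    names(v) <- names(l)
    v
  }
  cs <- if (length(x$causal_snps))
    do.call(rbind, lapply(x$causal_snps, function(r)
      data.frame(snp_id = r$snp_id, member = as.integer(r$member),
                 gene_id = r$gene_id, trait = r$trait,
                 effect = as.numeric(r$effect),
                 variance_explained = as.numeric(r$variance_explained))))
  else data.frame(snp_id = character(), member = integer(),
                  gene_id = character(), trait = character(),
                  effect = numeric(), variance_explained = numeric())
  new("TruthSet",
      member_of = toNamed(x$member_of, as.integer),
      cluster_of = toNamed(x$cluster_of, as.character),
      trajectory_of = toNamed(x$trajectory_of, as.character),
      causal_snps = cs,
      haplotype_of = lapply(x$haplotype_of, function(l)
        toNamed(l, as.integer)))
}

#' Simulate a complete study and write its files
#'
#' Runs [simulateGenome()], [simulateExpression()] and
#' [simulatePopulation()] under one configuration and writes the standard
#' file set: \code{genes.gff3}, \code{proteins.fasta}, \code{cds.fasta},
#' \code{fpkm.tsv}, \code{counts.tsv}, \code{genotypes.vcf},
#' \code{phenotypes.tsv}, \code{truth.json}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
writeSimulatedStudy <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- simulateGenome(config)
  e <- simulateExpression(g$catalog, config, g$truth)
  p <- simulatePopulation(g$catalog, config, e$truth)
  paths <- list(
    gff3 = file.path(dir, "genes.gff3"),
    proteins = file.path(dir, "proteins.fasta"),
    cds = file.path(dir, "cds.fasta"),
    fpkm = file.path(dir, "fpkm.tsv"),
    counts = file.path(dir, "counts.tsv"),
    vcf = file.path(dir, "genotypes.vcf"),
    pheno = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json"))
  writeCatalogGff3(g$catalog, paths$gff3)
  Biostrings::writeXStringSet(proteinSequences(g$catalog), paths$proteins)
  Biostrings::writeXStringSet(cdsSequences(g$catalog), paths$cds)
  writeExpressionTsv(e$expr, paths$fpkm, "fpkm")
  writeExpressionTsv(e$expr, paths$counts, "counts")
  writeGenotypesVcf(p$panel, paths$vcf)
  writePhenotypeTsv(p$pheno, paths$pheno)
  writeTruthJson(p$truth, paths$truth)
  invisible(list(catalog = g$catalog, expr = e$expr, panel = p$panel,
                 pheno = p$pheno, truth = p$truth, paths = paths))
}
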