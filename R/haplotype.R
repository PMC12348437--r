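#' @include association.R
NULL

#' SNPs in a gene's candidate region
#'
#' The region runs from 2000 bp upstream of the start codon to 500 bp
#' downstream of the stop codon (strand-aware) and covers the complete gene
#' body; SNPs are returned in 5' to 3' order along the gene.
#'
#' @param catalog a \linkS4class{NacCatalog}.
#' @param gene_id catalogue gene.
#' @param panel a \linkS4class{GenotypePanel}.
#' @return The subset of \code{snpRanges(panel)} in the region, ordered.
#' @export
geneRegionSnps <- function(catalog, gene_id, panel) {
  gr <- geneRanges(catalog)
  i <- match(gene_id, gr$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  strand <- as.character(GenomicRanges::strand(gr))[i]
  lo <- GenomicRanges::start(gr)[i]; hi <- GenomicRanges::end(gr)[i]
  win <- if (strand == "+") c(lo - 2000L, hi + 500L) else c(lo - 500L, hi + 2000L)
  snps <- snpRanges(panel)
  sel <- as.character(GenomicRanges::seqnames(snps)) ==
    as.character(GenomicRanges::seqnames(gr))[i] &
    GenomicRanges::start(snps) >= win[1] &
    GenomicRanges::start(snps) <= win[2]
  out <- snps[sel]
  out[order(GenomicRanges::start(out), decreasing = (strand == "-"))]
}

#' Build haplotypes over a gene region
#'
#' Accessions with any missing or heterozygous call in the region are
#' excluded (the panel is assumed inbred); the remaining accessions are
#' grouped by their allele string over the region SNPs, and groups are
#' labelled Hap1, Hap2, ... by descending frequency with allele-string
#' lexicographic order breaking ties.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param region_snps ordered SNP \code{GRanges} from [geneRegionSnps()].
#' @return list(haplotypes = data.frame(label, allele_string, n),
#'   assignments = named character (accession -> label),
#'   excluded = character vector of dropped accessions).
#' @export
buildHaplotypes <- function(panel, region_snps) {
  calls <- genotypeCalls(panel)[region_snps$snp_id, , drop = FALSE]
  clean <- apply(calls, 2L, function(x) all(x %in% c("0/0", "1/1")))
  excluded <- colnames(calls)[!clean]
  if (!any(clean)) {
    warning("all accessions excluded: no clean homozygous calls in region")
    return(list(haplotypes = data.frame(label = character(),
                                        allele_string = character(),
                                        n = integer()),
                assignments = character(), excluded = excluded))
  }
  calls <- calls[, clean, drop = FALSE]
  allele <- ifelse(calls == "0/0", region_snps$ref, region_snps$alt)
  strings <- apply(allele, 2L, paste, collapse = "")
  tab <- table(strings)
  ord <- order(-as.integer(tab), names(tab))
  labels <- setNames(paste0("Hap", seq_along(ord)), names(tab)[ord])
  list(haplotypes = data.frame(label = unname(labels),
                               allele_string = names(labels),
                               n = as.integer(tab[names(labels)]),
                               stringsAsFactors = FALSE),
       assignments = setNames(unname(labels[strings]), names(strings)),
       excluded = excluded)
}

#' Compare RSIR between the two major haplotypes
#'
#' Unequal-variance (Welch) t-test of the trait's RSIR between Hap1 and
#' Hap2 accessions, significant at p < \code{alpha} (default 0.01). The
#' direction field reports which haplotype has the lower injury rate, i.e.
#' the better salt tolerance.
#'
#' @param haps output of [buildHaplotypes()].
#' @param rsir output of [computeRSIR()].
#' @param trait one of [rootTraits()].
#' @param alpha significance level.
#' @return list(trait, n, group_means, t_statistic, df, p_value,
#'   significant, direction).
#' @export
haplotypePhenotypeTest <- function(haps, rsir, trait, alpha = 0.01) {
  a <- names(haps$assignments)[haps$assignments == "Hap1"]
  b <- names(haps$assignments)[haps$assignments == "Hap2"]
  y <- setNames(rsir$rsir[rsir$trait == trait],
                rsir$accession[rsir$trait == trait])
  ya <- y[intersect(a, names(y))]; yb <- y[intersect(b, names(y))]
  if (length(ya) < 2L || length(yb) < 2L)
    stop("each haplotype group needs at least 2 phenotyped accessions")
  w <- welchTest(ya, yb)
  list(trait = trait, n = c(Hap1 = length(ya), Hap2 = length(yb)),
       group_means = c(Hap1 = w$mean_a, Hap2 = w$mean_b),
       t_statistic = w$statistic, df = w$df, p_value = w$p.value,
       significant = w$p.value < alpha,
       direction = if (w$mean_b < w$mean_a) "Hap2 lower" else "Hap1 lower")
}

#' Compare trait distributions between two groups
#'
#' Welch t-test with the report-star convention: \code{***} for p < 0.001,
#' \code{****} for p < 0.0001. Used for mutant-versus-wild-type trait
#' comparisons.
#'
#' @param values_a,values_b numeric trait values (each n >= 2).
#' @return list(group_means, t_statistic, df, p_value, stars).
#' @export
compareGroups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 observations")
  w <- welchTest(values_a, values_b)
  list(group_means = c(a = w$mean_a, b = w$mean_b),
       t_statistic = w$statistic, df = w$df, p_value = w$p.value,
       stars = pStars(w$p.value))
}
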