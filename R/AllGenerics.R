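#' @include AllClasses.R
NULL

#' Accessors for catalogue and panel objects
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x a \linkS4class{NacCatalog}, \linkS4class{GenotypePanel} or
#'   \linkS4class{TruthSet}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))
#' @rdname accessors
#' @export
setGeneric("cdsSequences", function(x) standardGeneric("cdsSequences"))
#' @rdname accessors
#' @export
setGeneric("memberTable", function(x) standardGeneric("memberTable"))
#' @rdname accessors
#' @export
setGeneric("memberTable<-", function(x, value) standardGeneric("memberTable<-"))
#' @rdname accessors
#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))
#' @rdname accessors
#' @export
setGeneric("panelAccessions", function(x) standardGeneric("panelAccessions"))
#' @rdname accessors
#' @export
setGeneric("memberOf", function(x) standardGeneric("memberOf"))
#' @rdname accessors
#' @export
setGeneric("clusterOf", function(x) standardGeneric("clusterOf"))
#' @rdname accessors
#' @export
setGeneric("trajectoryOf", function(x) standardGeneric("trajectoryOf"))
#' @rdname accessors
#' @export
setGeneric("causalSnps", function(x) standardGeneric("causalSnps"))
#' @rdname accessors
#' @export
setGeneric("haplotypeBlocks", function(x) standardGeneric("haplotypeBlocks"))

setMethod("geneRanges", "NacCatalog", function(x) x@genes)
setMethod("proteinSequences", "NacCatalog", function(x) x@proteins)
setMethod("cdsSequences", "NacCatalog", function(x) x@cds)
setMethod("memberTable", "NacCatalog", function(x) x@members)
setMethod("memberTable<-", "NacCatalog", function(x, value) {
  x@members <- value
  validObject(x)
  x
})

setMethod("snpRanges", "GenotypePanel", function(x) x@snps)
setMethod("genotypeCalls", "GenotypePanel", function(x) x@calls)
setMethod("panelAccessions", "GenotypePanel", function(x) colnames(x@calls))
setMethod("dosageMatrix", "GenotypePanel", function(x) {
  d <- matrix(NA_real_, nrow(x@calls), ncol(x@calls),
              dimnames = dimnames(x@calls))
  d[x@calls == "0/0"] <- 0
  d[x@calls %in% c("0/1", "1/0")] <- 1
  d[x@calls == "1/1"] <- 2
  d
})

setMethod("memberOf", "TruthSet", function(x) x@member_of)
setMethod("clusterOf", "TruthSet", function(x) x@cluster_of)
setMethod("trajectoryOf", "TruthSet", function(x) x@trajectory_of)
setMethod("causalSnps", "TruthSet", function(x) x@causal_snps)
setMethod("haplotypeBlocks", "TruthSet", function(x) x@haplotype_of)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_members, "members,",
      object@n_accessions, "accessions, seed", object@seed, "\n")
  cat("  subgenome presence", object@subgenome_presence,
      "| tandem fraction", object@tandem_fraction,
      "| decoys", object@decoy_fraction, "\n")
  cat("  trajectory mix:",
      paste(names(object@trajectory_mix),
            signif(object@trajectory_mix, 3), sep = "=", collapse = " "), "\n")
  if (nrow(object@causal_spec))
    cat("  causal SNPs:", nrow(object@causal_spec), "planted\n")
})

setMethod("show", "NacCatalog", function(object) {
  cat("NacCatalog with", length(object@genes), "genes")
  if (nrow(object@members)) {
    mem <- object@members$member
    cat(",", length(unique(mem[!is.na(mem)])), "members")
  }
  cat("\n  chromosomes:",
      paste(sort(unique(as.character(GenomicRanges::seqnames(object@genes)))),
            collapse = " "), "\n")
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object@calls), "SNPs x",
      ncol(object@calls), "accessions\n")
  miss <- mean(object@calls == "./.")
  cat("  missing call rate:", signif(miss, 3), "\n")
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", length(object@member_of), "genes,",
      length(unique(object@member_of[!is.na(object@member_of)])), "members,",
      nrow(object@causal_snps), "causal SNPs\n")
})

setMethod("show", "KaspDesign", function(object) {
  cat("KASP design for", object@snp_id,
      sprintf("[%s/%s]\n", object@ref, object@alt))
  cat("  FAM :", object@fam_primer, "\n")
  cat("  HEX :", object@hex_primer, "\n")
  cat("  Rev :", object@common_reverse, "\n")
  cat("  product", object@product_length, "bp; Tm",
      paste(names(object@tm_estimates),
            sprintf("%.1f", object@tm_estimates), sep = "=", collapse = " "),
      "\n")
})
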