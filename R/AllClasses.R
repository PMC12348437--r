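#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings AAStringSet DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic study: a three-subgenome (AABBDD) genome with
#' homoeologous gene copies and tandem clusters, a salt-stress expression
#' time course (0/1/6/24/48 h after treatment, 3 replicates), and a panel of
#' inbred accessions genotyped over candidate-gene regions and phenotyped for
#' root traits under control (CK) and NaCl conditions.
#'
#' @slot seed integer; master seed for all randomness.
#' @slot n_members number of homoeolog members (gene families share one
#'   planted domain motif; each member is a homoeolog group).
#' @slot subgenome_presence probability a member has a copy in each of A/B/D
#'   (conditioned on at least one copy).
#' @slot tandem_fraction probability a member carries a tandem cluster.
#' @slot tandem_cluster_size_range integer range of tandem cluster sizes.
#' @slot chromosome_length length of each synthetic chromosome in bp.
#' @slot decoy_fraction fraction of extra genes lacking the domain motif.
#' @slot n_accessions panel size.
#' @slot snps_per_gene_region SNPs simulated per candidate-gene region.
#' @slot causal_spec data.frame with columns \code{member}, \code{trait},
#'   \code{variance_explained}; each row plants one causal SNP.
#' @slot trajectory_mix named proportions over Group1..Group4 and nonDE.
#' @slot replicate_cv coefficient of variation of FPKM replicates.
#' @slot plant_cv coefficient of variation of per-plant root traits.
#' @slot n_plants plants measured per accession and replicate.
#' @slot n_phenotype_reps phenotyping replicates.
#' @slot missing_rate genotype missingness rate injected into the VCF.
#' @slot het_rate heterozygosity rate (0 for a selfing panel).
#' @slot two_haplotype_members integer vector of members whose gene region is
#'   simulated as one tightly linked block yielding exactly two haplotypes;
#'   causal members are always included.
#' @seealso [SimConfig()]
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  n_members = "integer",
  subgenome_presence = "numeric",
  tandem_fraction = "numeric",
  tandem_cluster_size_range = "integer",
  chromosome_length = "numeric",
  decoy_fraction = "numeric",
  n_accessions = "integer",
  snps_per_gene_region = "integer",
  causal_spec = "data.frame",
  trajectory_mix = "numeric",
  replicate_cv = "numeric",
  plant_cv = "numeric",
  n_plants = "integer",
  n_phenotype_reps = "integer",
  missing_rate = "numeric",
  het_rate = "numeric",
  two_haplotype_members = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(n_members = object@n_members, n_accessions = object@n_accessions,
              snps_per_gene_region = object@snps_per_gene_region,
              n_plants = object@n_plants, n_phenotype_reps = object@n_phenotype_reps)
  if (any(counts < 1L))
    msg <- c(msg, paste("counts must be >= 1:",
                        paste(names(counts)[counts < 1L], collapse = ", ")))
  mix <- object@trajectory_mix
  lvl <- c("Group1", "Group2", "Group3", "Group4", "nonDE")
  if (!identical(sort(names(mix)), sort(lvl)))
    msg <- c(msg, "trajectory_mix must be named Group1..Group4, nonDE")
  else if (abs(sum(mix) - 1) > 1e-9)
    msg <- c(msg, "trajectory_mix proportions must sum to 1")
  if (any(mix < 0)) msg <- c(msg, "trajectory_mix proportions must be >= 0")
  for (p in c("subgenome_presence", "tandem_fraction", "decoy_fraction",
              "missing_rate", "het_rate")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, paste(p, "must be in [0,1]"))
  }
  r <- object@tandem_cluster_size_range
  if (length(r) != 2L || r[1] < 2L || r[2] < r[1])
    msg <- c(msg, "tandem_cluster_size_range must be c(lo, hi) with 2 <= lo <= hi")
  cs <- object@causal_spec
  if (nrow(cs)) {
    if (!all(c("member", "trait", "variance_explained") %in% names(cs)))
      msg <- c(msg, "causal_spec needs columns member, trait, variance_explained")
    else {
      if (any(cs$variance_explained < 0 | cs$variance_explained >= 1))
        msg <- c(msg, "variance_explained must be in [0,1)")
      if (any(cs$member < 1 | cs$member > object@n_members))
        msg <- c(msg, "causal_spec names nonexistent members")
      if (!all(cs$trait %in% rootTraits()))
        msg <- c(msg, "causal_spec traits must be among TRL, RSA, RV, RD, RTN, RBN")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth labels of a simulated study
#'
#' Oracle labels recorded by the simulators so downstream stages can be tested
#' for recovery: the member partition, tandem-cluster assignment, expression
#' trajectory archetypes, the planted causal SNPs, and the haplotype block
#' carried by each accession in two-haplotype regions.
#'
#' @export
setClass("TruthSet", representation(
  member_of = "integer",        # named by gene_id
  cluster_of = "character",     # named by gene_id; NA = not in a tandem cluster
  trajectory_of = "character",  # named by gene_id; Group1..Group4 or nonDE
  causal_snps = "data.frame",   # snp_id, member, trait, effect, variance_explained
  haplotype_of = "list"         # member -> named integer (accession -> block 1/2)
))

setValidity("TruthSet", function(object) {
  ids <- names(object@member_of)
  if (anyDuplicated(ids)) return("gene ids must appear exactly once in member_of")
  if (!identical(sort(ids), sort(names(object@cluster_of))))
    return("cluster_of must cover exactly the genes in member_of")
  TRUE
})

#' Catalogue of domain-positive genes
#'
#' The central container of the family catalogue: gene models as a
#' \linkS4class{GRanges} (with subgenome, homoeologous group and exon
#' structure in \code{mcols}), protein and CDS sequences, and the member
#' table produced by homoeolog grouping, tandem detection and naming.
#'
#' @slot genes GRanges of gene spans on chromosomes 1A..7D; mcols carry
#'   \code{gene_id}, \code{subgenome}, \code{group_number} and an
#'   \code{exons} IRangesList.
#' @slot proteins AAStringSet named by gene_id.
#' @slot cds DNAStringSet named by gene_id (may be empty).
#' @slot members DataFrame keyed by gene_id with \code{member}, \code{name},
#'   \code{cluster_id}, \code{expression_class} (filled in as stages run).
#' @export
setClass("NacCatalog", representation(
  genes = "GRanges",
  proteins = "AAStringSet",
  cds = "DNAStringSet",
  members = "DataFrame"
))

setValidity("NacCatalog", function(object) {
  ids <- object@genes$gene_id
  if (is.null(ids)) return("genes must carry a gene_id mcol")
  if (anyDuplicated(ids)) return("duplicate gene ids")
  if (!all(names(object@proteins) %in% ids))
    return("protein names must be catalogue gene ids")
  if (nrow(object@members) && !all(object@members$gene_id %in% ids))
    return("member table refers to unknown gene ids")
  TRUE
})

#' Salt-stress expression time course
#'
#' A \linkS4class{SummarizedExperiment} whose columns are time-point x
#' replicate samples of the NaCl time course and whose assays hold FPKM (and
#' optionally fragment counts). \code{colData} carries \code{time} (hours
#' after treatment) and \code{replicate}; \code{rowData} carries
#' \code{transcript_length_kb}.
#'
#' @export
setClass("SaltExpressionSet", contains = "SummarizedExperiment")

setValidity("SaltExpressionSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time", "replicate") %in% names(cd)))
    return("colData must have 'time' and 'replicate'")
  if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
    return("an 'fpkm' assay is required")
  fpkm <- SummarizedExperiment::assay(object, "fpkm")
  if (any(!is.finite(fpkm)) || any(fpkm < 0))
    return("fpkm must be finite and nonnegative")
  TRUE
})

#' Accession genotype panel
#'
#' Biallelic SNP calls for a panel of (largely inbred) accessions. SNP
#' coordinates, alleles and display identifiers live in a
#' \linkS4class{GRanges}; calls are a SNP x accession character matrix of
#' VCF-style genotypes ("0/0", "1/1", "0/1", "./.").
#'
#' @slot snps GRanges with mcols \code{snp_id}, \code{ref}, \code{alt},
#'   \code{display_id} and optionally \code{gene_id}.
#' @slot calls character matrix, rows = snp_id, columns = accessions.
#' @export
setClass("GenotypePanel", representation(
  snps = "GRanges",
  calls = "matrix"
))

setValidity("GenotypePanel", function(object) {
  if (length(object@snps) != nrow(object@calls))
    return("one call row per SNP required")
  if (!identical(object@snps$snp_id, rownames(object@calls)))
    return("call rownames must equal snp_id in order")
  bad <- !(object@calls %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(bad)) return("genotype calls must be 0/0, 0/1, 1/0, 1/1 or ./.")
  TRUE
})

#' KASP marker design
#'
#' Two tailed allele-specific forward primers (FAM tail for the reference
#' allele, HEX tail for the alternative) differing only at their 3'-terminal
#' base, plus a common reverse primer on the opposite strand.
#'
#' @export
setClass("KaspDesign", representation(
  snp_id = "character",
  ref = "character",
  alt = "character",
  fam_primer = "character",
  hex_primer = "character",
  common_reverse = "character",
  product_length = "integer",
  tm_estimates = "numeric"
))

setValidity("KaspDesign", function(object) {
  if (!startsWith(object@fam_primer, kaspTails()["FAM"]))
    return("FAM primer must start with the FAM tail")
  if (!startsWith(object@hex_primer, kaspTails()["HEX"]))
    return("HEX primer must start with the HEX tail")
  f <- sub(kaspTails()["FAM"], "", object@fam_primer, fixed = TRUE)
  h <- sub(kaspTails()["HEX"], "", object@hex_primer, fixed = TRUE)
  if (nchar(f) != nchar(h) ||
      substr(f, 1L, nchar(f) - 1L) != substr(h, 1L, nchar(h) - 1L))
    return("allele-specific parts must differ only at the 3' base")
  if (toupper(substring(f, nchar(f))) != toupper(object@ref) ||
      toupper(substring(h, nchar(h))) != toupper(object@alt))
    return("3'-terminal bases must be the ref (FAM) and alt (HEX) alleles")
  TRUE
})

#' Root traits measured on the panel
#'
#' TRL total root length (cm), RSA root surface area (cm^2), RV root volume
#' (cm^3), RD root diameter (mm), RTN root-tip number, RBN root-branching
#' number.
#' @return Character vector of the six trait codes.
#' @export
rootTraits <- function() c("TRL", "RSA", "RV", "RD", "RTN", "RBN")

#' KASP tail sequences
#'
#' The standard FAM and HEX universal tails prepended to the two
#' allele-specific forward primers.
#' @return Named character vector with elements \code{FAM} and \code{HEX}.
#' @export
kaspTails <- function() {
  c(FAM = "GAAGGTGACCAAGTTCATGCT", HEX = "GAAGGTCGGAGTCAACGGATT")
}
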