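#' @include AllClasses.R
NULL

#' Build a simulation configuration
#'
#' Defaults emulate the study design the package targets: a hexaploid genome
#' in which most homoeolog members keep two or three subgenome copies (about
#' 5\% remain single-copy), roughly 27\% of members carry a tandem cluster of
#' 2--9 genes, about a third of genes are salt-responsive with the largest
#' trajectory group showing successive upregulation, and a panel of 114
#' inbred accessions phenotyped on ten plants in three replicates.
#'
#' @param seed integer master seed.
#' @param n_members number of homoeolog members to simulate.
#' @param subgenome_presence per-subgenome copy probability.
#' @param tandem_fraction probability a member carries a tandem cluster.
#' @param tandem_cluster_size_range integer range of cluster sizes.
#' @param chromosome_length bp per synthetic chromosome.
#' @param decoy_fraction extra motif-free decoy genes, as a fraction of the
#'   domain-positive gene count.
#' @param n_accessions panel size.
#' @param snps_per_gene_region SNPs per candidate-gene region.
#' @param causal_spec data.frame(member, trait, variance_explained); one
#'   causal SNP is planted per row.
#' @param trajectory_mix named proportions over Group1..Group4 and nonDE.
#'   The default sends 78/446 of genes to Group 4, 22/446 to each of Groups
#'   1--3 and the remainder to nonDE.
#' @param replicate_cv,plant_cv coefficients of variation for FPKM replicates
#'   and per-plant root traits.
#' @param n_plants,n_phenotype_reps phenotyping design.
#' @param missing_rate,het_rate genotype missingness and heterozygosity.
#' @param two_haplotype_members members whose gene region is one linked block
#'   (two haplotypes); causal members are always added.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(seed = 1, n_members = 6)
#' cfg
#' @export
SimConfig <- function(seed = 1L,
                      n_members = 24L,
                      subgenome_presence = 0.85,
                      tandem_fraction = 32 / 118,
                      tandem_cluster_size_range = c(2L, 9L),
                      chromosome_length = 1.5e8,
                      decoy_fraction = 0.15,
                      n_accessions = 114L,
                      snps_per_gene_region = 8L,
                      causal_spec = data.frame(member = integer(),
                                               trait = character(),
                                               variance_explained = numeric()),
                      trajectory_mix = c(Group1 = 22 / 446, Group2 = 22 / 446,
                                         Group3 = 22 / 446, Group4 = 78 / 446,
                                         nonDE = 302 / 446),
                      replicate_cv = 0.1,
                      plant_cv = 0.2,
                      n_plants = 10L,
                      n_phenotype_reps = 3L,
                      missing_rate = 0.02,
                      het_rate = 0,
                      two_haplotype_members = integer()) {
  two_hap <- sort(unique(c(as.integer(two_haplotype_members),
                           as.integer(causal_spec$member))))
  new("SimConfig",
      seed = as.integer(seed),
      n_members = as.integer(n_members),
      subgenome_presence = subgenome_presence,
      tandem_fraction = tandem_fraction,
      tandem_cluster_size_range = as.integer(tandem_cluster_size_range),
      chromosome_length = as.numeric(chromosome_length),
      decoy_fraction = decoy_fraction,
      n_accessions = as.integer(n_accessions),
      snps_per_gene_region = as.integer(snps_per_gene_region),
      causal_spec = causal_spec,
      trajectory_mix = trajectory_mix,
      replicate_cv = replicate_cv,
      plant_cv = plant_cv,
      n_plants = as.integer(n_plants),
      n_phenotype_reps = as.integer(n_phenotype_reps),
      missing_rate = missing_rate,
      het_rate = het_rate,
      two_haplotype_members = two_hap)
}
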