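#' @include kasp.R
NULL

#' Select candidate genes
#'
#' A candidate is a gene in trajectory Group 4 (successive upregulation)
#' whose candidate region (start codon - 2000 bp to stop codon + 500 bp)
#' contains at least one significant, QC-passing SNP. Candidates are
#' ordered by member number; the evidence table lists every supporting
#' (SNP display id, trait, context) triple.
#'
#' @param catalog a named \linkS4class{NacCatalog}.
#' @param trajectories output of [classifyTrajectories()].
#' @param assoc combined association results over traits (rbind of
#'   [associateRSIR()] outputs).
#' @param panel the \linkS4class{GenotypePanel} scanned.
#' @param qc output of [qcSnps()].
#' @param neg_log10_threshold candidates use SNPs whose -log10 p strictly
#'   exceeds this (relaxing it can only add candidates).
#' @return list(candidates = data.frame(gene_id, name, member, group,
#'   n_snps), evidence = data.frame(gene_id, display_id, trait, context,
#'   coding_effect)).
#' @export
selectCandidates <- function(catalog, trajectories, assoc, panel, qc,
                             neg_log10_threshold = 4) {
  for (nm in c("trajectories", "assoc", "qc"))
    if (is.null(get(nm)) || !nrow(get(nm)))
      stop("candidate selection: missing upstream table '", nm, "'")
  mt <- memberTable(catalog)
  snps <- snpRanges(panel)
  pass <- qc$snp_id[qc$qc_pass]
  hits <- assoc[assoc$neg_log10_p > neg_log10_threshold &
                  assoc$snp_id %in% pass, , drop = FALSE]
  g4 <- trajectories$gene_id[!is.na(trajectories$group) &
                               trajectories$group == 4L]
  cand_rows <- list(); evid_rows <- list()
  for (g in intersect(g4, mt$gene_id)) {
    region <- geneRegionSnps(catalog, g, panel)
    sup <- hits[hits$snp_id %in% region$snp_id, , drop = FALSE]
    if (!nrow(sup)) next
    mrow <- mt[mt$gene_id == g, ]
    ev <- lapply(seq_len(nrow(sup)), function(k) {
      i <- match(sup$snp_id[k], snps$snp_id)
      ann <- annotateSnpContext(catalog, g, GenomicRanges::start(snps)[i],
                                alt = snps$alt[i])
      data.frame(gene_id = g, display_id = snps$display_id[i],
                 trait = sup$trait[k], context = ann$context,
                 coding_effect = ann$coding_effect,
                 neg_log10_p = sup$neg_log10_p[k],
                 stringsAsFactors = FALSE)
    })
    evid_rows[[g]] <- do.call(rbind, ev)
    cand_rows[[g]] <- data.frame(gene_id = g, name = mrow$name,
                                 member = mrow$member, group = 4L,
                                 n_snps = length(unique(sup$snp_id)),
                                 stringsAsFactors = FALSE)
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(gene_id = character(), name = character(), member = integer(),
               group = integer(), n_snps = integer())
  candidates <- candidates[order(candidates$member, candidates$gene_id), ]
  rownames(candidates) <- NULL
  evidence <- if (length(evid_rows)) do.call(rbind, evid_rows) else
    data.frame(gene_id = character(), display_id = character(),
               trait = character(), context = character(),
               coding_effect = character(), neg_log10_p = numeric())
  rownames(evidence) <- NULL
  list(candidates = candidates, evidence = evidence)
}

#' Load a pipeline configuration from YAML
#'
#' Reads simulation and threshold settings; unknown keys are rejected. Keys
#' mirror the [SimConfig()] arguments plus \code{n_pcs},
#' \code{neg_log10_threshold} and \code{identity_threshold}.
#'
#' @param path YAML file.
#' @return list(sim = \linkS4class{SimConfig}, n_pcs, neg_log10_threshold,
#'   identity_threshold).
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known_sim <- names(formals(SimConfig))
  known_top <- c("n_pcs", "neg_log10_threshold", "identity_threshold")
  extra <- setdiff(names(y), c(known_sim, known_top))
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  sim_args <- y[intersect(names(y), known_sim)]
  if (!is.null(sim_args$causal_spec))
    sim_args$causal_spec <- do.call(rbind, lapply(sim_args$causal_spec,
                                                  as.data.frame))
  if (!is.null(sim_args$trajectory_mix))
    sim_args$trajectory_mix <- unlist(sim_args$trajectory_mix)
  list(sim = do.call(SimConfig, sim_args),
       n_pcs = if (is.null(y$n_pcs)) 3L else as.integer(y$n_pcs),
       neg_log10_threshold = if (is.null(y$neg_log10_threshold)) 4
                             else y$neg_log10_threshold,
       identity_threshold = if (is.null(y$identity_threshold)) 0.9
                            else y$identity_threshold)
}

#' Run the whole screening pipeline on a simulated study
#'
#' simulate -> catalogue -> expression trajectories -> RSIR association ->
#' haplotypes and KASP -> candidate selection, writing per-stage TSV files
#' and a JSON manifest (seed, thresholds actually applied, per-stage row
#' counts) into \code{out_dir}. Idempotent: rerunning with the same
#' configuration rewrites identical files.
#'
#' @param config a \linkS4class{SimConfig} or the list returned by
#'   [readPipelineConfig()].
#' @param out_dir output directory.
#' @param write_inputs also write the simulated input files (GFF3, FASTA,
#'   VCF, TSV, truth JSON) under \code{out_dir/inputs}.
#' @return Invisibly, a list with all stage objects and the manifest.
#' @export
runPipeline <- function(config, out_dir, write_inputs = FALSE) {
  if (methods::is(config, "SimConfig"))
    config <- list(sim = config, n_pcs = 3L, neg_log10_threshold = 4,
                   identity_threshold = 0.9)
  sim <- config$sim
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  g <- simulateGenome(sim)
  e <- simulateExpression(g$catalog, sim, g$truth)
  p <- simulatePopulation(g$catalog, sim, e$truth)
  if (write_inputs)
    writeSimulatedStudy(sim, file.path(out_dir, "inputs"))

  catalog <- buildCatalog(g$catalog,
                          identity_threshold = config$identity_threshold)
  catalog <- classifyCatalogExpression(catalog, e$expr)
  mt <- memberTable(catalog)
  cat_df <- data.frame(gene_id = mt$gene_id, name = mt$name,
                       member = mt$member, cluster_id = mt$cluster_id,
                       expression_class = mt$expression_class)
  write.table(cat_df, file.path(out_dir, "catalog.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  de <- callDifferentialExpression(e$expr)
  traj <- classifyTrajectories(de)
  write.table(de, file.path(out_dir, "de_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(traj, file.path(out_dir, "trajectories.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  if (is.null(p$pheno) || !nrow(p$pheno))
    stop("associate stage failed: no phenotype table available")
  rsir <- computeRSIR(p$pheno)
  write.table(rsir, file.path(out_dir, "rsir.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  qc <- qcSnps(p$panel)
  assoc <- do.call(rbind, lapply(rootTraits(), function(tr)
    associateRSIR(p$panel, rsir, tr, n_pcs = config$n_pcs, qc = qc,
                  neg_log10_threshold = config$neg_log10_threshold)))
  write.table(assoc, file.path(out_dir, "association.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(manhattanTable(assoc, snpRanges(p$panel)),
              file.path(out_dir, "manhattan.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  sel <- selectCandidates(catalog, traj, assoc, p$panel, qc,
                          neg_log10_threshold = config$neg_log10_threshold)
  write.table(sel$candidates, file.path(out_dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sel$evidence, file.path(out_dir, "candidate_evidence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # haplotype + KASP report for the top candidate (if any)
  hap_report <- NULL
  if (nrow(sel$candidates)) {
    top <- sel$candidates$gene_id[1L]
    region <- geneRegionSnps(catalog, top, p$panel)
    haps <- buildHaplotypes(p$panel, region)
    tr <- sel$evidence$trait[sel$evidence$gene_id == top][1L]
    ht <- if (nrow(haps$haplotypes) >= 2L)
      haplotypePhenotypeTest(haps, rsir, tr) else NULL
    hap_df <- data.frame(accession = names(haps$assignments),
                         haplotype = unname(haps$assignments))
    write.table(hap_df, file.path(out_dir, "haplotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    top_snp <- sel$evidence$display_id[sel$evidence$gene_id == top][1L]
    i <- match(top_snp, snpRanges(p$panel)$display_id)
    kasp <- withSeed(sim@seed + 3L, {
      # synthetic flank: the real genomic context is not materialized by the
      # simulator, so a seeded flank with the reference base at the SNP
      # stands in for primer design in the demo report
      fl <- paste(sample(c("A", "C", "G", "T"), 161, replace = TRUE),
                  collapse = "")
      substr(fl, 81, 81) <- snpRanges(p$panel)$ref[i]
      designKasp(fl, 81, snpRanges(p$panel)$ref[i],
                 snpRanges(p$panel)$alt[i],
                 snp_id = snpRanges(p$panel)$snp_id[i])
    })
    hap_report <- list(gene = top, trait = tr, test = ht, kasp = kasp,
                       haplotypes = haps$haplotypes)
    jsonlite::write_json(
      list(gene = top, trait = tr,
           haplotypes = haps$haplotypes,
           p_value = if (!is.null(ht)) ht$p_value else NA,
           direction = if (!is.null(ht)) ht$direction else NA,
           kasp = list(snp_id = kasp@snp_id, fam = kasp@fam_primer,
                       hex = kasp@hex_primer, reverse = kasp@common_reverse,
                       product_length = kasp@product_length)),
      file.path(out_dir, "haplotype_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package = "saltNAC",
    version = as.character(utils::packageVersion("saltNAC")),
    seed = sim@seed,
    thresholds = list(
      domain_scan = ceiling(0.9 * nchar(namMotifConsensus())),
      identity_threshold = config$identity_threshold,
      tandem_gap_bp = 1e7,
      lfc_threshold = 1, fdr_threshold = 0.01,
      maf_min = 0.10, missing_max = 0.05,
      n_pcs = config$n_pcs,
      neg_log10_threshold = config$neg_log10_threshold,
      haplotype_alpha = 0.01),
    rows = list(genes = length(geneRanges(g$catalog)),
                catalogued = nrow(mt),
                members = length(unique(mt$member)),
                de_calls = nrow(de),
                salt_responsive = sum(traj$salt_responsive),
                snps = nrow(qc), snps_qc_pass = sum(qc$qc_pass),
                associations = nrow(assoc),
                significant = sum(assoc$significant),
                candidates = nrow(sel$candidates)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(catalog = catalog, expr = e$expr, panel = p$panel,
                 pheno = p$pheno, truth = p$truth, de = de, traj = traj,
                 rsir = rsir, qc = qc, assoc = assoc, selection = sel,
                 haplotype_report = hap_report, manifest = manifest))
}
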