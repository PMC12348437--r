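#' @include sim-genome.R
NULL

saltTimePoints <- function() c(0, 1, 6, 24, 48)

# Archetype log2 fold changes (vs 0 h, pseudocount scale) at 1/6/24/48 HAT.
# Group 1: downregulation; Group 2: early repression then steady rise;
# Group 3: transient upregulation at interior time points; Group 4:
# successive upregulation; nonDE: flat.
trajectoryArchetypes <- function() {
  list(Group1 = c(-1.5, -2.0, -2.5, -3.0),
       Group2 = c(-2.0, -0.5, 0.5, 1.5),
       Group3 = c(0.0, 2.0, 2.0, 0.0),
       Group4 = c(1.5, 2.0, 2.5, 3.0),
       nonDE = c(0, 0, 0, 0))
}

# Lognormal draws with exact mean `mu` and coefficient of variation `cv`.
rlnormCV <- function(n, mu, cv) {
  if (mu <= 0) return(rep(0, n))
  if (cv <= 0) return(rep(mu, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, log(mu) - sdlog^2 / 2, sdlog))
}

#' Simulate the salt-stress expression time course
#'
#' Assigns every family gene a trajectory archetype according to
#' \code{trajectory_mix} (decoy genes are always nonDE; genes of members
#' named in \code{causal_spec} are always Group 4, since the spiked
#' candidates must satisfy the downstream selection rule) and generates an FPKM
#' grid over 0/1/6/24/48 h after treatment with three replicates. Archetype
#' means are constructed on the pseudocount scale, i.e. the time-t mean
#' satisfies log2((mean_t + 1) / (mean_0 + 1)) = archetype value exactly, so
#' in the noise-free limit the downstream trajectory classifier recovers
#' every label. nonDE genes stay within |log2FC| < 1 in expectation.
#' Fragment counts consistent with the FPKM formula are generated from
#' per-sample library sizes.
#'
#' @param catalog a \linkS4class{NacCatalog} from [simulateGenome()].
#' @param config the \linkS4class{SimConfig}.
#' @param truth the \linkS4class{TruthSet} to fill in.
#' @return list(expr = \linkS4class{SaltExpressionSet}, truth = updated
#'   TruthSet).
#' @export
simulateExpression <- function(catalog, config, truth) {
  stopifnot(methods::is(config, "SimConfig"), methods::is(truth, "TruthSet"))
  withSeed(config@seed + 1L, {
    ids <- geneRanges(catalog)$gene_id
    fam <- ids[!is.na(memberOf(truth)[ids])]
    arch <- trajectoryArchetypes()
    mix <- config@trajectory_mix

    traj <- setNames(rep("nonDE", length(ids)), ids)
    traj[fam] <- sample(names(mix), length(fam), replace = TRUE, prob = mix)
    # genes of causal members carry the successive-upregulation archetype:
    # the spiked candidates must satisfy the Group-4 selection rule
    if (nrow(config@causal_spec)) {
      causal_genes <- fam[memberOf(truth)[fam] %in% config@causal_spec$member]
      traj[causal_genes] <- "Group4"
    }

    # Baseline (0 h) FPKM. DE genes get baselines >= 7 so even the deepest
    # repression archetype keeps all means nonnegative on the pseudocount
    # scale; nonDE genes span the expressed / low / silent classes.
    base <- numeric(length(ids))
    names(base) <- ids
    de <- traj != "nonDE"
    base[de] <- 8 + rlnormCV(sum(de), 15, 0.6)
    cls <- sample(c("none", "low", "normal"), sum(!de),
                  replace = TRUE, prob = c(0.35, 0.35, 0.30))
    base[!de][cls == "low"] <- runif(sum(cls == "low"), 0.05, 0.95)
    base[!de][cls == "normal"] <- 1 + rlnormCV(sum(cls == "normal"), 10, 0.8)

    tp <- saltTimePoints()
    nrep <- 3L
    samples <- paste0("T", sprintf("%02d", rep(tp, each = nrep)),
                      "_R", rep(seq_len(nrep), length(tp)))
    fpkm <- matrix(0, length(ids), length(samples),
                   dimnames = list(ids, samples))
    for (g in seq_along(ids)) {
      a <- arch[[traj[g]]]
      means <- c(base[g], pmax((base[g] + 1) * 2^a - 1, 0))
      for (t in seq_along(tp)) {
        cols <- (t - 1L) * nrep + seq_len(nrep)
        fpkm[g, cols] <- rlnormCV(nrep, means[t], config@replicate_cv)
      }
    }

    length_kb <- setNames(Biostrings::width(cdsSequences(catalog)[ids]) / 1000,
                          ids)
    mapped <- setNames(runif(length(samples), 20, 40), samples)
    counts <- round(sweep(fpkm * length_kb, 2L, mapped, `*`))

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(fpkm = fpkm, counts = counts),
      rowData = S4Vectors::DataFrame(gene_id = ids,
                                     transcript_length_kb = length_kb),
      colData = S4Vectors::DataFrame(sample = samples,
                                     time = rep(tp, each = nrep),
                                     replicate = rep(seq_len(nrep), length(tp)),
                                     mapped_millions = mapped,
                                     row.names = samples))
    truth@trajectory_of[ids] <- traj
    list(expr = new("SaltExpressionSet", se), truth = truth)
  })
}
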