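#' @include catalog.R
NULL

#' Fragments per kilobase per million mapped fragments
#'
#' FPKM = fragments / (mapped fragments in millions x transcript length in
#' kb); linear in fragments, inversely proportional to each denominator
#' term.
#'
#' @param fragments fragment count mapped to the transcript.
#' @param mapped_millions total mapped fragments, in millions.
#' @param length_kb transcript length in kilobases.
#' @return FPKM value(s).
#' @examples
#' computeFPKM(50, 2, 2.5)  # 10
#' @export
computeFPKM <- function(fragments, mapped_millions, length_kb) {
  if (any(mapped_millions <= 0) || any(length_kb <= 0))
    stop("mapped_millions and length_kb must be positive")
  if (any(fragments < 0)) stop("fragments must be nonnegative")
  fragments / (mapped_millions * length_kb)
}

deVerdict <- function(log2fc, fdr, lfc_threshold = 1, fdr_threshold = 0.01) {
  ifelse(fdr <= fdr_threshold & log2fc >= lfc_threshold, "up",
         ifelse(fdr <= fdr_threshold & log2fc <= -lfc_threshold, "down", "ns"))
}

#' Call differential expression against the 0 h control
#'
#' For every gene and treated time point: log2 fold change of mean FPKM with
#' a pseudocount of 1, a two-sample unequal-variance (Welch) test on
#' log2(FPKM + 1) replicate values, Benjamini--Hochberg FDR across genes
#' within each time point, and a verdict of \code{up}/\code{down}/\code{ns}
#' at |log2FC| >= 1 and FDR <= 0.01. When both replicate groups have zero
#' variance the p-value is 1 for equal means and 0 otherwise.
#'
#' @param expr a \linkS4class{SaltExpressionSet}.
#' @param pseudocount added to both means before the ratio.
#' @param lfc_threshold,fdr_threshold verdict thresholds.
#' @return data.frame(gene_id, time, log2fc, p_value, fdr, verdict).
#' @export
callDifferentialExpression <- function(expr, pseudocount = 1,
                                       lfc_threshold = 1,
                                       fdr_threshold = 0.01) {
  fpkm <- SummarizedExperiment::assay(expr, "fpkm")
  cd <- SummarizedExperiment::colData(expr)
  t0 <- cd$time == 0
  if (sum(t0) < 2L) stop("at least 2 replicates required at 0 h")
  times <- sort(unique(cd$time[!t0]))
  out <- list()
  for (tt in times) {
    ti <- cd$time == tt
    if (sum(ti) < 2L) stop("at least 2 replicates required at ", tt, " h")
    m0 <- rowMeans(fpkm[, t0, drop = FALSE])
    mt <- rowMeans(fpkm[, ti, drop = FALSE])
    log2fc <- log2((mt + pseudocount) / (m0 + pseudocount))
    l0 <- log2(fpkm[, t0, drop = FALSE] + 1)
    lt <- log2(fpkm[, ti, drop = FALSE] + 1)
    p <- vapply(seq_len(nrow(fpkm)), function(g)
      welchTest(lt[g, ], l0[g, ])$p.value, numeric(1))
    fdr <- p.adjust(p, method = "BH")
    out[[as.character(tt)]] <- data.frame(
      gene_id = rownames(fpkm), time = tt, log2fc = log2fc, p_value = p,
      fdr = fdr,
      verdict = deVerdict(log2fc, fdr, lfc_threshold, fdr_threshold),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ingest a precomputed differential-expression table
#'
#' Alternate input path for users with external DE output (e.g. a
#' negative-binomial pipeline): takes per-gene, per-time log2 fold changes
#' and FDR values and derives verdicts under the package thresholds.
#'
#' @param df data.frame with columns gene_id, time, log2fc, fdr.
#' @param lfc_threshold,fdr_threshold verdict thresholds.
#' @return data.frame in the [callDifferentialExpression()] layout
#'   (p_value NA).
#' @export
ingestDETable <- function(df, lfc_threshold = 1, fdr_threshold = 0.01) {
  need <- c("gene_id", "time", "log2fc", "fdr")
  if (!all(need %in% names(df)))
    stop("DE table needs columns: ", paste(need, collapse = ", "))
  data.frame(gene_id = df$gene_id, time = df$time, log2fc = df$log2fc,
             p_value = NA_real_, fdr = df$fdr,
             verdict = deVerdict(df$log2fc, df$fdr, lfc_threshold,
                                 fdr_threshold),
             stringsAsFactors = FALSE)
}

#' Flag salt-responsive genes
#'
#' A gene is salt-responsive when it is differentially expressed (verdict
#' not \code{ns}, either direction) at two or more treated time points.
#'
#' @param verdicts character vector of verdicts over the treated time
#'   points of one gene.
#' @return logical flag.
#' @export
selectSaltResponsive <- function(verdicts) {
  sum(verdicts != "ns") >= 2L
}

#' Assign a salt-responsive gene to a trajectory group
#'
#' Rules over the four treated time points (1, 6, 24, 48 HAT), evaluated in
#' order: Group 2 when the 1 h verdict is \code{down} and log2FC never
#' decreases thereafter (early repression, then recovery/rise); else Group 1
#' when no time point is upregulated (downregulation trend); else Group 4
#' when no time point is downregulated and both 24 and 48 HAT are
#' upregulated (successive upregulation); else Group 3 (transient or
#' specific upregulation).
#'
#' @param log2fc,verdicts vectors ordered by time 1, 6, 24, 48 HAT.
#' @return integer group 1--4.
#' @export
assignTrajectoryGroup <- function(log2fc, verdicts) {
  if (length(log2fc) != 4L || length(verdicts) != 4L)
    stop("expected values for the four treated time points")
  if (!selectSaltResponsive(verdicts))
    stop("trajectory groups are defined only for salt-responsive genes")
  if (verdicts[1] == "down" && all(diff(log2fc) >= 0)) return(2L)
  if (!any(verdicts == "up")) return(1L)
  if (!any(verdicts == "down") && verdicts[3] == "up" && verdicts[4] == "up")
    return(4L)
  3L
}

#' Classify all genes into trajectory groups
#'
#' @param de_calls output of [callDifferentialExpression()] (or
#'   [ingestDETable()]).
#' @return data.frame(gene_id, salt_responsive, group) with \code{group} NA
#'   for non-responsive genes.
#' @export
classifyTrajectories <- function(de_calls) {
  de_calls <- de_calls[order(de_calls$gene_id, de_calls$time), ]
  split_by <- split(de_calls, de_calls$gene_id)
  rows <- lapply(split_by, function(d) {
    resp <- selectSaltResponsive(d$verdict)
    data.frame(gene_id = d$gene_id[1], salt_responsive = resp,
               group = if (resp) assignTrajectoryGroup(d$log2fc, d$verdict)
                       else NA_integer_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Relative expression from qPCR cycle thresholds
#'
#' The 2^-dCT statistic with dCT = CT(target) - CT(reference).
#'
#' @param ct_target,ct_reference cycle-threshold values.
#' @return relative expression, vectorized.
#' @examples
#' qpcrRelativeExpression(25, 20)  # 2^-5
#' @export
qpcrRelativeExpression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("CT values must be finite")
  2^(-(ct_target - ct_reference))
}
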