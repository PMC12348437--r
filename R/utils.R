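#' @import methods
#' @importFrom stats p.adjust prcomp pt rnorm runif rbinom sd var complete.cases setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Round half away from zero to `digits` decimal places. summarizeCatalog()
# reports percentages at 2 dp with half-up rounding, which base round() (banker's)
# does not guarantee.
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporarily seeded RNG, restoring global RNG state.
# All simulator randomness flows through this so no function leaks global state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Welch two-sample t-test that tolerates zero-variance groups: with no
# variability on either side the p-value is 1 for equal means and 0 otherwise
# (the test statistic is degenerate, the conclusion is not).
welchTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(statistic = if (p == 1) 0 else Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p.value = p,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

# Parse "2D" style chromosome labels into homoeologous group and subgenome.
parseChromosome <- function(chrom) {
  ok <- grepl("^[1-7][ABD]$", chrom)
  if (!all(ok))
    stop("malformed chromosome label(s): ", paste(unique(chrom[!ok]), collapse = ", "))
  list(group = as.integer(substr(chrom, 1L, 1L)),
       subgenome = substr(chrom, 2L, 2L))
}

#' Chromosome labels of the hexaploid genome
#'
#' The 21 chromosome names \code{1A..7D} in homoeologous-group order with
#' subgenomes ordered A < B < D within a group.
#'
#' @return Character vector of length 21.
#' @export
wheatChromosomes <- function() {
  as.vector(t(outer(1:7, c("A", "B", "D"), paste0)))
}

# Significance stars used in mutant/haplotype group reports.
pStars <- function(p) {
  ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***", "ns"))
}
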