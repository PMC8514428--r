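#' Poisson replicate simulation for confidence intervals
#'
#' Generates `nReps` in-silico studies: for every (gene, category) cell a
#' replicate mutated count is drawn from a Poisson law whose mean is the
#' observed numerator m_gh (so the sequencing counts, not the much larger
#' epidemiological counts, carry the sampling noise; the incidence shares
#' are held fixed). Each replicate count is converted to a proportion
#' against the fixed denominator n_h, clipped at 1, and the replicate
#' matrix is pushed through the same weighting as the point estimate.
#'
#' @param C a [ConditionalMatrix-class].
#' @param sPrime normalized [IncidenceVector-class] aligned with `C`.
#' @param nReps number of replicates (default 2000; at least 2).
#' @param seed mandatory seed — reproducibility is part of the contract;
#'   the same seed gives a bit-identical replicate set.
#' @param keepCounts retain the replicate count array in the result?
#' @return A [ReplicateSet-class].
#' @export
simulateReplicates <- function(C, sPrime, nReps = 2000L, seed,
                               keepCounts = TRUE) {
  stopifnot(is(C, "ConditionalMatrix"), is(sPrime, "IncidenceVector"))
  if (missing(seed) || is.null(seed))
    stopf("a seed is required for the replicate simulation")
  nReps <- as.integer(nReps)
  if (is.na(nReps) || nReps < 2L) stopf("nReps must be at least 2")
  if (!isNormalized(sPrime)) stopf("sPrime must be normalized")
  v <- incidenceValues(sPrime)
  if (!identical(colnames(C), names(v)))
    stopf("category lists of C and S' are misaligned")
  m <- mutatedCounts(C)
  n <- sampleCounts(C)
  nG <- nrow(m); nH <- ncol(m)
  counts <- withSeed(seed,
    stats::rpois(nG * nH * nReps, lambda = rep(as.numeric(m),
                                               times = nReps)))
  arr <- array(counts, dim = c(nG, nH, nReps),
               dimnames = list(rownames(m), colnames(m), NULL))
  props <- pmin(arr / as.numeric(rep(n, each = nG)), 1)
  flat <- matrix(aperm(props, c(1L, 3L, 2L)), nrow = nG * nReps, ncol = nH)
  g <- matrix(flat %*% v, nrow = nG, ncol = nReps,
              dimnames = list(rownames(m), NULL))
  new("ReplicateSet", gValues = g,
      counts = if (keepCounts) arr else array(integer(0), c(0, 0, 0)),
      nReps = nReps, seed = as.integer(seed))
}

#' Percentile confidence intervals from replicates
#'
#' Per gene, the interval between the (1-level)/2 and 1-(1-level)/2
#' quantiles of the replicate weighted proportions, with linear
#' interpolation ([stats::quantile()] type 7). `level = 1` gives the
#' replicate range.
#'
#' @param replicates a [ReplicateSet-class].
#' @param level confidence level in (0, 1] (default 0.95).
#' @return data.frame with columns `gene`, `ci_low`, `ci_high`.
#' @export
percentileCI <- function(replicates, level = 0.95) {
  stopifnot(is(replicates, "ReplicateSet"), level > 0, level <= 1)
  a <- (1 - level) / 2
  g <- replicateValues(replicates)
  q <- t(apply(g, 1L, stats::quantile, probs = c(a, 1 - a),
               names = FALSE, type = 7))
  data.frame(gene = rownames(g), ci_low = q[, 1], ci_high = q[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted proportions with Poisson-replicate confidence intervals
#'
#' Convenience wrapper: computes the point estimate with
#' [weightedProportions()] and attaches percentile intervals from
#' [simulateReplicates()].
#'
#' @inheritParams simulateReplicates
#' @param level confidence level (default 0.95).
#' @return A [ProportionEstimate-class] with `ci_low`/`ci_high` filled.
#' @export
estimateWithCI <- function(C, sPrime, nReps = 2000L, seed, level = 0.95) {
  est <- weightedProportions(C, sPrime)
  reps <- simulateReplicates(C, sPrime, nReps = nReps, seed = seed,
                             keepCounts = FALSE)
  ci <- percentileCI(reps, level = level)
  stopifnot(identical(ci$gene, est@estimates$gene))
  est@estimates$ci_low <- pmin(ci$ci_low, est@estimates$proportion)
  est@estimates$ci_high <- pmax(ci$ci_high, est@estimates$proportion)
  validObject(est)
  est
}
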