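#' Incidence-weighted mutation proportions G = C %*% S'
#'
#' The core estimator: for each gene g the population-level mutation
#' proportion is the incidence-weighted average of the per-category mutated
#' fractions, G_g = sum_h c_gh * s'_h. The category lists of `C` and `S'`
#' must be identical and identically ordered — misalignment is an error,
#' never silently reindexed.
#'
#' @param C a [ConditionalMatrix-class].
#' @param sPrime a normalized [IncidenceVector-class] over exactly the
#'   categories (columns) of `C`.
#' @return A [ProportionEstimate-class] carrying the point estimates and
#'   the per-category contribution shares c_gh * s'_h / G_g.
#' @export
weightedProportions <- function(C, sPrime) {
  stopifnot(is(C, "ConditionalMatrix"), is(sPrime, "IncidenceVector"))
  if (!isNormalized(sPrime))
    stopf("sPrime must be normalized (use restrictAndNormalize)")
  v <- incidenceValues(sPrime)
  if (!identical(colnames(C), names(v)))
    stopf("category lists of C and S' are misaligned; no silent reindexing is performed")
  cc <- condProb(C)
  G <- as.numeric(cc %*% v)
  contrib <- sweep(cc, 2L, v, "*")
  shares <- contrib / ifelse(G > 0, G, NA_real_)
  shares[G == 0, ] <- NA_real_
  est <- data.frame(gene = rownames(cc), proportion = G,
                    ci_low = NA_real_, ci_high = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  new("ProportionEstimate", estimates = est, contributions = shares,
      weights = v)
}

#' Patient-level union proportion for a gene set
#'
#' The proportion of cancers with a qualifying mutation in ANY gene of a
#' set (for example KRAS, NRAS or HRAS). Because genes co-mutate, the union
#' cannot be computed from the conditional matrix; it needs the patient
#' sets, so this takes the cohort: per category
#' u_h = |patients mutated in any listed gene| / n_h, then the usual
#' weighting sum_h u_h * s'_h.
#'
#' @param cohort a [MutationCohort-class].
#' @param genes nonempty character vector of canonical gene symbols.
#' @param sPrime normalized [IncidenceVector-class]; its categories must be
#'   a subset of the cohort's.
#' @param nReps,seed,level optional: when both `nReps` and `seed` are
#'   given, a Poisson-replicate confidence interval is attached by
#'   perturbing the per-category union counts.
#' @return A single-row [ProportionEstimate-class] labelled with the genes
#'   joined by `"|"`.
#' @export
unionProportion <- function(cohort, genes, sPrime, nReps = NULL,
                            seed = NULL, level = 0.95) {
  stopifnot(is(cohort, "MutationCohort"), is(sPrime, "IncidenceVector"))
  if (!length(genes)) stopf("the gene set must be nonempty")
  if (!isNormalized(sPrime)) stopf("sPrime must be normalized")
  v <- incidenceValues(sPrime)
  n <- sampleCounts(cohort)
  missing <- setdiff(names(v), names(n))
  if (length(missing))
    stopf("cohort lacks categories: %s", paste(missing, collapse = ", "))
  mu <- cohort@mutated[cohort@mutated$gene %in% genes, , drop = FALSE]
  u_count <- vapply(names(v), function(h)
    length(unique(mu$patient_id[mu$category_id == h])), integer(1))
  u <- u_count / n[names(v)]
  G <- sum(u * v)
  label <- paste(genes, collapse = "|")
  contrib <- matrix(u * v / ifelse(G > 0, G, NA_real_), nrow = 1,
                    dimnames = list(label, names(v)))
  ci <- c(NA_real_, NA_real_)
  if (!is.null(nReps) && !is.null(seed)) {
    reps <- withSeed(seed, {
      cnt <- matrix(stats::rpois(length(v) * nReps,
                                 rep(u_count, times = nReps)),
                    nrow = length(v))
      colSums(pmin(cnt / n[names(v)], 1) * v)
    })
    a <- (1 - level) / 2
    ci <- stats::quantile(reps, probs = c(a, 1 - a), names = FALSE,
                          type = 7)
  }
  est <- data.frame(gene = label, proportion = G, ci_low = ci[1],
                    ci_high = ci[2], stringsAsFactors = FALSE)
  new("ProportionEstimate", estimates = est, contributions = contrib,
      weights = v)
}

#' Subclass-restricted weighted estimates
#'
#' Runs the weighted analysis limited to the categories of one
#' histological subclass (pan-adenocarcinoma, pan-SCC, ...): the subclass
#' incidence vector is restricted to sequenced subclass categories,
#' renormalized, and dotted with the matching columns of C.
#'
#' @param C a [ConditionalMatrix-class].
#' @param S the full (raw or normalized) [IncidenceVector-class].
#' @param tag a subclass tag (see [subclassCategories()]).
#' @param map the [CategoryMap-class] carrying the tags.
#' @return A [ProportionEstimate-class] over the subclass categories.
#'   A subclass with no sequenced representative is an error.
#' @export
subclassEstimates <- function(C, S, tag, map) {
  stopifnot(is(C, "ConditionalMatrix"))
  sub <- subclassVector(S, tag, map)
  keep <- intersect(names(incidenceValues(sub)), colnames(C))
  if (!length(keep))
    stopf("subclass '%s' has no sequenced categories", tag)
  weightedProportions(C[, sort(keep)], restrictAndNormalize(sub, keep))
}

#' Contribution breakdown of a gene's weighted proportion
#'
#' Decomposes G_g into per-category shares w_gh = c_gh * s'_h / G_g — which
#' cancer types account for the gene's mutated cases — sorted descending,
#' ties broken by category id. A gene with G_g = 0 yields an empty table.
#'
#' @param x a [ProportionEstimate-class], or a [ConditionalMatrix-class]
#'   together with `sPrime`.
#' @param gene the gene symbol (or union label).
#' @param ... passed between methods; the ConditionalMatrix method takes
#'   `sPrime`, a normalized [IncidenceVector-class].
#' @return data.frame with columns `category_id`, `share`.
#' @export
setGeneric("contributionBreakdown",
           function(x, gene, ...) standardGeneric("contributionBreakdown"))

#' @rdname contributionBreakdown
#' @export
setMethod("contributionBreakdown", "ProportionEstimate",
          function(x, gene, ...) {
  if (!gene %in% rownames(x@contributions))
    stopf("gene '%s' is not in the estimate", gene)
  w <- stats::setNames(as.numeric(x@contributions[gene, ]),
                       colnames(x@contributions))
  if (all(is.na(w)))
    return(data.frame(category_id = character(0), share = numeric(0)))
  o <- order(-w, names(w))
  data.frame(category_id = names(w)[o], share = as.numeric(w[o]),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname contributionBreakdown
#' @param sPrime normalized [IncidenceVector-class] aligned with `x`.
#' @export
setMethod("contributionBreakdown", "ConditionalMatrix",
          function(x, gene, sPrime, ...) {
  contributionBreakdown(weightedProportions(x, sPrime), gene)
})

#' Compare pooled (unweighted) with incidence-weighted proportions
#'
#' The pooled frequency ignores epidemiology: pooled_g =
#' sum_h m_gh / sum_h n_h, the fraction of all sequenced patients mutated.
#' When cohort sizes are not proportional to incidence, pooled and
#' weighted values diverge — oversampled cancers drag the pooled value
#' toward their own mutation rates.
#'
#' @param C a [ConditionalMatrix-class].
#' @param sPrime normalized [IncidenceVector-class] aligned with `C`.
#' @return data.frame with columns `gene`, `pooled`, `weighted`,
#'   `difference` (pooled minus weighted).
#' @export
compareUnweighted <- function(C, sPrime) {
  stopifnot(is(C, "ConditionalMatrix"))
  m <- mutatedCounts(C)
  n <- sampleCounts(C)
  pooled <- rowSums(m) / sum(n)
  weighted <- proportionTable(weightedProportions(C, sPrime))$proportion
  data.frame(gene = rownames(m), pooled = as.numeric(pooled),
             weighted = weighted,
             difference = as.numeric(pooled) - weighted,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ranked view of the estimates for a gene set
#'
#' Restricts the estimates to a gene list (genes absent from the data are
#' reported with proportion 0, not dropped), sorts descending with ties
#' broken by symbol, and truncates to the top `topN`.
#'
#' @param estimate a [ProportionEstimate-class].
#' @param geneList character vector of gene symbols.
#' @param topN number of rows to keep (default all).
#' @return data.frame with columns `gene`, `proportion`, `ci_low`,
#'   `ci_high`.
#' @export
geneSetView <- function(estimate, geneList, topN = Inf) {
  stopifnot(is(estimate, "ProportionEstimate"))
  e <- proportionTable(estimate)
  hit <- match(geneList, e$gene)
  out <- data.frame(gene = geneList,
                    proportion = ifelse(is.na(hit), 0, e$proportion[hit]),
                    ci_low = e$ci_low[hit], ci_high = e$ci_high[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$proportion, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = topN)
}

#' Bar chart of the top weighted proportions
#'
#' @param estimate a [ProportionEstimate-class].
#' @param topN number of genes to draw (default 25).
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plotTopGenes <- function(estimate, topN = 25, ...) {
  e <- proportionTable(estimate)
  e <- utils::head(e[order(-e$proportion, e$gene), ], topN)
  graphics::barplot(100 * rev(e$proportion), names.arg = rev(e$gene),
                    horiz = TRUE, las = 1,
                    xlab = "mutation proportion (%)", ...)
}

#' Write estimates, contributions and comparison tables
#'
#' @param estimate a [ProportionEstimate-class].
#' @param path output TSV path (`gene`, `proportion`, `ci_low`,
#'   `ci_high`).
#' @return `path`, invisibly.
#' @export
writeEstimates <- function(estimate, path) {
  writeTsv(proportionTable(estimate), path)
}

#' @rdname writeEstimates
#' @export
writeContributions <- function(estimate, path) {
  stopifnot(is(estimate, "ProportionEstimate"))
  cb <- estimate@contributions
  out <- data.frame(gene = rep(rownames(cb), times = ncol(cb)),
                    category_id = rep(colnames(cb), each = nrow(cb)),
                    share = as.numeric(cb))
  out <- out[!is.na(out$share) & out$share > 0, , drop = FALSE]
  out <- out[order(out$gene, -out$share, out$category_id), , drop = FALSE]
  writeTsv(out, path)
}
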