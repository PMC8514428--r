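# generics and accessor/show methods for the core classes

#' Category universe of an object
#'
#' @param x a [CategoryMap-class], [IncidenceTable-class],
#'   [IncidenceVector-class], [MutationCohort-class] or
#'   [ConditionalMatrix-class].
#' @return Character vector of category ids (lexicographic order).
#' @export
setGeneric("categoryIds", function(x) standardGeneric("categoryIds"))

#' @rdname categoryIds
#' @export
setMethod("categoryIds", "CategoryMap",
          function(x) sort(unique(x@categories$category_id)))

#' @rdname categoryIds
#' @export
setMethod("categoryIds", "IncidenceTable",
          function(x) sort(setdiff(colnames(x@counts), UNMAPPED)))

#' @rdname categoryIds
#' @export
setMethod("categoryIds", "IncidenceVector", function(x) names(x@values))

#' @rdname categoryIds
#' @export
setMethod("categoryIds", "MutationCohort", function(x) sort(names(x@patients)))

#' @rdname categoryIds
#' @export
setMethod("categoryIds", "ConditionalMatrix", function(x) colnames(x))

#' Subclass tags of the categories in a map
#'
#' @param x a [CategoryMap-class].
#' @return Named character vector, category_id -> subclass tag.
#' @export
subclassTags <- function(x) {
  stopifnot(is(x, "CategoryMap"))
  stats::setNames(x@categories$subclass, x@categories$category_id)
}

#' Values of an incidence vector
#'
#' @param x an [IncidenceVector-class].
#' @return Named numeric vector of counts (raw vector S) or shares
#'   (normalized restriction S').
#' @export
incidenceValues <- function(x) {
  stopifnot(is(x, "IncidenceVector"))
  x@values
}

#' Is an incidence vector normalized?
#'
#' @param x an [IncidenceVector-class].
#' @return `TRUE` when the values are shares summing to 1.
#' @export
isNormalized <- function(x) {
  stopifnot(is(x, "IncidenceVector"))
  isTRUE(x@normalized)
}

#' Conditional probability matrix c_gh
#'
#' @param x a [ConditionalMatrix-class].
#' @return Numeric matrix genes x categories of mutated fractions.
#' @export
condProb <- function(x) {
  stopifnot(is(x, "ConditionalMatrix"))
  SummarizedExperiment::assay(x, "cond")
}

#' Mutated-patient numerators m_gh
#'
#' @param x a [ConditionalMatrix-class].
#' @return Integer matrix genes x categories of mutated patient counts.
#' @export
mutatedCounts <- function(x) {
  stopifnot(is(x, "ConditionalMatrix"))
  SummarizedExperiment::assay(x, "mutated")
}

#' Sequenced-patient denominators n_h
#'
#' @param x a [ConditionalMatrix-class] or [MutationCohort-class].
#' @return Named integer vector of sequenced patients per category.
#' @export
setGeneric("sampleCounts", function(x) standardGeneric("sampleCounts"))

#' @rdname sampleCounts
#' @export
setMethod("sampleCounts", "ConditionalMatrix", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$nSamples, colnames(x))
})

#' @rdname sampleCounts
#' @export
setMethod("sampleCounts", "MutationCohort", function(x) {
  n <- vapply(x@patients, length, integer(1))
  n[sort(names(n))]
})

#' Estimates table of a ProportionEstimate
#'
#' @param x a [ProportionEstimate-class].
#' @return data.frame with columns `gene`, `proportion`, `ci_low`, `ci_high`.
#' @export
proportionTable <- function(x) {
  stopifnot(is(x, "ProportionEstimate"))
  x@estimates
}

#' @describeIn proportionTable coerce to the estimates data.frame.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
setMethod("as.data.frame", "ProportionEstimate",
          function(x, row.names = NULL, optional = FALSE, ...) x@estimates)

#' Replicate weighted-proportion draws
#'
#' @param x a [ReplicateSet-class].
#' @return Numeric matrix genes x replicates.
#' @export
replicateValues <- function(x) {
  stopifnot(is(x, "ReplicateSet"))
  x@gValues
}

setMethod("show", "CategoryMap", function(object) {
  cat(sprintf(
    "CategoryMap: %d code entries (%d wildcard), %d categories, %d study assignment rules\n",
    nrow(object@entries), sum(object@entries$site_code == "*"),
    nrow(object@categories), nrow(object@studyAssignments)))
  tab <- table(object@categories$subclass)
  if (length(tab))
    cat("  subclasses:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
})

setMethod("show", "IncidenceTable", function(object) {
  un <- if (UNMAPPED %in% colnames(object@counts))
    sum(object@counts[, UNMAPPED]) else 0
  cat(sprintf(
    "IncidenceTable: %d sites x %d categories, total %s diagnoses (%s unmapped)\n",
    nrow(object@counts), ncol(object@counts),
    format(object@total, big.mark = ","), format(un, big.mark = ",")))
})

setMethod("show", "IncidenceVector", function(object) {
  cat(sprintf("IncidenceVector: %d categories, %s\n", length(object@values),
              if (isTRUE(object@normalized)) "normalized shares (sum 1)"
              else sprintf("raw counts (total %s)",
                           format(sum(object@values), big.mark = ","))))
  v <- sort(object@values, decreasing = TRUE)
  k <- min(5L, length(v))
  if (k) cat("  top:", paste(sprintf("%s=%.4g", names(v)[seq_len(k)],
                                     v[seq_len(k)]), collapse = ", "), "\n")
})

setMethod("show", "MutationCohort", function(object) {
  n <- sampleCounts(object)
  cat(sprintf(
    "MutationCohort: %d categories, %d patients, %d genes, %d (gene,patient) mutation marks\n",
    length(n), sum(n), length(unique(object@mutated$gene)),
    nrow(object@mutated)))
})

setMethod("show", "ConditionalMatrix", function(object) {
  cat(sprintf(
    "ConditionalMatrix: %d genes x %d categories (n_h range %d-%d)\n",
    nrow(object), ncol(object),
    min(SummarizedExperiment::colData(object)$nSamples),
    max(SummarizedExperiment::colData(object)$nSamples)))
})

setMethod("show", "ProportionEstimate", function(object) {
  e <- object@estimates
  cat(sprintf("ProportionEstimate: %d genes over %d categories%s\n",
              nrow(e), length(object@weights),
              if (all(is.na(e$ci_low))) "" else " (with 95% CIs)"))
  o <- order(-e$proportion, e$gene)
  k <- min(5L, nrow(e))
  if (k) {
    top <- e[o[seq_len(k)], ]
    cat("  top:", paste(sprintf("%s=%.1f%%", top$gene,
                                100 * top$proportion), collapse = ", "), "\n")
  }
})

setMethod("show", "ReplicateSet", function(object) {
  cat(sprintf("ReplicateSet: %d genes x %d replicates (seed %d)\n",
              nrow(object@gValues), object@nReps, object@seed))
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario: %d genes, %d sequenced / %d total categories, %d studies\n",
    nrow(object@probs), ncol(object@probs), length(object@shares),
    nrow(object@studies)))
  cat(sprintf("  rates: %s\n",
              paste(sprintf("%s=%.2g", names(object@rates), object@rates),
                    collapse = ", ")))
})
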