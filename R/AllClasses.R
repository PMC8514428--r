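#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

SUBCLASS_TAGS <- c("adenocarcinoma", "squamous_cell_carcinoma",
                   "malignant_melanoma", "transitional_cell_carcinoma",
                   "other")

#' CategoryMap: the common cancer taxonomy and its code maps
#'
#' Holds (a) the map from ICD-O-3 (morphology, site) code pairs onto analysis
#' categories, with `"*"` as a site wildcard, (b) per-study assignment rules
#' for sequencing-cohort samples (explicit sample lists, metadata predicates,
#' and study-level defaults) and (c) the category universe with an optional
#' histological subclass tag per category. The map is the bridge that lets
#' registry incidence records and tumor-sequencing samples be counted on one
#' taxonomy.
#'
#' Invariants enforced by the validity method: each (morphology, site) key
#' maps to exactly one category; every category referenced by a study
#' assignment exists; subclass tags are drawn from
#' adenocarcinoma / squamous_cell_carcinoma / malignant_melanoma /
#' transitional_cell_carcinoma / other.
#'
#' @slot entries data.frame with columns `morphology_code`, `site_code`
#'   (may be `"*"`), `category_id`. Morphology codes are stored
#'   slash-normalized so `"8140/3"` and `"81403"` address the same entry.
#' @slot studyAssignments data.frame with columns `study_id`,
#'   `selector_type` (one of `"sample"`, `"metadata"`, `"default"`),
#'   `selector_value`, `category_id`.
#' @slot categories data.frame with columns `category_id`, `subclass`.
#'
#' @seealso [categoryMap()], [readCategoryMap()], [classifyEpiRecord()],
#'   [classifyGenomicSample()]
#' @export
setClass("CategoryMap", slots = c(
  entries = "data.frame",
  studyAssignments = "data.frame",
  categories = "data.frame"
))

setValidity("CategoryMap", function(object) {
  e <- object@entries
  msgs <- character(0)
  need <- c("morphology_code", "site_code", "category_id")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  key <- paste(e$morphology_code, e$site_code, sep = "\r")
  if (anyDuplicated(key)) {
    conf <- unique(key[duplicated(key)])
    for (k in conf) {
      cats <- unique(e$category_id[key == k])
      if (length(cats) > 1L)
        msgs <- c(msgs, sprintf(
          "conflicting categories for key (%s): %s",
          gsub("\r", ", ", k), paste(cats, collapse = ", ")))
    }
  }
  a <- object@studyAssignments
  if (nrow(a)) {
    if (!all(c("study_id", "selector_type", "selector_value",
               "category_id") %in% names(a)))
      msgs <- c(msgs, "studyAssignments is missing required columns")
    else {
      bad <- setdiff(a$category_id, object@categories$category_id)
      if (length(bad))
        msgs <- c(msgs, sprintf(
          "study assignments reference unknown categories: %s",
          paste(bad, collapse = ", ")))
      badtype <- setdiff(a$selector_type, c("sample", "metadata", "default"))
      if (length(badtype))
        msgs <- c(msgs, sprintf("unknown selector_type: %s",
                                paste(badtype, collapse = ", ")))
    }
  }
  badsub <- setdiff(stats::na.omit(object@categories$subclass), SUBCLASS_TAGS)
  if (length(badsub))
    msgs <- c(msgs, sprintf("unknown subclass tags: %s",
                            paste(badsub, collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' IncidenceTable: registry counts on the common taxonomy
#'
#' Diagnosis counts indexed by anatomical site (rows) and analysis category
#' (columns) after reclassification of registry (morphology, site) records.
#' Mass from records that no map entry covers is retained in a reserved
#' `UNMAPPED` column so that the table total always equals the input total
#' (the conservation QC check).
#'
#' @slot counts numeric matrix, sites x categories, nonnegative.
#' @slot total total input count; always equals `sum(counts)`.
#' @seealso [buildIncidenceTable()], [incidenceVector()]
#' @export
setClass("IncidenceTable", slots = c(counts = "matrix", total = "numeric"))

setValidity("IncidenceTable", function(object) {
  if (length(object@counts) && any(object@counts < 0))
    return("negative cells are not allowed")
  if (!isTRUE(all.equal(sum(object@counts), object@total)))
    return("total does not equal the sum of all cells")
  TRUE
})

#' IncidenceVector: per-category diagnosis counts or shares
#'
#' The incidence vector S (raw per-category counts marginalized over sites)
#' or its normalized restriction S' (shares over the sequenced categories,
#' summing to 1). Categories are kept in lexicographic order so that vectors
#' and conditional matrices align deterministically.
#'
#' @slot values named nonnegative numeric vector, one element per category.
#' @slot normalized logical; when `TRUE` the values sum to 1 (+/- 1e-9).
#' @seealso [incidenceVector()], [restrictAndNormalize()], [subclassVector()]
#' @export
setClass("IncidenceVector",
         slots = c(values = "numeric", normalized = "logical"))

setValidity("IncidenceVector", function(object) {
  v <- object@values
  if (length(v) && is.null(names(v))) return("values must be named")
  if (any(v < 0)) return("values must be nonnegative")
  if (anyDuplicated(names(v))) return("duplicate category names")
  if (isTRUE(object@normalized) && length(v) &&
      abs(sum(v) - 1) > 1e-9)
    return("normalized vector must sum to 1")
  TRUE
})

#' MutationCohort: deduplicated per-patient mutation indicators
#'
#' The qualifying-mutation cohort after class filtering, longitudinal
#' first-sample selection and cross-study deduplication: per category, the
#' set of sequenced patients (the denominator n_h) and, per gene, the set of
#' patients with at least one qualifying mutation (the numerator m_gh).
#' A patient belongs to exactly one category.
#'
#' @slot patients named list, category_id -> character vector of patient ids.
#' @slot mutated data.frame with columns `category_id`, `gene`, `patient_id`;
#'   one row per distinct (category, gene, mutated patient).
#' @slot meta list of QC bookkeeping (dropped sample counts etc.).
#' @seealso [tallyCohort()], [conditionalMatrix()], [unionProportion()]
#' @export
setClass("MutationCohort",
         slots = c(patients = "list", mutated = "data.frame", meta = "list"))

setValidity("MutationCohort", function(object) {
  p <- object@patients
  if (length(p) && is.null(names(p))) return("patients list must be named")
  all_p <- unlist(p, use.names = FALSE)
  if (anyDuplicated(all_p))
    return("a patient appears in more than one category")
  m <- object@mutated
  if (nrow(m)) {
    if (!all(c("category_id", "gene", "patient_id") %in% names(m)))
      return("mutated must have category_id, gene, patient_id columns")
    if (!all(m$category_id %in% names(p)))
      return("mutated references categories absent from the patient roster")
    ok <- mapply(function(cat, pid) pid %in% p[[cat]],
                 m$category_id, m$patient_id)
    if (!all(ok))
      return("mutated references patients absent from their category roster")
  }
  TRUE
})

#' ConditionalMatrix: per-gene per-category mutated fractions
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the conditional
#' probability matrix C: assay `"cond"` stores c_gh = m_gh / n_h (the
#' fraction of sequenced patients of category h with a qualifying mutation
#' in gene g), assay `"mutated"` stores the integer numerators m_gh, and
#' `colData()$nSamples` stores the per-category denominators n_h. Rows are
#' genes, columns categories, both lexicographically ordered.
#'
#' @seealso [conditionalMatrix()], [condProb()], [mutatedCounts()],
#'   [sampleCounts()], [weightedProportions()]
#' @export
setClass("ConditionalMatrix", contains = "SummarizedExperiment")

setValidity("ConditionalMatrix", function(object) {
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("cond", "mutated") %in% an))
    return("assays 'cond' and 'mutated' are required")
  if (!"nSamples" %in% names(SummarizedExperiment::colData(object)))
    return("colData must carry nSamples")
  n <- SummarizedExperiment::colData(object)$nSamples
  if (any(n <= 0)) return("all categories must have nSamples > 0")
  cc <- SummarizedExperiment::assay(object, "cond")
  if (length(cc) && (min(cc) < 0 || max(cc) > 1))
    return("conditional probabilities must lie in [0, 1]")
  m <- SummarizedExperiment::assay(object, "mutated")
  if (length(m) && any(m > rep(n, each = nrow(m))))
    return("numerators m_gh exceed denominators n_h")
  TRUE
})

#' ProportionEstimate: weighted mutation proportions with contributions
#'
#' Per-gene population-level mutation proportions G_g = sum_h c_gh * s'_h,
#' optionally with percentile confidence bounds, together with the
#' per-category contribution shares w_gh = c_gh * s'_h / G_g that say which
#' cancer types account for the gene's mutated cases (NA rows where
#' G_g = 0).
#'
#' @slot estimates data.frame with columns `gene`, `proportion`, `ci_low`,
#'   `ci_high` (bounds NA until intervals are attached).
#' @slot contributions numeric matrix genes x categories of contribution
#'   shares; each non-NA row sums to 1.
#' @slot weights the normalized incidence shares s' the estimate used.
#' @seealso [weightedProportions()], [estimateWithCI()],
#'   [contributionBreakdown()]
#' @export
setClass("ProportionEstimate", slots = c(
  estimates = "data.frame",
  contributions = "matrix",
  weights = "numeric"
))

setValidity("ProportionEstimate", function(object) {
  e <- object@estimates
  if (!all(c("gene", "proportion", "ci_low", "ci_high") %in% names(e)))
    return("estimates must have gene, proportion, ci_low, ci_high")
  if (nrow(e)) {
    if (any(e$proportion < -1e-12 | e$proportion > 1 + 1e-12))
      return("proportions must lie in [0, 1]")
    has_ci <- !is.na(e$ci_low) & !is.na(e$ci_high)
    if (any(has_ci & (e$ci_low[has_ci] > e$proportion[has_ci] + 1e-9 |
                      e$ci_high[has_ci] < e$proportion[has_ci] - 1e-9)))
      return("confidence bounds must bracket the point estimate")
  }
  cb <- object@contributions
  if (nrow(cb)) {
    s <- rowSums(cb)
    bad <- !is.na(s) & abs(s - 1) > 1e-9
    if (any(bad)) return("contribution shares must sum to 1 per gene")
  }
  TRUE
})

#' ReplicateSet: Poisson replicate draws behind the confidence intervals
#'
#' For each (gene, category) the replicate mutated counts are drawn from a
#' Poisson law centred on the observed numerator m_gh, converted to
#' proportions against the fixed denominator n_h (clipped at 1), and pushed
#' through the weighting pipeline; the per-gene replicate G values feed the
#' percentile confidence intervals.
#'
#' @slot gValues numeric matrix genes x nReps of replicate weighted
#'   proportions.
#' @slot counts integer array genes x categories x nReps of replicate
#'   numerators (may be empty when not retained).
#' @slot nReps number of replicates (>= 2).
#' @slot seed the seed the draws were made under.
#' @seealso [simulateReplicates()], [percentileCI()]
#' @export
setClass("ReplicateSet", slots = c(
  gValues = "matrix", counts = "array", nReps = "integer", seed = "integer"
))

setValidity("ReplicateSet", function(object) {
  if (object@nReps < 2L) return("nReps must be at least 2")
  if (ncol(object@gValues) != object@nReps)
    return("gValues must have nReps columns")
  g <- object@gValues
  if (length(g) && (min(g) < 0 || max(g) > 1 + 1e-12))
    return("replicate proportions must lie in [0, 1]")
  TRUE
})

#' SyntheticScenario: ground truth for the synthetic-data generator
#'
#' Fully specifies a synthetic study: category shares pi_h over sequenced
#' and unsequenced categories, per-category per-gene Bernoulli mutation
#' probabilities p_gh, the category map (including ICD-O-3-style codes and
#' study assignment rules), multi-study cohort sizes, and the nuisance
#' rates the pipeline must be robust to (cross-study patient overlap,
#' longitudinal samples, gene-name aliases, excluded mutation classes).
#'
#' @slot shares named numeric over all categories, summing to 1.
#' @slot probs numeric matrix genes x sequenced categories in [0, 1].
#' @slot map the [CategoryMap-class] covering all categories.
#' @slot studies data.frame `study_id`, `study_date` (ISO date string).
#' @slot cohortSizes integer matrix studies x sequenced categories; 0 where
#'   a study does not cover a category.
#' @slot rates named numeric: `overlap`, `longitudinal`, `alias`,
#'   `excludedClass`, each in [0, 1].
#' @slot sentinel character; optional gene symbol placed only on
#'   longitudinal follow-up samples (a tripwire for first-sample selection).
#' @slot synonyms data.frame `alias`, `canonical` gene-symbol map.
#' @seealso [syntheticScenario()], [generateRegistry()], [generateCohorts()]
#' @export
setClass("SyntheticScenario", slots = c(
  shares = "numeric", probs = "matrix", map = "CategoryMap",
  studies = "data.frame", cohortSizes = "matrix", rates = "numeric",
  sentinel = "character", synonyms = "data.frame"
))

setValidity("SyntheticScenario", function(object) {
  if (abs(sum(object@shares) - 1) > 1e-9)
    return("category shares must sum to 1")
  p <- object@probs
  if (length(p) && (min(p) < 0 || max(p) > 1))
    return("mutation probabilities must lie in [0, 1]")
  r <- object@rates
  need <- c("overlap", "longitudinal", "alias", "excludedClass")
  if (!all(need %in% names(r)))
    return(paste("rates must name", paste(need, collapse = ", ")))
  if (any(r < 0 | r > 1)) return("rates must lie in [0, 1]")
  if (!identical(dim(object@cohortSizes),
                 c(nrow(object@studies), ncol(p))))
    return("cohortSizes must be studies x sequenced categories")
  if (!all(colnames(p) %in% names(object@shares)))
    return("probs columns must be categories with shares")
  TRUE
})
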