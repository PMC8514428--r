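#' Construct a CategoryMap
#'
#' @param entries data.frame with columns `morphology_code`, `site_code`
#'   (use `"*"` for any site), `category_id` and optionally `subclass`.
#' @param studyAssignments optional data.frame with columns `study_id`,
#'   `selector_type` (`"sample"`, `"metadata"` or `"default"`),
#'   `selector_value` and `category_id`. Metadata selectors are written
#'   `"column=value"` and matched case-insensitively against sample
#'   metadata; sample selectors name an explicit sample id; default
#'   selectors leave `selector_value` empty.
#' @param categories optional data.frame with columns `category_id` and
#'   `subclass`; inferred from `entries`/`studyAssignments` when omitted,
#'   with subclass `"other"`.
#' @return A validated [CategoryMap-class].
#' @examples
#' m <- categoryMap(data.frame(
#'   morphology_code = c("8140/3", "8720/3"),
#'   site_code = c("C18", "*"),
#'   category_id = c("colorectal_ac", "melanoma")))
#' classifyEpiRecord("8140/3", "C18", m)
#' @export
categoryMap <- function(entries, studyAssignments = NULL, categories = NULL) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries))
    entries$morphology_code <- normalizeMorphology(entries$morphology_code)
  sub_from_entries <- NULL
  if ("subclass" %in% names(entries)) {
    sub_from_entries <- unique(entries[, c("category_id", "subclass")])
    entries$subclass <- NULL
  }
  if (is.null(studyAssignments))
    studyAssignments <- data.frame(
      study_id = character(0), selector_type = character(0),
      selector_value = character(0), category_id = character(0),
      stringsAsFactors = FALSE)
  studyAssignments <- as.data.frame(studyAssignments,
                                    stringsAsFactors = FALSE)
  if (is.null(categories)) {
    ids <- sort(unique(c(entries$category_id,
                         studyAssignments$category_id)))
    categories <- data.frame(category_id = ids,
                             subclass = rep("other", length(ids)),
                             stringsAsFactors = FALSE)
    if (!is.null(sub_from_entries)) {
      hit <- match(categories$category_id, sub_from_entries$category_id)
      ok <- !is.na(hit) & !is.na(sub_from_entries$subclass[hit]) &
        nzchar(sub_from_entries$subclass[hit])
      categories$subclass[ok] <- sub_from_entries$subclass[hit][ok]
    }
  } else {
    categories <- as.data.frame(categories, stringsAsFactors = FALSE)
    if (!"subclass" %in% names(categories)) categories$subclass <- "other"
    categories$subclass[is.na(categories$subclass) |
                          !nzchar(categories$subclass)] <- "other"
  }
  new("CategoryMap", entries = entries,
      studyAssignments = studyAssignments, categories = categories)
}

#' Read a category map (and study assignments) from TSV
#'
#' The map file has columns `morphology_code`, `site_code` (`"*"` wildcard
#' allowed), `category_id` and optional `subclass`. Rows that duplicate a
#' (morphology, site) key with a conflicting category are rejected; exact
#' duplicates are collapsed. An empty file yields an empty map with a
#' warning.
#'
#' @param path path to the map TSV.
#' @param assignmentsPath optional path to a study-assignment TSV with
#'   columns `study_id`, `selector_type`, `selector_value`, `category_id`.
#' @return A [CategoryMap-class].
#' @seealso [writeCategoryMap()]
#' @export
readCategoryMap <- function(path, assignmentsPath = NULL) {
  e <- readTsv(path)
  need <- c("morphology_code", "site_code", "category_id")
  missing <- setdiff(need, names(e))
  if (length(missing))
    stopf("category map %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  e <- as.data.frame(e)
  bad <- !nzchar(e$morphology_code) | !nzchar(e$category_id)
  if (any(bad))
    stopf("category map %s: malformed row(s) at line(s) %s",
          path, paste(which(bad) + 1L, collapse = ", "))
  e <- unique(e)
  if (!nrow(e)) warning("category map '", basename(path), "' is empty")
  a <- NULL
  if (!is.null(assignmentsPath)) a <- as.data.frame(readTsv(assignmentsPath))
  categoryMap(e, studyAssignments = a)
}

#' Write a category map (and its study assignments) to TSV
#'
#' @param map a [CategoryMap-class].
#' @param path output path for the map TSV.
#' @param assignmentsPath optional output path for the study-assignment TSV.
#' @return `path`, invisibly.
#' @export
writeCategoryMap <- function(map, path, assignmentsPath = NULL) {
  stopifnot(is(map, "CategoryMap"))
  e <- map@entries
  e$subclass <- subclassTags(map)[e$category_id]
  writeTsv(e, path)
  if (!is.null(assignmentsPath)) writeTsv(map@studyAssignments,
                                          assignmentsPath)
  invisible(path)
}

#' Classify registry records onto the common taxonomy
#'
#' Looks up (morphology, site) pairs in the map: an exact site match is
#' preferred, then a `"*"` wildcard entry for the morphology; records that
#' neither covers get the [UNMAPPED] sentinel (a value, never an error).
#' Morphology codes are slash-normalized, so `"8140/3"` and `"81403"` are
#' equivalent.
#'
#' @param morphology,site character vectors of equal length (or length 1,
#'   recycled) of ICD-O-3 morphology and site codes.
#' @param map a [CategoryMap-class].
#' @return Character vector of category ids, `UNMAPPED` where no entry
#'   applies.
#' @export
classifyEpiRecord <- function(morphology, site, map) {
  stopifnot(is(map, "CategoryMap"))
  n <- max(length(morphology), length(site))
  morphology <- rep_len(normalizeMorphology(morphology), n)
  site <- rep_len(trimws(as.character(site)), n)
  e <- map@entries
  res <- rep(UNMAPPED, n)
  if (!nrow(e)) return(res)
  exact <- match(paste(morphology, site, sep = "\r"),
                 paste(e$morphology_code, e$site_code, sep = "\r"))
  wild <- e[e$site_code == "*", , drop = FALSE]
  wmatch <- match(morphology, wild$morphology_code)
  res[!is.na(wmatch)] <- wild$category_id[wmatch[!is.na(wmatch)]]
  res[!is.na(exact)] <- e$category_id[exact[!is.na(exact)]]
  res
}

#' Classify sequencing-cohort samples onto the common taxonomy
#'
#' Applies the study-assignment rules of the map to a sample sheet. The
#' precedence contract is: explicit per-sample assignment, then metadata
#' predicates in file order (first match wins), then the study default;
#' samples of unknown studies get the [UNMAPPED] sentinel. A single study
#' may fan out to several categories through metadata predicates.
#'
#' @param samples data.frame with columns `study_id`, `sample_id` and any
#'   metadata columns that predicates refer to.
#' @param map a [CategoryMap-class] whose `studyAssignments` hold the rules.
#' @return Character vector of category ids, one per sample row.
#' @export
classifyGenomicSample <- function(samples, map) {
  stopifnot(is(map, "CategoryMap"))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("study_id", "sample_id") %in% names(samples)))
  a <- map@studyAssignments
  res <- rep(UNMAPPED, nrow(samples))
  if (!nrow(a) || !nrow(samples)) return(res)

  # study defaults first (lowest precedence)
  d <- a[a$selector_type == "default", , drop = FALSE]
  if (nrow(d)) {
    hit <- match(samples$study_id, d$study_id)
    res[!is.na(hit)] <- d$category_id[hit[!is.na(hit)]]
  }

  # metadata predicates: apply in reverse file order so the first matching
  # rule in the file ends up winning
  mrows <- which(a$selector_type == "metadata")
  for (i in rev(mrows)) {
    sel <- a$selector_value[i]
    kv <- regmatches(sel, regexec("^([^=]+)=(.*)$", sel))[[1]]
    if (length(kv) != 3L)
      stopf("malformed metadata selector '%s' for study %s",
            sel, a$study_id[i])
    col <- trimws(kv[2]); val <- trimws(kv[3])
    if (!col %in% names(samples)) next
    hit <- samples$study_id == a$study_id[i] &
      normalizeToken(as.character(samples[[col]])) == normalizeToken(val)
    res[hit] <- a$category_id[i]
  }

  # explicit per-sample assignments override everything
  s <- a[a$selector_type == "sample", , drop = FALSE]
  if (nrow(s)) {
    hit <- match(paste(samples$study_id, samples$sample_id, sep = "\r"),
                 paste(s$study_id, s$selector_value, sep = "\r"))
    res[!is.na(hit)] <- s$category_id[hit[!is.na(hit)]]
  }
  res
}

#' Categories carrying a given subclass tag
#'
#' @param map a [CategoryMap-class].
#' @param tag one of `"adenocarcinoma"`, `"squamous_cell_carcinoma"`,
#'   `"malignant_melanoma"`, `"transitional_cell_carcinoma"`, `"other"`.
#' @return Character vector of category ids with that tag.
#' @export
subclassCategories <- function(map, tag) {
  stopifnot(is(map, "CategoryMap"))
  tag <- match.arg(tag, SUBCLASS_TAGS)
  sort(map@categories$category_id[map@categories$subclass == tag])
}
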