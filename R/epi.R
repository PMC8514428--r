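#' Read a registry incidence table from TSV
#'
#' Accepts either the long dialect (columns `morphology_code`, `site_code`,
#' `count`; column names `morphology`/`site` also accepted) or the wide
#' dialect exported by registry software (first column the morphology code,
#' remaining columns one per site code, integer cells). The dialect is
#' auto-detected from the header: a `count` column means long format.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `morphology_code`, `site_code`, `count`.
#' @export
readRegistryTable <- function(path) {
  x <- as.data.frame(readTsv(path))
  nm <- names(x)
  if ("count" %in% nm) {
    mcol <- intersect(c("morphology_code", "morphology"), nm)[1]
    scol <- intersect(c("site_code", "site"), nm)[1]
    if (is.na(mcol) || is.na(scol))
      stopf("long-format registry %s needs morphology and site columns", path)
    out <- data.frame(morphology_code = x[[mcol]], site_code = x[[scol]],
                      count = as.numeric(x$count),
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(x) < 2L)
      stopf("wide-format registry %s needs site columns", path)
    sites <- nm[-1]
    out <- data.frame(
      morphology_code = rep(x[[1]], times = length(sites)),
      site_code = rep(sites, each = nrow(x)),
      count = as.numeric(unlist(x[-1], use.names = FALSE)),
      stringsAsFactors = FALSE)
    out <- out[out$count != 0, , drop = FALSE]
  }
  if (anyNA(out$count)) stopf("registry %s has non-numeric counts", path)
  out
}

#' Build the reclassified incidence table
#'
#' Accumulates registry (morphology, site, count) records into a site x
#' category table using [classifyEpiRecord()]. Mass from unmappable records
#' is retained under the reserved [UNMAPPED] column, so the output total
#' always equals the input total exactly — the conservation check every
#' later stage relies on.
#'
#' @param records data.frame with columns `morphology_code`, `site_code`,
#'   `count` (counts must be nonnegative).
#' @param map a [CategoryMap-class].
#' @return An [IncidenceTable-class].
#' @export
buildIncidenceTable <- function(records, map) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!nrow(records)) {
    return(new("IncidenceTable",
               counts = matrix(numeric(0), 0, 0,
                               dimnames = list(NULL, NULL)),
               total = 0))
  }
  stopifnot(all(c("morphology_code", "site_code", "count") %in%
                  names(records)))
  cnt <- as.numeric(records$count)
  if (any(is.na(cnt)) || any(cnt < 0))
    stopf("registry counts must be nonnegative numbers")
  cat <- classifyEpiRecord(records$morphology_code, records$site_code, map)
  sites <- sort(unique(records$site_code))
  cats <- sort(unique(cat))
  m <- matrix(0, length(sites), length(cats),
              dimnames = list(sites, cats))
  agg <- stats::aggregate(cnt,
                          by = list(site = records$site_code, category = cat),
                          FUN = sum)
  m[cbind(match(agg$site, sites), match(agg$category, cats))] <- agg$x
  new("IncidenceTable", counts = m, total = sum(cnt))
}

#' Marginalize an incidence table into the vector S
#'
#' Sums counts over sites to give per-category diagnosis counts. The
#' reserved `UNMAPPED` column is dropped unless requested, in which case the
#' dropped mass is reported via `message()` so nothing disappears silently.
#'
#' @param table an [IncidenceTable-class].
#' @param includeUnmapped keep the `UNMAPPED` mass as a category?
#' @return An unnormalized [IncidenceVector-class] (categories sorted).
#' @export
incidenceVector <- function(table, includeUnmapped = FALSE) {
  stopifnot(is(table, "IncidenceTable"))
  v <- colSums(table@counts)
  if (!includeUnmapped && UNMAPPED %in% names(v)) {
    dropped <- v[[UNMAPPED]]
    v <- v[setdiff(names(v), UNMAPPED)]
    if (dropped > 0)
      message(sprintf("incidenceVector: dropping %s unmapped diagnoses (%.2f%% of total)",
                      format(dropped, big.mark = ","),
                      100 * dropped / table@total))
  }
  v <- v[sort(names(v))]
  new("IncidenceVector", values = v, normalized = FALSE)
}

#' Restrict S to sequenced categories and renormalize (S')
#'
#' Keeps only the categories with representative sequencing data and
#' rescales so the shares sum to 1 (the 100% normalization). Idempotent on
#' already-restricted vectors.
#'
#' @param S an [IncidenceVector-class].
#' @param sequencedIds character vector of category ids with sequencing
#'   data; must intersect the categories of `S`.
#' @return A normalized [IncidenceVector-class] over the intersection.
#' @export
restrictAndNormalize <- function(S, sequencedIds) {
  stopifnot(is(S, "IncidenceVector"))
  keep <- intersect(names(S@values), sequencedIds)
  if (!length(keep))
    stopf("no category of S has sequencing data; no estimate is possible")
  v <- S@values[sort(keep)]
  tot <- sum(v)
  if (tot <= 0)
    stopf("sequenced categories carry zero incidence; cannot normalize")
  new("IncidenceVector", values = v / tot, normalized = TRUE)
}

#' Fraction of incidence covered by sequenced categories
#'
#' @param S an [IncidenceVector-class] (raw or normalized).
#' @param sequencedIds character vector of sequenced category ids.
#' @return The coverage fraction in [0, 1]: incidence mass of sequenced
#'   categories over all mass in `S`.
#' @export
coverageFraction <- function(S, sequencedIds) {
  stopifnot(is(S, "IncidenceVector"))
  tot <- sum(S@values)
  if (tot == 0) return(0)
  sum(S@values[intersect(names(S@values), sequencedIds)]) / tot
}

#' Share of incidence held by the N most abundant categories
#'
#' @param S an [IncidenceVector-class].
#' @param n number of top categories; ties in abundance are broken by
#'   category id (lexicographic) so the answer is deterministic.
#' @return Fraction in [0, 1] of total incidence in the top `n` categories.
#' @export
topCategoriesShare <- function(S, n) {
  stopifnot(is(S, "IncidenceVector"), n >= 0)
  if (n == 0 || !length(S@values)) return(0)
  shares <- S@values / sum(S@values)
  o <- order(-shares, names(shares))
  sum(shares[o[seq_len(min(n, length(shares)))]])
}

#' Restrict S to a histological subclass
#'
#' Keeps the categories carrying a subclass tag (adenocarcinoma, squamous
#' cell carcinoma, ...) and renormalizes to sum 1, supporting
#' pan-subclass analyses as a filter over the one taxonomy rather than a
#' second map.
#'
#' @param S an [IncidenceVector-class].
#' @param tag a subclass tag (see [subclassCategories()]).
#' @param map the [CategoryMap-class] carrying the tags.
#' @return A normalized [IncidenceVector-class] over the subclass.
#' @export
subclassVector <- function(S, tag, map) {
  cats <- subclassCategories(map, tag)
  keep <- intersect(names(incidenceValues(S)), cats)
  if (!length(keep))
    stopf("no category of S carries subclass tag '%s'", tag)
  restrictAndNormalize(S, keep)
}

#' Write an incidence vector to TSV
#'
#' @param S an [IncidenceVector-class].
#' @param path output path; columns `category_id`, `value`, `share`.
#' @return `path`, invisibly.
#' @export
writeIncidenceVector <- function(S, path) {
  v <- incidenceValues(S)
  writeTsv(data.frame(category_id = names(v), value = as.numeric(v),
                      share = as.numeric(v) / sum(v)), path)
}
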