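# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Qualifying mutation classes
#'
#' The whitelist of MAF `Variant_Classification` tokens that count as a
#' qualifying coding mutation: missense, nonsense, nonstop and small
#' in-frame / frameshift indels. Splice-site, fusion, silent and other
#' non-coding classes are excluded. Matching is case-insensitive and
#' treats spaces and underscores as equivalent.
#'
#' @return Character vector of the ten accepted class tokens (lower case,
#'   underscore-normalized).
#' @examples
#' "Missense_Mutation" %in% mutationClassWhitelist()  # FALSE: compare normalized
#' tolower("Missense_Mutation") %in% mutationClassWhitelist()
#' @export
mutationClassWhitelist <- function() {
  c("nonsense_mutation", "frame_shift_del", "frame_shift", "frame_shift_ins",
    "missense_mutation", "missense", "nonsense", "in_frame_del",
    "in_frame_ins", "nonstop_mutation")
}

#' Sentinel category for unmappable records
#'
#' Records whose codes or study labels have no entry in the category map are
#' assigned this sentinel rather than being dropped silently; downstream
#' stages report the mass carried by it so conservation checks can be made.
#'
#' @format A length-one character constant, `"UNMAPPED"`.
#' @export
UNMAPPED <- "UNMAPPED"

# normalize a variant-class or metadata token: case and space/underscore folding
normalizeToken <- function(x) {
  gsub("[ ]+", "_", tolower(trimws(x)))
}

# accept both "8140/3" and "81403" morphology dialects
normalizeMorphology <- function(x) {
  gsub("/", "", trimws(as.character(x)), fixed = TRUE)
}

readTsv <- function(path, ...) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE,
                    colClasses = "character", na.strings = NULL, ...)
}

writeTsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# run expr under a fixed seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# per-purpose substream seeds derived from one master seed (kept < 2^31)
deriveSeed <- function(master, purpose) {
  as.integer((as.numeric(master) * 7919 + as.numeric(purpose) * 104729) %%
               2147483399) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
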