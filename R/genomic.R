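#' @importFrom data.table as.data.table data.table setorder setnames := .N .SD
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "patient_id", "study_id", "sample_id", "sample_order", "study_date",
  "gene_symbol", "variant_classification", "category_id", "gene", "count",
  ".keep"))

#' Read a MAF-style mutation call file
#'
#' Reads a Mutation Annotation Format TSV. Comment lines starting with `#`
#' (for example `#version 2.4`) are skipped. The mandatory columns are
#' `Hugo_Symbol`, `Variant_Classification` and `Tumor_Sample_Barcode`; a
#' missing one is an error naming the column. The patient identity used for
#' deduplication is configurable: a patient-id column when present, else a
#' barcode prefix of fixed length, else the full barcode (one sample per
#' patient). Genomic coordinate columns are accepted but ignored — only the
#' classification columns drive the analysis.
#'
#' @param path path to the MAF TSV.
#' @param studyId study label for the records; defaults to the file name
#'   without extension.
#' @param patientIdColumn column holding the patient id (default
#'   `"Patient_ID"`), used when present.
#' @param barcodePrefixLength optional integer; when the patient-id column
#'   is absent, the first `barcodePrefixLength` characters of the barcode
#'   identify the patient (the TCGA-style rule).
#' @param sampleOrderColumn column holding the longitudinal order of a
#'   patient's samples within the study (default `"Sample_Order"`); samples
#'   lacking it get order 1.
#' @return data.frame of mutation records with columns `study_id`,
#'   `patient_id`, `sample_id`, `gene_symbol`, `variant_classification`,
#'   `sample_order`.
#' @export
readMAF <- function(path, studyId = NULL, patientIdColumn = "Patient_ID",
                    barcodePrefixLength = NULL,
                    sampleOrderColumn = "Sample_Order") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stopf("MAF %s has no header", path)
  x <- data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                         header = TRUE, colClasses = "character",
                         data.table = TRUE)
  need <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
  for (col in need)
    if (!col %in% names(x))
      stopf("MAF %s is missing mandatory column '%s'", path, col)
  studyId <- studyId %||% sub("\\.[^.]*$", "", basename(path))
  pid <- if (patientIdColumn %in% names(x)) {
    x[[patientIdColumn]]
  } else if (!is.null(barcodePrefixLength)) {
    substr(x$Tumor_Sample_Barcode, 1L, as.integer(barcodePrefixLength))
  } else {
    x$Tumor_Sample_Barcode
  }
  ord <- if (sampleOrderColumn %in% names(x))
    suppressWarnings(as.integer(x[[sampleOrderColumn]])) else 1L
  ord[is.na(ord)] <- 1L
  out <- data.table::data.table(
    study_id = studyId,
    patient_id = pid,
    sample_id = x$Tumor_Sample_Barcode,
    gene_symbol = x$Hugo_Symbol,
    variant_classification = x$Variant_Classification,
    sample_order = ord)
  if (any(!nzchar(out$patient_id)) || any(!nzchar(out$sample_id)))
    stopf("MAF %s has empty patient or sample identifiers", path)
  as.data.frame(out)
}

#' Keep only qualifying coding mutation classes
#'
#' Retains exactly the records whose `variant_classification`, compared
#' case-insensitively with space/underscore folding, is one of the ten
#' accepted coding classes ([mutationClassWhitelist()]): missense,
#' nonsense, nonstop, and in-frame or frameshift indels. Splice-site,
#' fusion, silent, UTR and other classes are dropped.
#'
#' @param records mutation records (see [readMAF()]).
#' @return The qualifying subset of `records`.
#' @export
filterMutationClasses <- function(records) {
  records <- as.data.frame(records)
  keep <- normalizeToken(records$variant_classification) %in%
    mutationClassWhitelist()
  records[keep, , drop = FALSE]
}

#' Deduplicate longitudinal and cross-study samples
#'
#' Applies the two patient-level dedup rules: within a study, only a
#' patient's first sample (minimum `sample_order`, ties by sample id) is
#' kept; when the same patient appears in several studies, only the rows
#' from the most recently dated study survive (ties on `study_date` broken
#' by study id, lexicographically greatest winning — deterministic).
#'
#' Works on any table carrying `patient_id`, `study_id`, `sample_id` and
#' `sample_order` columns: apply it to the sample sheet (so that
#' mutation-free patients keep exactly one sample) and subset mutation
#' records to the surviving sample ids, or directly to records.
#'
#' @param x data.frame of samples or mutation records.
#' @param manifest data.frame with columns `study_id`, `study_date`
#'   (ISO-format date strings or anything ordered correctly as text).
#' @return The rows of `x` belonging to kept (patient, study, sample)
#'   triples.
#' @export
dedupSamples <- function(x, manifest) {
  x <- data.table::as.data.table(x)
  manifest <- as.data.frame(manifest)
  stopifnot(all(c("study_id", "study_date") %in% names(manifest)))
  if (!nrow(x)) return(as.data.frame(x))
  missing <- setdiff(unique(x$study_id), manifest$study_id)
  if (length(missing))
    stopf("manifest lacks study_date for: %s",
          paste(missing, collapse = ", "))

  units <- unique(x[, list(patient_id, study_id, sample_id, sample_order)])
  # rule 1: first sample per (patient, study)
  data.table::setorder(units, patient_id, study_id, sample_order, sample_id)
  first <- units[, .SD[1L], by = list(patient_id, study_id)]
  # rule 2: latest-dated study per patient (tie: greatest study_id)
  first[, study_date := manifest$study_date[match(study_id,
                                                  manifest$study_id)]]
  data.table::setorder(first, patient_id, -study_date, -study_id)
  kept <- first[, .SD[1L], by = patient_id]

  key <- paste(x$patient_id, x$study_id, x$sample_id, sep = "\r")
  keepkey <- paste(kept$patient_id, kept$study_id, kept$sample_id,
                   sep = "\r")
  as.data.frame(x[key %in% keepkey])
}

#' Standardize gene symbols through a synonym map
#'
#' Replaces every alias by its canonical symbol; symbols absent from the
#' map pass through unchanged and their count is reported via `message()`.
#' After standardization two aliases of one gene observed in one patient
#' collapse to a single mutated-gene indicator downstream.
#'
#' @param records mutation records with a `gene_symbol` column.
#' @param synonyms data.frame with columns `alias`, `canonical`.
#' @return `records` with canonical gene symbols.
#' @export
standardizeGeneNames <- function(records, synonyms) {
  records <- as.data.frame(records)
  synonyms <- as.data.frame(synonyms)
  stopifnot(all(c("alias", "canonical") %in% names(synonyms)))
  hit <- match(records$gene_symbol, synonyms$alias)
  unmatched <- unique(records$gene_symbol[is.na(hit) &
                                            !records$gene_symbol %in%
                                            synonyms$canonical])
  if (length(unmatched))
    message(sprintf("standardizeGeneNames: %d symbol(s) not in the synonym map passed through unchanged",
                    length(unmatched)))
  records$gene_symbol[!is.na(hit)] <- synonyms$canonical[hit[!is.na(hit)]]
  records
}

#' Tally the deduplicated cohort per category
#'
#' Assigns every sheet sample to a category with
#' [classifyGenomicSample()], drops `UNMAPPED` samples (their count is kept
#' in the QC metadata, never lost silently), and counts, per category, the
#' distinct sequenced patients (n_h) and, per gene, the distinct patients
#' with at least one qualifying mutation record (m_gh) — a patient counts
#' once per gene no matter how many mutations it carries there. Patients
#' with zero qualifying records still count in the denominator: n_h is the
#' number of sequenced patients, not of mutated ones.
#'
#' @param records qualifying, deduplicated mutation records (apply
#'   [filterMutationClasses()], [dedupSamples()] and
#'   [standardizeGeneNames()] first, or pass `manifest` to have the dedup
#'   applied here to both sheet and records).
#' @param samples the sample sheet: data.frame with `study_id`,
#'   `sample_id`, `patient_id`, `sample_order` and any metadata columns the
#'   map's predicates use. It defines the denominators.
#' @param map a [CategoryMap-class].
#' @param manifest optional study manifest (`study_id`, `study_date`);
#'   when supplied, [dedupSamples()] is applied to the sheet and the
#'   records are restricted to the surviving samples.
#' @return A [MutationCohort-class]. A patient assigned to two categories
#'   is an invariant breach and raises an error.
#' @export
tallyCohort <- function(records, samples, map, manifest = NULL) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("study_id", "sample_id", "patient_id") %in%
                  names(samples)))
  if (!"sample_order" %in% names(samples)) samples$sample_order <- 1L
  if (!is.null(manifest)) samples <- dedupSamples(samples, manifest)
  records <- as.data.frame(records)

  cat <- classifyGenomicSample(samples, map)
  n_unmapped <- sum(cat == UNMAPPED)
  if (n_unmapped)
    message(sprintf("tallyCohort: excluding %d unmapped sample(s)",
                    n_unmapped))
  keep <- cat != UNMAPPED
  samples <- samples[keep, , drop = FALSE]
  cat <- cat[keep]

  pc <- unique(data.frame(patient_id = samples$patient_id,
                          category_id = cat, stringsAsFactors = FALSE))
  dup <- unique(pc$patient_id[duplicated(pc$patient_id)])
  if (length(dup))
    stopf("patient(s) assigned to more than one category: %s%s",
          paste(utils::head(dup, 5L), collapse = ", "),
          if (length(dup) > 5L) ", ..." else "")

  patients <- split(pc$patient_id, pc$category_id)
  patients <- patients[sort(names(patients))]

  skey <- paste(samples$study_id, samples$sample_id, sep = "\r")
  rkey <- paste(records$study_id, records$sample_id, sep = "\r")
  hit <- match(rkey, skey)
  n_orphan <- sum(is.na(hit))
  if (n_orphan)
    message(sprintf("tallyCohort: dropping %d record(s) from samples outside the sheet",
                    n_orphan))
  rec <- records[!is.na(hit), , drop = FALSE]
  rec_cat <- cat[hit[!is.na(hit)]]
  rec_pat <- samples$patient_id[hit[!is.na(hit)]]
  mutated <- unique(data.frame(category_id = rec_cat,
                               gene = rec$gene_symbol,
                               patient_id = rec_pat,
                               stringsAsFactors = FALSE))
  mutated <- mutated[order(mutated$category_id, mutated$gene,
                           mutated$patient_id), , drop = FALSE]
  rownames(mutated) <- NULL
  new("MutationCohort", patients = patients, mutated = mutated,
      meta = list(unmappedSamples = n_unmapped,
                  orphanRecords = n_orphan,
                  sheetSamples = nrow(samples)))
}

#' Build the conditional matrix C from a cohort
#'
#' Computes c_gh = m_gh / n_h for every observed canonical gene symbol and
#' every category with sequenced patients. The gene universe is the union
#' of observed symbols, optionally extended by a supplied gene list:
#' listed-but-unobserved genes get explicit zero rows so their estimate is
#' 0 with a confidence interval, not missing.
#'
#' @param cohort a [MutationCohort-class].
#' @param genes optional character vector extending the gene universe.
#' @return A [ConditionalMatrix-class] (genes x categories,
#'   lexicographically ordered).
#' @export
conditionalMatrix <- function(cohort, genes = NULL) {
  stopifnot(is(cohort, "MutationCohort"))
  n <- sampleCounts(cohort)
  n <- n[n > 0]
  cats <- sort(names(n))
  gene_univ <- sort(unique(c(cohort@mutated$gene, genes)))
  if (!length(gene_univ) || !length(cats))
    stopf("cohort has no genes or no populated categories")
  m <- matrix(0L, length(gene_univ), length(cats),
              dimnames = list(gene_univ, cats))
  mu <- cohort@mutated[cohort@mutated$category_id %in% cats, , drop = FALSE]
  if (nrow(mu)) {
    tab <- table(factor(mu$gene, levels = gene_univ),
                 factor(mu$category_id, levels = cats))
    m[] <- as.integer(tab)
  }
  cond <- sweep(m, 2L, n[cats], "/")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cond = cond, mutated = m),
    colData = S4Vectors::DataFrame(nSamples = as.integer(n[cats]),
                                   row.names = cats))
  new("ConditionalMatrix", se)
}

#' Write per-category mutation counts to TSV
#'
#' @param C a [ConditionalMatrix-class].
#' @param path output path; columns `gene`, `category_id`, `mutated`,
#'   `sequenced`, `fraction`.
#' @return `path`, invisibly.
#' @export
writeMutationCounts <- function(C, path) {
  stopifnot(is(C, "ConditionalMatrix"))
  m <- mutatedCounts(C)
  n <- sampleCounts(C)
  out <- data.frame(
    gene = rep(rownames(m), times = ncol(m)),
    category_id = rep(colnames(m), each = nrow(m)),
    mutated = as.integer(m),
    sequenced = rep(as.integer(n), each = nrow(m)),
    fraction = as.numeric(condProb(C)))
  writeTsv(out[out$mutated > 0 | out$fraction > 0, , drop = FALSE], path)
}
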