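# shared fixtures and independent oracles used across test files

# the two-entry map from the package examples: colorectal AC keyed exactly,
# melanoma by site wildcard
tinyMap <- function() {
  categoryMap(
    data.frame(morphology_code = c("8140/3", "8720/3"),
               site_code = c("C18", "*"),
               category_id = c("colorectal_ac", "melanoma"),
               subclass = c("adenocarcinoma", "malignant_melanoma")),
    studyAssignments = data.frame(
      study_id = c("lung_study_1", "lung_study_1", "lung_study_1"),
      selector_type = c("metadata", "default", "sample"),
      selector_value = c("histology=squamous", "", "SAMPLE_X"),
      category_id = c("lung_scc", "lung_ac", "melanoma")),
    categories = data.frame(
      category_id = c("colorectal_ac", "melanoma", "lung_ac", "lung_scc"),
      subclass = c("adenocarcinoma", "malignant_melanoma",
                   "adenocarcinoma", "squamous_cell_carcinoma")))
}

# build a ConditionalMatrix directly from numerators and denominators
makeC <- function(m, n) {
  patients <- lapply(seq_along(n), function(j)
    sprintf("%s_p%04d", names(n)[j], seq_len(n[j])))
  names(patients) <- names(n)
  mut <- do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    do.call(rbind, lapply(seq_len(nrow(m)), function(g) {
      k <- m[g, j]
      if (k == 0) return(NULL)
      data.frame(category_id = colnames(m)[j], gene = rownames(m)[g],
                 patient_id = patients[[colnames(m)[j]]][seq_len(k)])
    }))
  }))
  if (is.null(mut))
    mut <- data.frame(category_id = character(0), gene = character(0),
                      patient_id = character(0))
  cohort <- new("MutationCohort", patients = patients, mutated = mut,
                meta = list())
  conditionalMatrix(cohort, genes = rownames(m))
}

# fast ConditionalMatrix construction from raw numerators/denominators,
# bypassing the cohort bookkeeping (for estimator-level tests)
makeCraw <- function(m, n) {
  cond <- sweep(m, 2L, n, "/")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cond = cond, mutated = m),
    colData = S4Vectors::DataFrame(nSamples = as.integer(n),
                                   row.names = colnames(m)))
  new("ConditionalMatrix", se)
}

makeSprime <- function(v) {
  v <- v[sort(names(v))]
  new("IncidenceVector", values = v / sum(v), normalized = TRUE)
}

# independent brute-force oracle for the cohort tally: plain loops over
# patients, no joins
bruteTally <- function(records, samples, manifest, map, synonyms = NULL) {
  # dedup by explicit per-patient loops
  kept <- list()
  for (pid in unique(samples$patient_id)) {
    rows <- samples[samples$patient_id == pid, , drop = FALSE]
    dates <- manifest$study_date[match(rows$study_id, manifest$study_id)]
    best <- order(dates, rows$study_id, decreasing = TRUE)[1]
    study <- rows$study_id[best]
    srows <- rows[rows$study_id == study, , drop = FALSE]
    first <- srows[order(srows$sample_order, srows$sample_id)[1], ,
                   drop = FALSE]
    kept[[pid]] <- first
  }
  kept <- do.call(rbind, kept)
  cats <- classifyGenomicSample(kept, map)
  keep <- cats != UNMAPPED
  kept <- kept[keep, , drop = FALSE]
  cats <- cats[keep]

  wl <- mutationClassWhitelist()
  canon <- function(g) {
    if (is.null(synonyms)) return(g)
    i <- match(g, synonyms$alias)
    ifelse(is.na(i), g, synonyms$canonical[i])
  }
  n_h <- table(cats)
  m <- list()
  for (i in seq_len(nrow(kept))) {
    rr <- records[records$study_id == kept$study_id[i] &
                    records$sample_id == kept$sample_id[i], , drop = FALSE]
    ok <- tolower(gsub(" ", "_", rr$variant_classification)) %in% wl
    genes <- unique(canon(rr$gene_symbol[ok]))
    for (g in genes) {
      key <- paste(cats[i], g, sep = "\r")
      m[[key]] <- c(m[[key]], kept$patient_id[i])
    }
  }
  counts <- vapply(m, function(x) length(unique(x)), integer(1))
  list(n_h = n_h, m = counts)
}

# a tiny two-study scenario used by several genomic tests
smallScenario <- function(seed = 5, ...) {
  syntheticScenario(seed = seed, nCategories = 3, nGenes = 6,
                    nStudies = 2, patientsPerCategory = 60,
                    unsequencedShare = 0, ...)
}
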