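#' Read and validate a pipeline run configuration
#'
#' The YAML configuration names the input files and the run options:
#'
#' ```yaml
#' paths:
#'   registry: registry_long.tsv        # long or wide dialect
#'   maf_dir: mafs/                     # *.maf or *.maf.tsv files
#'   samples: samples.tsv               # sample sheet (defines denominators)
#'   category_map: category_map.tsv
#'   study_assignments: study_assignments.tsv
#'   manifest: manifest.tsv             # study_id, study_date
#'   synonyms: synonyms.tsv             # optional
#'   gene_sets: gene_sets.tsv           # optional: set_name, gene
#' options:
#'   n_reps: 2000
#'   seed: 1                            # mandatory when CIs are computed
#'   ci_level: 0.95
#'   top_n: 25
#'   subclasses: [adenocarcinoma]       # optional subclass analyses
#'   union_genes: [[GENE01, GENE02]]    # optional union analyses
#' output_dir: out/
#' ```
#'
#' Every referenced path must exist at validation time; a missing one is a
#' validation error raised before any computation.
#'
#' @param path path to the YAML file.
#' @return The validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopf("validation error: config '%s' not found", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  need <- c("registry", "maf_dir", "samples", "category_map",
            "study_assignments", "manifest")
  p <- cfg$paths %||% list()
  for (k in need)
    if (is.null(p[[k]]))
      stopf("validation error: config is missing paths$%s", k)
  resolve <- function(f)
    if (startsWith(f, "/")) f else file.path(base, f)
  for (k in names(p)) p[[k]] <- resolve(p[[k]])
  for (k in c(need, intersect(c("synonyms", "gene_sets"), names(p))))
    if (!file.exists(p[[k]]))
      stopf("validation error: paths$%s ('%s') does not exist", k, p[[k]])
  cfg$paths <- p
  o <- cfg$options %||% list()
  o$n_reps <- as.integer(o$n_reps %||% 2000L)
  o$ci_level <- as.numeric(o$ci_level %||% 0.95)
  o$top_n <- as.integer(o$top_n %||% 25L)
  if (is.null(o$seed))
    stopf("validation error: options$seed is mandatory when confidence intervals are computed")
  o$seed <- as.integer(o$seed)
  cfg$options <- o
  cfg$output_dir <- resolve(cfg$output_dir %||% file.path(base, "out"))
  cfg
}

#' Run the full weighted-estimation pipeline
#'
#' Executes map -> registry -> genomic -> estimator -> confidence
#' intervals: reclassifies the registry table, builds S and S', ingests
#' and filters the MAF files, deduplicates patients, standardizes gene
#' names, tallies the cohort, computes G = C %*% S' with Poisson-replicate
#' CIs, the pooled-vs-weighted comparison, any requested subclass and
#' union analyses, and writes the report bundle (estimates, contributions,
#' comparison, incidence and counts TSVs plus a JSON report with the run
#' log). Conservation totals are checked and logged at every stage; any
#' stage failure aborts with the stage name. Rerunning with the same
#' configuration and seed reproduces the report byte for byte.
#'
#' @param config path to a YAML configuration or the list returned by
#'   [readRunConfig()].
#' @return Invisibly, a list with the main objects: `incidence` (S),
#'   `sPrime`, `coverage`, `cohort`, `C`, `estimate`, `comparison`,
#'   `subclasses`, `unions`, `log`, and `files`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  p <- config$paths; o <- config$options
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = o$seed, n_reps = o$n_reps, ci_level = o$ci_level)
  stage <- function(name, expr) {
    message("stage ", name)
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  map <- stage("remap", readCategoryMap(p$category_map,
                                        p$study_assignments))

  epi <- stage("epi", {
    reg <- readRegistryTable(p$registry)
    tab <- buildIncidenceTable(reg, map)
    stopifnot(isTRUE(all.equal(sum(reg$count), tab@total)))
    list(records = reg, table = tab, S = incidenceVector(tab))
  })
  log$registry_total <- epi$table@total
  log$registry_unmapped <- epi$table@total - sum(incidenceValues(epi$S))

  gen <- stage("genomic", {
    manifest <- as.data.frame(readTsv(p$manifest))
    mafs <- list.files(p$maf_dir, pattern = "\\.maf(\\.tsv)?$",
                       full.names = TRUE)
    if (!length(mafs)) stopf("no MAF files under %s", p$maf_dir)
    recs <- lapply(mafs, function(f)
      readMAF(f, studyId = sub("\\.maf(\\.tsv)?$|\\.tsv$", "",
                               basename(f))))
    records <- do.call(rbind, recs)
    raw_n <- nrow(records)
    records <- filterMutationClasses(records)
    filt_n <- nrow(records)
    samples <- as.data.frame(readTsv(p$samples))
    samples$sample_order <- as.integer(samples$sample_order %||% 1L)
    sheet_n <- nrow(samples)
    samples <- dedupSamples(samples, manifest)
    records <- records[paste(records$study_id, records$sample_id) %in%
                         paste(samples$study_id, samples$sample_id), ,
                       drop = FALSE]
    if (!is.null(p$synonyms))
      records <- standardizeGeneNames(records,
                                      as.data.frame(readTsv(p$synonyms)))
    cohort <- tallyCohort(records, samples, map)
    list(cohort = cohort, records = records,
         counts = c(raw_records = raw_n, qualifying_records = filt_n,
                    sheet_samples = sheet_n,
                    dedup_samples = nrow(samples)))
  })
  log$genomic_counts <- as.list(gen$counts)
  log$cohort_patients <- sum(sampleCounts(gen$cohort))
  log$unmapped_samples <- gen$cohort@meta$unmappedSamples

  est <- stage("estimate", {
    C <- conditionalMatrix(gen$cohort)
    sPrime <- restrictAndNormalize(epi$S, categoryIds(C))
    C <- C[, names(incidenceValues(sPrime))]
    list(C = C, sPrime = sPrime,
         coverage = coverageFraction(epi$S, categoryIds(C)),
         top10 = topCategoriesShare(epi$S, 10L))
  })
  log$coverage_fraction <- est$coverage
  log$top10_share <- est$top10

  fit <- stage("ci", estimateWithCI(est$C, est$sPrime, nReps = o$n_reps,
                                    seed = o$seed, level = o$ci_level))
  comparison <- stage("compare", compareUnweighted(est$C, est$sPrime))

  subcl <- list()
  for (tag in o$subclasses %||% character(0))
    subcl[[tag]] <- stage(paste0("subclass_", tag),
                          subclassEstimates(est$C, epi$S, tag, map))
  unions <- list()
  for (gs in o$union_genes %||% list()) {
    gs <- unlist(gs)
    unions[[paste(gs, collapse = "|")]] <-
      stage("union", unionProportion(gen$cohort, gs, est$sPrime,
                                     nReps = o$n_reps,
                                     seed = deriveSeed(o$seed, 41L),
                                     level = o$ci_level))
  }

  files <- stage("report", {
    out <- config$output_dir
    f <- c(
      estimates = writeEstimates(fit, file.path(out, "estimates.tsv")),
      contributions = writeContributions(fit,
                                         file.path(out,
                                                   "contributions.tsv")),
      comparison = writeTsv(comparison, file.path(out, "comparison.tsv")),
      incidence = writeIncidenceVector(epi$S,
                                       file.path(out, "incidence.tsv")),
      counts = writeMutationCounts(est$C, file.path(out, "counts.tsv")))
    top <- geneSetView(fit, proportionTable(fit)$gene, topN = o$top_n)
    report <- list(
      log = log,
      coverage_fraction = est$coverage,
      top10_category_share = est$top10,
      top_genes = top,
      unions = lapply(unions, proportionTable),
      subclasses = lapply(subcl, function(x)
        utils::head(proportionTable(x)[
          order(-proportionTable(x)$proportion), ], o$top_n)))
    rp <- file.path(out, "report.json")
    jsonlite::write_json(report, rp, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE, dataframe = "rows")
    c(f, report = rp)
  })

  invisible(list(incidence = epi$S, sPrime = est$sPrime,
                 coverage = est$coverage, cohort = gen$cohort, C = est$C,
                 estimate = fit, comparison = comparison,
                 subclasses = subcl, unions = unions, log = log,
                 files = files))
}
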