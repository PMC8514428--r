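# Synthetic study generator: registry tables and multi-study MAF-style
# cohorts with known ground truth, so every stage and the end-to-end
# estimator can be validated without external downloads.

EXCLUDED_CLASS_TOKENS <- c("Splice_Site", "Fusion", "Silent", "3'UTR",
                           "Intron", "5'Flank")
WHITELIST_DIALECTS <- c("Missense_Mutation", "missense_mutation", "Missense",
                        "Nonsense_Mutation", "nonsense", "Frame_Shift_Del",
                        "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
                        "Nonstop_Mutation", "frame shift")

#' Define a synthetic study scenario
#'
#' Builds the ground truth for a synthetic population and its sequencing
#' cohorts. The default scenario has six sequenced categories with
#' incidence shares 0.30/0.20/0.15/0.12/0.10/0.06 plus one unsequenced
#' category at 0.07 (so the sequenced categories cover 93% of incidence),
#' 40 genes, three dated studies each covering two categories (adjacent
#' categories share a study, so cross-study patient overlap can occur) and
#' 2,000 patients per category. Per-gene mutation probabilities are drawn
#' once from the scenario seed: a background rate U(0.005, 0.05) per
#' category, one elevated driver category per gene at U(0.08, 0.35), and
#' the first gene set to 0.8 in the smallest category — a marker mimicking
#' a near-ubiquitous driver of a rare cancer.
#'
#' All randomness is derived from `seed` through per-purpose substreams,
#' so regenerating with the same seed is bit-reproducible and changing one
#' feature does not shift unrelated draws.
#'
#' @param seed master seed for the scenario (and default for generators).
#' @param nCategories number of sequenced categories.
#' @param nGenes number of genes.
#' @param nStudies number of sequencing studies.
#' @param patientsPerCategory distinct sequenced patients per category
#'   (scalar or one value per category).
#' @param shares optional named shares for the sequenced categories
#'   (they may sum to less than 1 when `unsequencedShare > 0`).
#' @param probs optional genes x categories probability matrix overriding
#'   the drawn one.
#' @param unsequencedShare incidence share of the category with no
#'   sequencing data (0 disables it).
#' @param overlapFraction fraction of a shared category's patients
#'   duplicated into the later of the two studies covering it.
#' @param longitudinalRate probability a patient contributes a second,
#'   later sample within the study.
#' @param aliasRate probability a mutation row uses an alias symbol
#'   (for genes that have one in the synonym map).
#' @param excludedClassRate probability a mutation row carries a
#'   non-qualifying class (splice site, fusion, ...) instead of a
#'   whitelist class.
#' @param sentinel optional gene symbol written only on longitudinal
#'   follow-up samples; it must never survive first-sample selection.
#' @return A [SyntheticScenario-class].
#' @export
syntheticScenario <- function(seed = 1L, nCategories = 6L, nGenes = 40L,
                              nStudies = 3L, patientsPerCategory = 2000L,
                              shares = NULL, probs = NULL,
                              unsequencedShare = 0.07,
                              overlapFraction = 0.1,
                              longitudinalRate = 0.1, aliasRate = 0.1,
                              excludedClassRate = 0,
                              sentinel = character(0)) {
  cats <- sprintf("CAT%02d", seq_len(nCategories))
  genes <- sprintf("GENE%02d", seq_len(nGenes))
  if (is.null(shares)) {
    base <- c(0.30, 0.20, 0.15, 0.12, 0.10, 0.06)
    raw <- if (nCategories <= length(base)) base[seq_len(nCategories)]
           else c(base, rep(0.03, nCategories - length(base)))
    shares <- stats::setNames(raw / sum(raw) * (1 - unsequencedShare), cats)
  } else {
    stopifnot(length(shares) == nCategories)
    names(shares) <- cats
  }
  all_shares <- shares
  if (unsequencedShare > 0)
    all_shares <- c(shares, UNSEQ01 = unsequencedShare)
  all_shares <- all_shares / sum(all_shares)

  if (is.null(probs)) {
    probs <- withSeed(deriveSeed(seed, 1L), {
      p <- matrix(stats::runif(nGenes * nCategories, 0.005, 0.05),
                  nGenes, nCategories, dimnames = list(genes, cats))
      driver_cat <- sample.int(nCategories, nGenes, replace = TRUE)
      p[cbind(seq_len(nGenes), driver_cat)] <-
        stats::runif(nGenes, 0.08, 0.35)
      p[1L, which.min(shares)] <- 0.8
      p
    })
  } else {
    stopifnot(identical(dim(probs), c(as.integer(nGenes),
                                      as.integer(nCategories))))
    dimnames(probs) <- list(genes, cats)
  }

  # ICD-O-3-style codes: one morphology per category; the last sequenced
  # category maps by wildcard site to exercise that path
  all_cats <- names(all_shares)
  subcls <- rep(c("adenocarcinoma", "squamous_cell_carcinoma",
                  "malignant_melanoma", "transitional_cell_carcinoma"),
                length.out = length(all_cats))
  if (unsequencedShare > 0) subcls[length(all_cats)] <- "other"
  entries <- data.frame(
    morphology_code = sprintf("8%03d/3", seq_along(all_cats)),
    site_code = sprintf("C%02d", seq_along(all_cats)),
    category_id = all_cats, stringsAsFactors = FALSE)
  entries$site_code[nCategories] <- "*"
  studies <- data.frame(
    study_id = sprintf("study_%02d", seq_len(nStudies)),
    study_date = sprintf("%d-06-01", 2014L + seq_len(nStudies)),
    stringsAsFactors = FALSE)

  # coverage: category j is covered by studies 1+((j-1) %% nStudies) and,
  # when more than one study exists, also by the next study (wrapped)
  cover <- matrix(FALSE, nStudies, nCategories,
                  dimnames = list(studies$study_id, cats))
  for (j in seq_len(nCategories)) {
    s1 <- 1L + ((j - 1L) %% nStudies)
    cover[s1, j] <- TRUE
    if (nStudies > 1L) cover[1L + (j %% nStudies), j] <- TRUE
  }
  ppc <- rep_len(as.integer(patientsPerCategory), nCategories)
  sizes <- matrix(0L, nStudies, nCategories,
                  dimnames = dimnames(cover))
  for (j in seq_len(nCategories)) {
    s <- which(cover[, j])
    sz <- rep(ppc[j] %/% length(s), length(s))
    sz[1L] <- sz[1L] + ppc[j] - sum(sz)
    sizes[s, j] <- sz
  }

  # study assignment rules: metadata predicate per covered category plus a
  # study default (the study's first category)
  arows <- list()
  for (s in seq_len(nStudies)) {
    covered <- cats[cover[s, ]]
    if (!length(covered)) next
    arows[[length(arows) + 1L]] <- data.frame(
      study_id = studies$study_id[s], selector_type = "metadata",
      selector_value = paste0("histology=", covered),
      category_id = covered, stringsAsFactors = FALSE)
    arows[[length(arows) + 1L]] <- data.frame(
      study_id = studies$study_id[s], selector_type = "default",
      selector_value = "", category_id = covered[1L],
      stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, arows)
  map <- categoryMap(entries, studyAssignments = assignments,
                     categories = data.frame(category_id = all_cats,
                                             subclass = subcls,
                                             stringsAsFactors = FALSE))

  aliased <- genes[seq_len(max(0L, nGenes %/% 2L))]
  synonyms <- data.frame(alias = character(0), canonical = character(0),
                         stringsAsFactors = FALSE)
  if (length(aliased))
    synonyms <- data.frame(alias = paste0(aliased, "_ALT"),
                           canonical = aliased, stringsAsFactors = FALSE)

  new("SyntheticScenario", shares = all_shares, probs = probs, map = map,
      studies = studies, cohortSizes = sizes,
      rates = c(overlap = overlapFraction, longitudinal = longitudinalRate,
                alias = aliasRate, excludedClass = excludedClassRate),
      sentinel = as.character(sentinel), synonyms = synonyms)
}

#' True weighted proportions of a scenario
#'
#' @param scenario a [SyntheticScenario-class].
#' @param sequencedOnly restrict (and renormalize) the shares to the
#'   sequenced categories, matching what the estimator can see.
#' @return Named numeric vector of true G_g = sum_h p_gh * pi_h.
#' @export
trueProportions <- function(scenario, sequencedOnly = TRUE) {
  p <- scenario@probs
  pi <- scenario@shares[colnames(p)]
  if (sequencedOnly) pi <- pi / sum(pi)
  as.numeric(p %*% pi) |> stats::setNames(rownames(p))
}

#' Generate a synthetic registry incidence table
#'
#' Draws `totalCount` diagnoses over the scenario categories from a
#' multinomial law with the true shares, placing each category at its
#' morphology code and a concrete site code, and optionally writes both
#' the long and the wide registry dialects.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param totalCount total diagnoses to draw.
#' @param seed seed for the multinomial draw (defaults to a substream of
#'   nothing — pass one for reproducibility; mandatory).
#' @param dir optional directory; when given, `registry_long.tsv` and
#'   `registry_wide.tsv` are written there.
#' @return List with `records` (long-format data.frame), `table` (the
#'   [IncidenceTable-class] after reclassification) and `files`.
#' @export
generateRegistry <- function(scenario, totalCount = 1e6, seed, dir = NULL) {
  stopifnot(is(scenario, "SyntheticScenario"))
  if (missing(seed)) stopf("a seed is required")
  sh <- scenario@shares
  e <- scenario@map@entries
  counts <- if (totalCount > 0)
    withSeed(deriveSeed(seed, 11L),
             as.numeric(stats::rmultinom(1L, totalCount, sh)))
  else rep(0, length(sh))
  hit <- match(names(sh), e$category_id)
  site <- e$site_code[hit]
  site[site == "*"] <- sprintf("C%02d", 90L + which(site == "*"))
  records <- data.frame(morphology_code = e$morphology_code[hit],
                        site_code = site, count = counts,
                        stringsAsFactors = FALSE)
  records <- records[records$count > 0, , drop = FALSE]
  files <- character(0)
  if (!is.null(dir)) {
    long <- file.path(dir, "registry_long.tsv")
    writeTsv(records, long)
    wide <- file.path(dir, "registry_wide.tsv")
    sites <- sort(unique(records$site_code))
    morphs <- sort(unique(records$morphology_code))
    w <- matrix(0, length(morphs), length(sites),
                dimnames = list(morphs, sites))
    w[cbind(match(records$morphology_code, morphs),
            match(records$site_code, sites))] <- records$count
    writeTsv(data.frame(morphology_code = morphs, w, check.names = FALSE),
             wide)
    files <- c(long = long, wide = wide)
  }
  list(records = records,
       table = buildIncidenceTable(records, scenario@map),
       files = files)
}

#' Generate synthetic multi-study sequencing cohorts
#'
#' Draws the cohorts the genomic pipeline must digest: per study and
#' category, patients with per-gene Bernoulli(p_gh) mutation presence,
#' each present gene expanded to 1-3 MAF rows with classes drawn from the
#' whitelist (or, at the excluded-class rate, from splice-site/fusion-like
#' classes the filter must drop); a fraction of patients of categories
#' covered by two studies is duplicated into the later study (cross-study
#' overlap, independent re-draw); a fraction of patients contributes a
#' longitudinal second sample (optionally carrying the sentinel gene); and
#' rows use alias symbols at the alias rate.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param seed mandatory seed; same seed, same cohorts.
#' @param dir optional directory: per-study `<study>.maf.tsv`,
#'   `samples.tsv`, `manifest.tsv`, `synonyms.tsv`, `category_map.tsv`,
#'   `study_assignments.tsv` and `truth.json` are written there.
#' @return List with `records` (MAF-style rows), `samples` (the sample
#'   sheet), `manifest`, `synonyms`, `map`, `truth` (list: true presence
#'   per kept patient, expected m_gh, n_h) and `files`.
#' @export
generateCohorts <- function(scenario, seed, dir = NULL) {
  stopifnot(is(scenario, "SyntheticScenario"))
  if (missing(seed)) stopf("a seed is required")
  p <- scenario@probs
  genes <- rownames(p)
  cats <- colnames(p)
  sizes <- scenario@cohortSizes
  studies <- scenario@studies
  r <- scenario@rates

  withSeed(deriveSeed(seed, 21L), {
    samp_list <- list()
    rec_list <- list()
    truth_pres <- list()  # per (study, cat): presence matrix of its draws

    # distinct patients per category, partitioned over covering studies;
    # the overlap fraction of the earliest study's patients is duplicated
    # into the latest covering study
    pat_of <- list()
    for (j in seq_along(cats)) {
      N <- sum(sizes[, j])
      ids <- sprintf("P_%s_%05d", cats[j], seq_len(N))
      covering <- which(sizes[, j] > 0L)
      covering <- covering[order(studies$study_date[covering],
                                 studies$study_id[covering])]
      split_idx <- rep(covering, times = sizes[covering, j])
      pat_of[[cats[j]]] <- split(ids, split_idx)
      names(pat_of[[cats[j]]]) <- studies$study_id[
        as.integer(names(pat_of[[cats[j]]]))]
      if (length(covering) > 1L && r[["overlap"]] > 0) {
        early <- studies$study_id[covering[1L]]
        late <- studies$study_id[covering[length(covering)]]
        ndup <- round(r[["overlap"]] * length(pat_of[[cats[j]]][[early]]))
        if (ndup > 0) {
          dups <- pat_of[[cats[j]]][[early]][seq_len(ndup)]
          pat_of[[cats[j]]][[late]] <-
            c(pat_of[[cats[j]]][[late]], dups)
        }
      }
    }

    draw_sample <- function(study, cat, patients, order) {
      nPat <- length(patients)
      if (!nPat) return(NULL)
      z <- matrix(stats::rbinom(nPat * length(genes), 1L,
                                rep(p[, cat], each = nPat)),
                  nPat, length(genes), dimnames = list(patients, genes))
      idx <- which(z == 1L, arr.ind = TRUE)
      sample_ids <- sprintf("%s-%s-S%02d", study, patients, order)
      samp <- data.frame(study_id = study,
                         sample_id = sample_ids,
                         patient_id = patients,
                         sample_order = order,
                         histology = cat, stringsAsFactors = FALSE)
      rec <- NULL
      if (nrow(idx)) {
        nrows <- sample(1:3, nrow(idx), replace = TRUE)
        rep_i <- rep(seq_len(nrow(idx)), times = nrows)
        gsym <- genes[idx[rep_i, 2L]]
        excl <- stats::runif(length(rep_i)) < r[["excludedClass"]]
        cls <- ifelse(excl,
                      sample(EXCLUDED_CLASS_TOKENS, length(rep_i),
                             replace = TRUE),
                      sample(WHITELIST_DIALECTS, length(rep_i),
                             replace = TRUE))
        ali <- match(gsym, scenario@synonyms$canonical)
        use_alias <- !is.na(ali) & stats::runif(length(rep_i)) < r[["alias"]]
        gsym[use_alias] <- scenario@synonyms$alias[ali[use_alias]]
        rec <- data.frame(
          study_id = study,
          patient_id = patients[idx[rep_i, 1L]],
          sample_id = sprintf("%s-%s-S%02d", study,
                              patients[idx[rep_i, 1L]], order),
          gene_symbol = gsym,
          variant_classification = cls,
          sample_order = order, stringsAsFactors = FALSE)
      }
      if (order > 1L && length(scenario@sentinel)) {
        sent <- data.frame(
          study_id = study, patient_id = patients,
          sample_id = sample_ids, gene_symbol = scenario@sentinel[1L],
          variant_classification = "Missense_Mutation",
          sample_order = order, stringsAsFactors = FALSE)
        rec <- rbind(rec, sent)
      }
      list(samples = samp, records = rec, presence = z)
    }

    for (j in seq_along(cats)) for (study in names(pat_of[[cats[j]]])) {
      patients <- pat_of[[cats[j]]][[study]]
      d1 <- draw_sample(study, cats[j], patients, 1L)
      key <- paste(study, cats[j], sep = "\r")
      truth_pres[[key]] <- d1$presence
      samp_list[[length(samp_list) + 1L]] <- d1$samples
      if (!is.null(d1$records))
        rec_list[[length(rec_list) + 1L]] <- d1$records
      if (r[["longitudinal"]] > 0) {
        follow <- patients[stats::runif(length(patients)) <
                             r[["longitudinal"]]]
        if (length(follow)) {
          d2 <- draw_sample(study, cats[j], follow, 2L)
          samp_list[[length(samp_list) + 1L]] <- d2$samples
          if (!is.null(d2$records))
            rec_list[[length(rec_list) + 1L]] <- d2$records
        }
      }
    }

    samples <- do.call(rbind, samp_list)
    records <- do.call(rbind, rec_list)
    if (is.null(records))
      records <- data.frame(study_id = character(0),
                            patient_id = character(0),
                            sample_id = character(0),
                            gene_symbol = character(0),
                            variant_classification = character(0),
                            sample_order = integer(0))
    rownames(samples) <- rownames(records) <- NULL

    # ground truth at the level the pipeline should recover: for each
    # patient keep the first sample of the latest-dated covering study
    truth_m <- matrix(0L, length(genes), length(cats),
                      dimnames = list(genes, cats))
    n_h <- stats::setNames(integer(length(cats)), cats)
    for (j in seq_along(cats)) {
      covering <- names(pat_of[[cats[j]]])
      dates <- studies$study_date[match(covering, studies$study_id)]
      o <- order(dates, covering)  # ascending; later overrides earlier
      pres <- NULL
      for (study in covering[o]) {
        z <- truth_pres[[paste(study, cats[j], sep = "\r")]]
        if (is.null(pres)) pres <- z
        else {
          old <- intersect(rownames(z), rownames(pres))
          if (length(old)) pres[old, ] <- z[old, , drop = FALSE]
          pres <- rbind(pres, z[setdiff(rownames(z), rownames(pres)), ,
                                drop = FALSE])
        }
      }
      truth_m[, j] <- colSums(pres)
      n_h[j] <- nrow(pres)
    }
    truth <- list(expected_m = truth_m, n_h = n_h,
                  probs = p, shares = scenario@shares)

    files <- character(0)
    if (!is.null(dir)) {
      for (study in studies$study_id) {
        rs <- records[records$study_id == study, , drop = FALSE]
        maf <- data.frame(Hugo_Symbol = rs$gene_symbol,
                          Chromosome = "1", Start_Position = "1000",
                          End_Position = "1000",
                          Variant_Classification = rs$variant_classification,
                          Tumor_Sample_Barcode = rs$sample_id,
                          Patient_ID = rs$patient_id,
                          Sample_Order = rs$sample_order,
                          stringsAsFactors = FALSE)
        path <- file.path(dir, paste0(study, ".maf.tsv"))
        con <- file(path, "w")
        writeLines("#version 2.4", con)
        close(con)
        data.table::fwrite(maf, path, sep = "\t", quote = FALSE,
                           append = TRUE, col.names = TRUE)
        files[paste0("maf_", study)] <- path
      }
      files["samples"] <- writeTsv(samples, file.path(dir, "samples.tsv"))
      files["manifest"] <- writeTsv(studies, file.path(dir, "manifest.tsv"))
      files["synonyms"] <- writeTsv(scenario@synonyms,
                                    file.path(dir, "synonyms.tsv"))
      files["map"] <- file.path(dir, "category_map.tsv")
      files["assignments"] <- file.path(dir, "study_assignments.tsv")
      writeCategoryMap(scenario@map, files[["map"]],
                       files[["assignments"]])
      files["truth"] <- file.path(dir, "truth.json")
      jsonlite::write_json(
        list(expected_m = as.data.frame(truth_m),
             n_h = as.list(n_h),
             probs = as.data.frame(p),
             shares = as.list(scenario@shares)),
        files[["truth"]], digits = NA, auto_unbox = TRUE, pretty = TRUE)
    }
    list(records = records, samples = samples, manifest = studies,
         synonyms = scenario@synonyms, map = scenario@map, truth = truth,
         files = files)
  })
}

#' Fast count-level cohort simulation
#'
#' Draws the sufficient statistics of a cohort directly — m_gh ~
#' Binomial(n_h, p_gh) — skipping MAF-row generation. This is the
#' generator used for repeated-cohort studies such as confidence-interval
#' coverage checks, where only the tally matters.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param seed mandatory seed.
#' @return A [ConditionalMatrix-class] with the drawn numerators.
#' @export
simulateCohortCounts <- function(scenario, seed) {
  stopifnot(is(scenario, "SyntheticScenario"))
  if (missing(seed)) stopf("a seed is required")
  p <- scenario@probs
  n <- stats::setNames(colSums(scenario@cohortSizes), colnames(p))
  m <- withSeed(deriveSeed(seed, 31L),
                matrix(stats::rbinom(length(p), rep(n, each = nrow(p)),
                                     as.numeric(p)),
                       nrow(p), ncol(p), dimnames = dimnames(p)))
  cond <- sweep(m, 2L, n, "/")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cond = cond, mutated = m),
    colData = S4Vectors::DataFrame(nSamples = as.integer(n),
                                   row.names = colnames(p)))
  new("ConditionalMatrix", se)
}
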