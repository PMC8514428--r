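writeToyMAF <- function(path, rows, version = TRUE) {
  header <- "Hugo_Symbol\tVariant_Classification\tTumor_Sample_Barcode\tPatient_ID\tSample_Order"
  writeLines(c(if (version) "#version 2.4", header, rows), path)
}

test_that("MAF parsing: comments skipped, mandatory columns enforced", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeToyMAF(f, c("TP53\tMissense_Mutation\tS1\tP1\t1",
                   "KRAS\tSplice_Site\tS1\tP1\t1",
                   "TP53\tNonsense_Mutation\tS2\tP2\t1"))
  rec <- readMAF(f, studyId = "toy")
  expect_equal(nrow(rec), 3L)
  expect_identical(unique(rec$study_id), "toy")
  expect_identical(rec$patient_id, c("P1", "P1", "P2"))

  g <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode", "TP53\tS1"), g)
  expect_error(readMAF(g), "Variant_Classification")
})

test_that("patient identity falls back to barcode prefix or full barcode", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tVariant_Classification\tTumor_Sample_Barcode",
               "TP53\tMissense_Mutation\tTCGA-AB-1234-01"), f)
  expect_identical(readMAF(f, barcodePrefixLength = 12)$patient_id,
                   "TCGA-AB-1234")
  expect_identical(readMAF(f)$patient_id, "TCGA-AB-1234-01")
})

test_that("mutation-class filter keeps exactly the coding whitelist", {
  kept <- c("Missense_Mutation", "missense", "NONSENSE", "In_Frame_Del",
            "frame shift", "Nonstop_Mutation", "Frame_Shift_Ins")
  dropped <- c("Splice_Site", "Fusion", "Silent", "3'UTR", "Intron",
               "Translation_Start_Site", "")
  rec <- data.frame(study_id = "s", patient_id = "p", sample_id = "x",
                    gene_symbol = "G",
                    variant_classification = c(kept, dropped),
                    sample_order = 1L)
  out <- filterMutationClasses(rec)
  expect_setequal(out$variant_classification, kept)
  # the whitelist is exactly ten tokens
  expect_length(mutationClassWhitelist(), 10L)
})

test_that("dedup keeps the first sample within a study and the latest study across", {
  manifest <- data.frame(study_id = c("A", "B"),
                         study_date = c("2015-01-01", "2018-01-01"))
  x <- data.frame(
    study_id = c("A", "A", "B", "A"),
    patient_id = c("P1", "P1", "P1", "P2"),
    sample_id = c("a1", "a2", "b1", "a3"),
    sample_order = c(1L, 2L, 1L, 1L))
  out <- dedupSamples(x, manifest)
  # P1 appears in A and B: only latest study B survives
  expect_identical(out$sample_id[out$patient_id == "P1"], "b1")
  # single-sample patient unchanged
  expect_identical(out$sample_id[out$patient_id == "P2"], "a3")

  # within one study: earliest sample_order wins
  y <- data.frame(study_id = "A", patient_id = "P1",
                  sample_id = c("s2", "s1"), sample_order = c(2L, 1L))
  expect_identical(dedupSamples(y, manifest)$sample_id, "s1")

  # date tie broken by greatest study_id, deterministically
  mtie <- data.frame(study_id = c("A", "B"),
                     study_date = c("2018-01-01", "2018-01-01"))
  out2 <- dedupSamples(x, mtie)
  expect_identical(out2$study_id[out2$patient_id == "P1"], "B")
})

test_that("gene-name standardization maps aliases and passes unknowns through", {
  syn <- data.frame(alias = "MLL3", canonical = "KMT2C")
  rec <- data.frame(study_id = "s", patient_id = "p", sample_id = "x",
                    gene_symbol = c("MLL3", "KMT2C", "NOVEL1"),
                    variant_classification = "Missense_Mutation",
                    sample_order = 1L)
  expect_message(out <- standardizeGeneNames(rec, syn), "passed through")
  expect_identical(out$gene_symbol, c("KMT2C", "KMT2C", "NOVEL1"))
})

test_that("two aliases of one gene in one patient count that patient once", {
  map <- categoryMap(
    data.frame(morphology_code = "8000/3", site_code = "*",
               category_id = "A"),
    studyAssignments = data.frame(study_id = "st",
                                  selector_type = "default",
                                  selector_value = "", category_id = "A"),
    categories = data.frame(category_id = "A", subclass = "other"))
  syn <- data.frame(alias = c("MLL3", "KMT2C-ALT"),
                    canonical = c("KMT2C", "KMT2C"))
  rec <- data.frame(study_id = "st", patient_id = "P1", sample_id = "s1",
                    gene_symbol = c("MLL3", "KMT2C-ALT"),
                    variant_classification = "Missense_Mutation",
                    sample_order = 1L)
  samples <- data.frame(study_id = "st", sample_id = "s1",
                        patient_id = "P1", sample_order = 1L)
  rec <- standardizeGeneNames(rec, syn)
  ch <- tallyCohort(rec, samples, map)
  expect_equal(nrow(ch@mutated), 1L)
  expect_equal(as.integer(mutatedCounts(conditionalMatrix(ch))["KMT2C", "A"]),
               1L)
})

test_that("tally semantics: multiplicity collapsed, zero-mutation patients in n_h", {
  map <- tinyMap()
  samples <- data.frame(
    study_id = "lung_study_1",
    sample_id = c("s1", "s2", "s3"),
    patient_id = c("P1", "P2", "P3"),
    sample_order = 1L,
    histology = c("adeno", "adeno", "adeno"))
  rec <- data.frame(
    study_id = "lung_study_1",
    patient_id = "P1", sample_id = "s1",
    gene_symbol = "TP53",
    variant_classification = rep("Missense_Mutation", 3),
    sample_order = 1L)
  ch <- tallyCohort(rec, samples, map)
  expect_equal(unname(sampleCounts(ch)["lung_ac"]), 3L)  # denominator: all sequenced
  C <- conditionalMatrix(ch)
  expect_equal(unname(condProb(C)["TP53", "lung_ac"]), 1 / 3)
  expect_equal(unname(mutatedCounts(C)["TP53", "lung_ac"]), 1L)  # 3 rows -> 1 patient
})

test_that("a patient assigned to two categories is an invariant breach", {
  map <- tinyMap()
  samples <- data.frame(
    study_id = "lung_study_1", sample_id = c("s1", "s2"),
    patient_id = "P1", sample_order = 1L,
    histology = c("adeno", "squamous"))
  expect_error(tallyCohort(data.frame(), samples, map),
               "more than one category")
})

test_that("unmapped samples are excluded and counted, not lost", {
  map <- tinyMap()
  samples <- data.frame(
    study_id = c("lung_study_1", "unknown_study"),
    sample_id = c("s1", "s2"), patient_id = c("P1", "P2"),
    sample_order = 1L, histology = "adeno")
  expect_message(ch <- tallyCohort(data.frame(study_id = character(0),
                                              sample_id = character(0),
                                              gene_symbol = character(0)),
                                   samples, map), "1 unmapped")
  expect_equal(ch@meta$unmappedSamples, 1L)
  expect_equal(sum(sampleCounts(ch)), 1L)
})

test_that("tally agrees with the brute-force per-patient oracle on synthetic streams", {
  sc <- smallScenario(seed = 31)
  co <- generateCohorts(sc, seed = 31)
  oracle <- bruteTally(co$records, co$samples, co$manifest, co$map,
                       co$synonyms)

  rec <- filterMutationClasses(co$records)
  samp <- dedupSamples(co$samples, co$manifest)
  rec <- rec[paste(rec$study_id, rec$sample_id) %in%
               paste(samp$study_id, samp$sample_id), ]
  rec <- suppressMessages(standardizeGeneNames(rec, co$synonyms))
  ch <- tallyCohort(rec, samp, co$map)

  n <- sampleCounts(ch)
  expect_equal(as.integer(n[names(oracle$n_h)]),
               as.integer(oracle$n_h), ignore_attr = TRUE)
  C <- conditionalMatrix(ch)
  m <- mutatedCounts(C)
  for (key in names(oracle$m)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    expect_equal(unname(m[parts[2], parts[1]]), unname(oracle$m[[key]]),
                 label = key)
  }
  # and no extra mass anywhere
  expect_equal(sum(m), sum(unlist(oracle$m)))
})

test_that("filter and dedup commute for class-only filtering", {
  # sample selection is driven by the sheet, so class filtering and the
  # restriction to surviving samples must commute
  sc <- smallScenario(seed = 13, excludedClassRate = 0.3)
  co <- generateCohorts(sc, seed = 13)
  kept <- dedupSamples(co$samples, co$manifest)
  restrict <- function(x) x[paste(x$study_id, x$sample_id) %in%
                              paste(kept$study_id, kept$sample_id), ,
                            drop = FALSE]
  a <- restrict(filterMutationClasses(co$records))
  b <- filterMutationClasses(restrict(co$records))
  key <- function(x) sort(paste(x$study_id, x$sample_id, x$gene_symbol,
                                x$variant_classification))
  expect_identical(key(a), key(b))
  expect_gt(nrow(a), 0L)

  # record-level dedup also commutes with class filtering as long as the
  # kept sample retains at least one qualifying row
  manifest <- data.frame(study_id = c("A", "B"),
                         study_date = c("2015-01-01", "2018-01-01"))
  rec <- data.frame(
    study_id = c("A", "A", "B", "B"),
    patient_id = "P1",
    sample_id = c("a1", "a2", "b1", "b2"),
    gene_symbol = c("G1", "G2", "G3", "G4"),
    variant_classification = c("Missense_Mutation", "Missense_Mutation",
                               "Nonsense_Mutation", "Splice_Site"),
    sample_order = c(1L, 2L, 1L, 2L))
  a2 <- dedupSamples(filterMutationClasses(rec), manifest)
  b2 <- filterMutationClasses(dedupSamples(rec, manifest))
  expect_identical(key(a2), key(b2))
  expect_identical(a2$gene_symbol, "G3")
})

test_that("conditional matrix entries are valid probabilities with zero rows for listed genes", {
  m <- matrix(c(2L, 4L, 0L, 4L), 2, 2,
              dimnames = list(c("G1", "G2"), c("A", "B")))
  C <- makeC(m, c(A = 4L, B = 8L))
  expect_equal(unname(condProb(C)["G1", "A"]), 0.5)
  expect_equal(unname(condProb(C)["G2", "B"]), 0.5)
  expect_true(all(condProb(C) >= 0 & condProb(C) <= 1))
  # gene present only in a supplied list gets an explicit zero row
  cohort <- new("MutationCohort",
                patients = list(A = c("p1", "p2")),
                mutated = data.frame(category_id = "A", gene = "G1",
                                     patient_id = "p1"),
                meta = list())
  C2 <- conditionalMatrix(cohort, genes = c("G1", "LISTED"))
  expect_equal(unname(condProb(C2)["LISTED", "A"]), 0)
})
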