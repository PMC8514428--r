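epiMap <- function() {
  categoryMap(data.frame(
    morphology_code = c("8140/3", "8140/3", "8720/3"),
    site_code = c("C18", "C34", "*"),
    category_id = c("A", "A", "B"),
    subclass = c("adenocarcinoma", "adenocarcinoma",
                 "malignant_melanoma")))
}

test_that("incidence table accumulates, conserves totals and keeps UNMAPPED mass", {
  m <- epiMap()
  recs <- data.frame(
    morphology_code = c("8140/3", "8140/3", "8720/3", "9999/3"),
    site_code = c("C18", "C18", "C44", "C18"),
    count = c(3, 4, 10, 5))
  tab <- buildIncidenceTable(recs, m)
  expect_equal(tab@counts["C18", "A"], 7)           # additivity
  expect_equal(tab@counts["C18", UNMAPPED], 5)      # conservation
  expect_equal(tab@total, 22)
  expect_equal(sum(tab@counts), 22)

  expect_error(buildIncidenceTable(
    data.frame(morphology_code = "8140/3", site_code = "C18", count = -1),
    m), "nonnegative")
  empty <- buildIncidenceTable(recs[0, ], m)
  expect_equal(empty@total, 0)
})

test_that("conservation holds for random record streams", {
  m <- epiMap()
  set.seed(42)
  for (i in 1:10) {
    n <- sample(1:60, 1)
    recs <- data.frame(
      morphology_code = sample(c("8140/3", "8720/3", "1111/1"), n, TRUE),
      site_code = sample(c("C18", "C34", "C44", "C80"), n, TRUE),
      count = rpois(n, 20))
    tab <- buildIncidenceTable(recs, m)
    expect_equal(tab@total, sum(recs$count))
    expect_equal(sum(tab@counts), sum(recs$count))
    S_all <- incidenceVector(tab, includeUnmapped = TRUE)
    expect_equal(sum(incidenceValues(S_all)), sum(recs$count))
  }
})

test_that("incidenceVector marginalizes over sites and reports dropped mass", {
  m <- epiMap()
  recs <- data.frame(
    morphology_code = c("8140/3", "8140/3", "8720/3"),
    site_code = c("C18", "C34", "C44"),
    count = c(7, 3, 10))
  S <- incidenceVector(buildIncidenceTable(recs, m))
  expect_equal(incidenceValues(S), c(A = 10, B = 10))
  expect_false(isNormalized(S))

  recs2 <- rbind(recs, data.frame(morphology_code = "9999/9",
                                  site_code = "C18", count = 4))
  tab2 <- buildIncidenceTable(recs2, m)
  expect_message(S2 <- incidenceVector(tab2), "unmapped")
  expect_equal(sum(incidenceValues(S2)), 20)  # 4 dropped, logged
})

test_that("restrict-and-normalize matches hand renormalization and is idempotent", {
  S <- new("IncidenceVector", values = c(A = 60, B = 30, C = 10),
           normalized = FALSE)
  Sp <- restrictAndNormalize(S, c("A", "B"))
  expect_equal(incidenceValues(Sp), c(A = 2 / 3, B = 1 / 3))
  expect_true(isNormalized(Sp))
  # identity restriction and singletons
  expect_equal(incidenceValues(restrictAndNormalize(S, c("A", "B", "C"))),
               c(A = 0.6, B = 0.3, C = 0.1))
  expect_equal(incidenceValues(restrictAndNormalize(S, "C")), c(C = 1))
  # idempotence on already-restricted vectors
  Sp2 <- restrictAndNormalize(Sp, c("A", "B"))
  expect_equal(incidenceValues(Sp2), incidenceValues(Sp))
  expect_error(restrictAndNormalize(S, "Z"), "no category")
})

test_that("coverage fraction is exact and monotone in the sequenced set", {
  S <- new("IncidenceVector", values = c(A = 60, B = 30, C = 10),
           normalized = FALSE)
  expect_equal(coverageFraction(S, c("A", "B")), 0.9)
  expect_equal(coverageFraction(S, c("A", "B", "C")), 1.0)
  expect_equal(coverageFraction(S, character(0)), 0.0)
  # monotone nondecreasing as the sequenced set grows
  sets <- list("C", c("C", "B"), c("C", "B", "A"))
  covs <- vapply(sets, function(s) coverageFraction(S, s), numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("top-N share sums the largest normalized shares deterministically", {
  S <- new("IncidenceVector", values = c(A = 50, B = 30, C = 20),
           normalized = FALSE)
  expect_equal(topCategoriesShare(S, 2), 0.8)
  expect_equal(topCategoriesShare(S, 10), 1.0)
  expect_equal(topCategoriesShare(S, 0), 0.0)
  # ties broken by category id: with equal shares top-1 takes one of them
  T2 <- new("IncidenceVector", values = c(B = 10, A = 10), normalized = FALSE)
  expect_equal(topCategoriesShare(T2, 1), 0.5)
})

test_that("subclass restriction renormalizes within the tag", {
  m <- categoryMap(data.frame(
    morphology_code = c("1", "2", "3"), site_code = "*",
    category_id = c("A", "B", "C"),
    subclass = c("adenocarcinoma", "adenocarcinoma",
                 "squamous_cell_carcinoma")))
  S <- new("IncidenceVector", values = c(A = 30, B = 10, C = 60),
           normalized = FALSE)
  sub <- subclassVector(S, "adenocarcinoma", m)
  expect_equal(incidenceValues(sub), c(A = 0.75, B = 0.25))
  expect_error(subclassVector(S, "malignant_melanoma", m), "no category")
  # tag covering everything equals plain normalization
  m2 <- categoryMap(data.frame(
    morphology_code = c("1", "2", "3"), site_code = "*",
    category_id = c("A", "B", "C"), subclass = "adenocarcinoma"))
  expect_equal(incidenceValues(subclassVector(S, "adenocarcinoma", m2)),
               c(A = 0.3, B = 0.1, C = 0.6))
})

test_that("registry reader accepts long and wide dialects equivalently", {
  long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("morphology_code\tsite_code\tcount",
               "8140/3\tC18\t7", "8720/3\tC44\t10"), long)
  wide <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("morphology_code\tC18\tC44",
               "8140/3\t7\t0", "8720/3\t0\t10"), wide)
  a <- readRegistryTable(long)
  b <- readRegistryTable(wide)
  key <- function(x) x[order(x$morphology_code, x$site_code),
                       c("morphology_code", "site_code", "count")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})
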