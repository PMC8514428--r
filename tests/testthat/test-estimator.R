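test_that("weighted proportions match hand arithmetic and refuse misalignment", {
  C <- makeC(matrix(c(5L, 1L), 1, 2, dimnames = list("G1", c("A", "B"))),
             c(A = 10L, B = 10L))
  sp <- makeSprime(c(A = 0.6, B = 0.4))
  est <- weightedProportions(C, sp)
  expect_equal(proportionTable(est)$proportion, 0.5 * 0.6 + 0.1 * 0.4)

  # single category: G equals that column of C
  C1 <- makeC(matrix(c(3L, 0L), 2, 1,
                     dimnames = list(c("G1", "G2"), "A")),
              c(A = 10L))
  est1 <- weightedProportions(C1, makeSprime(c(A = 1)))
  expect_equal(proportionTable(est1)$proportion, c(0.3, 0))

  # misaligned category lists: error, no silent reindexing
  expect_error(weightedProportions(C, makeSprime(c(A = 0.5, Z = 0.5))),
               "misaligned")
  # unnormalized weights refused
  expect_error(weightedProportions(
    C, new("IncidenceVector", values = c(A = 0.6, B = 0.4),
           normalized = FALSE)), "normalized")
})

test_that("estimator equals the brute-force category loop and obeys mean bounds", {
  set.seed(7)
  for (i in 1:25) {
    nG <- sample(2:12, 1); nH <- sample(2:6, 1)
    n <- setNames(sample(5:50, nH, TRUE),
                  sprintf("C%02d", seq_len(nH)))
    m <- matrix(rbinom(nG * nH, rep(n, each = nG), 0.3), nG, nH,
                dimnames = list(sprintf("G%02d", seq_len(nG)), names(n)))
    C <- makeC(m, n)
    w <- runif(nH); w <- w / sum(w)
    sp <- makeSprime(setNames(w, names(n)))
    G <- proportionTable(weightedProportions(C, sp))$proportion
    cc <- condProb(C); v <- incidenceValues(sp)
    brute <- vapply(seq_len(nG), function(g) {
      acc <- 0
      for (h in seq_len(nH)) acc <- acc + cc[g, h] * v[h]
      acc
    }, numeric(1))
    expect_equal(G, brute, tolerance = 1e-14)
    # weighted-mean bounds
    expect_true(all(G <= apply(cc, 1, max) + 1e-12))
    expect_true(all(G >= apply(cc, 1, min) - 1e-12))
  }
})

test_that("contribution shares decompose G and rank deterministically", {
  C <- makeC(matrix(c(6L, 2L), 1, 2, dimnames = list("G1", c("A", "B"))),
             c(A = 10L, B = 10L))
  sp <- makeSprime(c(A = 0.5, B = 0.5))
  # contributions 0.03 / 0.01 of G = 0.04 -> shares 0.75 / 0.25
  bd <- contributionBreakdown(C, "G1", sPrime = sp)
  expect_equal(bd$category_id, c("A", "B"))
  expect_equal(bd$share, c(0.75, 0.25))

  # single category -> one entry with share 1
  C1 <- makeC(matrix(2L, 1, 1, dimnames = list("G1", "A")), c(A = 4L))
  bd1 <- contributionBreakdown(weightedProportions(C1, makeSprime(c(A = 1))),
                               "G1")
  expect_equal(bd1$share, 1)

  # G = 0 -> empty breakdown
  C0 <- makeC(matrix(0L, 1, 1, dimnames = list("G1", "A")), c(A = 4L))
  bd0 <- contributionBreakdown(weightedProportions(C0, makeSprime(c(A = 1))),
                               "G1")
  expect_equal(nrow(bd0), 0L)

  # shares of every estimated gene sum to 1
  est <- weightedProportions(C, sp)
  expect_equal(unname(rowSums(est@contributions)), 1)
})

test_that("union proportion uses patient sets, bracketing and consistency hold", {
  patients <- list(A = sprintf("p%02d", 1:10))
  # G1 mutates p1-p3, G2 mutates p4-p5: disjoint -> union adds
  mut <- data.frame(
    category_id = "A",
    gene = c(rep("G1", 3), rep("G2", 2)),
    patient_id = c("p01", "p02", "p03", "p04", "p05"))
  ch <- new("MutationCohort", patients = patients, mutated = mut,
            meta = list())
  sp <- makeSprime(c(A = 1))
  u <- proportionTable(unionProportion(ch, c("G1", "G2"), sp))$proportion
  expect_equal(u, 0.5)  # 0.3 + 0.2, disjoint

  # identical patient sets: union equals the single-gene proportion
  mut2 <- data.frame(category_id = "A", gene = rep(c("G1", "G2"), each = 3),
                     patient_id = rep(c("p01", "p02", "p03"), 2))
  ch2 <- new("MutationCohort", patients = patients, mutated = mut2,
             meta = list())
  expect_equal(
    proportionTable(unionProportion(ch2, c("G1", "G2"), sp))$proportion,
    0.3)

  # union over one gene equals weightedProportions for that gene
  C <- conditionalMatrix(ch)
  expect_equal(
    proportionTable(unionProportion(ch, "G1", sp))$proportion,
    proportionTable(weightedProportions(C, sp))$proportion[
      rownames(C) == "G1"])
  expect_error(unionProportion(ch, character(0), sp), "nonempty")
})

test_that("union bracket: at least the max single gene, at most the sum", {
  set.seed(11)
  for (i in 1:10) {
    sc <- syntheticScenario(seed = i, nCategories = 3, nGenes = 5,
                            nStudies = 1, patientsPerCategory = 80,
                            unsequencedShare = 0, overlapFraction = 0,
                            longitudinalRate = 0, aliasRate = 0)
    co <- generateCohorts(sc, seed = 100 + i)
    rec <- filterMutationClasses(co$records)
    samp <- dedupSamples(co$samples, co$manifest)
    ch <- tallyCohort(rec, samp, co$map)
    C <- conditionalMatrix(ch)
    sp <- makeSprime(sc@shares[categoryIds(C)])
    genes <- c("GENE01", "GENE02", "GENE03")
    u <- proportionTable(unionProportion(ch, genes, sp))$proportion
    e <- proportionTable(weightedProportions(C, sp))
    singles <- e$proportion[match(genes, e$gene)]
    expect_gte(u, max(singles) - 1e-12)
    expect_lte(u, sum(singles) + 1e-12)
  }
})

test_that("subclass estimates restrict and renormalize the weighting", {
  map <- categoryMap(data.frame(
    morphology_code = c("1", "2", "3"), site_code = "*",
    category_id = c("A", "B", "C"),
    subclass = c("adenocarcinoma", "adenocarcinoma",
                 "squamous_cell_carcinoma")))
  m <- matrix(c(2L, 4L, 9L), 1, 3, dimnames = list("G1", c("A", "B", "C")))
  C <- makeC(m, c(A = 10L, B = 10L, C = 10L))
  S <- new("IncidenceVector", values = c(A = 100, B = 100, C = 300),
           normalized = FALSE)
  # two equal-incidence AC categories with c = 0.2 and 0.4 -> 0.3
  ac <- subclassEstimates(C, S, "adenocarcinoma", map)
  expect_equal(proportionTable(ac)$proportion, 0.3)
  # one-category subclass equals that column of C
  scc <- subclassEstimates(C, S, "squamous_cell_carcinoma", map)
  expect_equal(proportionTable(scc)$proportion, 0.9)
  expect_error(subclassEstimates(C, S, "malignant_melanoma", map),
               "no category")
})

test_that("pooled vs weighted: proportional sampling agrees, oversampling biases", {
  # cohort sizes exactly proportional to incidence -> pooled == weighted
  m <- matrix(c(30L, 5L, 10L, 2L), 2, 2,
              dimnames = list(c("G1", "G2"), c("A", "B")))
  C <- makeC(m, c(A = 300L, B = 100L))
  sp <- makeSprime(c(A = 0.75, B = 0.25))
  cmp <- compareUnweighted(C, sp)
  expect_equal(cmp$pooled, cmp$weighted, tolerance = 1e-12)

  # rare cancer B (10% incidence) oversampled to half the cohort: its
  # marker gene is inflated in the pooled view
  C2 <- makeC(matrix(c(5L, 90L), 1, 2, dimnames = list("MRK", c("A", "B"))),
              c(A = 100L, B = 100L))
  sp2 <- makeSprime(c(A = 0.9, B = 0.1))
  cmp2 <- compareUnweighted(C2, sp2)
  expect_gt(cmp2$pooled, cmp2$weighted)

  # gene absent everywhere: both zero
  C3 <- makeC(matrix(0L, 1, 2, dimnames = list("G0", c("A", "B"))),
              c(A = 10L, B = 10L))
  cmp3 <- compareUnweighted(C3, makeSprime(c(A = 0.5, B = 0.5)))
  expect_equal(cmp3$pooled, 0)
  expect_equal(cmp3$weighted, 0)
})

test_that("gene-set view ranks, zero-fills missing genes and truncates", {
  C <- makeC(matrix(c(3L, 1L, 0L), 3, 1,
                    dimnames = list(c("G1", "G2", "G3"), "A")),
             c(A = 10L))
  est <- weightedProportions(C, makeSprime(c(A = 1)))
  v <- geneSetView(est, c("G2", "G1", "ABSENT"), topN = 10)
  expect_equal(v$gene, c("G1", "G2", "ABSENT"))
  expect_equal(v$proportion, c(0.3, 0.1, 0))
  expect_equal(nrow(geneSetView(est, c("G1", "G2"), topN = 1)), 1L)
})

test_that("sampling patients proportional to S' pools back to G in expectation", {
  set.seed(99)
  p <- c(A = 0.3, B = 0.05)
  sp <- makeSprime(c(A = 0.7, B = 0.3))
  nTot <- 6000
  nA <- round(nTot * 0.7); nB <- nTot - nA
  mA <- rbinom(1, nA, p["A"]); mB <- rbinom(1, nB, p["B"])
  C <- makeC(matrix(c(mA, mB), 1, 2, dimnames = list("G1", c("A", "B"))),
             c(A = nA, B = nB))
  cmp <- compareUnweighted(C, sp)
  trueG <- sum(p * incidenceValues(sp))
  se <- sqrt(trueG * (1 - trueG) / nTot)
  expect_lt(abs(cmp$pooled - cmp$weighted), 4 * se)
  expect_lt(abs(cmp$pooled - trueG), 4 * se)
})
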