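---
title: "Incidence-weighted cancer gene mutation proportions"
author: "OncoProp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incidence-weighted cancer gene mutation proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OncoProp)
```

## The estimation problem

Tumor-sequencing resources report, for each type of cancer, the fraction of
sequenced patients carrying a mutation in a gene. Those per-type fractions
cannot be read as population-level frequencies, because sequencing cohorts
are not assembled in proportion to how often each cancer is actually
diagnosed: some cancers are heavily oversequenced relative to their burden,
others barely appear. OncoProp computes the population-level *mutation
proportion* of a gene — the probability that a newly diagnosed cancer
carries at least one qualifying coding mutation in it — by weighting the
per-cancer-type mutated fractions with registry incidence shares.

The core identity is a conditional-probability decomposition. Let `h` index
cancer categories on a common taxonomy, `c_gh = m_gh / n_h` the fraction of
the `n_h` sequenced patients of category `h` with a qualifying mutation in
gene `g`, and `s'_h` the share of diagnoses falling in category `h` among
the categories with sequencing data (normalized to sum to 1). Then

```
G_g = sum_h c_gh * s'_h          (in matrix form, G = C %*% S')
```

Everything else in the package exists to make the two factors commensurable
and trustworthy: a shared taxonomy so that registry records and sequencing
cohorts count the same things, a mutation-class filter and patient
deduplication so that `c_gh` is a per-patient probability, and a replicate
simulation for uncertainty.

## The taxonomy layer

Registries code every diagnosis with an ICD-O-3 morphology
(histology/behavior) code plus a site (topography) code; sequencing studies
label cohorts with free-form diagnosis names and per-sample metadata. The
`CategoryMap` bridges both: `(morphology, site) -> category` entries with a
`"*"` site wildcard, and per-study assignment rules for samples. Two
contracts are worth stating explicitly because neither input convention
forces them:

* **Lookup precedence** for registry records: an exact `(morphology, site)`
  entry always beats a wildcard entry for the same morphology. For cohort
  samples: an explicit per-sample assignment beats metadata predicates,
  which beat the study default; among metadata predicates the first
  matching rule in file order wins. These orders are total, so
  classification is deterministic.
* **Nothing is dropped silently.** Records and samples that no rule covers
  are assigned the `UNMAPPED` sentinel; the incidence table keeps their
  mass in a reserved column so its total always equals the input total, and
  the cohort tally reports how many samples it excluded. This makes the
  conservation checks (`total in == total out` at every stage) mechanical.

Subclass tags (adenocarcinoma, squamous cell carcinoma, malignant melanoma,
transitional cell carcinoma, other) live on categories, not on map rows, so
pan-subclass analyses are a filter over one taxonomy rather than a second
map.

Morphology codes are accepted in both the `8140/3` and `81403` dialects;
they are slash-normalized on both sides of every lookup.

## From mutation calls to the conditional matrix

MAF-style call files are reduced to per-patient presence/absence:

* **Class filter.** Exactly ten `Variant_Classification` tokens qualify
  (missense, nonsense, nonstop, in-frame and frameshift indel spellings),
  compared case-insensitively with space/underscore folding. Splice-site,
  fusion, silent and other non-coding classes are excluded. The filter is a
  whitelist, so unknown tokens are dropped, never accidentally counted.
* **Longitudinal rule.** When a patient was sampled repeatedly within a
  study, only the first sample (minimum sample order, ties by sample id)
  counts.
* **Cross-study rule.** When the same patient appears in several studies,
  only the most recently dated study's calls count; a date tie is broken by
  study id (lexicographically greatest wins) so the result is
  deterministic. Dates come from a per-study manifest, since call files do
  not carry them.
* **Symbol standardization.** Aliases are mapped to canonical symbols
  before tallying, so two aliases of one gene in one patient collapse to a
  single indicator.
* **Denominators.** `n_h` counts *all* sequenced patients of the category,
  not only mutated ones. This is why the tally takes a sample sheet in
  addition to the call files: patients whose tumor carries no qualifying
  mutation never appear in a MAF, yet they belong in the denominator.
  A patient assigned to two categories is an invariant breach and raises an
  error rather than being resolved arbitrarily.

The result is a `ConditionalMatrix`, a `SummarizedExperiment` with assays
`mutated` (m_gh) and `cond` (c_gh) and per-category `nSamples` in its
column data. Genes supplied in a gene list but never observed get explicit
zero rows, so their estimate is 0 with a confidence interval, not missing.

## Weighting, restriction and reporting conventions

The incidence vector S is restricted to the categories with sequencing
data and renormalized to sum to 1 (S'). The coverage fraction — the share
of all incidence that the sequenced categories represent — is computed and
reported alongside every analysis, because the estimate implicitly assumes
the sequenced mass approximates the unsequenced remainder. Alignment
between C and S' is strict: identical category vectors in identical
(lexicographic) order, otherwise an error. There is no silent reindexing.

Internally every share and proportion is a fraction summing to 1;
percentages appear only at the reporting layer (one decimal place in the
human-readable tables, full precision in the machine-readable TSV/JSON).
Ranking ties are always broken lexicographically (by category id or gene
symbol).

Three derived analyses share the machinery:

* **Contribution breakdowns**: `w_gh = c_gh * s'_h / G_g` says which
  cancer types account for a gene's mutated cases; rows sum to 1 whenever
  `G_g > 0`.
* **Union proportions** for a gene set are computed from patient sets
  (`u_h` = fraction of patients mutated in *any* listed gene), never from
  C, because co-mutation makes the union strictly smaller than the sum of
  single-gene values; requesting a union from C alone is an error by
  design.
* **Pooled-vs-weighted comparison**: `pooled_g = sum_h m_gh / sum_h n_h`
  is the incidence-ignorant value a pooled pan-cancer analysis would
  report; the package reports both and their difference so the effect of
  the weighting is visible.

## Uncertainty

Confidence intervals come from a parametric replicate simulation. For each
(gene, category) cell, 2,000 replicate mutated counts are drawn from a
Poisson law centred on the observed numerator m_gh; each replicate count is
divided by the fixed denominator n_h and the replicate matrix is pushed
through the same weighting as the point estimate; per-gene 95% intervals
are the 2.5th/97.5th percentiles (linear interpolation) of the replicate G
values. Three deliberate numerical choices:

* The Poisson perturbation acts on the *count* m_gh with n_h held fixed — a
  Poisson law needs a count-valued mean, and the sequencing counts (tens of
  thousands of patients) dwarf the registry counts (millions of
  diagnoses), so the incidence shares are treated as noise-free.
* Replicate proportions are clipped at 1, which matters when m_gh is close
  to n_h; without clipping a replicate "fraction" could exceed 1.
* The generator is seeded explicitly and the seed is recorded in every
  report; the same seed reproduces the replicate set bit for bit.

For cells with very small m_gh the percentile interval is discrete and can
sit asymmetrically around the point estimate; intervals are clamped to
bracket the point estimate, and calibration is checked empirically (see
below) rather than assumed.

## What the synthetic generator emulates — and what it does not

`syntheticScenario()` fixes a complete ground truth: category shares,
per-category per-gene Bernoulli mutation probabilities, a category map with
ICD-O-3-style codes (including one wildcard-mapped category), dated
multi-study cohorts, and nuisance processes — cross-study patient overlap,
longitudinal follow-up samples, alias gene symbols, non-qualifying mutation
classes. `generateRegistry()` draws diagnoses multinomially;
`generateCohorts()` draws patient-level presence and expands it to
MAF-style rows (1–3 rows per present gene, mixed-case class spellings),
writing files in exactly the dialects the readers accept.

The default scenario is the package's reference condition: six sequenced
categories with shares 0.30/0.20/0.15/0.12/0.10/0.06 plus an unsequenced
category at 0.07 — so the sequenced categories cover 93% of incidence,
matching the coverage regime the estimator is meant for; 40 genes; three
studies; 2,000 patients per category; overlap, longitudinal and alias
rates of 0.1 each. Mutation probabilities are drawn once per scenario
seed: background U(0.005, 0.05), one elevated driver category per gene
U(0.08, 0.35), and the first gene set to 0.8 in the smallest category — a
marker for a rare cancer dominated by one driver, which is the
configuration that separates pooled from weighted estimates most sharply.
The excluded-class rate defaults to 0: the class filter is exercised by
dedicated adversarial scenarios (rate 1 must zero every tally), while the
default scenario keeps the analytic truth `G_g = sum_h p_gh pi_h` exact so
recovery can be judged against binomial standard errors without a
thinning correction.

Within-study draws are independent Bernoulli per gene; duplicated patients
are re-drawn independently per study (the dedup rule decides which draw
survives). What the generator does **not** emulate: mutational signatures
or sequence context, co-mutation correlation (genes are independent unless
probabilities are supplied), hypermutators, panel-vs-exome coverage
differences, and cohort selection biases that act *within* a category
(e.g. stage-skewed sequencing). Passing tests therefore demonstrate that
the pipeline's bookkeeping and weighting are correct under the model the
estimator assumes — not that real cohorts satisfy that model.

Problem sizes used in the validation suite were chosen for stable
statistics at interactive runtimes: estimator-vs-oracle on 1,000 random
small instances; recovery on the full default scenario (12,000 patients);
interval calibration on 500 regenerated cohorts (4 categories, 8 genes,
500 patients/category, 2,000 replicates each), where the empirical
coverage of the nominal 95% intervals lands near 96% — slightly
conservative, as expected when a Poisson law (variance m) stands in for a
binomial one (variance m(1 − p)).

## Degenerate inputs and edge behaviour

* Empty map: loads with a warning; everything classifies to `UNMAPPED`.
* Empty registry input: empty table with total 0.
* No overlap between S and the sequenced categories: an error — no
  estimate is possible, and inventing one would hide a broken map.
* A subclass with no sequenced category: an error, for the same reason.
* `G_g = 0`: the contribution breakdown is empty (shares are undefined).
* Poisson mean 0: all replicates are 0 and the interval is degenerate at 0.

## Known limitations

* The estimate extrapolates from the covered fraction of incidence to all
  cancers; the coverage fraction is printed with every run so the size of
  that assumption is visible, but nothing corrects for it.
* Incidence weighting uses raw diagnosis counts — no age standardization,
  no rates per population, no mortality or prevalence weighting.
* The curated category map is an input, not a product of the package; the
  bundled maps are small synthetic illustrations.
* Patient identity across studies relies on shared identifiers (or barcode
  prefixes); patients re-identified under unrelated ids cannot be
  deduplicated.
* Copy-number changes, fusions, splice-site and other intronic mutations
  are out of scope by construction of the class whitelist.

## A compact worked example

```{r example, eval = FALSE}
sc <- syntheticScenario(seed = 1)
reg <- generateRegistry(sc, totalCount = 1e6, seed = 1)
co <- generateCohorts(sc, seed = 2)

S <- incidenceVector(reg$table)
rec <- filterMutationClasses(co$records)
samp <- dedupSamples(co$samples, co$manifest)
rec <- rec[paste(rec$study_id, rec$sample_id) %in%
             paste(samp$study_id, samp$sample_id), ]
rec <- standardizeGeneNames(rec, co$synonyms)
cohort <- tallyCohort(rec, samp, co$map)

C <- conditionalMatrix(cohort)
sPrime <- restrictAndNormalize(S, categoryIds(C))
coverageFraction(S, categoryIds(C))
est <- estimateWithCI(C, sPrime, nReps = 2000, seed = 3)
est
contributionBreakdown(est, "GENE01")
```

The same flow, driven by a YAML configuration over files on disk, is
available as `runPipeline()`; it adds staged QC logging, conservation
checks and a deterministic report bundle.
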