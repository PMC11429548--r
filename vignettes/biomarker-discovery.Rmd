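---
title: "Plasma metabolomics biomarker discovery for pulmonary neuroendocrine neoplasms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasma metabolomics biomarker discovery for pulmonary neuroendocrine neoplasms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nenplasma)
```

## The analysis problem

Pulmonary neuroendocrine neoplasms (NENs) — carcinoid tumors, small-cell
lung carcinoma (SCLC) and large-cell neuroendocrine carcinoma (LCNEC) —
are diagnosed late because tissue is hard to obtain. Targeted plasma
metabolomics offers a liquid-biopsy alternative: a fixed panel of
metabolites (amino acids, biogenic amines, organic acids, sugars,
acylcarnitines, glycerophospholipids, sphingomyelins) is quantified in
micromolar concentrations by LC-MS/MS, and the question becomes a
statistical one — which metabolites separate each tumor subtype from
healthy controls (and from the non-small-cell lung cancer outgroup), and
how well does a sparse panel of them predict subtype membership?

`nenplasma` implements that discovery workflow end to end:

1. **Preprocessing** — drop metabolites missing in more than half the
   samples, impute the remainder, z-score, compute fold changes and
   cohort demographics.
2. **Marker selection** — a bootstrap-resampled Mann–Whitney procedure
   with a Bonferroni-corrected *median* p-value decision rule.
3. **Classification** — class-weighted lasso/ridge/elastic-net logistic
   models, tuned by repeated stratified cross-validation with backward
   elimination.
4. **Metabolite-set enrichment** — a generalized-linear-model global
   test (Q statistic) with permutation p-values over a GMT pathway
   library, restricted to non-lipid markers.
5. **Reporting** — volcano tables, Venn overlaps across subtypes, a
   Ward-clustered heatmap, JSON model reports and a run manifest.

Because the motivating cohort is not publicly available, the package
ships a first-class synthetic cohort generator that emulates the study
design, so every stage is testable without any download.

## The synthetic cohort generator

`cohort_design()` encodes the emulated study: five groups of 71 healthy
controls, 50 carcinoids, 40 SCLC, 30 LCNEC and 466 NSCLC (657 samples,
120 NEN cases), a 166-metabolite panel, and a table of planted per-group
effects.

Concentrations are simulated **log-normal**: for metabolite $j$ in a
sample of group $g$,

$$\log C_{ij} = \mu_j + \log(2)\,\delta_{jg} + \varepsilon_{ij},\qquad
\varepsilon_{ij}\sim N(0, \sigma_j^2),$$

where $\mu_j$ is the baseline log-concentration (log µM), $\delta_{jg}$
the planted log2 fold change relative to healthy, and $\sigma_j = 0.35$
by default. Log-normality keeps concentrations positive and
right-skewed, and makes effects multiplicative: the case/control ratio
of geometric means converges to $2^{\delta}$, which the fold-change
stage then estimates. The within-group log-SD of 0.35 yields
standardized effect sizes of about $2$ per unit of $|\delta|$ — strong
but realistic for the clearly separated markers this workflow is
designed to find.

Planted effects follow the reported marker biology: fumaric acid and
lysoPC a C16:0 altered in all three subtypes; glucose raised only in
carcinoids, N-acetylputrescine only in SCLC, spermine only in LCNEC;
four markers shared by carcinoids and LCNEC and two by carcinoids and
SCLC; NSCLC carries a partly overlapping generic lung-cancer signature
so the NEC-versus-NSCLC contrasts are sparse. Magnitudes are fixed at
$|\delta| \in [1, 1.5]$. The resulting per-subtype marker counts (18
carcinoid, 5 SCLC, 10 LCNEC, 23 in the union) reproduce the study's
arithmetic by construction.

**Missingness** is modeled per metabolite with two mechanisms, because
targeted assays lose values for different reasons and the true mechanism
is usually unknown:

* `"mcar"` — each cell missing independently with probability $p$;
* `"lod"` — left-censoring: the lowest $p$-fraction of that metabolite's
  draws is removed, emulating values below the limit of detection.

Exactly 13 panel metabolites carry $p = 0.7$ (mechanism `"lod"`), so the
standard "more than 50% missing" filter reduces the panel from 166 to
153 — the same arithmetic as the emulated assay. All other metabolites
use a background $p = 0.05$.

**Covariates** (age, sex, smoking, BMI, stage) are drawn from per-group
distributions matching the published cohort tables. By default they do
*not* influence concentrations — there is no confounding, so passing
selection tests demonstrates calibration and power, not robustness to
confounders. `cohort_design(confounded = TRUE)` adds a deliberate
smoking effect on a few amines for robustness experiments.

What the generator does **not** emulate: batch effects and instrument
drift, correlated metabolite blocks (noise is independent across
metabolites given the group), non-normal log-scale noise, and
covariate-driven concentration differences (unless requested). Green
tests on this cohort therefore validate the statistical machinery under
its stated assumptions; they do not certify performance on real plasma.

## Marker selection: bootstrap Mann–Whitney with a median-p rule

For a case group and a control group, each of `n_boot` iterations
(default 10,000) draws `resample_size` samples **with replacement,
independently from each group**, where `resample_size` defaults to the
smaller group's size — the two resampled groups are balanced. A
two-sided Mann–Whitney test is run per metabolite on each resample, and
the U statistic and p-value are recorded. A metabolite is flagged when
the **median** p-value over iterations falls below the Bonferroni
threshold $\alpha/m$ (0.05/153 ≈ 0.0003 at the default panel size).

Numerical choices:

* The exact null distribution of U is used when both samples have at
  most 8 observations and no ties; otherwise the normal approximation
  with midranks, tie-corrected variance and continuity correction. The
  exact path never sees ties (it falls back to the approximation). The
  implementation is validated against exhaustive rank-set enumeration
  for all sizes up to (7, 7) and against the reference rank-sum test.
* A metabolite with no observed values in a resampled group contributes
  p = 1 to that iteration (conservative) rather than being dropped.
* Resampling indices are drawn from a single seeded RNG stream per
  `bootstrap_select()` call; the sampling does not depend on the data
  values, so results are identical on raw and z-scored input (the test
  is rank-based), and fully reproducible from the seed. Execution is
  single-threaded; reproducibility does not depend on a scheduler.
* Direction calls (`increased`/`decreased`) come from the fold change
  FC = Y/X of raw concentrations, where Y and X are the case and
  control **arithmetic means** over observed values (the median is
  available as an option). FC is computed on raw, never z-scored, data.
* Subsampling without replacement is available (`replace = FALSE`) but
  is not the default.

Under the global null with the default design (153 metabolites, 120
pooled cases vs 71 controls), the median-p rule at 0.05/153 flags
nothing in almost every run — the suite asserts 0 flags in at least 19
of 20 seeded runs. A single marker with $|\delta| = 1$ at sizes 30 vs 71
is flagged in at least 9 of 10 seeded runs at `n_boot = 2000`.

## Classification: weighted regularized logistic models

Features are the pre-selected metabolites, imputed (half of the observed
minimum per metabolite) and z-scored jointly over the two groups being
modeled. The model is a binomial regression with the elastic-net
penalty

$$\lambda\left[\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\right],$$

fit by glmnet with an unpenalized intercept and no internal
re-standardization. λ values are only meaningful relative to a stated
parameterization; this package uses glmnet's, with the weighted
log-likelihood scaled by the total weight. Per-sample weights
$w_c = N/(2 n_c)$ balance the two classes to a 1:1 effective ratio.

The grid is $\alpha \in \{0, 0.5, 1\}$ ×
$\lambda \in \{0.001, 0.01, 0.1, 1, 10\}$, scored by stratified 5-fold
cross-validation repeated 10 times (50 held-out fold estimates of
accuracy, sensitivity and specificity at the 0.5 probability
threshold). The winning pair has the highest mean CV accuracy; exact
ties go to the larger λ, then the larger α — deterministic and
parsimony-favoring. Stratification preserves the class ratio in every
fold, the defensible default at 30-vs-71 imbalance.

The reported 95% CI is mean ± 1.96 × SD of the fold-level accuracies —
a presentation convention, not a formal coverage statement. The winning
model is refit on all samples and also evaluated on them; that
confusion matrix is labeled **resubstitution** throughout, because
evaluating on the training cohort overstates performance. The positive
class is always the cancer group, so sensitivity is the cancer
detection rate.

`backward_eliminate()` iteratively removes the feature with the
smallest absolute standardized coefficient in the current best model,
stops when a removal costs more than 0.5 accuracy percentage points
(or one feature remains), and returns the smallest panel within that
tolerance of the best accuracy. The tolerance is configurable; with
very small cohorts the CV noise can exceed it, in which case a larger
value is appropriate.

## Enrichment: the global test

For a pathway with $m$ matched metabolites and z-scored data matrix
$X$, with binary outcome $y$ and intercept-only null mean
$\hat\mu = \bar y$,

$$Q = \frac{(y-\hat\mu)^\top X X^\top (y-\hat\mu)}{m\,\hat\mu(1-\hat\mu)}.$$

Q is nonnegative, invariant to swapping the class labels, and — thanks
to the $1/m$ normalization — unchanged when every column is duplicated.
Significance uses permutation of the class labels with the add-one
correction $p = (1 + \#\{Q^\pi \ge Q\})/(1 + n_\mathrm{perm})$, which
is robust at group sizes as small as 30, never exactly zero, and
trivially testable for null uniformity; asymptotic p-values are not
used.

Lipid-class metabolites (acylcarnitines, lysoPCs, PC aa/ae,
sphingomyelins) are excluded from the query by default, restricting
enrichment to the non-lipid markers; pathway membership is matched on
canonicalized names (case-folded, punctuation-stripped). The packaged
99-set GMT library is a **synthetic** SMPDB-style fixture (citric acid
cycle, Warburg effect, urea cycle, purine metabolism, and so on) built
for this package; it is not a copy of SMPDB, and real GMT exports can
be supplied instead.

## Reporting and determinism

`run_pipeline()` executes preprocessing, the six default comparisons
(each subtype and the pooled NENs vs healthy; SCLC and LCNEC vs NSCLC),
models and enrichment for the versus-healthy contrasts, the Venn
partition, and the clustered heatmap (Euclidean distance, Ward
`ward.D2` linkage, deterministic leaf order with ties broken by input
order — a conventional default, chosen once). Every tabular artifact is
TSV, models and the manifest JSON; a configuration plus root seed fixes
every output byte, and the manifest records a hash of the
analysis-relevant configuration. Stage failures abort with the stage
name, leaving an `INCOMPLETE` marker in the output directory.

## Problem sizes used by the tests

The full-scale procedure (10,000 bootstrap iterations, 9,999
permutations) is the user-facing default. The package's own test suite
and the acceptance script run the same code at reduced scale — 2,000
bootstrap iterations, 999 permutations, and 150–200 iterations for
byte-identity checks — sizes at which every selection decision and
calibration property asserted above is stable across seeds.

## Known limitations

* The generator's independence assumptions (no metabolite correlation,
  no batch structure, no confounding by default) are stated above; the
  bootstrap's claimed robustness to batch effects is not exercised.
* Resubstitution metrics are reported for fidelity to the emulated
  workflow but should never be quoted as generalization performance;
  the CV estimates are the honest ones, and even they are selection-
  biased by the grid search.
* The median-of-bootstrap-p decision statistic has no closed-form null
  distribution; its calibration here is empirical (simulation under the
  global null), not analytic.
* Enrichment p-values are marginal per pathway; no multiplicity
  correction is applied across the 99 sets, matching the emulated
  analysis (significance at p < 0.05 per set).
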