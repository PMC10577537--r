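---
title: "The intersection clock: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The intersection clock: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Epigenetic clocks predict age from DNA methylation levels at a fixed panel of
CpG sites. That works well for array data, where every sample measures the
same probes, but breaks down for bisulfite sequencing (RRBS/WGBS): which CpGs
are covered at usable depth varies strongly between samples, protocols, and
studies, so a clock trained on one fixed site panel finds many of its sites
missing in a new dataset. Imputing those sites injects bias exactly where the
clock is most sensitive.

The intersection clock sidesteps missingness instead of imputing it. For each
test sample **separately**:

1. intersect the CpG sites of the training cohort with the sites covered in
   that sample;
2. restrict the training matrix and the test sample to the intersected sites;
3. train an ensemble of penalized linear clocks on the restricted training
   set by fivefold cross-validation (five clocks, each fit on four fifths of
   the samples);
4. predict the test sample with each clock and report the **mean of the five
   predictions** as its epigenetic age.

Every clock is trained only on sites the test sample actually measures, so no
clock site is ever missing at prediction time. The price is that each test
sample gets its own retrained ensemble, and that predictions from different
intersections are not built from literally identical models — which is why
the per-sample cross-validated performance (`cv_r`, `cv_medae`) is reported
alongside each prediction: it measures, on the training cohort restricted to
that sample's intersection, how much age signal that particular site set
carries.

## The model

Each clock is an elastic-net linear regression of chronological age (years)
on CpG methylation percentages (0–100):

$$\hat a(x) = \beta_0 + \sum_{s \in S} \beta_s x_s,$$

with the penalty $\lambda \left( \alpha \|\beta\|_1 + \tfrac{1-\alpha}{2}
\|\beta\|_2^2 \right)$, fit by `glmnet`. The mixing parameter is fixed at
$\alpha = 0.5$; the total penalty $\lambda$ is chosen per fit by inner
10-fold cross-validation over the solver's default lambda path, taking the
minimum-mean-squared-error lambda (not the one-standard-error rule).
Predictors are standardized internally by the solver (its default);
coefficients are reported back on the percent scale. Ages enter untransformed
— no log-linear juvenile transform — and predictions are **not** clipped at
zero: group contrasts for rejuvenation depend on relative values, and
clipping would bias group means.

## Data model and I/O conventions

A sample's data is a set of strand-collapsed CpG calls: methylated and
unmethylated read counts per site, keyed by chromosome and the **1-based
position of the plus-strand cytosine** of the CpG dinucleotide. Reading a
Bismark-style CpG report sums a plus-strand record at position $p$ with a
minus-strand record at $p+1$; an unpaired minus-strand record is kept and
re-keyed to $p$ (the summing rule is stated for paired records; keeping
re-keyed singletons is this package's choice, and it is what makes strand
collapse idempotent). The coverage filter (default: at least 5 reads) is
applied **after** collapsing, because the filtered entities are CpG sites,
not per-strand calls. Methylation percentages are always computed from the
collapsed counts, `100 * meth / (meth + unmeth)`.

Processed public tables that store a methylation fraction and a coverage
rather than counts are converted by rounding half-up (`meth = floor(f*c +
0.5)`); dialects that carry counts are preferred when available. All basis
conversion (0-based tables get `+1`) happens at the reader boundary so that
everything downstream speaks one convention. Chromosome-name normalization
(`chr1` vs `1`) is an explicit reader option, default **off**: a naming
mismatch should fail loudly as an empty intersection error, not silently
shrink the intersection.

Assembly lifting is a pluggable interface (identity map, or a lookup table
from a 4-column TSV, e.g. exported from an external liftover run). Unmapped
sites are dropped with a counted report by default; a strict mode raises
instead. Many-to-one lifts raise a collision error — they signal a bad map.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `min_coverage` | 5 | reads | per-site coverage floor, after strand collapse |
| `alpha` | 0.5 | — | elastic-net L1/L2 mix |
| `inner_splits` | 10 | folds | inner CV for lambda selection |
| `outer_folds` | 5 | folds | clocks per ensemble |
| `min_intersection` | 10000 | sites | admission threshold for a test sample |
| `rng_seed` | 1 | — | master seed for all fold draws |

A test sample whose intersection falls below `min_intersection` is marked
not admitted (`admitted = FALSE`) and receives no prediction — this is a
reported outcome, not an error.

## Randomness and reproducibility

The outer fold partition is a seeded random split of the training samples
into near-equal fifths, drawn over the samples **sorted by id**, so fold
membership depends only on the id set and the seed, never on input row
order. By default each test sample's partition is drawn from a stream
derived from the master seed and a stable hash of the sample **id** (not its
position in the cohort), so predictions are invariant to cohort order and to
adding or removing other samples. The whole pipeline is bit-reproducible
under a fixed seed.

`share_partition = TRUE` switches to one partition drawn once from the
master seed and reused for all test samples; the per-sample re-draw is the
default because the restricted training set differs per sample, but the
shared mode is useful for simulation studies — with it, two test samples
with identical intersections provably receive identical ensembles, and
`predict_cohort()` exploits that by caching the fitted ensemble per distinct
site set.

## Group comparisons

Rejuvenation calls are two-sided t-tests on predicted ages between two
groups of admitted samples: Student's equal-variance test by default (Welch
behind a flag), or a paired test on per-pair differences when samples are
matched (e.g. fibroblast lines and their derived iPSC lines, paired by
donor). P-values are reported raw, with the conventional star bands
(`ns` > 0.05 ≥ `*` > 0.01 ≥ `**` > 0.001 ≥ `***` > 1e-4 ≥ `****`; upper
edges inclusive). No multiple-testing correction is applied across
comparisons. Only admitted samples enter the means and tests.

## The synthetic-data generator

The generator (`generator_spec()`, `generate_training_cohort()`,
`generate_test_sample()`, `generate_rejuvenation_cohort()`) emulates the
features the clock relies on:

- a fixed panel of `n_sites` CpGs (default 20000) with baselines uniform in
  10–90%;
- `n_informative` sites (default 300) whose latent percent changes linearly
  with age, slopes of random sign with magnitude uniform in 0.1–0.5 percent
  points per year;
- Gaussian latent noise (`noise_sd`, default 2 points), clipped to
  \[0, 100\] **before** count sampling so the binomial probability is valid;
- read depths drawn negative-binomially (mean 30, size 5, capped at 200) —
  overdispersed enough that the five-read filter occasionally bites;
  training samples are floored at depth 5 so the full panel survives table
  assembly;
- per-test-sample missingness, site-wise independent by default, with a
  block mode (contiguous chunks) to mimic RRBS fragment structure.

Defaults mirror the training cohort the method targets: 182 blood samples
with ages spanning roughly 4–40 years.

What the generator does **not** emulate: genome-wide CpG density and
island/shore structure, cell-composition shifts with age, correlated
(co-methylated) site blocks, SNP-at-CpG artifacts, batch effects, and
nonlinear age trajectories. Passing tests on this generator therefore
demonstrate that the workflow is implemented correctly and recovers linear
age signal under realistic sampling noise — not that the clock attains any
particular accuracy on real tissues.

## Validation scales and numerical choices

The test suite validates the full-scale workflow on one synthetic cohort of
182 samples by 20000 sites (300 informative, noise sd 2): pooled out-of-fold
performance is checked against `cv_r >= 0.9` and `cv_medae <= 3` years, and
the 10000-site admission boundary is checked exactly at 9999 vs 10000
intersected sites. Power and type-I behaviour of the group comparison are
simulated at a reduced scale — an 80-sample by 1000-site training cohort
(150 informative sites, admission threshold 200) backing cohorts of 8 vs 8
test samples — chosen because at that scale the ensemble is well calibrated
(a designed 10-year latent gap yields a detected gap of ~8.5 years);
markedly smaller training designs under-calibrate the clock (strong
shrinkage toward the training mean), which is a property of the design, not
of the workflow. With a 10-year gap the comparison rejects at 0.05 in
essentially all replicates, and with no gap the rejection rate sits at the
nominal level.

Numerical details worth knowing:

- fraction-to-count conversion rounds half-up, so `0.5` at coverage 9 gives
  5 methylated reads;
- ties in lambda selection are resolved by the solver (first minimum on the
  path);
- a constant (zero-variance) predictor column is handled by the solver and
  simply receives a zero coefficient; an all-constant **age** vector is an
  error;
- the ensemble mean is an exact arithmetic mean, so
  `predicted_age == mean(fold_predictions)` to machine identity;
- intersections and column orders are sorted by chromosome string (C
  locale), then numeric position, everywhere, which is what makes outputs
  permutation-invariant.

## Known limitations

- Elastic-net fitting needs at least two intersected sites and, per fold, at
  least `inner_splits + 1` training samples; far smaller training cohorts
  than ~40 samples leave too few samples per inner fold for stable lambda
  selection.
- The per-sample retraining cost is one `cv.glmnet` per outer fold per test
  sample (seconds to ~a minute per sample at 182 x 20000); cohorts of
  identically covered samples can amortize this only in `share_partition`
  mode.
- The lookup-table assembly map cannot express strand flips or indel-aware
  remapping; it is a carrier for externally computed lifts, not a liftover
  engine.
- Predictions for latent ages outside the training range extrapolate
  linearly and inherit the usual shrinkage toward the training mean;
  negative predictions are possible and intentionally not clipped.
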