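---
title: "Methylation haplotype blocks, six block measurements, and a blood-based diagnostic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplomet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomet)
```

`haplomet` analyses read-level bisulfite methylation haplotypes: it
calls methylation haplotype blocks (MHBs) from methylation linkage
disequilibrium, summarises each block with six read-pattern
measurements, funnels those measurements into a marker set, and trains a
random-forest classifier that scores a blood sample's likelihood of
coming from a patient with a malignant thyroid nodule. This vignette is
the package's account of the methods: the statistics, the tunable
parameters, the numerical conventions, and the design choices that were
genuinely open — plus what the synthetic test-bed does and does not
establish.

## Input model and coordinates

The unit of data is a read-level haplotype record: `(chrom, start, end,
pattern, count, strand)` with a 0/1 `pattern` giving the methylation
state of each covered CpG in genomic order. All coordinates are 0-based
half-open (BED convention) and a CpG is addressed by the position of its
C on the forward strand; reverse-strand reads are assumed already
projected onto forward-strand CpG coordinates by the upstream extractor,
so the strand column is carried but ignored by every measurement. When a
reference CpG set is supplied, the parser enforces that a record's
pattern length equals the number of reference CpGs inside `[start, end)`
— this catches extractor/reference mismatches early, at the line level.

## Block calling

For two CpGs the package computes r², the squared Pearson correlation of
the two binary methylation states across the reads covering both sites,
weighting each distinct read pattern by its multiplicity. This is the
methylation analogue of genetic linkage disequilibrium: fully
co-methylated or co-unmethylated reads give r² = 1, independent sites
give r² ≈ 0. The estimate is *flagged undefined* — not set to zero —
when fewer than `min_pairs` (count-weighted) reads cover both sites or
when either site is constant across them; treating a degenerate pair as
evidence against a block, rather than as r² = 0 noise, is the
conservative choice and means a flagged pair always terminates a block.

Calling proceeds in two stages:

1. **Candidate runs.** Reference CpGs are segmented into maximal runs in
   which every adjacent pair is ≤ `max_gap_bp` apart *and* jointly
   covered by at least one read. RRBS coverage is patchy; restricting
   the search to runs avoids testing pairs no fragment can span.
2. **Greedy maximal extension.** Within a run, consecutive-pair r² is
   computed left to right, and maximal stretches in which every
   consecutive pair has defined r² ≥ `r2_min` are emitted as blocks if
   they contain ≥ `min_cpgs` CpGs.

Only consecutive pairs are tested (not all pairs within a block): this
is the standard choice for LD-style block calling, it is what the greedy
extension naturally controls, and the unit tests verify that the greedy
result coincides with an exhaustive search over all contiguous sub-runs,
maximal by inclusion, on small cases.

Defaults — `r2_min = 0.5`, `min_cpgs = 3`, `min_pairs = 10`,
`max_gap_bp = 200` (bp) — are conventional values for methylation-LD
block calling; all are exposed in the configuration. Blocks are called
once on the pooled discovery-cohort reads, then frozen
(`write_regions_bed()` / `mhb_set_from_regions()`) and reused for every
downstream cohort, mirroring the train-once-apply-downstream structure
of the modeling stages.

## The six measurements

Let a block have L CpGs and let each overlapping read contribute its
pattern *clipped* to the block CpGs it actually covers (a contiguous
index range; co-methylation is only ever measured where it was observed,
never imputed across gaps). For substring length l, let P(Mₗ) be the
count-weighted fraction of fully methylated length-l contiguous
substrings among all length-l substrings of the clipped patterns,
enumerated within reads only. With weights wₗ = lᵏ:

- **MHL** = Σₗ wₗ P(Mₗ) / Σₗ wₗ at k = 1; **UMHL** is identical with
  fully *un*methylated substrings — the identity
  UMHL(x) = MHL(complement(x)) holds for any k and is property-tested.
- **MHL3 / UMHL3**: the same loads at k = 3. Cubic weights up-weight
  long concordant stretches much more aggressively than linear ones,
  giving a second operating point on the haplotype-length axis. The
  exact alternative weighting is a design choice here (the exponent is a
  parameter, recorded in the matrix metadata, so another reading is one
  flag away).
- **AMF**: methylated CpG calls over all CpG calls — the read-weighted
  analogue of the classical beta value.
- **PDR**: among reads whose clipped pattern covers at least
  `pdr_min_cpgs = 3` CpGs, the count-weighted fraction containing both
  a 0 and a 1. The floor keeps one- and two-CpG fragments — which can
  hardly be discordant — from diluting the signal; blocks have ≥ 3 CpGs
  by calling, so fully covering reads are always eligible. No eligible
  read yields an explicit missing value, never 0.

The sum over l runs over exactly the lengths with at least one observed
substring, in both the numerator and the normaliser: a block observed
only through short fragments is normalised over the lengths it could
have shown, not over an unobservable maximum. Note MHL ≤ AMF is *not* an
identity and is not asserted anywhere; for single-CpG blocks
AMF = MHL = 1 − UMHL, which is tested.

Coverage is reported as the mean per-CpG read depth over the block's L
CpGs (the "X" unit), not as a read count — a read covering half a block
contributes half as much.

`build_metric_matrix()` computes all six measurements for every
(sample, block) pair in one vectorized pass (run-length encoding of each
distinct clipped pattern, then grouped matrix aggregation); the test
suite checks it cell-for-cell against the per-block functions and checks
those against a naive substring enumerator, to 1e-12.

## The marker funnel

1. **Coverage filter** — a block is kept iff
   `min_cov ≤ coverage < max_cov` holds in at least `min_frac` of the
   discovery samples (defaults 10X, 500X, 0.8; lower bound and fraction
   inclusive, upper bound exclusive).
2. **Screen** — per block, all six measurements are tested MTN vs BTN
   with the Mann–Whitney U test and the lowest-p measurement represents
   the block; blocks pass at p < `alpha` (default 0.001, strict).
   Equal p-values are broken by a fixed measurement precedence (AMF,
   MHL, UMHL, MHL3, UMHL3, PDR) so the screen is deterministic. The
   test uses the exact null distribution when both groups have ≤ 8
   values and no ties, and the tie-corrected normal approximation with
   continuity correction otherwise; complete ties return p = 1.
   Screening happens on observed values (pairwise deletion) and
   imputation happens afterwards on the screened matrix — the order in
   which the steps are quoted in the modeling recipe. Because the six
   measurements of one block are correlated, min-p selection inflates
   the per-block pass rate slightly above `alpha`; the continuity
   correction is conservative in the extreme tail and largely offsets
   this, and the permutation-null calibration run (5,000 null blocks)
   checks the realised rate against binomial bounds.
3. **KNN imputation** — missing cells are completed as the mean of the
   `k = 5` nearest rows by masked Euclidean distance
   (d = sqrt(p/|S| · Σ_{j∈S}(xᵢⱼ−xᵣⱼ)²) over co-observed columns S).
   In fit mode the discovery matrix is its own reference (no
   self-donation); each later sample is imputed *one at a time* against
   the pooled discovery rows, so validation samples never inform each
   other.
4. **RFECV** — recursive feature elimination with stratified k-fold
   cross-validation (default 10 folds, step 1, AUC scoring): the
   current set is CV-scored, the least Gini-important features of a
   full-data forest are dropped, and the retained size maximises the
   mean CV score, ties going to the smaller set. The full per-size score
   log is kept in the result. If fewer than `min_markers = 5` blocks
   pass the screen the 5 smallest-p markers are used (with a warning) so
   the downstream stages remain defined — this matters only for
   null-like data.

## Classifier, cutoff, evaluation

Markers are z-scored with the *population*-SD convention (1/n), fitted
on discovery and frozen; a constant marker is an error naming the
column, never a silent division. The random forest (500 trees, balanced
per-class bootstrap sampling) chooses `mtry` from a small grid —
sqrt(p) and p/3 — by stratified 10-fold CV AUC, ties to the first grid
row, then refits on all discovery rows.

The decision threshold is derived by 3 repetitions of stratified 5-fold
cross-validation: each held-out fold is scored by a pipeline refit on
the remainder and its Youden-optimal threshold recorded; the cutoff is
the mean of the 15 fold thresholds (all logged). The Youden search
maximises J(t) = sensitivity(t) + specificity(t) − 1 under the call rule
*score ≥ t is positive* (the boundary side is a convention, recorded
here), over the midpoints of adjacent distinct scores plus the two
boundary candidates, ties to the smallest t; an exhaustive-scan oracle
confirms the search in tests. Averaging the per-fold optimal
*thresholds* (not the J values) is the natural reading of using "the
average Youden index … as the cutoff", and is stated prominently because
the two are easy to conflate.

Evaluation reports sensitivity, specificity, PPV, NPV and accuracy as
full-precision percentages (rounded to 2 decimals only when printed),
with empty denominators flagged undefined rather than coerced to 0. AUC
uses the rank (Mann–Whitney) formulation with midrank ties — identical
to the trapezoidal ROC area and checked against a pairwise brute force —
and its CI is a stratified bootstrap percentile interval (2,000
resamples, seeded; the method is recorded in the output because CI
conventions differ). The ultrasonography comparator is binarized at
TI-RADS ≥ 4 — the triage boundary at which a confirmatory test would be
ordered — and is configurable; subgroup strata are TI-RADS ≥ 4, = 4,
= 5, and nodule size ≤ 10 mm vs > 10 mm (micronodule boundary
inclusive). The per-group sample-size helper implements
n = ⌈z²P(1−P)/d²⌉ (z the normal quantile at 1 − (1−α)/2): at P = 0.90,
d = 0.1, 95% confidence it gives 35 per group, the design point of a
two-arm sensitivity/specificity study.

## The synthetic test-bed

`simulate_cohort()` generates what the modeling stages assume: two-group
cohorts with block-level methylation differences detectable through
read-pattern measurements.

Per block, a baseline mean is drawn from a bimodal mixture
(0.5·Beta(2,6) + 0.5·Beta(6,2) — methylomes are mostly low or high, not
mid-range); differential blocks shift the MTN group mean by `delta` on
the probability scale (sign random, flipped if it would leave
[0.02, 0.98], clipped with a warning otherwise; a logit-scale option
exists). Per sample and block the methylation probability p is
Beta-distributed around the group mean with concentration 15 (moderate
between-subject variability); read depth is negative-binomial
(mean 30, size 5) with 5% block dropout; 80% of reads span the whole
block, the rest a random contiguous sub-window, so partial-coverage
clipping is exercised end to end. Within a read the first CpG is
Bernoulli(p) and each next CpG copies its neighbour with probability
`concordance = 0.9`, else resamples — the simplest mechanism that makes
PDR, MHL and AMF respond differently (at concordance 1 every read is
constant and PDR ≡ 0; at 0 reads are independent Bernoulli noise).
TI-RADS is sampled conditionally on the true label at a
high-sensitivity / moderate-specificity operating point, nodule size is
log-normal (median 12 mm), age normal (48 ± 12, truncated 18–85), sex
0.75 F — these exist to exercise the subgroup machinery and are not
claims about real covariate distributions.

Default cohort sizes follow the three-phase design the pipeline targets:
discovery 59 BTN / 49 MTN, validation 55/42, test 53/35. Of the default
150 blocks, 25 are differential. `benchmark_scenarios()` freezes four
presets: `paper_shaped` (Δ = 0.2), `easy` (Δ = 0.3), `null` (Δ = 0) and
`hard` (Δ = 0.1 at 10X).

**What passing tests show — and don't.** The generator produces
exchangeable groups under Δ = 0 (so screen calibration and chance-level
AUC are meaningful null checks) and known planted truth under Δ > 0 (so
recall and held-out AUC are meaningful recovery checks). It does *not*
emulate leukocyte cell-type composition shifts, batch or library-size
effects, bisulfite conversion error, genuine genomic CpG spacing, or
correlated blocks — so synthetic recovery demonstrates that the
machinery works as specified, not that any particular clinical
performance would be attained on real cohorts. The headline clinical
reference values this pipeline is modelled on (validation AUC 0.858,
test AUC 0.863, a 60-marker model, cutoff 0.51, 33,871
coverage-filtered blocks) derive from patient RRBS data that is not
publicly deposited; they are documented as reference values and are not
reproduction targets of this package.

## Numerical conventions and degenerate inputs

- Measurements of an empty block, PDR without eligible reads, and a
  Mann–Whitney test with an empty group are explicit missings/flags.
- r² is clamped to [0, 1] against floating-point overshoot; variance
  degeneracy is detected at machine tolerance.
- Matrix exports encode missing as the literal token `NA`; NaN never
  reaches a file.
- All stochastic stages (simulation, fold assignment, forests,
  bootstrap) are driven by explicit integer seeds; identical seeds give
  byte-identical cohorts and bit-identical scores, and a serialized
  model bundle reloads to identical scores.
- Test problem sizes are chosen to keep the default suite fast while
  leaving the statistics well-powered: oracle suites use 150–500 random
  small blocks and 200 score sets; the calibration run uses 5,000
  permuted-label block tests at the default 108-sample discovery size;
  the end-to-end runs use the full 293-sample three-phase design at 150
  blocks.

## Known limitations

- Block calling tests only consecutive-pair r², so a weakly linked
  interior pair splits a block even when all longer-range pairs are
  strongly linked; all-pairs criteria and alternative LD measures (D′)
  are out of scope.
- The KNN imputer is O(rows × reference) per incomplete sample; it is
  intended for marker matrices (tens of columns), not genome-wide ones.
- `randomForest` scales adequately to the marker-set sizes used here;
  very large screens would warrant `ranger` behind the same interface.
- The decision-threshold refits inside `derive_threshold()` reuse the
  already-chosen forest hyperparameters and refit standardization and
  forest per fold; the imputation reference is not refit per fold (its
  effect on fold thresholds is second-order for marker-scale matrices).
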