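---
title: "Methods: detecting geographic clusters of antiemetic under-treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting geographic clusters of antiemetic under-treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raapscan)
```

## The question and the outcome variable

Guidelines tie the intensity of prophylactic antiemetic treatment to a
patient's individual risk of postoperative nausea and vomiting (PONV). If
patients from some neighborhoods systematically receive fewer interventions
than *equally risky* peers, that is a process disparity. `raapscan` makes
this operational through risk-adjusted antiemetic prophylaxis (RAAP):

- The **PONV risk score** counts seven binary factors — female sex,
  PONV/motion-sickness history, nonsmoking status, opioid use, inhalational
  anesthesia longer than one hour, age under 50, and a high-PONV-risk
  procedure — and is categorized on a 6-level ordinal scale (0–1, 2, 3, 4,
  5, 6+).
- The **intervention count** is the number of distinct prophylactic
  antiemetic classes administered plus one if propofol-based total
  intravenous anesthesia was used, categorized on the same scale.
- Within each risk stratum, each case is labeled **below**, **median**, or
  **above** by strict comparison of its intervention level to the stratum
  reference.

**Lower median, on the categorized scale.** The stratum reference is the
`ceiling(n/2)`-th order statistic of the intervention *levels*, not the
midpoint median of raw counts. Two reasons. First, a midpoint median of
integer data can be half-integer (e.g. 2.5), which makes a three-way
below/equal/above split ill-defined — no case can ever equal the reference,
and the "median" class would be empty. The lower median is always an
attained level, so every non-empty stratum contains at least one
median-labeled case (a property the test suite asserts). Second, computing
the reference on the capped 6-level scale matches how both quantities are
defined clinically; a reference computed on raw counts could sit above the
cap and would not correspond to any reportable category.

**Inclusion rules.** Cases are dropped for age < 18, ASA physical status 5
or 6, ICU transfer, anesthesia without a general or regional technique
(monitored anesthesia care and deep sedation), or the lack of a usable
in-region location, with one primary reason per case in the fixed precedence
order age > ASA > ICU > anesthesia type > geography. Regional anesthetics
are retained deliberately: the case mix this package is calibrated to
contains a ~5% regional fraction in its final cohort, so a blanket
"general-only" rule would contradict the population it emulates. Records
with missing risk indicators are rejected outright — risk adjustment by
imputation would manufacture comparability exactly where the data cannot
support it.

## Neighborhood disadvantage and quartiles

Neighborhood disadvantage (ND) for a census block group (CBG) is the
arithmetic mean of five census proportions: non-Hispanic Black population,
female-headed families, households on public assistance or food stamps,
income below the poverty level, and unemployment. ND is recomputed from its
five components whenever a geography is read, so the stored index can never
drift from its definition.

Quartiles are assigned at the **patient level**, not the CBG level: patients
are stably sorted by `(nd, cbg_id, patient_id)` and split into four
contiguous blocks of sizes `q+1` (first `r` blocks) and `q` where
`N = 4q + r`. This choice reproduces near-`N/4` quartile row totals (e.g.
4870/4869/4869/4869 at `N = 19,477`), which is how disparity tables in this
literature are laid out; CBG-level quartiles would weight small and large
block groups equally and give unequal patient rows. The full sort key makes
the assignment deterministic under ties and invariant to input order.

**Point-in-polygon assignment** (the geocoding surrogate) uses even-odd ray
casting with an explicit boundary rule: a point on a shared edge or vertex
belongs to the lowest-index containing polygon. Any deterministic rule would
do; this one is simple to state and test. Points contained by no polygon are
unmatched and excluded under the geography rule, mirroring the exclusion of
unresolvable addresses in registry practice.

## The Poisson spatial scan statistic

Let `c_i` be low-RAAP cases and `n_i` at-risk patients in CBG `i`, with
totals `C` and `N`. Candidate clusters are **circular windows**: for every
CBG taken as a center, the nested prefixes of all CBGs sorted by Euclidean
centroid distance (ties broken by `cbg_id`), truncated once the cumulative
at-risk count exceeds `max_fraction × N`. Every singleton window is always
kept. Each window `Z` with observed `c` and expected `E = C·n_Z/N` is scored

```
LLR(Z) = c·ln(c/E) + (C−c)·ln((C−c)/(C−E))   if c > E,  else 0
```

(with the `0·ln 0 = 0` convention) — the one-sided, high-rate Poisson scan,
appropriate because the question is specifically about *under-treatment*
clusters. Inference conditions on `C`: each of `R` null replicates
redistributes the `C` cases multinomially with probabilities `n_i/N`,
recomputes the maximum LLR over all windows, and
`p = (1 + #{null max ≥ observed max})/(R+1)`. The most likely cluster is the
argmax window (ties resolved toward fewer members, then the lowest center
`cbg_id` — pure determinism, no scientific content); secondary clusters are
reported in decreasing LLR among windows sharing no CBG with an
already-reported cluster, while significant at `alpha`. Cluster strength is
the relative risk `RR = (c/E)/((C−c)/(C−E))`, and the same formula on each
member CBG's own `(c_i, E_i)` gives the within-cluster RR range; a window
holding every case has infinite RR and is reported with a warning, and an
empty window has RR 0.

**Defaults** (all surfaced in the pipeline configuration): window cap
`max_fraction = 0.5` of the at-risk population, `R = 999` replicates,
`alpha = 0.05`. These are the canonical defaults of the standard
implementation of this scan; the source analysis names no alternatives.

**Calibration, and a deliberate conservatism.** The test suite calibrates
the Monte Carlo p-value by drawing observed counts from the scan's own
conditional null (multinomial over a fixed geography) — 400 runs at
`R = 199` must reject at 0.05 within ±2 binomial standard errors, and do.
Feeding the scan *cohort-level* null data instead (patients labeled
independently, no planted effect) yields p-values that are markedly
conservative: given `C`, per-CBG counts of an independently labeled cohort
are multivariate hypergeometric, with variance a factor `(N−C)/(N−1)`
below the multinomial null the scan conditions on. At this cohort's ~35%
low-RAAP share that deficit is large, so the scan under-rejects on such
data (the suite asserts one-sidedly that it never over-rejects). This is
the known behavior of the Poisson scan model applied to Bernoulli-type
data at high case fractions; it biases the analysis toward missing weak
clusters, never toward false ones. At the ~15% case share typical of real
cohorts the effect is smaller but present. A Bernoulli scan model would
remove it and is a natural extension; it is out of scope here.

## The synthetic study region

The generator exists to validate the pipeline against known ground truth,
and its defaults *are* the study conditions the package targets.

- **Geography**: a `grid_rows × grid_cols` tiling of unit squares
  (`cell_size = 1`; planar coordinates, no CRS — the distance math is what
  matters, not projection machinery). Populations are uniform integers in
  [600, 3000], the typical census block group size band. Each census
  proportion is `(1−s)·Beta(a,b) + s·g`, where `g` falls linearly with
  normalized distance from the planted center (`s = spatial_trend_strength`,
  default 0.3) — a deprivation gradient that makes ND spatially structured
  the way segregated metropolitan areas are. Beta shape pairs put the
  indicator means at plausible ACS-like values (e.g. poverty mean 0.125,
  unemployment 0.05).
- **Cohort**: `n = 20,000` cases; CBG assignment proportional to population;
  uniform point within the CBG. Binary risk factors are independent
  Bernoulli draws at a published academic-center case mix: female 0.560,
  nonsmoker 0.986, PONV history 0.111, opioid use 0.985, duration > 1 h
  0.402. Age is rounded normal (mean 48.7, SD 17.55, clamped to [0, 100]),
  giving the target median near 48 and P(age < 50) ≈ 0.52. The high-risk
  procedure flag has no published marginal; its default 0.23 was chosen
  once so that the *expected risk factor count* matches the published mean
  of 3.79 (the other six factors sum to ≈ 3.56). Race is
  White/non-White/unknown at 0.782/0.218/0 and ASA, anesthesia type, ICU
  transfer and geocode failure (rate 0.069, i.e. a 93.1% street-point match
  rate) carry small realistic fractions so the exclusion rules are actually
  exercised.
- **Interventions**: total count `T ~ Binomial(6, plogis(α + β·score −
  ln(OR)·1{inside planted region}))` with `β = 0.45` and `α = −2.05`. The
  intercept is pinned by the calibration target, not free: at the
  configured risk profile (mean score 3.79), `6·plogis(−2.05 + 0.45·3.79)
  = 2.49`, the published mean intervention count, with median 2 — which the
  test suite checks empirically. The planted odds divisor
  (`planted_undertreat_or`, default 1.5) is the ground-truth effect size;
  the planted region is every CBG whose centroid lies within
  `planted_radius` (default 3.5 cells ≈ 9.6% of a 20×20 grid) of the
  planted center.
- **Determinism**: one Mersenne-Twister stream per product (geography
  consumes `seed`, cohort `seed + 1`), draws in a fixed order, RNG state
  restored afterwards; same config + seed gives byte-identical GeoJSON/CSV.

What the generator does **not** emulate: joint dependence among risk
factors (only marginals), realistic street networks or address strings,
irregular polygon shapes, within-CBG heterogeneity, and provider-level
clustering of practice style. Passing recovery tests therefore show that
the pipeline detects the kind of spatial signal it models — a compact
region of elevated under-treatment odds on a contiguous geography — not
that it would detect every disparity structure real data can hold.

## Cluster profiling

- **Contingency tables** report counts and row percentages (2 decimals in
  tables, 1 in prose) of RAAP by ND quartile and by race
  (White / non-White / unknown), with pairwise Pearson chi-squares (no
  continuity correction, raw p-values — multiplicity correction is
  deliberately not applied, matching reporting practice for these
  descriptive comparisons).
- **Regression**: univariate and multivariate logistic fits of the binary
  CBG-level indicator "member of a significant low-RAAP cluster" on % non-
  White, % less than high school, % below poverty, % married, % over 65,
  % renters and % male. Fitting is iteratively reweighted least squares
  (`stats::glm`, binomial; convergence at relative deviance change 1e-8,
  max 25 iterations) with Wald standard errors from the inverse Fisher
  information. Degenerate outcomes and separation (fitted probabilities
  within 1e-8 of 0/1, or exploding standard errors) are flagged and no
  coefficients are reported for that fit — a separated logistic "estimate"
  is noise.
- **Moran's I** on the multivariate fit's deviance residuals:
  `I = (n/S₀)·Σ w_ij z_i z_j / Σ z_i²` with null expectation `−1/(n−1)`.
  Weights are queen contiguity (polygons sharing at least one boundary
  vertex, which is exact for tiled layers such as census geographies and
  this package's grids), row-standardized; neighborless CBGs are dropped
  with a warning. Significance is a two-sided permutation test (999 label
  shuffles, weights fixed, each tail with the +1 correction, doubled and
  capped at 1). The permutation route was chosen over the normal or
  randomization variance approximations because residuals of a logistic
  fit are neither exchangeable-Gaussian nor variance-homogeneous.

## Pipeline and reproducibility choices

`run_pipeline()` executes synth/ingest → geocode → inclusion → RAAP →
quartiles → scan → profiling, aborts on the first stage error with a
stage-tagged message, and writes all artifacts plus a manifest recording
the case count after every exclusion step. The manifest deliberately
carries **no wall-clock timestamp** and omits the output directory from its
config echo, so identical configurations produce byte-identical manifests —
reproducibility is favored over provenance timestamps, which belong in logs
(and are emitted to stderr in verbose mode). A known inconsistency in the
published contingency material this package validates against: the
race-block column totals of the source table are not internally additive
(its row totals instead match the quartile block's column sums, suggesting
transposed labels), and its prose low-RAAP count disagrees with both; all
validation anchors therefore use the quartile block, which is additive in
both margins.

## Problem sizes used in the checks

The routine suite labels cohorts of 1–8 thousand cases on grids of 16–64
CBGs; the deeper end-to-end checks use the full default conditions — a
20×20 grid with 20,000 patients and 999 scan replicates for
planted-cluster recovery, 400 seeded runs at `R = 199` for null
calibration, and 50-seed batches for the generator's distributional
checks. These sizes were chosen as the smallest at which each property is
statistically identifiable with comfortable margin: recovery at odds ratio
1.5 is unambiguous at 20,000 cases, and a ±2 binomial SE band around a 5%
rejection rate needs several hundred runs to be meaningful.

## Known limitations

- Area-level inference: cluster membership and its covariate associations
  are CBG-level statements; reading them as individual-level effects is the
  ecological fallacy.
- The Poisson scan's conservatism on Bernoulli-type outcomes at high case
  fractions, discussed above.
- Queen contiguity via shared vertices assumes a clean tiled layer;
  polygon layers with slivers or mismatched boundary vertices would need
  snapping beyond the built-in tolerance.
- The generator's independence assumptions understate real-world
  confounding between risk factors, race and geography; regression
  coefficients on synthetic data validate the machinery, not substantive
  effect sizes.
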