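---
title: "Deterioration biomarker fingerprints for cold-pressed oils: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterioration biomarker fingerprints for cold-pressed oils: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cold-pressed vegetable oils are oxidatively fragile: their polyunsaturated
fatty acids (PUFAs) are the primary oxidation substrates, their polyphenols
are antioxidants that deplete while protecting the matrix, and volatile
secondary oxidation products (aldehydes, furans, allylic alcohols)
accumulate as terminal markers of rancidity. A storage-stability study
tracks all three layers over months and asks: *which compounds are the most
reliable time-responsive indicators of deterioration for each oil type?*

`oxifinger` implements that analysis end to end for long-format
concentration tables from a crossed storage design — oil type × supplier
(commercial batch) × bottle replicate × sampling day — and ships a
synthetic generator of such datasets so every stage is testable at desk
scale.

## Data model

One record is one concentration of one compound in one bottle at one day.
Units are class-bound metadata (mg/g oil for fatty acids, µg/g oil for
polyphenol classes, ppm for volatiles) and are never converted; mixing
units within a class is an error. Values below the limit of quantification
(LOQ) carry a `below_loq` flag with the value *missing* — censoring is
never encoded as a substituted number, because the downstream imputation
is forward/backward filling rather than LOQ/2 substitution. The default
sampling schedule is days 0, 3, 7, 14, 28, 42, 56, 84, 112, 168 with
3 suppliers × 3 bottles = 9 observations per time point.

## The synthetic generator

The generator exists because measured storage datasets of this kind are
rarely public; it emulates the statistical structure the analysis assumes:

* **Fatty acids and polyphenols** decay as first-order pools,
  $C(d) = C_0 e^{-k d}$ — the simplest monotone model consistent with
  pseudo-first-order oxidation kinetics. Default profiles for the six oil
  types (black cumin, canola, sunflower, high-oleic sunflower, linseed,
  hempseed) anchor initial levels to typical day-0 compositions of these
  oils (e.g. ~68% linoleic acid in black cumin, ~83% oleic in high-oleic
  sunflower, ~65% α-linolenic in linseed, scaled to a 950 mg/g total) and
  solve decay rates from typical six-month percent declines; polyphenol
  rates are solved from printed start/end pairs where available. In every
  default profile phenolic acids deplete faster than flavonoids and
  lignans, matching the common observation that hydroxycinnamates are the
  earliest and steepest decliners.
* **Volatiles** follow a lagged propagation model: flat baseline through an
  induction lag (default day 14), exponential growth
  $C(d) = C_0 e^{k (d - t_0)}$ through the propagation phase (to a plateau
  day), then a linear drift floored at zero. The linseed and hempseed
  hexanal defaults use amplitude/rate pairs (0.08 ppm, 0.15 d⁻¹) and
  (0.11 ppm, 0.14 d⁻¹) with lag day 14 and plateau day 42.
* **Noise** is multiplicative log-normal on two layers: one fixed factor
  per (supplier, compound) pair drawn once (batch effect, default CV 0.15)
  and an independent factor per observation (bottle scatter, default
  CV 0.05). Concentrations therefore stay positive and CVs are
  scale-proportional, as is typical for chromatographic quantification.
  Published day-0 standard deviations do not decompose between- and
  within-batch variance, so these CVs are stated assumptions, not
  calibrated claims.
* **Censoring**: values below the class LOQ are flagged and removed.
  Defaults are typical instrument quantification limits — 0.5 mg/g
  (GC-FID fatty acids), 0.5 µg/g (LC-MS/MS polyphenols), 0.05 ppm
  (SPME-GC-MS volatiles) — so deeply depleted polyphenols censor late in
  storage and low-baseline volatiles censor before propagation, the two
  regimes where real below-LOQ values arise.

What the generator does **not** emulate: mechanistic radical chemistry
(no peroxide intermediates or tocopherol kinetics), non-exponential decay
shapes (transient early increases such as sinapic acid's are not
generated), matrix effects, or analytical drift. Passing tests on
generated data therefore demonstrate the pipeline's statistical behavior
under the declared model, not its validity on any particular measured
dataset.

## Preprocessing

The fixed order of operations is: below-LOQ → missing, Grubbs outlier
screen, forward/backward imputation, centered log-ratio (CLR) transform of
the fatty-acid block, z-score scaling. Screening precedes imputation so
imputed values cannot mask outliers. All steps are deterministic.

* **Grubbs screen**: two-sided single-outlier test per (day, compound)
  replicate group, $G = \max|x - \bar x| / s$ against the critical value
  at α = 0.05, one pass, at most one flag per group — the conservative
  reading of replicate "screening". Constant groups and groups smaller
  than 3 yield no flag.
* **Imputation**: forward-fill then backward-fill along each bottle's
  time series. Observed values are never altered and the operation is
  idempotent; an all-missing series is an error naming the series.
* **CLR**: fatty acids are compositional (shares of a constrained total),
  so each sample's fatty-acid sub-composition is mapped to
  $\ln(x_i / g(x))$ with $g$ the geometric mean. Rows sum to zero and the
  transform is scale-invariant. Non-positive entries are replaced by half
  the smallest positive entry of the same composition (config-overridable)
  before the logarithm. Polyphenols and volatiles are not compositional
  and skip CLR. Note one consequence: CLR converts exponential decays into
  *linear* functions of day, and flips the apparent trend of slow
  decliners whose compositional share rises as PUFAs vanish — a saturated
  fatty acid can legitimately carry an "up" trend arrow in CLR space.
* **z-score**: per compound, sample (n−1) standard deviation, within oil
  type by default (models are fit per oil type); a pooled global mode is
  available. Constant columns map to zero with a warning.

## Feature selection

Three models score each compound's association with storage time,
fit per (oil type, class) block — fatty acids, polyphenols, volatiles:

* **LASSO** regression of storage day on the z-scored concentrations,
  objective $\tfrac12\,\mathrm{MSE} + \alpha \sum_j |\beta_j|$ with a free
  intercept, default α = 0.01. A compound is selected when
  $|\beta_j| \ge 0.20 \max_k |\beta_k|$ within its block. An optional
  5-fold cross-validated α over 10 log-spaced values stands in for
  "adaptive" regularization; the fixed default is used unless enabled.
* **Random-forest regression** with 100 trees predicting day;
  impurity-based importances normalized to sum to 1, selection at 10% of
  the block maximum. The ensemble is seeded and reproducible.
* **Spearman correlation** of each compound with day (univariate,
  unaffected by blocks): mid-rank ρ with the t-approximation p-value.
  Zero-variance inputs are degenerate and report ρ = 0.

The response is raw storage day — not rank or log-day — because the
models' task is predicting storage time from composition.

## Composite scoring

Per compound the raw metrics are |LASSO coefficient|, RFR importance and
|ρ| (magnitude of monotone trend; the sign is kept separately as the trend
arrow, since both increasing volatiles and decreasing substrates are valid
markers). By default each significance threshold acts as a gate: a
non-selected compound contributes 0 for that metric. Each metric is
min–max normalized within its (oil type, class) block — the same grouping
the models were fit in; a pooled per-oil mode is provided and produces
systematically different scores (block winners no longer all reach 1),
which is tested explicitly. The composite is the weighted sum
0.4·RFR + 0.4·LASSO + 0.2·correlation, so a compound maximal in all three
metrics scores exactly 1.000 and ranks first. Ties break deterministically
by class order, then name. Min–max maps a degenerate (all-equal) metric to
0 with a warning; a single-compound block is therefore always degenerate
and scores 0 — rankings are only informative within multi-compound blocks.

## Volatile kinetics and descriptive statistics

The propagation fit is **log-linear least squares** of ln C on (t − t₀)
within a fit window (default days 14–42): the model is exactly linear in
log space, and R² is reported on the log scale, consistent with the
linearized loss. A nonlinear least-squares refinement is config-selectable
and agrees with the log-linear fit on noiseless data (tested). The lag t₀
is fixed, not estimated — estimating it from three propagation-phase
points is ill-posed. Percent declines, fold changes and per-bottle class
totals follow the standard arithmetic; group comparisons use one-way
ANOVA with Tukey HSD, summarized as a compact letter display built by the
insertion–absorption algorithm lettered from the smallest mean.

## Numerical choices and problem sizes

CLR zero-sum and z-score tolerances are 1e−10; composite-weight validation
1e−9; kinetic parameter recovery on noiseless data 1e−10. The test suite
simulates at the study's native scale (9 bottles × 10 days per oil,
~10–15 compounds per profile); repeated-run properties use 20–50 seeded
pipeline runs and 500 seeded kinetic fits, which complete in seconds.

## Known limitations

* With near-collinear monotone trends inside a block — the realistic case
  where *every* compound of a class declines — the LASSO coefficient
  distribution among block members is unstable and min–max normalization
  amplifies tiny |ρ| differences near 1, so *which* member wins the block
  is noise-driven. The steepest decliner is reliably recovered only when
  its decay rate is separated (roughly 4×) from its block neighbors; the
  recovery property is tested under that condition. Rankings on real data
  should accordingly be read as "time-responsive fingerprint members",
  not as a strict ordering by decay rate.
* Forward/backward filling flattens a censored tail at the last observed
  value, which weakens the apparent trend of compounds that decline
  through the LOQ late in storage.
* The propagation fit assumes the window is inside the exponential phase;
  it makes no attempt to detect the phase boundaries.
* Scores are comparable within an oil type only; no cross-oil universal
  ranking is produced, by design.
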