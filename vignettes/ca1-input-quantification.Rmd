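---
title: "Quantifying CA1 input connectivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CA1 input connectivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1circuit)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The connection strength index

Monosynaptic rabies tracing labels the direct presynaptic partners of a
small population of starter neurons. Raw labeled-cell counts scale with
injection size, so the quantity of interest is the starter-normalized
count,

$$\mathrm{CSI}_{c,r} \;=\; \frac{N^{\text{labeled}}_{c,r}}{N^{\text{starter}}_c},$$

for case $c$ and region $r$. `compute_csi()` performs exactly this
division after summing counts over layers within a
(case, region, hemisphere) cell; `summarize_gradient()` averages across
cases per region × targeted CA1 segment and reports mean ± SE with
$\mathrm{SE} = s/\sqrt{n}$ using the $n-1$ sample SD (the source data
report only "mean ± SE", so the conventional estimator is used; a single
case gets SE 0).

Assumptions worth keeping in mind:

* **Pooling.** Pressure and iontophoretic cases are pooled by default —
  normalization is the entire argument for doing so. `by_method = TRUE`
  stratifies instead.
* **Grouped sums are per-case first.** "All ipsilateral CA3" is computed
  by summing each case's CA3a–c CSIs and then averaging
  (`summarize_region_group()`). For fold ratios computed from a table of
  condition means (`fold_ratio()`), the sums are over the printed means —
  the order the comparative claims in the reference table were evidently
  computed in. Both routes are available because the choice is not neutral
  at small $n$.
* **Exclusions are data, not code.** A starter table row can carry
  `excluded = TRUE` plus a mandatory reason (the motivating example:
  injections contaminated by CA2-labeled neurons). The region ontology
  likewise carries an `include` flag; local ipsilateral CA1 is excluded by
  default because cells around the injection site cannot be classified as
  primarily vs trans-synaptically infected.
* **Strict gradient calls.** `gradient_direction()` uses strict
  inequalities over the three segment means; ties are reported
  non-monotonic with a message rather than silently rounded into a trend.

## 2. The synthetic tracing generator

`generate_tracing_dataset()` emulates the statistical structure the
analyses assume, not micrographs:

* Starter counts: normal around the configured per-segment/method mean,
  rounded and truncated at 1. Default means 126/136/80 (pressure) and
  21/27/26 (iontophoretic); default SDs are the published standard errors
  scaled to SDs at the published case counts (e.g. 17 × √6 ≈ 42).
* Labeled counts: Poisson with mean CSI × starters. The source material
  gives only across-case means ± SE, never per-case dispersion, so
  Poisson is a modeling decision: it is the minimal nonnegative-integer
  noise model and makes count/starters exactly unbiased for the true CSI.
  Real cases are likely over-dispersed (injection geometry, tissue
  quality); the parameter-recovery tests therefore demonstrate estimator
  correctness under the model, not biological effect sizes.
* Laminar structure: regions listed in `laminar_props` (default: the
  subiculum at 92/4/4% across pyramidal cell / polymorphic / molecular
  layers) are split multinomially.
* Case counts default to 6 pressure + 4 iontophoretic per segment — 30
  cases, the size of the quantified dataset the defaults mirror.
* Determinism: one `set.seed()` per generator call with a fixed loop
  order. Formal per-case substreams would only matter under parallel
  generation, which the generator does not do; identical `(config, seed)`
  gives byte-identical tables.

One deliberate limitation: with 6 cases per condition, profiles whose true
segment means differ by less than ~2 SE cannot be called reliably. The
pre/parasubiculum intermediate (0.28) vs distal (0.24) means are such a
pair (their published SEs, 0.04 and 0.06, overlap the difference), so the
test suite asserts the strict three-point direction only for the
well-separated subiculum, LEC and MEC profiles and the robust
proximal > distal bias for the pre/parasubiculum.

## 3. The gated statistical procedure

`compare_two_groups()` reproduces the conventional decision tree: both
groups pass Shapiro–Wilk normality *and* the pair passes an
equal-variance test at α = 0.05 → pooled two-sample t-test; otherwise
Mann–Whitney U. The variance gate is Levene's test with median centering
(Brown–Forsythe), via `car::leveneTest()`; the normality and variance
tests are not named in the source description, so the conventional
choices are used and recorded in every result object. Tests are
two-sided; a constant group fails the normality gate by definition (its
Shapiro p is undefined) and routes to the nonparametric branch. Three or
more groups: `aov()` + `TukeyHSD()`. No correction is applied across
separate region comparisons beyond Tukey within one ANOVA family,
matching how such panels are conventionally reported.

Calibration is tested empirically: under a normal null with n = 8 per
group the procedure's type-I error over 10,000 replicates must lie in
0.05 ± 0.01, and the Mann–Whitney branch must agree with an exhaustive
permutation oracle at n ≤ 6 (without ties the U permutation distribution
is the exact Wilcoxon null, so agreement is to 1e-10).

## 4. The VSD pipeline

Order of operations: ΔI/I → baseline-SD normalization → Gaussian
smoothing → thresholding / ROI extraction.

* **ΔI/I.** $100\,(I(t) - I_0)/I_0$ with $I_0$ the per-pixel mean over
  the 50 frames preceding stimulation (0-based frames
  $[\mathrm{stim}-50, \mathrm{stim})$; with stimulation at frame 500 the
  window is frames 450–499). Nonpositive $I_0$ is an error naming the
  affected pixel count.
* **SD normalization.** $(x - \mu)/\sigma$ per pixel with $\mu, \sigma$
  from the same 50-frame window. ΔI/I is an affine per-pixel transform,
  so normalizing raw and normalizing ΔI/I stacks are identical; the
  pipeline normalizes the ΔI/I stack. Zero-SD pixels are masked (`NA`)
  and counted, never propagated as infinities.
* **Smoothing.** Truncated Gaussians, renormalized to unit sum: spatial
  5 px, σ = 1 px (applied separably; border renormalization over
  in-bounds support factorizes for a separable kernel on a rectangular
  domain, so row-then-column equals the full 2-D renormalization),
  temporal 3 frames, σ = 1 frame. Constants pass through unchanged
  everywhere, including corners.
* **Activated pixels.** Inclusive threshold: amplitude ≥ 1 SD. On pure
  noise the pre-smoothing activated fraction per frame sits at
  Φ(−1) ≈ 0.159 (slightly above, because the baseline mean and SD are
  50-frame estimates); after smoothing the same threshold captures almost
  nothing, which is why the threshold/smoothing order matters. The
  default thresholds the smoothed stack — matching how activation maps
  are displayed — and `vsd_quantify(smooth = FALSE)` gives the
  unsmoothed rule.
* **ROI time courses.** Spatial mean per frame over a 0-based, half-open
  rectangle; the peak is searched over post-stimulation frames with ties
  broken to the earliest frame; latency = (peak − stim) × 4.4 ms.
* **Analysis window and artifact.** The summary window defaults to 114
  frames (~500 ms) from stimulation onset — the window extent is a free
  parameter here, as no canonical value exists — and the first 2 frames
  are excluded as the laser artifact (both configurable). The artifact
  exclusion also guards the peak search: the synthetic stimulation
  impulse sits at the stimulation site, which may fall inside an ROI.
* **Latency resolution.** Recovery is limited by the 4.4 ms frame grid:
  a configured 40.8 ms latency lands on frame 9 (39.6 ms) and 78.2 ms on
  frame 18 (79.2 ms). Noise-free recovery is exact on that grid; at the
  default 5-SD amplitude and 1-SD noise the suite requires ±1 frame over
  20 seeds, with the subiculum-before-CA1 ordering preserved.

A caveat on the SD scale: because σ is estimated from 50 frames, a
per-pixel normalized amplitude carries the estimate's chi-distribution
error (~10% per pixel, ~1.5% upward bias in 1/σ̂) regardless of how small
the noise is; amplitude checks therefore use ROI-mean traces, where
averaging across pixels suppresses it.

## 5. The synthetic VSD generator

`generate_vsd_movie()` builds baseline + Gaussian pixel noise +
stimulation artifact + activation components. Each component is a
temporal Gaussian bump (the true waveform is unknown; a symmetric bump is
the minimal choice with a well-defined peak) times an exponential spatial
decay with column distance from a designated border inside its footprint,
mimicking activation that falls off with distance from the CA1/subiculum
border. Amplitudes are in baseline-SD units, realized as
`amplitude × noise_sd` raw intensity (unit SD when `noise_sd = 0`, so
noise-free construction tests stay well-defined). A component with
`couple_to_stim = TRUE` is additionally attenuated by
`exp(-|stim_col - border_col|/decay_px)`: moving the stimulation site
away from the border weakens the downstream (CA1) response, which is what
makes the CA1/SUB activity ratio decrease monotonically across stimulation
distances in the tests.

Defaults: 2000 frames / 500 baseline / 4.4 ms / 60 × 88 px; subiculum
component peaking 40.8 ms and CA1 component 78.2 ms after stimulation,
both 5 SD nominal amplitude, 10 ms temporal width; border at column 44;
stimulation at (30, 48); decay lengths 25 px (SUB, from the stimulation
column) and 20 px (CA1, from the border). The geometry (footprints, ROI
rectangles, decay lengths) is invented but fixed: it is chosen so the two
ROIs are well inside their structures and the coupled CA1 response
retains a ~2–3 SD ROI-mean peak, i.e. the regime where single-trial
signals are discernible without averaging.

What the generator does *not* emulate: dye bleaching and slow drift,
correlated (shot/vignetting) noise, biphasic or propagating wavefronts
within a structure, and trial-to-trial latency jitter. Passing the
recovery tests therefore shows the pipeline's estimators are correct
under idealized noise, not that real-slice latencies are reproducible.

## 6. Numerical and interface conventions

* Frames and pixels are 0-based and windows half-open in every public
  contract (sidecar JSON, ROI rectangles, analysis windows); conversion
  to R's 1-based indexing happens once, inside the accessors.
* Movies are written as 32-bit multi-frame TIFF scaled to [0, 1] with the
  affine scale/offset stored in the JSON sidecar (round-trip error
  ~ range × 2⁻³²); metadata lives entirely in the sidecar.
* CSV is the native table dialect (UTF-8, "." decimal); TSV is accepted
  by sniffing the header. Duplicate (case, region, hemisphere, layer)
  rows, unknown regions, zero starter counts and excluded cases without a
  reason are all hard validation errors.
* Every CLI run writes a manifest (parameters, config MD5, seed, package
  and R versions); randomized commands refuse to run without an explicit
  seed.

## 7. Problem sizes used by the test suite

Simulation-based tests run at sizes chosen to keep the full suite fast
while leaving comfortable statistical margins: tracing-recovery tests use
100 seeds × 6 pressure cases/condition (600 cases per cell, giving
SE ≈ 0.007 on a CSI of 4 against a 5% tolerance); direction-call tests
use 20 seeds at the default 30-case design; VSD recovery uses 20 seeds of
174-frame movies (60 baseline); the calibration test uses 10,000 null
replicates (binomial SE ≈ 0.002 against a ±0.01 band). The acceptance
script mirrors these sizes and finishes in well under a minute.

## 8. Known limitations

* Poisson counts understate real per-case dispersion; SEs from synthetic
  data are accordingly optimistic.
* The CSI is a relative measure: it inherits rabies tropism and
  efficiency biases, so cross-region comparisons assume equal uptake —
  the standard caveat for rabies quantification.
* Peak latency is a frame-grid argmax; sub-frame interpolation is
  deliberately not attempted (single-trial SNR rarely supports it).
* The gated test procedure inherits the usual criticism of
  pretest-then-test inference; it is implemented because it is the
  procedure used with such data, and the calibration test shows its null
  behaviour is acceptable at the sizes used here.
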