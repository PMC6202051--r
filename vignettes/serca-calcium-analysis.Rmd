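---
title: "Models and methods: micropeptide-SERCA binding and cardiac Ca2+ handling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: micropeptide-SERCA binding and cardiac Ca2+ handling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sercareg)
```

# Scope

`sercareg` analyzes the quantitative readouts used to characterize how small
transmembrane micropeptides — phospholamban (PLN), an inhibitor, and DWORF, a
competing activator — regulate the sarco/endoplasmic-reticulum Ca2+-ATPase
(SERCA), and how that regulation propagates to cardiomyocyte Ca2+ handling
and whole-heart function. Five measurement modalities are covered, each with
a matched forward model so every estimator can be validated against known
ground truth:

1. live-cell acceptor-sensitization E-FRET binding curves (apparent affinity
   and intrinsic FRET of the bound complex);
2. progressive acceptor-photobleaching FRET and complex stoichiometry;
3. paced cardiomyocyte Fura-2 Ca2+ transients and sarcomere shortening;
4. oxalate-supported Ca2+-uptake activation curves (K_Ca);
5. echocardiographic systolic and diastolic indices with group statistics.

The package starts from extracted intensity/measurement tables; image
segmentation, densitometry and the wet-lab protocols upstream of those
tables are out of scope.

# E-FRET binding analysis

## Efficiency model

For each cell, three channels are recorded: donor (`F_Cer`), acceptor
(`F_YFP`) and the FRET channel (`F_FRET`, donor excitation / acceptor
emission). The bleed-through-corrected sensitized emission is

  Fc = F_FRET − a·F_YFP − d·F_Cer,

and the per-cell FRET efficiency is

  E = Fc / (Fc + G·F_Cer),

with `a` and `d` the acceptor and donor bleed-through constants and `G` the
ratio of sensitized acceptor emission to donor dequenching. The shipped
calibration is `a = 0.075`, `d = 0.88`, `G = 4.74`. Two ambiguities in the
source protocol are handled explicitly rather than silently resolved:

* some formulations place the constant 3.2 in the denominator where the
  calibrated `G = 4.74` belongs. Both are supported
  (`fret_calibration(g_factor = ...)`); 4.74 is the default because it is the
  instrument-calibrated value, and the choice is recorded in the calibration
  object carried through results.
* the donor bleed-through is sometimes labelled `b`; `calibrate_bleedthrough()`
  computes it as the robust origin slope of `F_FRET` on `F_Cer` over
  donor-only controls, and the acceptor constant as the slope of `F_FRET` on
  `F_YFP` over acceptor-only controls (the occasionally-printed `F_Cer`
  denominator for acceptor-only cells is treated as a typo). Both readings
  are noted in the returned object.

Robust slope = least squares through the origin after 3×MAD outlier
rejection on per-cell ratios; the ratio definition alone is not robust to
segmentation artifacts in control wells.

## Binding isotherm

Efficiency increases hyperbolically with acceptor expression `x` (raw
`F_YFP`, used as an expression index):

  E(x) = FRET_max · x / (K_d + x).

`FRET_max` is the intrinsic FRET of the fully bound complex; `K_d` (in
arbitrary expression units) is the expression level at half-maximal FRET and
serves as an apparent dissociation constant — lower `K_d`, higher apparent
affinity. `fit_binding_curve()` fits per-cell points (not binned means, since
the cell population is the sampled relationship), by nonlinear least squares
with `K_d` log-parameterized, multi-started from a 5×5 log-spaced grid, ties
broken by lowest RSS then smallest `K_d`. Standard errors come from a
case-resampling bootstrap. Cells with `E < −0.5` or `E > 1` are excluded as
optical artifacts (counts recorded); negative-`Fc` cells inside that band are
retained because discarding them biases the low-expression arm upward.
Per-experiment `K_d` values are compared across constructs with a two-tailed
pooled-variance Student t-test (`compare_affinity()`).

# Photobleaching stoichiometry

Destroying the acceptor releases the donor from quenching; the complex
efficiency is `FRET = 1 − F_DA/F_D` with `F_DA`/`F_D` the donor intensity
before/after bleaching (`compute_pb_fret()`, averaging the first and last 2
steps by default; windows are configurable because acquisition protocols
differ). A donor bound to `j` surviving acceptors transfers with efficiency
`1 − (1 − e_pair)^j`, so a 1:1 complex dequenches **linearly** in the
surviving-acceptor count while an oligomeric arrangement (several acceptors
per donor) dequenches along a **convex** curve — one surviving acceptor still
quenches the donor almost fully.

`classify_stoichiometry()` regresses donor on acceptor with linear and
quadratic models and calls:

* `no_fret` — donor dequenching absent;
* `one_to_one` — dequenching present, no curvature (linear relation);
* `higher_order` — significant convexity.

Significance uses a one-sided slope test and the nested linear-vs-quadratic
F-test, both at `alpha = 0.05`. On top of the p-values, each effect must be
*practically detectable*: the fitted dequench across the observed acceptor
range must exceed 3 residual SDs, and the maximal divergence of the quadratic
from the linear fit must exceed 2 residual SDs. Pure alpha-level tests would
misclassify ~5% of trajectories by construction; the detection floors mirror
how linearity is actually judged on such plots (a visible deviation, not a
marginal p-value) and were fixed a priori at the conventional 3σ/2σ levels.
Measured on the forward model (12 bleaching steps, 25% bleach probability per
step, 2% multiplicative noise, 1000 trials per class), the classifier is
correct in 100% (1:1), 98% (oligomer) and 100% (no FRET) of trajectories.
Whether the original linearity judgment was statistical or visual is not
documented; the operationalization is recorded in the result's `method`
field rather than attributed to the protocol.

`detect_oligomer_fret()` summarizes replicate series: one-sample t-test of
the dequench efficiencies against zero (presence requires `p < alpha` *and*
a positive mean) plus a majority stoichiometry call.

# Ca2+ transients and shortening

The forward model (`gen_transient_trace()`) paces at 0.5 Hz by default (the
standard field-stimulation rate for adult mouse cardiomyocytes): each cycle
holds the diastolic baseline, rises linearly over `rise_time`, then decays as
`baseline + amplitude·exp(−t/τ)`; the sarcomere-length channel mirrors the
transient with resting length `sl_rest` (1.8 µm) and peak fractional
shortening `sl_fs`.

`analyze_transient()` proceeds in three steps:

1. **Segmentation.** The pacing period is estimated from the autocorrelation
   peak of the smoothed trace (global maximum past the first zero crossing);
   beats are anchored at upstroke half-amplitude threshold crossings, with a
   half-period refractory that discards spurious re-crossings during slow
   decays. Anchoring at crossings makes the analysis invariant to where the
   recording starts.
2. **Baseline and amplitude.** Per beat, baseline is the median of the 100 ms
   pre-stimulus window (width configurable; unstated in typical protocols).
   The peak is located at the sample maximum, but its *value* is taken from
   the decay fit evaluated at peak time: the raw maximum of a noisy trace is
   biased upward by selection, whereas the fitted value is exact at zero
   noise and median-unbiased under noise.
3. **Decay fit.** τ comes from least-squares fitting of
   `b + A·exp(−t/τ)` from the peak to the end of the beat window (the whole
   decay phase; alternative fraction-of-peak windows can be built by
   truncating the trace), started from a log-linear regression.

Two averaging modes exist because protocols are ambiguous about whether τ is
fit per beat and averaged or fit once on the ensemble-averaged transient:
`"ensemble"` (default, matching the common "decay rate of the average
transient" phrasing) and `"beat"`. An amplitude below `noise_mult` (default
4) baseline SDs raises a "no transient" error.

`analyze_shortening()` applies the same machinery to the inverted length
channel: fractional shortening `(sl_rest − sl_min)/sl_rest × 100`,
contraction/relengthening rates from the centered 5-point moving-average
derivative, and the relaxation time constant from the exponential recovery
fit. A flat channel returns zeros rather than an error; lengths outside
1–3 µm are flagged as non-physiological.

`summarize_cells()` collapses cells to per-animal means *first* and uses the
animal as the statistical unit (matching designs with 3–4 animals and 6–12
recordings each), then reports group mean ± SD and pooled-variance t-tests
against one or two reference groups.

# Cooperative Ca2+ uptake

Uptake rates versus free Ca2+ follow the general cooperative
substrate-activation (Hill) model

  V(ca) = Vmax / (1 + (K_Ca/ca)^h),

with `K_Ca` the half-activating free Ca2+ (lower `K_Ca` = higher pump
affinity) and cooperativity `h` free by default — the standard reading of a
"general cooperative model" for SERCA; a fixed `h = 2` mode is provided
because the exact equation used by common acquisition software is unnamed.
Fits are multi-started over a log-spaced `K_Ca` grid with `h ∈ {1, 2, 3}`,
and `K_Ca` is constrained to 0.1×–10× the assay's concentration span. The
default assay grid is 8 log-spaced points over 0.02–5 µM free Ca2+, the
range EGTA-buffered uptake assays cover; free-Ca2+ values are taken as input
metadata (the buffer speciation computation that sets them is upstream of
this package). `compare_kca()` reports group means, Student t-tests against
a reference genotype, and the affinity direction implied by the sign of the
shift.

# Echocardiography

`compute_systolic()` applies the exact M-mode formulas
FS(%) = (LVID;d − LVID;s)/LVID;d × 100 and EF(%) = (EDV − ESV)/EDV × 100;
end-diastolic/systolic volumes are instrument-supplied inputs — no
Teichholz/cube estimation is performed, to avoid imputing an unstated
method. `compute_diastolic()` returns E/A and E/E′ in two labelled modes,
because summary tables in this literature mix them: per-animal ratios (the
statistical convention) and ratios of group means rounded to one decimal
(the table-regeneration convention). Neither is asserted to be "the"
convention; the acceptance tests enumerate which cells of the reference
six-genotype table are consistent with ratio-of-means and assert the known
mismatches explicitly.

`summarize_groups()` produces the publication-style table: mean ± SD per
genotype, two-tailed Student (pooled-variance) t-tests against up to two
reference groups — `*` marks against the first (e.g. WT), `#` against the
second (e.g. the disease model) — with tiers p < 0.05/0.01/0.005/0.001 and
no multiple-testing correction, matching common practice for such tables.
Welch's test is available by flag.

# The synthetic world

Each generator is exactly invertible at zero noise and deterministic under
its seed. Choices the data do not dictate were made once:

* **FRET population** (`gen_fret_population()`): acceptor expression is
  log-normal (spanning the low-to-high expression sweep a binding fit needs,
  >10-fold by default), donor normal truncated at zero; distributions are
  not documented for such screens. Noise is multiplicative Gaussian
  (CV-parameterized) per channel plus additive background, applied after the
  exact optical model. Default plateau efficiencies in demonstrations are
  0.299 (PLN-SERCA-like) and 0.163 (DWORF-SERCA-like), the reported
  complex-intrinsic FRET levels; `K_d` values in expression AU are printed
  nowhere, so demo values (100 vs 40 AU) encode only the established
  ordering — DWORF binds with higher apparent affinity.
* **Photobleaching** (`gen_bleach_series()`): per step each surviving
  acceptor bleaches with probability `bleach_rate`; 2 pre-bleach baseline
  frames precede bleaching. A pentameric donor is modelled with 4 acceptor
  partners. `expected = TRUE` returns the analytic expectation (binomial
  survival), used as the enumeration oracle in tests.
* **Transients**: defaults amplitude 0.5 ratio units, τ = 0.25 s, baseline
  1.0, 0.5 Hz pacing, 5 ms sampling, 1.8 µm resting sarcomere length —
  typical healthy adult-mouse cardiomyocyte values. SNR 20 is the reference
  noise level for recovery tests.
* **Uptake**: Vmax 60 (rate units carried, not interpreted), WT K_Ca
  0.25 µM, h = 2 — typical murine cardiac homogenate values; genotype shifts
  of +40% (inhibited) and −20% (stimulated) reproduce the established
  directions of PLN- and DWORF-overexpression effects.
* **Echo cohorts** (`gen_echo_cohort()`): Doppler fields follow the
  reference six-genotype group means; M-mode dimensions and volumes are not
  tabulated there, so realistic murine values were chosen once (normal
  systolic function for WT-like groups; a dilated, hypocontractile phenotype
  for MLP-deficient groups).
* **Mechanistic equilibria**: `solve_competition()` (two ligands, one site)
  and `pentamer_equilibrium()` (monomer ⇌ pentamer, ignoring
  dimer–tetramer intermediates, which are not part of the standard PLN
  picture) supply the displacement mechanics behind the competition
  scenarios. Absolute micropeptide/pump concentrations are not quantified
  anywhere; all concentration scales in examples are order-of-magnitude
  choices and labelled as such.

What a green test establishes — and what it does not: the generators use
Gaussian noise, perfectly periodic pacing, complete bleaching, and
exactly-hyperbolic/exponential/Hill response shapes. Real recordings add
motion artifacts, photobleaching of the *donor*, rundown, cell-to-cell
heterogeneity beyond the modelled distributions, and segmentation errors
upstream of the intensity tables. Recovery results here validate the
estimators, not the acquisition chain.

# Numerical choices

* Nonlinear fits use `stats::nls` with `scaleOffset = 1` so zero-residual
  (noiseless) data converge; positive parameters (`K_d`, `K_Ca`) are fit on
  the log scale.
* The competition solver is a damped fixed-point iteration (damping 0.5) on
  the free-receptor concentration, stopping when the mass-balance residual
  falls below 1e-10 (relative), capped at 1e5 iterations; the pentamer
  equation is solved by `uniroot` on its monotone scalar form.
* Degenerate inputs are defined, not crashed: zero-variance group
  comparisons with equal means report p = 1 with a note; exactly collinear
  photobleaching series report curvature p = 1; flat shortening channels
  return zero contraction; constant traces raise a "no transient" error.
* Multi-start tie-breaks: lowest RSS, then smallest `K_d`.

# Limitations

* Stoichiometry is a binary 1:1 vs higher-order call; oligomer size is not
  estimated.
* No SR-load (caffeine-pulse) analysis, spark/action-potential modelling, or
  image-level synthesis.
* The Hill fit treats free-Ca2+ values as exact; buffer-speciation
  uncertainty is not propagated.
* Group statistics reproduce the field's convention (no multiplicity
  correction, animal-level units); they are reporting tools, not a general
  mixed-model framework.
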