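# sercareg

Quantitative analysis of SERCA regulation by transmembrane micropeptides and
of downstream cardiac calcium handling.

Cardiac relaxation depends on SERCA, the sarco/endoplasmic-reticulum
Ca²⁺-ATPase that resequesters cytosolic Ca²⁺ after every beat.
Phospholamban (PLN) inhibits the pump by lowering its Ca²⁺ affinity; the
micropeptide DWORF competes with PLN for the same binding site and thereby
activates the pump. `sercareg` is for cell physiologists and cardiac
biologists who quantify that regulatory axis: it implements the full analysis
chain from live-cell FRET binding measurements down to whole-heart
echocardiography, and pairs every modality with a seeded forward model with
known ground truth, so every estimator in the package is testable end to end.

## Models at the core

* **E-FRET binding** — per-cell efficiency
  `E = Fc/(Fc + G·F_Cer)` with bleed-through-corrected sensitized emission
  `Fc = F_FRET − a·F_YFP − d·F_Cer` (defaults `a = 0.075`, `d = 0.88`,
  `G = 4.74`), then the binding isotherm `E(x) = FRET_max·x/(K_d + x)` fit
  across the cell population; a lower apparent `K_d` means higher affinity
  for the pump.
* **Photobleaching stoichiometry** — donor dequenching
  `FRET = 1 − F_DA/F_D`; a donor with `j` surviving acceptors transfers with
  `1 − (1 − e)^j`, so 1:1 complexes dequench linearly in the acceptor signal
  and oligomers convexly. The classifier calls `no_fret` / `one_to_one` /
  `higher_order`.
* **Ca²⁺ transients & shortening** — beat segmentation of paced Fura-2
  traces; decay constant τ from `baseline + A·exp(−t/τ)`; sarcomere
  fractional shortening `(SL_rest − SL_min)/SL_rest × 100` with
  contraction/relaxation kinetics.
* **Cooperative Ca²⁺ uptake** — Hill-type activation
  `V = Vmax/(1 + (K_Ca/ca)^h)` on 0.02–5 µM free Ca²⁺; `K_Ca` is the
  half-activating concentration (lower = higher pump affinity).
* **Echocardiography** — `FS(%) = (LVID;d − LVID;s)/LVID;d × 100`,
  `EF(%) = (EDV − ESV)/EDV × 100`, diastolic ratios E/A and E/E′, and
  publication-style group tables with tiered Student t-tests.
* **Mechanistic equilibria** — a two-ligand one-site competition solver
  (dose-dependent displacement of PLN by DWORF) and the PLN
  monomer/pentamer equilibrium.

See `vignettes/serca-calcium-analysis.Rmd` for assumptions, parameter
defaults and numerical choices.

## Worked example

Simulate a ~1000-cell FRET experiment at the reference plateau efficiency,
recover the binding curve, then analyze a paced myocyte trace and an uptake
curve:

```r
library(sercareg)

cal  <- fret_calibration()          # a = 0.075, d = 0.88, G = 4.74
pop  <- gen_fret_population(n_cells = 1000, fret_max = 0.299, kd = 60,
                            noise_cv = 0.1, seed = 42)
effs <- compute_efficiency(pop, cal)
fit_binding_curve(effs, bootstrap_n = 200, seed = 1)
#> Hyperbolic binding fit (n = 1000 cells, 0 excluded)
#>   FRET_max = 0.2962 (SE 0.0049)
#>   K_d      = 57.22 AU (SE 2.466)
#>   RSS = 1.46

tr <- gen_transient_trace(amplitude = 0.5, tau = 0.25, noise_sd = 0.025,
                          seed = 7)
m <- analyze_transient(tr)
sprintf("amplitude %.3f, tau %.3f s over %d beats", m$amplitude, m$tau,
        m$n_beats)
#> "amplitude 0.502, tau 0.248 s over 4 beats"

cu <- gen_uptake_curve(vmax = 60, k_ca = 0.25, hill = 2, noise_cv = 0.05,
                       seed = 3)
fit_cooperative_uptake(cu)
#> Cooperative uptake fit (n = 8 points)
#>   Vmax = 61.82, K_Ca = 0.2666 uM, hill = 1.931
#>   RSS = 6.134
```

The binding fit recovers the generating `FRET_max = 0.299` and `K_d = 60 AU`
within its bootstrap uncertainty; the transient analysis recovers the 0.5
amplitude and 0.25 s decay constant; the uptake fit recovers `K_Ca = 0.25 µM`
within the 5% assay noise.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end demonstration from scratch under the
given seed: four simulated binding experiments per construct fit and
compared (affinity ordering), photobleaching sets for 1:1, pentameric and
non-interacting pairs classified, paced-myocyte cohorts summarized per
animal, `K_Ca` shifts fit and sign-tested, and a six-genotype echo cohort
tabulated. Progress is logged to stderr and the results object is written to
`--out`.
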