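---
title: "Models and methods: magnetic-tweezers analysis of telomere mechanics and TRF1 dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teltrace)
```

## Scope

`teltrace` implements the analysis chain of single-molecule magnetic-tweezers
experiments on telomeric DNA and the shelterin subunit TRF1: polymer-elasticity
conversions, telomere-length (TL) measurement, rupture/step analysis of
force-jump and hairpin strand-separation traces, two-state hidden-Markov
analysis of fork hopping with Boltzmann energetics, and the supporting kinetic
and statistical fits. Because raw instrument data for this assay class are
rarely deposited, the package ships a first-class synthetic trace generator
that emulates each assay with known ground truth; every analysis stage is
validated by parameter recovery against that truth.

## Polymer models

Double-stranded DNA under tension follows the extensible worm-like chain
(WLC) in its high-force interpolation,

$$\frac{x}{L_c} = 1 - \frac{1}{2}\sqrt{\frac{k_BT}{F\,L_p}} + \frac{F}{S},$$

with persistence length $L_p = 51.1$ nm and stretch modulus $S = 1006$ pN
(values appropriate for ~100 mM NaCl), and $k_BT = 4.089$ pN·nm at 23 °C.
With a B-form helical rise of 0.34 nm/bp this gives the measurement ruler
0.334 nm/bp at 17 pN (0.33 when rounded), used by `extension_to_bp()` to
convert the extension of a stretched telomere into base pairs. The
interpolation diverges as $F \to 0$; the package refuses $F \le 0$ and the
pipeline performs no bp conversion below 0.5 pN. The rise per bp is not a
fitted quantity here: 0.34 nm/bp is the canonical crystallographic value,
and it is required to reproduce the 0.33 nm/bp working factor.

Single-stranded DNA uses the (inextensible) Marko–Siggia WLC,

$$F = \frac{k_BT}{L_p^{ss}}\left(\frac{1}{4}(1 - x/L_c)^{-2} + x/L_c -
\frac{1}{4}\right),$$

with $L_p^{ss} = 0.87$ nm and contour 0.69 nm/nt. Its inverse (extension at
given force) has no closed form; `ss_relative_extension()` brackets the
unique root in $[0, 1)$ by bisection to $10^{-9}$ absolute tolerance. At the
17 pN unzipping test force the release factor is 0.496 nm/nt, i.e. ~0.99 nm
per unzipped bp (two nucleotides enter the tether per bp).

A deliberate dimensional choice: rupture sizes $\Delta L$ measured at a test
force $F$ are converted with the force-dependent factor
$0.34 \cdot x/L_c(F)$ rather than a fixed 0.33 nm/bp, since test forces span
2–20 pN where the factor varies by several percent.

## Synthetic assays and their defaults

The generator reproduces the statistical structure each analysis assumes;
its defaults are the study conditions, not tuning knobs.

* **Force ramp** (`simulate_force_extension`): loading rate ±4 pN/s over
  0–17 pN. Protein-mediated loops rupture along the ramp with the
  Bell–Evans hazard $k(F) = k_0 e^{F x^\dagger / k_BT}$ integrated over the
  protocol; default $k_0 = 0.04\,\mathrm{s^{-1}}$, $x^\dagger = 0.7$ nm.
* **Force jump** (`simulate_force_jump`): four levels
  $F_{rest} < F_{test} < F_{high} < F_{max}$ (0, 2–8, 10, 20 pN) with jumps
  ramped over 0.39 s, the measured transition time of the instrument
  protocol. Bound loops rupture *sequentially*, each after an exponential
  wait at rate $k(F_{test})$: only the outermost complex of a compacted,
  possibly higher-order looped telomere bears the load at any instant, so
  inter-leap dwells follow the single-event exponential law that the
  downstream Bell–Evans analysis assumes. Event dwells are counted from
  arrival at $F_{test}$ (the 0.39 s transition is excluded). Per-cycle
  binding probabilities follow the measured lookup (38/50/76/60% at
  10/20/25/40 nM dimer).
* **Strand separation** (`simulate_strand_separation`): three levels 6, 17,
  22 pN on a hairpin whose 169-bp stem carries 23 TTAGGG repeats with TGG
  and CGTC spacers after repeats 10 and 20 (first bases at bp 79 and 142
  from the fork end). A bound TRF1 dimer occupies two adjacent repeats
  (12 bp). The fork invades the proximal motif and rests at the footprint
  midpoint — the proximal Myb contact yields before the dimer core — so a
  footprint starting at $s$ pauses the fork at $s+5$ unzipped bp and the
  residence signal sits at the footprint centre $s+6$. Pauses are
  exponential (default mean 0.36 s); each unzipped bp releases 2 nt of
  ssDNA converted at the instantaneous force. Backward steps are not
  generated at the default 17 pN test force (more than 0.9 pN above the
  15.1 pN melting force); the near-critical two-state regime is covered by
  the dedicated hopping generator.
* **Hopping** (`simulate_hopping`): a telegraph process obeying detailed
  balance, $k_{open}/k_{close} = e^{(F - F_{1/2})\Delta x / k_BT}$, with the
  attempt rate setting both rates at $F_{1/2}$. Presets share
  $F_{1/2} = 14.7$ pN and encode opening free energies of 50 $k_BT$ (bare
  fork) and 61 $k_BT$ (TRF1 present), back-calculating
  $\Delta x = \Delta G\,k_BT / F_{1/2}$ since the per-condition opening
  distances are not separately constrained.
* **Bead noise**: Gaussian, 8 nm at $\le$ 8 pN shrinking to 3 nm at
  $\ge$ 14 pN (tension stiffens the trap); chosen so ~10-bp unzipping steps
  are resolvable at 100 Hz. Sampling rates are $\ge$ 100 Hz everywhere and
  every generator demands an explicit seed and stores it in the trace
  metadata.
* **Loop populations** (`sample_loop_population`): loop sizes are drawn
  from concentration- and TL-class-specific Gaussian mixtures (e.g. 258 and
  470 bp centres at 20 nM for TL 2.5–3.5 kb) truncated to $\Delta L > 0$,
  accepted sequentially while $\sum \Delta L \le TL$. The budget constraint
  alone induces the negative correlation between loop number and loop size
  that the correlation analysis measures. TL itself is drawn from a normal
  (2.5 ± 0.9 kb) truncated to the observed 0.3–7.4 kb range.

What the generator does **not** emulate: instrument drift, camera/tracking
artifacts, bead-size heterogeneity, force-calibration error, nonspecific
sticking, and protein rebinding during a test phase. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
stochastic model, not robustness to every instrumental pathology.

## Step fitting

`fit_steps()` segments a constant-force trace by greedy recursive placement
of the single step that maximally reduces the residual SSE, in the style of
the step-fitting algorithms used for molecular motors. The step count is
chosen by a counter-fit quality ratio: for each candidate count the residual
SSE of a "counter staircase" (steps at the fitted plateau midpoints) is
divided by the fit's own residual SSE; the ratio rises while genuine steps
remain and flattens once added steps chase noise. The fewest steps within 5%
of the best ratio are kept (parsimony tie-break), none if the ratio never
exceeds 1. Accepted boundaries are then re-optimised locally (exact SSE
search between neighbours) until stable, which brings the greedy solution to
the exhaustive dynamic-programming optimum in all tested cases; ties in SSE
take the earlier index. Plateaus closer in level than one estimated noise SD
are merged, and plateaus at or below the 20 ms Nyquist floor (two samples at
100 Hz) are fused into the closer-levelled neighbour — dwells that short are
not resolvable at 100 Hz sampling. Localisation accuracy is bounded by
information, not implementation: at noise SD half the step size even the
exhaustive optimum misplaces a boundary by >2 samples in a noticeable
fraction of realisations, which is why the tests assert agreement with the
exhaustive oracle rather than exact truth recovery.

`extract_ruptures()` applies the fitter inside each test-force window,
keeps upward steps above three noise SDs, converts sizes to bp at
$F_{test}$, and reports each event's dwell (since $F_{test}$ arrival for the
first, since the previous event otherwise). Events from different test
forces are pooled for mixture analysis of $\Delta L$.

`zero_correct()` re-references a strand-separation trace to the fully-open
plateau at $F_{test}$ — the only level that is known absolutely — and
divides by the ssDNA release factor, so 0 bp means fully open and the
closed hairpin sits at the stem length. When the construct is supplied the
4 loop nucleotides released at full opening are accounted for, and values
are clamped at zero (the open state is the reference; the small loop offset
cannot be distributed linearly along the stem). A trace whose highest
plateau is too brief, or far below the expected open level, is rejected.
`residence_map()` then accumulates per-trace occupancy (sample counts over
the sampling rate) binned at the blocking site $L - \mathrm{round}(b) + 1$,
1-based from the fork end, and averages across traces with standard errors;
fully-open samples fall outside the stem and are excluded.

## Two-state HMM and energetics

`fit_two_state_hmm()` trains a two-state Gaussian-emission HMM (state
means, common SD) by expectation–maximisation with a scaled
forward–backward recursion (compiled), tolerance $10^{-6}$ on the
log-likelihood, at most 500 iterations, initialised from 2-means clustering
with 5 perturbed restarts (best likelihood kept; restart RNG seedable). The
likelihood is monotone across iterations by construction and this is
asserted in tests. States are decoded by Viterbi; the higher-extension
state is *forward* (more unzipped). Dwells are decoded run lengths over the
sampling rate; runs touching the trace boundaries are discarded
(right-censoring is ignored — a small documented bias toward short dwells
at slow hopping), and only dwells above 20 ms are retained.

Open probability is the forward time fraction with a binomial-style SE on
the number of decoded dwells. `fit_boltzmann()` fits

$$P_o(F) = \frac{1}{1 + e^{(F_{1/2} - F)\,\Delta x / k_BT}}$$

by weighted nonlinear least squares and reports
$\Delta G = F_{1/2}\,\Delta x / k_BT$ in $k_BT$ units at 23 °C. Note the
$1/k_BT$ in the exponent: the relation is sometimes printed without it,
which is dimensionally inconsistent (pN·nm in an exponent); the package
always includes it. The fit refuses tables whose open probabilities all lie
on one side of ½ (the midpoint would be an extrapolation).

## Kinetic and statistical fits

* **Bell–Evans** (`fit_bell_evans`): ordinary least squares of
  $\ln k = \ln(1/\langle\tau\rangle)$ on $F$; slope $x^\dagger/k_BT$,
  intercept $\ln k_0$. Unweighted by default (per-force dispersions are
  usually only available graphically); a weighted variant accepts SEs of
  $\ln k$. The extrapolated zero-force dwell is reported as $1/k_0$
  exactly — for $k_0 = 0.04\,\mathrm{s^{-1}}$ that is 25 s.
* **Exponential dwells** (`fit_exponential`): dwells are observed only
  above the 20 ms Nyquist floor; by memorylessness
  $\hat\tau = \overline{d - d_{min}}$ is unbiased, with SE
  $\hat\tau/\sqrt{n}$. A binned-histogram fit of $A e^{-t/\tau}$ is also
  run and its $R^2$ reported for comparability with histogram-based
  analyses.
* **Hill** (`fit_hill`): $f = C^n/(K_d^n + C^n)$ by Levenberg–Marquardt;
  the coefficient $n$ floats by default (the source analyses do not print
  it) and can be fixed at 1.
* **Gaussian mixtures** (`fit_gaussian_mixture`): 1-D unequal-variance
  mixtures via model-based EM (mclust), component count by BIC over 1–4
  when not fixed. mclust's hierarchical initialisation is deterministic,
  which replaces random-restart schemes without loss in the tested regimes.
  At least 50 observations per expected component are required.
* **Partial correlations** (`partial_correlation`): zero-, first- and
  second-order Pearson coefficients by the standard recursion, verified to
  $10^{-10}$ against regressing out the controls and correlating residuals;
  two-sided p from the t statistic on $n - 2 - \mathrm{order}$ df, no
  multiple-testing correction (single-test reporting).

## Study sizes used by tests and the acceptance script

Parameter-recovery runs use sizes at which the stated tolerances sit at
roughly two standard errors or better, chosen by power analysis before the
tests were frozen: 200 dwells per force at $F = 2$–8 pN for Bell–Evans
recovery ($k_0$ within 1.5×, $x^\dagger \pm 0.15$ nm); 1290 and 588 dwells
for the 0.36 s and 1.71 s exponential constants (2 SE); 500 draws for the
loop-size mixture (centres ±40 bp); 20 forces × 200 s hopping traces at
attempt rate 2 s⁻¹ per Boltzmann condition
($\Delta\Delta G = 11 \pm 2\,k_BT$); 3000 s traces at attempt rates
$1/9.5$ and $1/0.8$ s⁻¹ for the 8.7 s backward-dwell modulation (±20%); a
50-trace ensemble for the residence-map valleys; 131 molecules for the
loop-number/size correlation; and bare-molecule ramps at 0.1–17.5 pN for
the TL round-trip (±1%).

## Known limitations

* Dwell censoring at trace boundaries is ignored, biasing mean dwells
  slightly low for slow hopping; the bias is negligible at the study sizes
  above.
* The step fitter assumes piecewise-constant signals at constant force;
  drift correction and multi-state (>2) models are out of scope.
* Loop ruptures are strictly sequential in the generator; racing
  (parallel-load) topologies would make pooled dwells non-exponential and
  are not modelled.
* Whether the instrument dwell for the first rupture should exclude the
  390 ms force transition is ambiguous in the assay description; the
  package excludes it consistently in generator and analysis.
* The zero-force intercept of the Bell–Evans fit is reported as
  $1/k_0$; note that a dissociation time of 23 s sometimes quoted alongside
  $k_0 = 0.04\,\mathrm{s^{-1}}$ is internally inconsistent (1/0.04 = 25 s).
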