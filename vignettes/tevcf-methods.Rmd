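---
title: "Models, conventions and verification in tevcf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and verification in tevcf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
fits, the processing conventions it adopts where the experimental literature
leaves choices open, what the synthetic-data generator does and does not
emulate, and the numerical decisions that matter when reproducing results.

## The measurement and its two channels

Two-electrode voltage-clamp fluorometry records, from one oocyte expressing
a Kv channel with an environment-sensitive fluorophore attached to the top
of the S4 helix, two simultaneous signals per voltage step: the ionic
current, reporting pore-domain (PD) gating, and the fluorescence deflection,
reporting voltage-sensor-domain (VSD) movement. The default protocol steps
from a −100 mV holding potential to 250-ms test pulses from −140 to +40 mV
in 10-mV increments every 30 s, sampled at 5 kHz and low-pass filtered at
1 kHz (`make_default_protocol()`).

Comparing where each signal activates along the voltage axis — the Boltzmann
midpoint V½ of the G-V versus the F-V relationship — and how fast each
activates distinguishes lipids that act on the VSD from lipids that act on
the PD. The package's study design compares an untreated control with
C16-ceramide and C16-glucosylceramide loading, plus three membrane-order
assays (anisotropy, generalized polarization, dipole-potential imaging) that
locate where in the bilayer each lipid reorganizes structure.

## Trace processing

* **Filtering.** Zero-phase Gaussian smoothing with the kernel SD set so the
  −3 dB amplitude point equals the requested cutoff
  (σ = √(ln 2)/(2π f_c)); default 1 kHz, matching the acquisition
  bandwidth.
* **Leak.** An ordinary least-squares line through (V, mean pulse current)
  over −140…−80 mV, where channel open probability is below 0.4% for every
  condition studied; subtracted per sample against the commanded voltage.
  The subtraction runs on the raw trace, before any filtering, so that the
  sharp command steps cancel exactly and leave no filter ripple at the
  pulse edges.
* **Peak currents.** Signed extremum of the leak-corrected current inside
  the pulse, excluding an edge margin at *both* pulse edges (2 ms minimum;
  step transients and filter smearing occur at onset and offset alike). For
  peak detection only, the trace is additionally smoothed to 100 Hz:
  extremum picking on a wide-band trace rides the largest noise excursion
  and systematically inflates the near-zero subthreshold points of the I-V
  relationship, which in turn drags the fitted midpoint leftward by
  1–2 mV. For a non-inactivating current whose peak sits on the activation
  plateau, heavier smoothing before cursor placement is standard practice
  and removes ~80% of that bias. The edge exclusion widens with the
  smoothing kernel (600/f_c ms).
* **Bleach correction.** The fluorescence sweep at the most hyperpolarized
  potential carries no voltage-dependent deflection and serves as the
  baseline trace; it is smoothed to 20 Hz (it contains only the slow bleach
  envelope, so smoothing loses nothing and keeps the baseline's noise out
  of every corrected trace) and subtracted, with the pre-pulse mean added
  back so ΔF/F denominators stay meaningful.
* **ΔF/F.** 100·(F(t) − F̄)/F̄ with F̄ the mean over the 50 ms immediately
  preceding pulse onset. The steady-state value is the mean over the final
  10% of the pulse (25 ms, more than four fast time constants after
  onset at every analysed voltage); a window mean was chosen over a fit
  asymptote and is recorded in the processing metadata.

All windows are arguments of `process_sweep_set()` with the defaults above.

## Model fitting

* **G-V.** The GHK-rectification × Boltzmann current model is fitted to the
  19 I-V points per cell by bounded Levenberg–Marquardt (minpack.lm),
  initialized from a coarse grid scan over (Erev, V½, k) with Gmax solved
  linearly at each grid point. Bounds: Gmax > 0, Erev ∈ [−120, −40] mV,
  V½ ∈ [−100, 50] mV, k ∈ [1, 60] mV. The 25 mV rectification constant is
  fixed, not fitted. The removable singularity of V/(1 − e^(−V/25)) at
  V = 0 is handled by a 4th-order series for |V| < 0.5 mV; the seam agrees
  with the direct quotient to 10⁻¹⁰. A caveat worth knowing: with a
  strongly gated current almost nothing flows near Erev, so Erev is only
  weakly identified and can drift to its bound under noise; this flat
  direction is orthogonal to V½ and k, which is what the analysis reports.
* **F-V.** Steady-state ΔF/F per cell is normalized to its maximum and
  fitted with a unit-amplitude Boltzmann (V½, k bounded as above). Data
  with no discernible voltage dependence are flagged non-identifiable
  rather than fitted.
* **Kinetics.** Single-exponential fits to the current's rising phase and
  double-exponential fits to the fluorescence, over −10…+40 mV where the
  models describe the traces well. The current fit starts after the 2-ms
  capacitive margin; the fluorescence fit starts at pulse onset, because
  the optical channel has no capacitive transient and a margin would crop
  the fast component by e^(−margin/τf) and bias the amplitude split. The
  double-exponential surface has local minima in which one component grabs
  the whole amplitude, so four initializations (time-constant splits around
  the single-exponential estimate) are refined and the lowest-SSE solution
  kept; components are relabeled afterwards so τ_fast < τ_slow. Time
  constants are bounded to [0.5 ms, 2 × segment]: below ~0.5 ms the
  acquisition bandwidth dominates, and beyond twice the window an
  exponential degenerates into a ramp with unbounded amplitude. Fits with
  τ_slow/τ_fast < 2 are flagged poorly separated and excluded from cohort
  summaries.
* **Relative amplitudes.** The +40 mV leak-corrected peak of each cell is
  divided by the mean peak of the same recording day's control cells, which
  removes day-to-day expression variability and makes the control group's
  daily mean exactly 1.

## The synthetic-data generator

The generator emulates the study's three arms from explicit ground truth so
that every downstream stage can be checked by parameter recovery.

* **Sweeps.** Current = ohmic leak through the commanded voltage + a
  channel current rising mono-exponentially to the GHK × Boltzmann steady
  state + additive Gaussian noise (0.1 µA SD). Fluorescence = a 1000 a.u.
  baseline bleaching mono-exponentially at 0.02 s⁻¹, deflected during the
  pulse by a Boltzmann-dependent steady-state ΔF/F approached as a fast
  plus slow saturating exponential (fast fraction 0.9), with multiplicative
  Gaussian noise of 0.5% — i.e. 5% of the maximal ΔF amplitude, the noise
  level the closed-loop recovery targets are defined at. ΔF/F is
  positive-going on depolarization with a 10% saturating amplitude; sign
  and magnitude are conventions (`dff_sign`, `dff_max`) since only
  normalized curves are analysed downstream. Voltage dependence of the
  time constants is a synthetic convention — mono-exponentially decreasing
  with depolarization (τ_act: 12→5.7 ms over −10…+40 mV; τ_fast similar,
  τ_slow = 4·τ_fast) — because the experimental values are published only
  graphically. An optional 1-ms capacitive spike at the pulse edges is off
  by default. Between-cell variability is an independent truncated Gaussian
  per parameter with SD = SEM·√n of the corresponding reported group, so
  simulated cohorts reproduce the reported dispersion.
* **Probe intensities.** Quadruples and emission pairs are built by
  analytically inverting the anisotropy and GP formulas at the target
  values, then jittered multiplicatively; at zero noise the round trip is
  exact to 10⁻¹².
* **Images.** 512×512 fields of 30–40 non-overlapping circular cells
  (radius 15–30 px) with a 3-px membrane ring bright in both channels
  (red 300 counts, blue = ratio × red above a 50-count background, Gaussian
  noise 3 counts), dim interiors, one interior seed per cell plus
  background seeds, and ground-truth label/membrane masks.

What the generator does **not** emulate — and what recovery therefore cannot
attest to on real data: inactivation gating, capacitive transients of
realistic shape, correlated (pink) noise, endogenous/background
conductances, series-resistance error, non-circular cell morphology, uneven
illumination and focus drift in imaging, and probe internalization. Passing
the closed loop shows the analysis code is correct and unbiased under the
stated phenomenology, not that the phenomenology captures every property of
oocyte recordings.

## Imaging conventions

The watershed is marker-controlled priority flooding (Rcpp) on the Sobel
gradient magnitude of the summed channels, smoothed with a σ = 1.5 px
Gaussian: a ring only a few pixels wide produces two parallel edge ridges
with a zero-gradient channel along its midline, and smoothing merges them so
the watershed line settles on the membrane midline instead of hugging one
edge. Flooding order is deterministic — ties on plateau pixels resolve by
queue insertion order with seeds inserted in raster order. The membrane
band is the label boundary dilated to a total width of 3 px (both rings, an
open convention); the background is the median over label-0 pixels outside
a 2-px guard band; membrane pixels whose background-subtracted red signal
falls below 5% of the membrane's median red signal are excluded from the
ratio and counted. Cell-morphology screening ("cells of normal morphology")
is a data-curation step, not an algorithmic one, and is out of scope.

## Statistics

One-way fixed-effects ANOVA followed by Tukey's HSD (Tukey–Kramer for the
unequal group sizes of 10–14 cells), α = 0.05, dispersion reported as SEM.
Pairwise tables are always computed but marked "not interpreted" when the
ANOVA is not significant, mirroring the sequential procedure; p values below
10⁻¹² are floored and labeled `<1e-12`.

## Verification strategy and problem sizes

The acceptance loop (`scripts/acceptance.R`, ~30 s on one CPU) regenerates
the full study at a master seed: cohorts of 10–12 cells per condition for
the midpoint recoveries, a 14 + 12-cell day-structured cohort for relative
amplitudes, 9 samples per probe group, and 20 image pairs of 30–40 cells
per imaging condition. The test suite additionally runs module-level
oracles: closed-form trace values, an FFT attenuation check for the filter,
a lattice search behind the Boltzmann fit, a random multi-start behind the
I-V fit, a BFS flood-fill behind the watershed, and sum-of-squares
arithmetic behind the ANOVA. Stochastic module tests use cohorts of 3–12
cells and 64–256 px images to keep the default run under a minute.

## Known limitations

* **Fast-fraction estimator skew.** The generated fluorescence signal is
  90% fast by construction, and fitting the clean deflection recovers that
  split exactly. At the study's noise level, however, the slow component's
  amplitude is only about twice the per-sample noise SD, and the
  double-exponential amplitude split becomes weakly identified: the global
  SSE optimum occasionally splits the fast component into two nearby
  exponentials (τ ratio ≈ 3, past the ≥2 separation guard), which skews
  per-fit fractions left. Cohort means of the fitted fraction land around
  0.79–0.85 versus the generating 0.90, while the median fit stays above
  0.85. The package reports flag-filtered means and the tests assert the
  median; treat single-trace amplitude splits at this SNR with caution.
* **Erev identifiability** in the I-V fit, as noted above.
* **Translation equivariance** holds for the Boltzmann (F-V) fit; the full
  I-V model is anchored at V = 0 by the rectification quotient and is not
  translation-symmetric.
* The relative-amplitude recovery inherits the intrinsic dispersion of a
  ratio of small-sample means (SEM ≈ 0.035 at the study's group sizes);
  single-seed recoveries scatter accordingly.
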