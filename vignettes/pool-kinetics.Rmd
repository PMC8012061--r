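---
title: "Quantifying LDCV priming: models, fits and counting methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LDCV priming: models, fits and counting methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolkin)
```

Chromaffin cells release catecholamines by fusion of large dense-core
vesicles (LDCVs). Before fusion, vesicles must be *primed* — rendered
fusion-competent — a reversible reaction that fills two kinetically distinct
pools: the readily releasable pool (RRP, fusion time constant ~10–20 ms
after a calcium step) and the slowly releasable pool (SRP, ~hundreds of ms).
This vignette describes the models and numerical procedures the package
implements, the choices made where conventions were open, and what the
synthetic-data tests do and do not establish.

## Flash-response kinetics

A spatially uniform calcium step (flash photolysis of caged calcium)
triggers fusion of the primed pools; membrane capacitance reports the added
membrane area (~0.94 fF per vesicle). The standard response model is

$$\Delta C_m(t) = A_1\left(1 - e^{-t/\tau_1}\right)
  + A_2\left(1 - e^{-t/\tau_2}\right) + A_3\,t$$

where the amplitudes are the RRP and SRP sizes, the $\tau$ are their fusion
time constants, and the linear term is the *sustained* component (ongoing
priming followed by immediate fusion). Components are assigned RRP when
$\tau \le 60$ ms and SRP when $60\,\mathrm{ms} < \tau \le 1$ s
(`classify_components()`, both cut-offs configurable). If both exponentials
land in one class the trace is refitted with a single exponential for that
component (`refit_single_exponential()`); a component slower than the SRP
bound contributes to no pool and is reported in a diagnostics field — the
literature is silent on this case, so dropping-with-report was chosen over
silently inflating the SRP.

**Delayed SRP.** Strong overexpression of the priming protein ubMunc13-2
(especially without synaptotagmin-7) produces convex, S-shaped capacitance
traces: the SRP fuses only after a delay. If the SRP fusion rate grows
toward its final value with time constant $\tau_{delay}$, a first-order
expansion valid for long delays gives

$$\Delta C_m(t) = SRP\left(1 - e^{-t^2/\tau_{slow,delay}}\right),$$

where $\tau_{slow,delay}$ (units s²) is the *product* of the delay and
fusion time constants — the two are not separately identifiable, which is
why the fit estimates only the product. `select_model()` fits both families
(each has 5 free parameters) and keeps the one with the lower residual sum
of squares; with equal parameter counts raw RSS ranks models identically to
any per-trace variance-normalised chi-square, and a normalised variant
(baseline-variance estimate) is available via `normalize = TRUE`. Ties go
to the standard model. For delayed-SRP data sets the SRP upper bound is
conventionally raised to 1.6 s; the delayed amplitude is classified by its
effective time constant $\sqrt{\tau_{slow,delay}}$.

**Optimisation.** Fits use bounded Levenberg–Marquardt least squares with 8
multi-starts on log-spaced time constants (1 ms–2 s); at each start the
amplitudes are initialised by linear least squares given the time-constant
basis (variable projection), which makes noiseless round-trips exact to
better than $10^{-6}$ relative error. Bounds: amplitudes $\ge 0$, $\tau \in
(10^{-4}, 10]$ s, sustained rate unbounded (it can legitimately come out
negative for strongly convex traces). The fit window is 0–5 s after the
flash; the baseline is the mean of the pre-flash samples. A fit that
terminates at the iteration cap is flagged unconverged unless its deviance
is at numerical zero.

## Priming models and paired-flash recovery

Priming is reversible: a depot pool (DP) feeds the primed pool (PP) with
forward rate constant $k_1$ and loses vesicles back with depriming rate
$k_{-1}$; fusion drains PP with $k_f$ (0 between stimuli). Two variants:

* **Model I** (no release sites — the chromaffin-cell situation):
  $dPP/dt = k_1 DP - (k_{-1}+k_f) PP$. Recovery from an empty pool is
  exponential with rate $k_{-1}+k_f$ and steady state $k_1 DP/(k_{-1}+k_f)$.
  $k_1 DP$ is lumped (fF/s); DP is assumed constant during the experiment.
* **Model II** (release-site limit $PP_{max}$, the 'neuronal' situation,
  sites recycling immediately):
  $dPP/dt = k_1 DP\,(PP_{max}-PP) - (k_{-1}+k_f) PP$. The recovery rate is
  $k_{-1}+k_f+k_1 DP$ — sped up by priming — and $k_1 DP$ changes unit to
  s⁻¹.

Both closed forms are verified against independent `deSolve` integration to
$10^{-8}$ relative error in the test suite.

In a paired-flash experiment the first flash empties the pool; the ratio
Stim2/Stim1 at each inter-stimulus interval traces the refilling.
`fit_recovery()` fits $plateau\,(1-e^{-rate\,\Delta t})$ to the per-cell
points (using every point rather than interval means — the convention is
ambiguous in the literature, and per-point fitting uses all information; a
means mode is provided). Under Model I with $k_f = 0$ the rate *is*
$k_{-1}$, and `derive_rates()` gives the forward rate before stimulation as
$k_1 DP = k_{-1} \cdot PP(\infty)$ and after stimulation as that value
scaled by the plateau (overfilling plateau > 1 means priming increased
after stimulation; an incomplete plateau means it dropped). The switch of
the forward rate at the first flash is modelled as instantaneous; only
before/after values, not a time course, are identifiable from the ratios.

`translate_to_release_site()` maps a Model I estimate into the Model II
parameter set with the *identical* recovery curve, assuming release sites
are 90% occupied at rest: $PP_{max} = PP(\infty)/0.9$,
$k_1 DP = 0.9\,rate$, $k_{-1} = 0.1\,rate$. The translation is exactly
invertible and the equality of the two curves is asserted to $10^{-9}$ in
tests. With the worked numbers (pool 74.2 fF, rate 0.043 s⁻¹) this yields
$PP_{max} = 82.4$ fF, $k_1 DP = 0.039$ s⁻¹, $k_{-1} = 0.0043$ s⁻¹.

```{r translate}
translate_to_release_site(74.2, 0.043, occupancy = 0.9)[]
```

## Stereology

`stereology_chain()` computes vesicle counts per cell from three
measurements: the 2D density of vesicle profiles in ultrathin (60 nm)
sections, the vesicle diameter from 3D tomography, and the resting
capacitance. A profile is first treated as a cylinder (diameter × section
height); because vesicles are spheres and are still scored when sliced
tangentially, the volume fraction is corrected by the sphere /
circumscribed-cylinder ratio with the cylinder height extended by the
section thickness. The cell is a sphere (area from capacitance at
10 fF/µm²) with a nucleus of half its radius. The total count obeys

$$N_v = \frac{4\,\delta_v\,\pi\,r_{cell}^3\,(1-f^3)}{3\,(2 r_{ves}+h)}$$

which the tests verify to machine precision against the stepwise
volume-fraction route. Counts are always computed from this exact form;
`rounding = "printed"` rounds only the *displayed* intermediates to the
conventional printed precision (chaining rounded intermediates would
accumulate ~0.1% error). Membrane-proximal and docked counts use
$n_a = n_l/(d_v + 0.06)$ with the measured per-µm linear density and the
tomographic docked fraction.

```{r stereology}
wt <- stereology_input(delta_v = 4.71, d_v = 0.1755, h = 0.060,
                       c_rest = 3.83, n_l = 0.75, docked_fraction = 0.27)
stereology_chain(wt)
```

## Amperometric spikes

Single-vesicle catecholamine release is recorded as current spikes at a
carbon fiber. `preprocess_amperometry()` subtracts the cell's "empty" flash
artifact trace and applies a Gaussian low-pass at 500 Hz (kernel SD
$0.1325/f_c$, the standard Gaussian-filter cut-off relation).
`detect_spikes()` thresholds at 5 pA above the median baseline and extends
each event to its baseline crossings. Shape metrics follow the usual
conventions (peak, trapezoidal charge in pC, half-width, 50–90% rise and
75–25% decay with linear interpolation between samples). Two conventions
had to be fixed here because published analyses rely on unpublished macro
internals:

* **Foot**: onset is the first sustained crossing of a 2 pA foot threshold
  before the upstroke; the foot ends where the extrapolated maximal-slope
  line of the upstroke intercepts the baseline. A foot shorter than ~1.5
  samples is treated as absent (fields `NA`, never zero).
* **Compound events**: a second supra-threshold peak before the current
  falls below 25% of the first peak flags the window as compound; compound
  windows are excluded from shape statistics and reported.

The interspike interval statistic is the **median** interval between
spikes.

## Synthetic data: what it emulates, and what it does not

The generators produce (i) flash traces = model function + i.i.d. Gaussian
noise (default SD 2 fF); (ii) paired-flash experiments with per-cell
Gaussian amplitude noise; (iii) Poisson spike trains (50 ms refractory gap
so single spikes stay resolvable) rendered from a foot/rise/decay template
with 1 pA RMS noise; (iv) jittered stereology inputs. Noise magnitudes are
engineering defaults — recording-noise levels are rarely published — and
the noise is white, whereas real capacitance noise is correlated and
includes conductance crosstalk; real amperometric spikes vary in shape from
vesicle to vesicle. Passing round-trip tests therefore demonstrates the
estimators are unbiased and precise under the assumed noise model, not that
they are robust to every instrumental artifact. Seeded runs are
reproducible bit-for-bit and leave the session RNG untouched.

Simulation sizes used in the tests: recovery cohorts use inter-stimulus
intervals {2, 5, 10, 22, 60, 120} s with 5 cells per interval (the interval
set is the package's choice; published recovery figures name 22 s and
120 s); genotype-ordering checks use 200 replicate cohort pairs;
model-selection checks use 17-cell cohorts. The default trace grid is
[−0.5, 5] s at 1 ms — coarser than the 25 kHz acquisition but ample for
time constants ≥ 10 ms.

## Known limitations

* Capacitance is taken as given (baseline-subtracted fF); computing it from
  lock-in currents is out of scope, as are imaging-based colocalisation
  analyses and calcium calibration.
* The delayed-SRP fit estimates only the product $\tau_{slow,delay}$; the
  underlying delay and fusion constants are not identifiable.
* Group statistics beyond the exact 2×2 test (Mann–Whitney,
  Kruskal–Wallis, ANOVA…) are deliberately delegated to `stats`.
* The two-sided Fisher p-value uses the "sum of small point probabilities"
  convention (ties within 1e-7 relative); other software may use other
  two-sided definitions.
* Titration bins are left-closed/right-open with a closed final bin
  (0.8–1.2 µM); boundary handling is a declared convention.
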