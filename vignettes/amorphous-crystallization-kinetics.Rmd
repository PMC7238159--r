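---
title: "Crystallization kinetics and molecular mobility of amorphous drugs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crystallization kinetics and molecular mobility of amorphous drugs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amorphkin)
```

amorphkin quantifies the physical stability of amorphous (glassy or
supercooled) pharmaceuticals from the two workhorse experiments of the
field: isothermal differential scanning calorimetry (DSC) and broadband
dielectric spectroscopy (BDS). This vignette describes the models the
package implements, the numerical choices behind them, and what the
synthetic-data generators do and do not emulate.

## Relative crystallinity

Isothermal crystallization of a supercooled drug releases heat. The
relative crystallinity is the normalized cumulative exotherm,

$$\alpha_{\mathrm{DSC}}(t) =
  \frac{\int_{t_0}^{t} (\mathrm{d}H/\mathrm{d}t)\,\mathrm{d}t}
       {\int_{t_0}^{t_\infty} (\mathrm{d}H/\mathrm{d}t)\,\mathrm{d}t},$$

computed by `relative_crystallinity_dsc()` with trapezoidal quadrature and
an optional linear baseline between the window anchors. Exothermic heat
flow is stored positive; readers negate instrument conventions on request.

Dielectrically, crystallization converts relaxing dipoles into a rigid
crystal, so the static permittivity $\varepsilon_s$ decays. The normalized
real permittivity

$$\varepsilon'_N(t) =
  \frac{\varepsilon'(0) - \varepsilon'(t)}
       {\varepsilon'(0) - \varepsilon'(\infty)}$$

(`static_permittivity_track()` + `normalized_permittivity()`) is an
equivalent crystallinity measure: because $\varepsilon'$ at any fixed
frequency is affine in the dielectric strength, $\varepsilon'_N$ equals
$\alpha$ exactly whenever the strength decays proportionally to the
amorphous fraction. A series whose static permittivity does not drop (the
relative drop is below `min_contrast`, default 2%) is reported as
non-crystallizing rather than force-normalized — this is the behavior of a
successfully stabilized formulation.

## The Avramov construction

Both branches feed one code path, `avramov()`. Plotting $\alpha$ against
$\ln(t - t_0)$, the construction extracts:

* the **induction time** $t_0$: the offset that places the inflection of
  $\alpha(\ln(t - t_0))$ at $\alpha = 1 - 1/e \approx 0.632$;
* the **characteristic time** $\tau_{cr}$: the position of the maximum of
  $\mathrm{d}\alpha / \mathrm{d}\ln(t - t_0)$;
* the **dimensionality exponent** $n$, twice: from the derivative maximum,
  $n = \alpha'_{\max} / 0.368$, and from the tangent drawn at
  $t - t_0 = \tau_{cr}$, whose intersections with $\alpha = 0$ and
  $\alpha = 1$ give $n = e / (\ln t_2 - \ln t_1)$.

These constructions are exact for the Avrami law
$\alpha(t) = 1 - \exp\!\left[-\left((t - t_0)/\tau\right)^{n}\right]$: on
the $\ln(t-t_0)$ axis its derivative peaks at $t - t_0 = \tau$ with height
$n/e$ and the inflection sits at $1 - 1/e$. That uniqueness is why the
synthetic generator uses the Avrami form as ground truth even though the
analysis itself is model-free.

### Numerical design of the derivative estimate

The inputs are *integrals* of noisy signals (cumulative heat flow, or
per-spectrum permittivity readings), so the error in $\alpha$ is a random
walk, not white noise. Three consequences shaped the implementation:

1. **Resampling and smoothing.** The curve is linearly resampled onto a
   uniform $\ln(t - t_0)$ grid (801 points, capped at 5 decades below the
   endpoint); $\alpha$ itself is smoothed with an 11-point quadratic
   Savitzky–Golay window (`study_config()` exposes both).
2. **Differencing.** The derivative is estimated by central differences
   over a finite span (0.2 ln-units) with Richardson extrapolation,
   $(4 D_{S/2} - D_S)/3$. For random-walk noise this is near-optimal: the
   noise of a difference is set by the walk increments across the span,
   while Richardson removes the $S^2$ truncation bias. A narrow smoothing
   window applied to the *derivative* instead (the textbook
   Savitzky–Golay derivative) either flattens the peak (wide window) or
   transmits the walk increments (narrow window); we measured up to
   $-18\%$ bias or $\pm 10\%$ scatter in $\tau_{cr}$ on the standard test
   problem before adopting the present scheme.
3. **Peak reading with family calibration.** The derivative maximum is
   located by an iterated local-quadratic fit over a $\pm 0.15$ ln-unit
   window centered on the running vertex. A symmetric window on an
   asymmetric peak still leaves a small, systematic offset; because the
   limiting curve family is known, the identical read-out is applied to
   the exact Avrami curve at the estimated $n$ and the resulting offsets
   (peak position, apex value, $\alpha$-level at the peak) are subtracted.
   This makes the noiseless pipeline exact to better than 0.1% while
   keeping the noise rejection of a wide window.

The induction-time bisection compares the $\alpha$ read at the derivative
maximum against the *calibrated* target level, so the read-out offset
cancels between data and target. The criterion is intrinsically weak — the
target level moves by only $\sim 3\times10^{-5}$ per second of $t_0$ for
the standard DSC problem — so its precision is limited by the
$\sim 2\times10^{-3}$ irreducible level noise of $\alpha$; at 2%
multiplicative heat-flow noise this corresponds to a per-run scatter of
roughly $\pm 65$ s on $t_0$ and $\pm 1$ min on $\tau_{cr}$, matching the
uncertainties such experiments typically quote.

### Problem sizes

The recovery studies in the test suite use a 10 s sampling interval over a
30,000 s hold (the fast DSC case: $n = 3.8$, $\tau_{cr} = 55$ min,
$t_0 = 8800$ s) and a 60 s interval over $3\times10^5$ s for the slow
first-order case ($\tau_{cr} \approx 737$ min, $t_0 = 29{,}750$ s); Monte
Carlo loops run 20 seeds. These sizes resolve every feature the estimators
use while keeping the default suite fast.

## Dielectric relaxation

Loss spectra are fitted with the Havriliak–Negami (HN) function plus an
ohmic conductivity term,

$$\varepsilon^*(\omega) = \varepsilon_\infty +
  \sum_p \frac{\Delta\varepsilon_p}
       {\left[1 + (i\omega\tau_{HN,p})^{a_p}\right]^{b_p}} +
  \frac{\sigma_{dc}}{\varepsilon_0\, i\omega},$$

with $a, b \in (0, 1]$ the symmetric and asymmetric broadening exponents;
$b = 1$ is the Cole–Cole special case used for the sub-$T_g$ secondary
($\beta$, $\gamma$) relaxations (`fit_secondary_cole_cole()`), and
$a = b = 1$ is Debye. The loss-peak relaxation time of a process is the
closed form

$$\tau_{\max} = \tau_{HN}
  \left[\sin\frac{\pi a}{2 + 2b}\right]^{-1/a}
  \left[\sin\frac{\pi a b}{2 + 2b}\right]^{1/a},$$

validated in the tests against the numerical argmax of the single-process
loss (the two sine factors have *different* arguments; the variant with
both arguments equal collapses to $\tau_{\max} = \tau_{HN}$ for every
shape and contradicts the numerical peak, so it is not implemented).

`fit_hn()` minimizes uniform-weight least squares on $\log_{10}
\varepsilon''$ over the log-frequency grid — the natural objective for
peaks spanning decades — optionally jointly with relative residuals on
$\varepsilon'$. Note that $\varepsilon_\infty$ enters only $\varepsilon'$:
loss-only fits cannot identify it, so recovery of $\varepsilon_\infty$
requires the joint objective (`fit_real = TRUE`). Optimization uses
bounded Levenberg–Marquardt with eight randomized restarts (seeded); ties
are broken toward the smaller parameter vector. The conductivity exponent
is fixed at 1 (pure ohmic). When two fitted processes land within half a
decade of each other, the weaker is flagged degenerate: two free
Cole–Cole terms given single-process data otherwise split the peak into
equal halves at zero residual cost.

## Master plots and the KWW shape

Time–temperature superposition is implemented in `build_master_plot()`:
each loss spectrum is normalized by its peak and shifted horizontally (no
vertical shifts) to superimpose on the reference spectrum, processing
spectra from the temperature nearest the reference outward and minimizing
the squared log-loss mismatch against the accumulated merged curve by
golden-section search. For a shape-invariant series the recovered shifts
equal $\log_{10}\left[\tau(T) / \tau(T_{\mathrm{ref}})\right]$. Spectra
whose loss maximum lies below the measured window contribute only a
power-law flank, for which a horizontal shift is not identifiable; the
worked analyses therefore superpose the temperatures whose peaks are
in-window (312–350 K for the tabulated VFT parameters and a 0.1 Hz lower
edge).

The master curve's shape is summarized by the stretching exponent
$\beta_{KWW}$ of the Kohlrausch–Williams–Watts function: the loss is the
one-sided Fourier (sine) transform of $-\mathrm{d}\phi/\mathrm{d}t$ with
$\phi(t) = \exp[-(t/\tau_K)^{\beta}]$. `kww_loss()` evaluates
$\int_0^\infty \beta u^{\beta-1} e^{-u^\beta} \sin(cu)\,\mathrm{d}u$ by
Longman's method — integration between consecutive sine zeros (10-point
Gauss per half-period) with repeated averaging of the alternating partial
sums — after a $w = u^\beta$ substitution removes the $u^{\beta-1}$
singularity from the first interval; slowly oscillating cases integrate
directly. The tests pin this against the Debye closed form at $\beta = 1$
(agreement $\sim 10^{-15}$) and brute-force quadrature at $\beta = 0.5$
($\sim 10^{-15}$). `fit_kww()` then fits $(\beta, \tau_K)$ to the merged
curve on the log scale, ignoring points below 0.5% of the peak where, in
real data, conductivity and secondary processes dominate.

Because the HN and KWW shapes correspond only approximately, the
temperature-series generator offers `shape = "kww"`: spectra whose loss is
an exact KWW curve with known $\beta$, VFT-shifted in temperature. This is
what makes the $\beta$-recovery test a true round trip rather than a test
of an approximate HN-to-KWW mapping.

## Temperature dependence, $T_g$, fragility

Structural relaxation times follow the Vogel–Fulcher–Tammann law
$\tau_\alpha(T) = \tau_\infty \exp[D T_0 / (T - T_0)]$. `fit_vft()` works
in $\log_{10}\tau$ with uniform weights (relaxation times span >10
decades) and is parameterized internally by
$(\log_{10}\tau_\infty,\, DT_0,\, T_0)$ — the product $DT_0$ (kelvin) is
what dielectric studies tabulate and is much better conditioned than $D$
alone. Derived quantities are closed forms, each cross-checked in the
tests against brute-force root finding / numerical differentiation:

* glass transition at the conventional $\tau_\alpha = 100$ s:
  $T_g = T_0 + DT_0 \log_{10}e \,/\, (\log_{10}\tau_g -
  \log_{10}\tau_\infty)$;
* fragility $m_p = \mathrm{d}\log_{10}\tau_\alpha /
  \mathrm{d}(T_g/T)\big|_{T_g} = DT_0\, T_g / [\ln 10\, (T_g - T_0)^2]$,
  with the Arrhenius limit $m_p \to \log_{10}\tau_g -
  \log_{10}\tau_\infty$ (= 17 for $\tau_\infty = 10^{-15}$ s). Values
  outside the typical molecular-glass range 50–100 trigger a warning,
  never an error.

For the three tabulated parameter sets of the simvastatin study the chain
returns $T_g = 303$ K in every case and fragilities 91 and 94 for the
neat drug and the small-particle silica mixture. The third set prints
$m_p = 93$ but recomputes to $\approx 92.4$ from its own printed
parameters — within its rounding/uncertainty, and we report the
recomputed value.

Secondary relaxations are Arrhenius,
$\tau(T) = \tau_\infty \exp[E_a / RT]$, fitted by linear regression of
$\ln\tau$ on $1/T$ (`fit_arrhenius()`, $R = 8.314$ J mol⁻¹ K⁻¹ fixed,
$E_a$ in kJ/mol). `assemble_relaxation_map()` merges the VFT and
Arrhenius fits into a serializable relaxation map.

## Loading capacity on mesoporous silica

The Hempel method estimates how much drug a mesoporous silica (MS) can
immobilize as a surface monolayer: drug molecules adsorbed on the silica
surface no longer participate in the glass transition, so the
heat-capacity step $\Delta C_p$ at $T_g$ of a drug/MS mixture falls below
the ideal-mixing line and extrapolates to zero at the composition where
the entire drug fraction is immobilized. `fit_dcp_line()` regresses
$\Delta C_p$ on drug load (wt.%), excluding mixtures with no detectable
glass transition ($\Delta C_p \le 0$, below the breakpoint — they carry
no information about the line), and reports the capacity
$100 - w^*$ in wt.% MS with a delta-method standard error;
`compare_capacities()` propagates errors in quadrature for
material-to-material comparisons. The generator's breakpoint/linear form
and the published capacities (84.3 and 83.4 wt.% MS) serve as ground
truths; the underlying experimental points are not tabulated in the
source study, so validation is by synthetic recovery.

## What the generators emulate — and what they do not

`gen_dsc_isothermal()`, `gen_bds_crystallization_series()`,
`gen_bds_temperature_series()` and `gen_dcp_table()` are pure functions of
(truth, seed): bit-identical under the same seed and leaving the session
RNG untouched. Noise models: additive Gaussian on heat flow (instrument
noise floor, in mW), multiplicative log-normal on $\varepsilon'$,
$\varepsilon''$ and $\Delta C_p$ (sensor gain noise; preserves
positivity). Default frequency grid: 8 points per decade over
$10^{-1}$–$10^{6}$ Hz.

Not emulated: baseline drift and thermal-lag transients of real DSC
(only a linear drift is exercised in tests), electrode polarization and
fractional-exponent conductivity at low frequency, partial crystallinity
plateaus ($\alpha_\infty < 1$), overlap between the structural relaxation
and the exotherm time window, or sample-geometry effects (the reason DSC
and BDS kinetics of one material differ quantitatively). Passing the
round-trip suite therefore demonstrates correctness of the estimators
under the stated noise models, not robustness to every artifact of real
instruments.

## Degenerate inputs and tie-breaks

Readers reject non-monotone time/frequency grids, negative losses, and
missing tags or columns with typed errors. The induction-time search
reports a diagnostic error when no $t_0$ in $[0, t_{\alpha=0.05}]$
satisfies the inflection criterion; a derivative maximum on the grid
boundary (curve does not bracket its peak) is an error rather than a
silent extrapolation. Multiple derivative maxima resolve to the largest;
HN multi-start ties resolve to the smaller parameter norm; master-plot
spectra without overlap after shifting are an error.
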