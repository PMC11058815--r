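---
title: "Methods: ELF-weighted free-electron-gas stopping for compounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ELF-weighted free-electron-gas stopping for compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pennstop)
```

## The model

A proton traversing matter loses energy predominantly to electronic
excitations. For a homogeneous electron gas the stopping power
$S(v, r_s)$ is a function of two variables only: the projectile velocity
$v$ and the Wigner–Seitz radius $r_s$, which fixes the density
$n_0 = 3/(4\pi r_s^3)$ and plasmon energy
$\omega_p = \sqrt{3}\,r_s^{-3/2}$ (Hartree atomic units are used
internally throughout; interfaces use eV/keV/MeV, g/cm³ and
eV·cm²/10¹⁵ atoms).

Real polymers are not homogeneous. The Penn construction replaces the
material with a statistical ensemble of electron gases weighted by the
material's optical energy-loss function $\mathrm{ELF}(\omega) =
\mathrm{Im}[-1/\varepsilon(\omega)]$:

$$g(\omega_p) = \frac{2}{\pi\,\omega_p}\,\mathrm{ELF}(\omega_p), \qquad
S_{\mathrm{compound}}(v) = \int_0^{\infty} g(\omega_p)\,
S\!\left(v,\, r_s(\omega_p)\right)\, d\omega_p ,$$

with $r_s(\omega_p) = (\sqrt3/\omega_p)^{2/3}$. The perfect-screening
sum rule $\int \mathrm{ELF}/\omega\, d\omega = \pi/2$ implies
$\int g\, d\omega_p \approx 1$ for a conductor-like, untruncated ELF, so
$g$ acts as a probability density over gases. `penn_average()` evaluates
the integral by trapezoid on the ELF's native grid — measured ELFs are
densest exactly where the weight is — and `penn_stopping()` wraps the
whole pipeline (velocity mapping, averaging, cross-section conversion,
diagnostics) into one classed fit object.

Two deliberate policy choices:

* **No renormalisation by default.** The weight is applied exactly as
  the ELF dictates; `integral_mass` is reported so a truncated or badly
  normalised ELF announces itself (values far from 1). A
  `renormalize` flag divides by the mass for sensitivity studies.
* **Clamping at the kernel edge.** Grid points whose mapped $r_s$ falls
  outside the kernel's validity are evaluated at the nearest edge and
  the affected weight fraction is reported
  (`clamped_mass_fraction`), as is the weight below 1 eV, where the
  mapped gases become arbitrarily dilute. The integral runs over the
  grid exactly as supplied; no extrapolation below the first point is
  attempted (measured ELFs vanish there).

## The free-electron-gas kernel

The built-in kernel is linear response with the Mermin dielectric
function, the number-conserving relaxation-time extension of Lindhard:

$$S(v) = \frac{2}{\pi v^2} \int_0^{\infty} \frac{dk}{k}
\int_0^{kv} \omega\, \mathrm{Im}\!\left[\frac{-1}{\varepsilon_M(k,\omega)}
\right] d\omega$$

for a unit point charge (bare proton; higher charge states and their
capture/loss cycles are out of scope). The undamped RPA plasmon is a
delta line, so the kernel uses a finite damping $\gamma$ (default
0.02 Hartree, user-settable) which broadens the line while conserving
the f-sum — that is what makes the double quadrature robust.

Numerical choices, all visible as arguments of `lindhard_stopping()`:

* outer $k$: 400-point logarithmic grid on
  $[10^{-3}/r_s,\ \max(50/r_s,\ 3v)]$. The upper limit always covers
  the close-collision region $k \le 2v$; without the $3v$ term the
  high-velocity (Bethe) limit is silently truncated for dilute gases.
* inner $\omega$: a 300-point composite trapezoid grid per $k$ — a
  uniform backbone over $[0, kv]$ plus Cauchy-spaced points centred on
  the plasmon line. The line position is estimated by the Bohm–Gross
  dispersion and refined by bisection on
  $\mathrm{Re}\,\varepsilon_M = 0$; where no root exists (Landau-damped
  region) the extra points fall back to uniform.
* convergence is asserted in the tests by step-halving (< 0.5%
  change), and the kernel is checked against an independent adaptive
  Gauss–Kronrod oracle at five probe points (agreement is a few
  $10^{-4}$ relative) and against the Bethe asymptote
  $(\omega_p^2/v^2)\ln(2v^2/\omega_p)$ at $v = 10$ au.

Linear response is known to lose accuracy around the stopping maximum
and below, where non-linear effects matter; that is a documented
limitation of the built-in kernel, not of the averaging machinery. The
kernel is therefore a pluggable contract: `load_kernel_table()` ingests
any externally computed kernel (for instance, energy loss per traversal
of a jellium cluster divided by the cluster diameter) from a long-format
TSV, and the Penn machinery is agnostic to its origin.

For curve-level work the analytic kernel is sampled once per session
onto a 15 × 26 logarithmic $(r_s, v)$ grid ($r_s$ 0.3–10 bohr,
$v$ 0.05–25 au) and interpolated. Interpolation is bilinear in
$(\log r_s, \log v)$ applied to $\log S$: stopping is positive and
power-law-like in both variables, and interpolating the logarithm
removes a percent-level convexity bias that would otherwise be amplified
about sixfold when high-velocity curves are inverted to an effective
mean excitation energy. Above the grid-top velocity the kernel switches
to the Bethe asymptote; below the grid bottom it extrapolates the
friction regime $S \propto v$. Node values are reproduced to machine
precision either way.

## Sum rules, I values and dosimetry

Sum-rule diagnostics tie an ELF to the material's electron bookkeeping:
the running f-sum
$Z_{\mathrm{eff}}(\omega_{\max}) = [2/(\pi\Omega_m^2)]
\int_0^{\omega_{\max}} \omega'\,\mathrm{ELF}\, d\omega'$
(with $\Omega_m^2 = 4\pi n_{\mathrm{monomer}}$) counts effective
electrons per monomer, and the mean excitation energy is the
logarithmic moment

$$\ln I = \frac{\int \omega\,\mathrm{ELF}(\omega) \ln\omega\, d\omega}
               {\int \omega\,\mathrm{ELF}(\omega)\, d\omega},$$

integrated over the full tabulated range, core tails included. Moment
integrals resample the ELF onto a 2000-point logarithmic grid *merged
with the native grid points*, so narrow native features are never lost
to resampling. The Bragg-rule counterpart,
`bragg_mean_excitation()`, is the electron-weighted log mean of
elemental I values; comparing the two quantifies how far a compound
departs from elemental additivity.

The dosimetric consequence of revising I is computed with the plain
relativistic Bethe formula,
$S/\rho = K (Z/A) \beta^{-2} [\ln(2 m_e c^2 \beta^2 \gamma^2 / I) -
\beta^2]$, and the CSDA range $R = \int_{T_{\min}}^{T_0} dT/(\rho\,
S/\rho)$ by adaptive quadrature. Shell, density-effect and Barkas
corrections are deliberately omitted: they are common to both I values
and largely cancel in the range *difference* that is the quantity of
interest. The integration floor is 1 MeV; the residual range below it
is tens of micrometres and cancels in differences. Since the reference
statement of the range effect does not name the material explicitly,
`range_shift_report()` evaluates both readings — the explicit
74 → 66 eV pair for PMMA and a generic 10% reduction — which land
within a few percent of each other.

## The synthetic-data generator

All tests run on synthetic ELFs built from sums of Drude oscillators,

$$\mathrm{ELF}(\omega) = \sum_i \frac{A_i \gamma_i \omega}
{(\omega^2 - \omega_i^2)^2 + (\gamma_i\omega)^2},$$

chosen because their sum rules are closed-form
($\int \omega\,\mathrm{ELF}\,d\omega = \tfrac{\pi}{2}\sum A_i$,
$\int \mathrm{ELF}/\omega\, d\omega = \tfrac{\pi}{2}\sum
A_i/\omega_i^2$), which gives every quadrature in the package an exact
target. Two standard fixtures:

* `delta_like_elf()`: one narrow oscillator with unit screening mass
  ($A = \omega_0^2$), by default at the plasmon energy of an
  $r_s = 2$ gas. In the Penn integral this collapses the ensemble onto
  a single gas, so the average must reproduce the kernel itself — the
  sharpest end-to-end test the formalism admits.
* `polymer_like_elf()`: a dominant valence plasmon at 20 eV
  (width 8 eV) carrying 99.95% of the screening mass plus a weak, very
  broad core tail at 200 eV. The tail's screening share (5 × 10⁻⁴) is
  deliberately small: screening weight falls off as $A_i/\omega_i^2$,
  so core excitations that are prominent on a log-energy plot carry
  almost none of it. This fixture emulates the *shape* of polymer
  optical ELFs and their screening bookkeeping; it does not reproduce
  any specific polymer's f-sum partition or printed I value, so tests
  passing on it demonstrate properties of the machinery (linearity,
  delta limit, direction of the homogeneity bias), not agreement with
  any particular measured spectrum.

What the generator does **not** emulate: momentum-transfer dispersion
(the ELF enters at the optical limit only — dispersion lives in the
kernel), fine structure and anisotropy of real spectra, and
temperature or phase effects.

## Degenerate inputs and tie-breaks

ELFs must have at least 8 strictly increasing positive energies and
non-negative finite values; duplicate energies are rejected rather than
merged. An all-zero ELF raises a degenerate-input error in the moment
functions. A material/kernel pair with no overlap after the
$\omega_p \to r_s$ mapping fails fast with the offending span in the
message. Electron counts use the fixed valence convention H:1, C:4,
N:5, O:6. The PMMA registry entry corrects the repeat unit to C₅H₈O₂
(the printed formula is inconsistent with the printed 54/40 electron
pair, which C₅H₈O₂ matches exactly); the printed string is stored
alongside.

## Problem sizes

The shipped configuration keeps every computation at desk scale: the
default kernel table is 390 double-quadrature evaluations (about half a
minute, cached per session), Penn curves on the default 60-point energy
grid are interpolation-bound and effectively instant, and the CSDA
integrals converge to 10⁻¹⁰ relative in milliseconds. The test-suite
oracles (dense adaptive quadrature, 10⁵-step Riemann range integration,
10⁶-point moment quadrature) are sized to run in seconds each.

## Known limitations

* The built-in kernel is perturbative; around the stopping maximum it
  inherits linear-response errors, and no claim of agreement with
  measured stopping cross-sections is made there. Non-perturbative
  kernels must be supplied as tables.
* Projectile charge is fixed at $Z_1 = 1$; no charge-state averaging.
* Nuclear (elastic) stopping is not computed anywhere.
* Bethe/CSDA dosimetry omits shell and density corrections; absolute
  ranges carry percent-level bias even though range differences are
  robust.
* The Bragg-rule module consumes user-supplied elemental tables; the
  package bundles only toy closed-form fixtures, not reference
  compilations.
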