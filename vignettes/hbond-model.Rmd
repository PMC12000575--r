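---
title: "The dipole-in-field model of hydrogen bonding: methods and design"
author: "hbdipole"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dipole-in-field model of hydrogen bonding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbdipole)
```

## The model

A hydrogen bond D-H···A is treated as an elastic dipole in a uniform local
electric field: the covalently bound O-H pair carries a dipole moment
$p(d)$ along the bond, and the acceptor generates an effective field
$E_{HB}$ at the dipole's position.  The electrostatic binding energy is
$U_{HB} = p\,E$ (collinear convention; the magnitude is reported as a
positive binding energy).  The field does two things to the oscillator:

* it softens the spring, $k(E) = k_0 - p''E$, where
  $p'' = \partial^2 p/\partial d^2$, and
* it stretches the bond, $d(E) = d_0 + (E/k(E))\,p'$, where
  $p' = \partial p/\partial d$.

The stretching wavenumber measured by Raman, FTIR or SFG gives the force
constant through the harmonic relation $k = \mu(2\pi c\tilde\nu)^2$, so a
single red-shifted band determines, in order, $k$, $E = (k_0-k)/p''$,
$d(E)$, the bond dipole from the second-order Taylor expansion
$p(d) = p_0 + p'(d-d_0) + \tfrac12 p''(d-d_0)^2$, the binding energy
$U = pE$, and the bond polarizability
$\alpha(d) = [p' + p''(d-d_0)]^3/(p'k_0)$, which along the $d(E)$ map is
algebraically identical to $\alpha(E) = p'^2k_0^2/(k_0-p''E)^3$.  This
chain is `hb_predict()`.

The Taylor series is truncated at second order because the calibration
determines exactly two derivatives; offsets beyond 0.12 Å (the largest
calibrated offset) are extrapolation and are flagged.  Blue-shifted inputs
($k > k_0$) are rejected rather than extrapolated: strong blue-shifting
hydrogen bonds involve charge-transfer physics outside this model.

## The mass convention

The harmonic conversion needs a reduced mass.  The package default is the
*integer-mass* convention $m_O = 16$, $m_H = 1$ u, which reproduces the
reference free O-H force constant $k_0 = 762.0$ N m⁻¹ from the
free-molecule wavenumber 3706.491 cm⁻¹ (the mean of the gas-phase $\nu_1$
and $\nu_3$ modes).  Isotopic masses give 767.4 N m⁻¹ and would shift
every derived field by about 3%; the convention is therefore an explicit,
overridable argument (`oscillator_masses()`) rather than a hidden
constant.  Internally `default_coefficients()` pins $k_0$ to the force
constant of 3706.491 cm⁻¹ (761.81 N m⁻¹, i.e. 762.0 at quoted precision)
so the free molecule is an exact fixed point of the chain.

## Calibration

Two fits produce the five coefficients.

**Stage 1 — shared-slope fit (`fit_shared_slope()`).**  Field sweeps of the
two gypsum water dipoles (O-H$_A$ at $\vartheta$ = 69.60° to the field
axis, O-H$_B$ at 9.37°) are converted to force constants and fitted
jointly to $k = k_0 - p''(E_{HB}^{(s)} + E_{ext}\cos\vartheta)$ — one
shared slope $p''$, one local field per species.  Datasets whose dipole
points against the field axis red-shift in the opposite direction; they
are flipped automatically when the raw slope is positive (the flip is an
involution and preserves $|$slope$|$), with an explicit
`orientation_sign` override, and an error when the slope sign is not
resolvable from the data.  Weights are $1/\sigma_k^2$ when peak errors are
given, unit weights otherwise.

**Stage 2 — errors-in-variables line (`fit_york()`).**  The relation
$d = d_0 + p'\,(E/k)$ is fitted across 21 reference bonds (free molecule,
six ice phases, gypsum, five hydrates) with errors on both axes, using
York's unified iterative solution: weights
$W_i = (\sigma_{y,i}^2 + b^2\sigma_{x,i}^2)^{-1}$, convergence when
successive slopes agree to $10^{-12}$ relative (typically < 10
iterations).  The x-errors are pure first-order propagation of the
softening-slope uncertainty, $\sigma_x = |x|\,\sigma_{p''}/p''$, which is
how the error bars of this relation are constructed; the uncertainty
values are used exactly as quoted, and parameter errors are inflated by
$\sqrt{\chi^2_\nu}$ (the usual treatment when per-point errors are taken
at face value).  With those conventions the packaged table gives slope
$p' = 7.56\times10^{-19}$ C with $2\sigma = 1.25\times10^{-19}$ C,
intercept $d_0 = 0.9578$ Å, reduced $\chi^2 = 5.9$ — all inside the
quoted uncertainties of the reference calibration
($p' = (7.83 \pm 1.26)\times10^{-19}$ C, $d_0 = 0.957 \pm 0.001$ Å).

The free-molecule row is part of the fit: dropping it moves the intercept
to 0.933 Å, far outside the quoted band, so the reference calibration
evidently anchored the line at zero field.  Its bond length (0.9578 Å
from rotational-level fitting) is given $\sigma_d = 10^{-4}$ Å, the scale
of that spectroscopic determination.

Coefficient roundings: the package default is the full quoted precision
($p' = 7.83\times10^{-19}$ C, $p'' = 2.23\times10^{-8}$ C m⁻¹); a
`"main_text"` rounding ($7.7\times10^{-19}$, $2.2\times10^{-8}$) is kept
because several downstream reference values (the molecular dipole moments
and the confined-water dielectric constants) were evidently evaluated at
that rounding, and both roundings reproduce every reference value within
its stated uncertainty.

## Which bond length enters the energy

$U = p(d)\,E$ needs a bond length.  Where a thermally corrected
diffraction length exists (ice Ih: 1.014 Å; liquid water: 0.984 Å) the
dipole is evaluated at that measured length; the chain-predicted $d(E)$
is used where no diffraction length is available (water-carbon
interfaces).  The two differ: at the liquid band midpoint the chain
predicts 1.017 Å and would give 7.3 kcal mol⁻¹ instead of the reference
5.1, so the choice is substantive and is made the same way the reference
calculations made it.

Liquid water's broad stretching band (3200-3650 cm⁻¹) is represented by
its midpoint, 3425 cm⁻¹ (`liquid_water_wavenumber()`), an explicit,
overridable convention.

## Uncertainty propagation

`hb_predict()` propagates coefficient uncertainties to every output by
the delta method: a central-difference Jacobian of the whole chain with
respect to $(\tilde\nu, k_0, d_0, p_0, p', p'')$, contracted with the
coefficient covariance (fitted covariances when the coefficients come
from `calibrate()`, diagonal otherwise; quoted uncertainties are stored
as $2\sigma$).  A seeded Monte-Carlo mode re-runs the chain over Gaussian
coefficient draws and agrees with the linearization to within 15% on the
energy uncertainty for the worked examples — the chain is nearly linear
over the calibrated domain.

## Dielectrics

For rotationally frozen (confined or proton-ordered) water only bond
stretching polarizes, and contributions add:
$\epsilon_r = 1 + (1/\epsilon_0)\sum_i \alpha_i\cos^2\vartheta_i\,N_i$.
For gypsum (fields 5.33 and 3.82 V nm⁻¹, angles 69.60° and 9.37°, number
density $4.06\times10^{28}$ m⁻³ per dipole type in the confining space)
this gives $\epsilon_r = 6.65$ for the 2D water layer; combining with the
measured whole-crystal value 3.68 in a series-capacitor model (water
fraction 0.40) gives 2.84 for the bare CaSO₄ sheets.

Under an external field the four gypsum dipoles split into
$E_{HB} \pm E\cos\vartheta$ branches; recomputing the summation over the
±0.5 V nm⁻¹ range changes $\epsilon_r$ by at most 0.12% — a
second-order, even-in-field effect of order 0.1%, far below what the
crystal's capacitance measurement can resolve
(`field_modulation_epsilon()`).

For bulk liquid water, dipole reorientation dominates.  The
Langevin-Debye form with both contributions is
$\epsilon_r = 1 + \frac{N_0}{3\epsilon_0}[G_k p^2/k_BT + 2\alpha +
(2\alpha/15)(pE/k_BT)^2]$ with the Kirkwood correlation factor $G_k$
multiplying the orientation term only.  With the model dipole
$p = 2.66$ D (bond dipole at 0.984 Å summed over 103.924°) and $G_k = 1$
this gives $\epsilon_r \approx 28$; matching the experimental 79 requires
$G_k = 3.12$, inside the simulated range 2.72-3.70 for liquid water.
The orientation average behind the saturation term,
$\langle\cos^2\theta\rangle = \int_{-1}^{1}y^2e^{xy}dy /
\int_{-1}^{1}e^{xy}dy$ with $x = pE/k_BT$, is provided both by adaptive
quadrature (integrands rescaled by $e^{-x}$ so large $x$ cannot overflow;
relative tolerance $10^{-10}$) and as the quadratic Taylor expansion.
Note the exact average is $1 - 2\coth(x)/x + 2/x^2$: its quadratic
expansion is $1/3 + 2x^2/45$, which is what the Taylor mode implements
(the truncation error $\sim 4x^4/945$ stays below $10^{-4}$ for
$x \lesssim 0.4$), and saturation toward 1 goes like $1 - 2/x$, i.e. it
is reached only at very large reduced fields.  All reproduced results are
at $E = 0$, where the saturation term vanishes identically and the
distinction is immaterial.

Proton-ordered ices (XI, II, IX) follow the same summation, but their
dipole orientations must be supplied from published neutron structures
(`epsilon_ordered_ice()`); they are not packaged, and a clearly marked
synthetic example fixture is included only to exercise the code path.
The model deliberately does not address proton-disordered ices, whose
anomalously large $\epsilon_r$ comes from defect-mediated proton hopping.

## The synthetic field-sweep generator

`generate_field_sweep()` draws peak positions from the spring-softening
law and adds Gaussian peak noise.  Its defaults are the calibration
study's conditions: seven field points across ±0.5 V nm⁻¹ (the reversible
field window of the experiment), 1 cm⁻¹ peak-position noise (the scale of
Voigt-fit uncertainties on these bands), the gypsum angles and local
fields, 80 K.  What it emulates — and what it does not — bounds what the
recovery tests show: the generator produces ideal Gaussian, uncorrelated
peak noise on a perfectly linear response, with no baseline drift,
overlapping-peak bias, temperature-dependent zero-field shifts, or
field-calibration error.  Recovery of $(p'', E_{HB})$ within the quoted
2σ in ≥ 90% of 200 seeded replicates therefore validates the estimator,
not the spectroscopy.  Every stochastic operation takes an explicit seed
and restores the global RNG state.

## Numerical choices and degenerate inputs

* York iteration: relative slope tolerance $10^{-12}$, max 100
  iterations; non-convergence raises a typed condition carrying the last
  iterate.  Points with $\sigma_x = 0$ are handled exactly, so the fit
  degrades to y-weighted least squares as x-errors vanish.
* Shared-slope fit: the design matrix is built by hand (per-species
  indicator columns + shared slope) with the field column rescaled to
  unit magnitude before the QR solve — fields of order $10^9$ V m⁻¹ would
  otherwise make the normal equations numerically singular.
* Unit discipline: SI everywhere internally; `convert_units()` only at
  boundaries; 1 D = 3.33564 × 10⁻³⁰ C m; constants pinned to CODATA 2018
  (`hb_constants()`).
* Valid field domain: $E < k_0/p''$ (about 34 V nm⁻¹); beyond it the
  spring constant would be non-positive and every operation refuses.

## Problem sizes

The test suite runs the full calibration on the 21-bond table, 200-replicate
recovery studies for both estimators, and $10^4$-draw Monte-Carlo
uncertainty cross-checks; the whole suite completes in a few seconds on one
core, so all checks run at full size rather than sampled down.

## Known limitations

* One-dimensional: only the collinear response along the bond is modelled;
  bond bending and the full stiffness tensor are out of scope.
* No cooperativity: each bond sees an independent effective field, so
  many-body network effects enter only through $G_k$ in the liquid.
* The calibration's x-axis inherits the softening slope from the gypsum
  experiment; systems with very different acceptor chemistry extrapolate
  that calibration.
* Quoted-uncertainty conventions (1σ vs 2σ in source tables) are not
  always stated by the sources; the package uses values exactly as quoted
  and documents the resulting $\chi^2$ scaling.
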