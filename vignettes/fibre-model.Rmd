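---
title: "A statistical elasto-plastic model of a mineralised collagen fibre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A statistical elasto-plastic model of a mineralised collagen fibre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcfibre)
```

## Scope and assumptions

`mcfibre` simulates the compressive, quasi-static, one-dimensional response
of a single mineralised collagen fibre — a micrometre-scale bundle of
parallel mineralised collagen fibrils in a compliant extrafibrillar matrix
(EFM) — as tested in micropillar compression with in-situ X-ray scattering.
The model is rate-independent (experimental strain rates of order 1e-4 1/s
justify neglecting viscoelasticity), contains no damage variable (unloading
moduli are constant by construction, which is what such experiments report),
and treats dry tissue: bound water is folded into the organic volume
fractions. Tension–compression asymmetry, 2D/3D anisotropy and dash-pot
extensions are out of scope.

Compressive strain and stress are taken *positive* throughout the package.

## Composition

At the fibre level the tissue splits into fibrils (volume fraction
`phi_mc`, default 0.86) and EFM; at the constituent level into mineral,
collagen and non-collagenous proteins (NCP, includes bound water). The
tissue mineral density obeys the mixture rule
`rho = phi_min rho_min + phi_col rho_col + phi_ncp rho_ncp` with constituent
densities 2.90, 1.13 and 1.13 g/cm^3. Because the rule alone cannot
determine two unknowns, `fractions_from_density()` holds `phi_ncp` fixed at
its literature value (0.14) and solves the remaining linear equation for
`phi_min` without rounding. The default parameter set uses the tabulated
`phi_min = 0.29` directly (the measured density 1.64 g/cm^3 gives 0.288;
the difference is below every tolerance used here).

`fibril_count()` estimates the bundle size by the area ratio
`packing * (D/d)^2`; for a 6.08 um fibre, 224 nm fibrils and packing
density 0.86 this gives 634. The canonical bundle size 618 obtained from a
circle-packing optimisation is kept as the default `n_elements` — the
packing algorithm itself is not part of the package, the packing density
0.86 is an input constant.

## Nested shear-lag elasticity

Both composite levels assume that load transfers into the stiff phase only
by interfacial shear through the compliant phase, valid while the stiff
modulus exceeds the compliant shear modulus by an order of magnitude
(`shear_lag_params()` warns when violated). One convention required a
decision: the fibril-level formula needs the mineral fraction *within the
fibril*, while the tabulated 0.29 is a tissue-level fraction. With all
mineral assumed intrafibrillar, `phi_min_intra = phi_min / phi_mc = 0.337`,
the formula reproduces the canonical fibril modulus (20.36 GPa) to about
1 %; with the tissue fraction it misses by ~25 %. The intrafibrillar
convention is therefore the default (`mineral_intrafibrillar = TRUE`), and
the canonical value can always be pinned via the `E_mc` argument.

```{r}
p <- shear_lag_params()
c(fibril = fibril_modulus(p), fibre = fibre_modulus(p))
```

## The rheological element

Each fibril-plus-matrix element is a spring (apparent modulus `E_app` from
the nested shear lags) in series with two plastic sliders. Both sliders see
the same stress; slider `i` yields at
`|sigma| = E_app * eps_y_i + chi_i * alpha_i` with linear hardening on the
accumulated plastic strain, and the element is deactivated (zero stress,
forever) once a slider passes its ultimate plastic strain. Defaults: yield
strains 0.028 (mc) and 0.012 (ef), hardening 0.020 and 3e-6 GPa, ultimate
strains 9.0 and 0.09 — failure is extrafibrillar by assumption (the
intrafibrillar ultimate strain is one hundred times larger), and with the
default parameters the mc slider in fact never activates below the bundle's
strength, so plasticity is carried by EFM shearing.

*Numerics.* The strain-driven update is an implicit return mapping solved in
closed form: for one violated surface the classical radial return; when both
trial yield functions are positive, a 2x2 linear system in the two plastic
multipliers (they share one stress), falling back to the single-surface map
if a multiplier comes out negative. For linear hardening this update is
*exact* for any step size within a monotone strain segment, so the protocol
resolution (1e-4 strain) needs no sub-stepping. The test suite verifies
equality (to 1e-6 GPa and usually machine precision) against an independent
brute-force integrator that sub-steps at 1e-6 strain and solves the
two-surface case by scalar root finding, over 100 random parameter sets and
cyclic paths; Kuhn–Tucker consistency and non-negative dissipation are
asserted after every step. Dissipation is book-kept trapezoidally in the
stress, which makes work, stored energy and dissipation balance to machine
precision along any recorded path.

Deactivation is checked on the plastic-strain magnitude after the corrector;
an element failing within a step contributes zero stress for that whole
step. At the protocol resolution this blurs the failure instant by at most
1e-4 apparent strain.

## Statistical bundle and recruitment

`sample_elements()` draws every varied parameter independently per element:
the constituent moduli (`E_min`, `mu_col`, `mu_ef`) and the six plasticity
parameters, each normal with coefficient of variation 0.15 (the base value
for this tissue; the sensitivity scan spans 0.01–0.30). Each element's
fibril and apparent moduli are then computed through the two nested shear
lags from its own draws ("nested" mode; a "direct" mode sampling the fibril
modulus around its tabulated mean is available). Draws must be strictly
positive; invalid draws are rejected and redrawn, and more than 1000
consecutive rejections raise a configuration error. A skew-normal family
(Azzalini shape, re-centred to the requested mean and sd) covers the
skewed-distribution variation; `cov = 0` gives a degenerate, perfectly
homogeneous bundle. No cross-parameter correlation is imposed — only
marginal distributions are specified by the data.

Surface roughness of the micropillar delays contact between punch and
fibrils. The recruited fraction follows the sigmoid
`xi(eps) = 1/(1+exp(-(eps-mu)/beta))` with fitted `mu = 0.0215`,
`beta = 0.00635`; inverting it at `n/N` gives each element a deterministic
strain offset in element order. The expression is singular for the last
element, which receives the offset at `n = N - 0.5` (continuing the
midpoint convention); negative offsets mean the element is in contact from
the start (exactly 20 of 618 for the fitted parameters). Offsets are
assigned by element index, not shuffled against the sampled properties;
because properties are exchangeable across elements this only fixes which
random draw meets which offset.

*Unilateral contact.* The punch cannot pull: if an element's corrected
strain falls below its residual plastic strain during unloading it
separates and carries zero stress instead of going into tension. Without
this condition a full unload would drive plastified elements into reverse
yielding, inflating the accumulated plastic strains cycle by cycle and
changing the unloading moduli — both contrary to what the compression
experiments show. The symmetric two-slider element remains available (and
oracle-tested) through `element_step()`; the contact condition lives in the
bundle simulation only.

*Strain ratios.* Within one element the spring and the sliders form a
series chain, so the full element stress passes through the fibril segment:
the elastic fibril strain of element `n` is `sigma_n / E_mc_n` and its
mineral strain `sigma_n / (phi_min_intra * E_min_n)`. The ensemble
therefore evaluates the exported fibre-level formulas
(`fibril_strain_ratio()`, `mineral_strain_ratio()`) with `phi_mc = 1` per
element, against the total applied strain, including zero-stress
(unrecruited or failed) elements. This series convention is what reproduces
the measured ratio levels (about 0.20 fibril-to-fibre and 0.10
mineral-to-fibre at the yield point of the recruitment run); dividing the
element stress by the fibril volume fraction instead would overshoot both
by ~15 %.

## Protocol and derived quantities

The default protocol emulates the cyclic experiment: load–unload staircase
with peaks at 1–12 % strain, full unload between peaks, 1e-4 strain
resolution (~16,800 points), finishing reloaded at the last peak; 120
evenly spaced report points mimic the scattering read-out. A monotone ramp
is available (`cyclic = FALSE`) and gives identical loading envelopes, as
unload/reload cycles are elastic under the contact condition.

The *yield point* of the apparent curve is not uniquely defined by the
experiment, so `yield_point()` makes the criterion explicit and pluggable.
The default is a 0.2 % plastic-offset construction in which the reference
line takes the maximum smoothed slope of the loading envelope and is
anchored at that tangent's toe intercept. For a toe-free curve this is the
textbook offset method; for the recruitment curve — whose loading slope
never reaches the elastic modulus — the toe anchoring keeps the
construction meaningful. A bilinear tangent-intersection criterion
(`"intersect"`) is provided as the alternative; with the default parameters
the two differ by less than 10 % in yield stress. A curve that never
departs from the reference line returns an NA sentinel.

Apparent stiffness is reported twice: the shear-lag modulus of the mean
parameter set, and the maximum smoothed slope of the envelope (these agree
without recruitment; with recruitment the envelope slope is roughly halved
by the toe). Strength is the envelope maximum. First-fibril-failure is
recorded as the apparent strain, element index and accumulated plastic
strains at the first deactivation. With the default 15 % heterogeneity the
first element to fail is essentially the weakest of 618 draws of the
ultimate strain, so its accumulated plastic strain lies near the sample
minimum of N(0.09, 0.0135) — about 0.05–0.06 without recruitment and
0.055–0.07 with it (the offsets shift failure to ~0.071–0.077 apparent
strain). Readers comparing against published onset figures should note that
the printed onset values there are compatible with the apparent-strain
coordinate of first failure rather than with the failing element's own
plastic strain; both are exposed in the result object.

## Synthetic data and what the tests show

The fixture generators define the study conditions for everything that
cannot ship as data: `make_line_profiles()` builds quasi-periodic profiles
(Gaussian bump per fibril, 20 nm sampling — the instrument voxel size —
plus additive noise), `make_grey_histogram()` maps a Gaussian density
distribution through the forward Guinier model into reconstruction units
with a background offset, and `make_area_series()` evaluates the
recruitment sigmoid with optional multiplicative noise. They emulate the
*analysed* quantities, not the imaging physics: no reconstruction
artefacts, no spatially correlated speckle, no segmentation errors. Passing
tests therefore demonstrate that the analysis formulas are implemented
correctly and are robust to idealised noise, not that the pipeline would
survive raw tomography data.

The SRnCT analysis itself is deliberately small: the Guinier conversion is
linear in the grey value and exactly inverts its forward model; Gaussian
histogram fits use Levenberg–Marquardt least squares initialised from the
peak (FWHM = 2 sqrt(2 ln 2) sigma); fibril diameters combine an FFT period
estimate (parabolic interpolation of the log-amplitude peak, since profiles
contain few periods) with local-minima spacings (minima must be separated
by an excursion above the profile midline, for noise robustness), averaged
with the error propagated through the two variances — a documented
convention, as the published combination rule is not fully specified.
Sigmoid fits are bounded below in `beta` so that step-like series converge
to the bound and are flagged as degenerate rather than failing.

## Problem sizes and reproducibility

All shipped analyses are desk-scale: a full 618-element cyclic run takes
about one second; the acceptance script averages ten seeded runs per study
condition and finishes in well under a minute; the oracle comparison uses
short random paths at 1e-6 sub-stepping. Each run derives all randomness
from a single integer seed and is bit-reproducible for a fixed seed and
platform; `run_from_config()` writes a manifest (seed, configuration
snapshot, derived scalars) sufficient to re-execute a run exactly.

## Known limitations

* The bone presets implement the documented parameter transformations
  (density 1.90 g/cm^3, 1.8-fold smaller fibril diameter via the fibril
  aspect ratio, 1.81-fold fibril–matrix interaction scaling, 75 % lower
  roughness). They are qualitative scenarios: recomputing the composition
  from the bone density raises the shear-lag fibre modulus to ~28 GPa,
  i.e. the stiffness ordering of the scenarios is reproduced but not the
  published intermediate stiffness values, which depend on an unstated
  mapping of "higher mineralisation" into the shear lags.
* Linear hardening cannot represent strongly nonlinear post-yield
  behaviour; the sensitivity scan shows the consequences (a single
  softening mechanism: element deactivation).
* The yield criterion is a convention; yield strain and stress inherit an
  uncertainty of a few percent from it, which is why the package exposes
  the criterion rather than hard-coding one.
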