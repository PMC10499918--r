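---
title: "Modelling swimbladder backscatter with krmfish: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling swimbladder backscatter with krmfish: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krmfish)
```

## The model

A swimbladdered fish insonified dorsally scatters sound mainly from the
gas-filled bladder (a near-pressure-release inclusion) and secondarily
from the flesh (a weak fluid contrast). `krmfish` represents both as
stacks of finite cylinders read off digitized station tables and sums
their Kirchhoff-ray echoes coherently — the Kirchhoff Ray Mode (KRM)
picture. For an element of half-width $a_j$, axial extent
$\Delta u_j$ and upper-surface depth $v_j$ along the incidence
direction:

* gas-filled (swimbladder) elements contribute
  $$\Delta L_j = -\frac{i}{2\sqrt\pi}\,R_{bc}\,(1-R_{wb}^2)\,
  A_{sb}\sqrt{k_{fb}a_j + 1}\;
  e^{-i(2k_{fb}v_j+\psi_p)}\,\Delta u_j,$$
  where $R_{wb}$ and $R_{bc}$ are the water–body and body–bladder
  plane-wave reflection coefficients ($R = (Z_2-Z_1)/(Z_2+Z_1)$,
  $Z=\rho c$), $k_{fb}$ the wavenumber in the body tissue the ray
  traverses, and $A_{sb} = k a/(k a + 0.083)$,
  $\psi_p = k a/(40 + k a) - 1.05$ the classical empirical low-$ka$
  amplitude and phase corrections that blend the ray solution into the
  low-frequency modal regime;
* fluid (body) elements contribute a front-interface echo minus the
  internally transmitted back-interface echo,
  $$\Delta L_j = -\frac{i}{2\sqrt\pi}R_{wb}\sqrt{k_w a_j}\,\Delta u_j
  \left[e^{-2ik_w v_{U,j}} - (1-R_{wb}^2)\,
  e^{-i(2k_w v_{U,j} + 2k_{fb}h_j) + i\psi_b}\right],$$
  with $h_j$ the body thickness along the ray and
  $\psi_b = -\tfrac{\pi}{2}\,\kappa/(\kappa+0.4)$, $\kappa = k_{fb}h_j/2$,
  tending to $-\pi/2$ at high frequency.

$\sigma_{bs} = |L|^2$ and $TS = 10\log_{10}\sigma_{bs}$ (equivalently
$10\log_{10}(\sigma/4\pi)$ with $\sigma = 4\pi\sigma_{bs}$) are pure
conversions applied afterwards.

Assumptions inherited from this model class: single scattering, no
shadowing of the bladder by the backbone (not modelled), coherent
summation of body and bladder, no depth compression of the bladder, and
validity restricted to near-dorsal incidence — tilt angles
$\theta \in [65^\circ, 115^\circ]$, where $\theta = 90^\circ$ is
broadside and fish tilt is $90^\circ - \theta$ (so the "head-down 10°"
orientation is $\theta = 100$–$101^\circ$).

Two implementation details are deliberate design choices:

* **Tilt by rigid rotation.** The digitized geometry is rotated by
  $\theta - 90^\circ$ about the body centroid before depths are
  computed. $|L|$ is invariant to the choice of rotation centre (it
  only shifts a constant phase), which keeps the convention
  un-fragile; mirror symmetry of symmetric shapes about broadside then
  holds to machine precision.
* **Taper handling.** Elements span consecutive stations and use the
  trapezoidal mean of radius and boundaries, so terminal elements taper
  to the digitized tip radius; no separate end-cap factor is applied.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| $c_w,\rho_w$ | 1509, 1026 | m/s, kg/m³ | survey-water sound speed/density (CTD-derived) |
| $c_{fb},\rho_{fb}$ | 1570, 1070 | m/s, kg/m³ | fish flesh |
| $c_{sb},\rho_{sb}$ | 345, 1.24 | m/s, kg/m³ | swimbladder gas |
| $\Delta u$ | 1 | mm | slice thickness; 1 mm is the recommended operational trade-off, $\lambda/10$ (evaluated at 200 kHz, i.e. 0.75 mm) the refinement reference |
| $\theta$ grid | 65–115 step 1 | deg | KRM validity window |
| tilt models | 90±5, 90±10, 90±20, 101±12, 88±13 | deg | near-normal, spread, abnormal (head-down) and normal swimming |
| frequencies | 38, 70, 120, 200 | kHz | discrete survey frequencies; broadband grids at 1 kHz steps |

Tilt averaging uses a Gaussian evaluated at the grid nodes, truncated to
the support and renormalized to sum to one — a quadrature choice, made
explicit because the underlying studies state only the truncation. The
average is taken strictly in the linear $\sigma_{bs}$ domain;
log-transforming first would bias TS low.

TS–length regression is ordinary least squares of TS on
$\log_{10}(TL\,[\mathrm{cm}])$; the fixed-slope intercept is the mean
offset $b_{20} = \overline{TS - 20\log_{10}TL}$, whose reported
standard error is the intercept's ($s/\sqrt n$); the residual standard
error is also exported since published tables are ambiguous about which
is meant. The species comparison regresses each bladder measure on TL
over the *pooled* cohorts and compares the two species' residuals with
a Welch t-test: a within-species regression would centre both residual
sets on zero and void the comparison. The RFI confidence band is the
parametric mean ± 1.96 standard errors across fish; per-fish ratios are
exact divisions, so $r(38) \equiv 1$.

## The synthetic-fish generator

Real digitized radiographs of the two study species are not publicly
deposited, so the generator emulates them: linear scalings of
swimbladder length/height/width with total length anchored so that a
zero-noise fish at the reference length reproduces the template means
exactly (*T. mediterraneus*: 50/4/4.8 mm at 15.4 cm, inclination 10.9°;
*S. colias*: 30/5/7.1 mm at 14.4 cm, 11.4°); a "pear" family (posterior
taper, wide frontal region) versus a "spheroid" family; and a straight
bladder midline *sheared* (not rotated) to the drawn inclination so the
axial extent — and hence every measured dimension — round-trips exactly
through `measure_morphometrics()`.

The per-fish dispersion of the real cohorts is unpublished. The noise
model is multiplicative Gaussian with coefficient of variation 0.035 on
each dimension: with lengths uniform on $[lo, hi]$ the induced
dimension-on-length regression has
$r^2 = V/(V + cv^2\,\mathrm{E}[TL^2])$, $V = (hi-lo)^2/12$, and 0.035
places both species in the $r^2 \approx 0.95$–$0.99$ regime of real
digitized cohorts (0.08, for comparison, would give $r^2 \approx 0.86$
for the horse-mackerel length range).

What passing tests on synthetic cohorts do **not** show: the smooth
families omit haemal-spine surface ripples and all fine shape detail,
which drive the high-frequency spectrum and the depth of the real
relative-frequency-response contrast between species; synthetic RFI
curves are flatter than published ones. Morphometric scaling,
regression machinery, tilt averaging and the determinism of the
pipeline are what they exercise.

## Numerical choices

* Resampling is linear interpolation on a uniform grid spanning the
  original extent with endpoints preserved (the last interval shortens
  if the extent is not a multiple of $\Delta u$); it is idempotent at
  fixed spacing. Interpolation error behaves as chord sag — $O(\Delta
  u^2)$ on smooth arcs but $O(\sqrt{\Delta u})$ adjacent to a pole of a
  circular outline, so digitize rounded tips finely.
* The fluid-sphere modal series truncates no earlier than order
  $ka + 10$ and stops once three successive modes change $|L|$ by less
  than $10^{-6}$ relatively; stiff interior media use a small-argument
  ratio for $j_n'/j_n$ to avoid underflow. Non-convergence raises an
  error rather than returning a partial sum.
* Degenerate inputs are errors, not warnings: deflated specimens in
  acoustic calls (mirroring the exclusion of deflated fish from the
  study cohorts), tilt outside 65–115°, non-positive frequencies or
  material parameters, bladders outside the body outline.
* Zero acoustic contrast yields exactly $|L| = 0$; $TS = -\infty$ is
  deliberately representable.

## Benchmarks and a known limitation

The package carries its own exact references. The gas-sphere KRM agrees
with the partial-wave series within 1.5 dB for $ka \in [1, 10]$, and
the rigid-sphere series reaches the geometric limit $\sigma_{bs} =
a^2/4$ at $ka = 50$ to better than 0.1 dB. For the slender gas-filled
prolate spheroid (semi-axes 15 mm / 2 mm) the repository ships a
certified sound-soft exact solution
(`inst/extdata/spheroid_ts_soft_synthetic_oracle.tsv`, generated by
`tools/soft_spheroid_oracle.py` with the method of fundamental
solutions; per-frequency boundary residuals $< 4\times10^{-3}$ certify
the far field, and the generator reproduces the sphere series to
machine precision and the slender-body electrostatic capacitance limit
to $3\times10^{-6}$ relative).

Against that reference the KRM spectrum runs 0.9–2.1 dB hot across
38–200 kHz. The test suite asserts the published 0.5 dB / 1 dB
agreement bands and therefore fails them — intentionally left so. The
error is not a tunable-constant issue: at the same cross-sectional
$ka = 0.32$, the exact references require the element amplitude to be
*larger* than KRM's for a 2 mm gas sphere (+5.8 dB) but *smaller* for
the slender spheroid (−0.9 dB), so no local per-element correction can
satisfy both. This is the intrinsic accuracy floor of the
stacked-cylinder ansatz at $ka \lesssim 2$ for near-constant-radius
shapes, and it bounds the fidelity claims that should be attached to
KRM TS spectra in the 38–70 kHz band for small bladders.

Problem sizes used by the shipped tests — cohorts of 6–57 synthetic
fish, four discrete frequencies by 51 tilt angles, 1–2 kHz broadband
steps, 200-replicate recovery loops — are the package's choice of
desk-scale defaults; all scale linearly if enlarged.
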