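---
title: "The ntcsim optical model: assumptions, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ntcsim optical model: assumptions, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcsim)
```

## The system being modelled

A galvo–galvo two-photon microscope (Sutter-MOM geometry) whose excitation
path is, in the standard diffraction-limited (DL) arrangement, a 50 mm scan
lens 56.6 mm after the mirrors, a 200 mm tube lens 250 mm further (their
focal lengths sum to the separation, so the beam leaves collimated), and a
×20/1.0 water-immersion objective whose back aperture sits 95 mm after the
tube lens. The non-telecentric variants replace the scan lens: nTC₁ uses a
fixed L1 (f = 190 mm, exactly 190 mm before the tube lens, so that its focus
falls *on* the tube lens) plus a movable L2 (f = 175 mm); nTC₂ uses a single
movable L3 (f = 200 mm). Sliding the movable lens between 100 mm and a few
mm from the tube lens moves the intermediary focal point (IFP) and with it
the divergence of the beam at the objective: the field of view grows, the
focus moves beyond the nominal working distance, and the effective
excitation N.A. falls.

`ntcsim` models this path with ideal paraxial thin lenses composed by ABCD
matrices, a Gaussian beam carried as a complex beam parameter, and a single
limiting aperture. Everything downstream of the objective is immersed
(n = 1.33): image distances from the air-side trace are multiplied by n and
ray slopes divided by n, which leaves lateral focus positions unchanged —
so the field-of-view mapping is immersion-independent while focal depths
are not.

## The objective as an equivalent thick lens

The objective is known only by its catalogue identity (EFL 8.25 mm for a
×20 lens on a 165 mm reference tube length, N.A. 1.0, working distance
1.8 mm, back aperture ring 95 mm from the tube lens). A subtle but
consequential choice is *where* to put the single equivalent refracting
plane. Collapsing it onto the back-aperture ring is wrong for this system:
with L3 close to the tube lens the combined L3+TL power places the beam
crossing ~99 mm after the tube lens — past the aperture ring — so a lens
*at* the ring would see a still-converging beam and would focus *closer*
than nominal, the opposite of the design's behaviour. Physically, a long
water-immersion ×20 focuses ~10 mm beyond its rear principal plane, which
therefore sits near the objective's nose, several centimetres past the back
aperture. We model the objective as an ideal thick lens: the equivalent
refracting plane stands 50 mm beyond the aperture ring (a round geometric
estimate for a ~60–75 mm housing), and the 16.5 mm clear aperture
(2·N.A.·EFL) is evaluated at that plane. With this placement every nTC
setting focuses beyond the nominal plane and diverges at the aperture, as
the design requires, and the predicted field-of-view scaling of the nTC₂
family (2.5 mm → 3.5 mm as L3 moves from 100 mm to 5 mm) emerges from the
trace.

## Free parameters and their calibration anchors

Four quantities are not derivable from the lens prescription and are
treated as calibration parameters (`calibrate_optics()`), each anchored by
default to one published observable of the reference design:

| parameter | units | default anchor | fitted default |
|---|---|---|---|
| input beam waist `w0` (1/e² at the ETL/mirrors) | mm | DL axial two-photon FWHM 3.15 µm | 1.393 |
| usable mirror half-angle | deg | DL square field 0.5 mm | 6.94 |
| ETL gain | dpt/mA | 50 mA step → 600 µm shift (nTC₁) | 0.0382 |
| focal-sphere radius | mm | field-curvature 20 µm @ 1.2 mm and 87 µm @ 2.5 mm fields | 9.02 |

The fits are deterministic 1-D least squares (the model is separable in
these parameters); duplicated contradictory observables surface as nonzero
residuals rather than being averaged into silence. Reassuringly, the fitted
ETL gain (0.0382 dpt/mA) lands on the nominal sensitivity of the class of
current-driven tunable lenses used in such systems (~0.04 dpt/mA), and the
fitted beam waist implies a DL effective N.A. of 0.68 — the familiar
"effective" excitation N.A. of a Gaussian-overfilled 1.0 aperture.

## Field curvature

An all-ideal-thin-lens trace has an exactly flat field: an `f·tanθ` lens
cannot produce Petzval curvature, so the curvature cannot emerge from ray
composition alone. The reported curvature of the instrument behaves like a
property of the objective: the edge–centre defocus values at the four field
settings (20, 45, 87, 170 µm at 1.2, 1.8, 2.5, 3.5 mm) are mutually
consistent with a *single* sphere of radius ≈ 9 mm regardless of
configuration — the signature of glass-dominated (Petzval-like) curvature
rather than of the conjugate geometry. The model therefore carries the
focal surface as a sphere of configuration-independent radius, an objective
property calibrated once, by least squares, against the two
smaller-field observables (20 µm and 87 µm); the two larger-field values
are then predictions of the trace (the chief ray supplies r(θ), the sphere
the sagitta `R − sqrt(R² − r²)`), and come out within ~1%:

```{r curvature}
field_curvature_sagitta(optical_config("nTC1", 5), fov_mm = 1.8)   # ~45 um
field_curvature_sagitta(optical_config("nTC2", 5), fov_mm = 3.5)   # ~171 um
```

The sign convention: z increases away from the objective, edges focus
closer to it, sagitta ≥ 0. In the DL limit the same sphere predicts only
~3.5 µm of curvature across the 0.5 mm field — effectively flat, as a
telecentric design should be.

## Field of view and vignetting

`fov_diameter()` reports the mirror-limited diameter `2·|dx/dθ|·θ_max`, the
vignetting-limited diameter (the scan angle at which half of the 1/e² beam
footprint area is clipped by the aperture, threshold configurable), and
their minimum with the binding limit named. Whether a given printed field
endpoint is mirror- or aperture-limited is not stated by the design, so the
package always reports both.

A known limitation sits here. Calibrating the mirror range on the nTC₂
2.5 mm endpoint predicts the other endpoint at 3.500 mm — but the same
procedure on the nTC₁ family predicts 1.99 mm where the instrument reports
1.8 mm. The mirror-limited ratio of the nTC₁ trains is structurally ≈ 1.66
in any single-stop paraxial model of this prescription (we verified this
across a wide range of principal-plane standoffs and thick-lens offsets),
and the chief-ray heights at L2 at these angles exceed 10 mm — beyond the
clear radius of the one-inch L2 — so the real 1.8 mm endpoint is very
likely clipped by the *lens* apertures, an aperture chain the single-stop
model deliberately omits (the individual clear apertures and their
as-mounted positions are not published). We report the model's honest
1.99 mm rather than tuning geometry to the answer.

## ETL and axial scanning

The ETL enters the trace as a thin lens 200 mm upstream of the mirrors
whose power is linear in current. Axial shifts are reported positive toward
the objective (the "elevated planes" direction); they are monotone in
current over the modelled range, and the trace reproduces the leverage of
the design (hundreds of µm of focal travel from a few diopters). Settling
is a linear second-order system, natural frequency 300 Hz and damping
ratio 0.7 by default, chosen so a 150 µm step settles below a 5 µm error
band in under 3 ms — matching the observed 2–3 ms settling of such jumps —
and settling time is non-decreasing in step size. The real lens's thermal
and large-signal nonlinearities are out of scope.

## Two-photon PSF model

The excitation volume is the squared intensity of a Gaussian focus. The 1/e
radii of the two-photon volume use the standard Gaussian-focus closed
forms, `ω_xy = 0.320·λ/(√2·NA)` below N.A. 0.7 and
`0.325·λ/(√2·NA^0.91)` above, and
`ω_z = (0.532·λ/√2)·[n − sqrt(n² − NA²)]⁻¹`; FWHM = 2√(ln 2)·ω, with the
familiar 2√(2 ln 2) factor connecting σ and FWHM in the fitting code. The
effective N.A. comes from the focused Gaussian waist of the q-parameter
trace, clamped at the objective's 1.0.

Predicted absolute PSF sizes at the large-field settings are substantially
larger than the measured values of real instruments, because the paraxial
aberration-free model concentrates all PSF growth into the N.A. reduction
while real systems split it with aberrations; the *ordering* across
configurations (DL < nTC₁ 1.2 < nTC₁ 1.8 < nTC₂ 2.5 < nTC₂ 3.5 in both
lateral and axial width) and the low-N.A. scaling laws (lateral ∝ 1/NA,
axial ∝ 1/NA²) are the meaningful outputs, and those are what the test
suite asserts, including through full render→measure round trips.

## Scan engine conventions

* The stated ms-per-line *includes* the turnaround: printed frame rates
  equal `1/(n_lines · line_period)` exactly. Timing is summed in integer
  microseconds; rates are exact rationals of that.
* `n_lines` is always explicit — pixel-count strings like "340 × 170" are
  never parsed, since width×height and lines×pixels orders are mixed in
  common usage.
* Transitions between random-access regions cost 2 blanked lines each by
  default (configurable), including the wrap-around jump; rates are
  reported both with and without transition lines since conventions differ.
* The fast-axis ramp occupies 90% of the line by default
  (`turnaround_fraction = 0.1`); the Pockels channel is 1 on active pixels
  and 0 on every turnaround, retrace and transition sample — the blanking
  contract is asserted sample-wise in the tests.
* The halfpipe drive is `peak · sqrt(max(cos(π(l/(n−1) − ½)), 0))` over the
  slow-axis line index: zero at the frame edges, peak at the centre line.
  The `sqrt(cos)` form is the documented choice of argument scaling (one
  half-period across the frame, clipped at zero).
* The ETL command is piecewise constant per line (the hardware receives one
  command per line tick), so z-profiles quantize to lines.

## Rendering model

Pixel values are `background + Σ_e brightness_e × overlap(emitter sphere,
excitation volume at the pixel's focus)`. The squared-intensity Gaussian
has FWHMs from the PSF model; a sphere of diameter D is approximated by a
Gaussian of matched per-axis variance (σ = D/√20), making the overlap a
product of 1-D Gaussian convolutions (`amp = B·(σ_L/σ_L')²·(σ_A/σ_A')`,
primes denoting broadened widths). `brightness` is the emitter's total
signal; sub-PSF emitters therefore dim relative to PSF-sized ones at equal
fluorophore density, reproducing optical merging. At field edges the
Gaussian is tilted along the local chief ray (rotation in the radial
plane, evaluated per emitter since only nearby pixels contribute).
Vignetting scales the excitation as (1 − clipped fraction)², the two-photon
power-squared dependence. By default the renderer "refocuses" like a user
would — the phantom plane z = 0 coincides with the configuration's on-axis
focal plane — while `refocus = FALSE` keeps absolute focal depths. Noise is
additive Gaussian with a recorded seed; shot noise is deliberately not
modelled.

The generator and renderer emulate geometry, PSF-size effects, field
curvature, vignetting and kernel-shaped calcium dynamics. They do not
emulate scattering, depth-dependent aberrations, detector/photon noise
statistics, motion, or realistic neuroanatomy — so tests passing on
rendered data validate the geometry and the analysis pipeline, not
robustness to real-tissue artefacts.

## Analysis conventions

* Bead detection: local maxima above median + 8 s.d. of the background
  (the detection rule is ours; the protocol it mimics does not state one).
  Beads whose fit window would cross the stack border, or with a second
  bead inside ~3 widths, are excluded rather than mis-fit — the protocol
  measures isolated beads and averages ≥10 of them.
* No bead-size deconvolution is applied; estimates are convolved widths,
  matching how such measurements are reported (the 0.175 µm bead broadens
  the DL lateral FWHM by ~1.5% in quadrature).
* The neighbour-correlation map defaults to 8-connectivity; zero-variance
  pixels map to 0 by convention; the map is invariant to per-pixel affine
  intensity rescaling by construction (time series are centred and
  normalized before the products).
* Z-scores are relative to each ROI's own baseline window (mean 0, s.d. 1
  on the baseline by construction); zero baseline variance is an explicit
  error, and a constant or non-converging profile yields an explicit
  fit-failure object, never a silent number.

## Numerical choices

Rays and matrices are exact closed forms, so the geometric focus, the
101-ray fan trace and the ABCD crossing agree to machine precision; the
Gaussian waist differs from the geometric focus only by the diffraction
focal shift (< 0.02% of the focal distance everywhere in the modelled
regime). One-dimensional calibrations run a 61-point grid pre-scan before
`optimize()` (tolerance 1e-12) because the ETL-shift landscape wraps
through infinity at unphysically large gains and is only locally unimodal.
Timing uses integer microseconds. The vignetting area fraction uses the
analytic two-disc intersection. Degenerate inputs (flat fit profiles, empty
baselines, zero-focal-length lenses, out-of-range scan angles and
currents, profiles beyond the ETL range) raise typed errors naming the
offending quantity.

Test problem sizes are chosen to exercise the full protocols at desk
scale: the bead protocol runs at its native 30 µm / 256 px / 0.5 µm
sampling on the DL configuration, while the five-configuration ordering
check scales pixel size and z-step to each PSF (96 px stacks) so the whole
suite completes in seconds.

## Known limitations

* Single-stop vignetting: intermediate lens apertures are not modelled;
  the nTC₁ large-field endpoint is over-predicted by ~10% as a result (see
  above).
* Aberrations beyond the spherical focal surface — spherical aberration,
  coma, astigmatism, and the aberration part of PSF growth — are out of
  scope; absolute nTC PSF sizes are upper-bounded by geometry only.
* The two galvos are collapsed to one pivot; the ~1 cm inter-mirror
  separation is a second-order effect at these angles.
* The ETL is linear in current and in its second-order settling; no
  thermal drift or hysteresis.
* Collection optics, detectors and power throughput are not modelled at
  all: the twin predicts excitation-side geometry and relative
  brightness, not absolute photon budgets.
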