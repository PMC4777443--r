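---
title: "Simulating subjective refraction from wavefront aberrometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating subjective refraction from wavefront aberrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`refractsim` computes the monochromatic retinal image of a reduced schematic
eye (focal length 22.4 mm, refractive index 1.33, wavelength 587 nm) whose
wavefront error is given as OSA-indexed Zernike coefficients over a
measurement pupil. Image formation is scalar Fourier optics. The total
pupil-plane phase is the pointwise sum

W_T(x, y) = W_eye + W_lens + W_JCC · S (+ W_CL),

where `W_eye` is the aberrometry wavefront (piston and tilts excluded by
default: they do not affect image quality), `W_lens` the summed phase of the
virtual phoropter's thin lenses, `W_JCC` the cross-cylinder phase gated by
its activation state `S`, and `W_CL` an optional multifocal contact-lens
phase plate. The PSF is the squared modulus of the Fourier transform of the
complex pupil function `p(x,y) exp(-i 2π W_T / λ)`, normalized to unit sum,
and the retinal image is the convolution of the PSF with the paraxial image
of an optotype chart, after applying anamorphic spectacle magnification to
the chart.

Every trial lens lives at the phoropter plane a vertex distance `d_v` in
front of the entrance pupil: its power is transposed per principal meridian
with `F' = F / (1 - d_v F)` before its phase is evaluated at the pupil, and
its apparent-size effect is `SM = 1 / (1 - d_v F)` per meridian. Contact
lenses sit at the pupil plane: no transposition, no magnification. Each lens
in a stack is transposed independently and the phases summed — consistent
with the thin-lens assumption throughout.

Sign conventions (the field uses both; the choice here is enforced by
round-trip tests and documented rather than load-bearing): minus-cylinder
notation, TABO axes counterclockwise from horizontal with 0° displayed as
180°; a lens of power vector (M, J0, J45) contributes
`W = -1/2 [M r² + J0 (x² - y²) + 2 J45 x y]` (r in mm, powers in D, W in
µm), so a myopic eye carries positive defocus `c(2,0)`.

## Units and sampling

All imagery lives in visual-angle coordinates (arcmin);
`arcmin_to_retinal_um()` converts to retinal microns for reporting only.
A `grid_spec` fixes the discretization: `n_pupil` samples across the pupil
diameter and an FFT zero-padding factor, giving a PSF pixel scale of
`λ / (n_fft Δx)` radians. Defaults are 256 samples and pad 4 for metric
work; refraction sessions default to 128 samples and pad 2, which keeps a
full procedure under ~15 s while leaving every 0.25 D / 5° decision
unchanged (the padding-convergence test shows metric shifts below 1% when
the padding doubles). FFT centring uses the standard checkerboard
pre-multiplication so the zero-phase PSF peaks exactly on pixel
`n_fft/2 + 1`.

Zernike coefficients are rescaled to a smaller simulation pupil analytically
(per azimuthal family, via the monomial expansion of the radial
polynomials — a triangular, exact transform); a dense least-squares refit
serves as the independent oracle in the tests. Up-scaling is refused: it
would extrapolate the measurement.

## The automated observer

The clinical procedures need a numeric stand-in for the patient:

* **Acuity** (`estimate_va`): the smallest logMAR size (0.1 steps, -0.3 to
  1.3) at which the rendered Snellen E is identified. Identification scores
  the image against four diffraction-limited orientation templates with a
  contrast-retaining matched filter (the regression slope of image on
  template) and requires the true orientation to win by a margin of 0.02.
  A plain normalized correlation was rejected: it "recognizes" orientation
  from sub-threshold residual contrast that no observer could see. Both the
  0° and 90° orientations must be identified, which guards against
  astigmatic blur favouring one meridian. Beyond roughly 2 D of defocus,
  spurious resolution (contrast reversal in the defocused OTF) can make
  single sizes identifiable again; acuity is therefore only claimed to be
  monotone in blur over the clinical 0–1.5 D range.
* **Dial sharpness** (`dial_line_sharpness`): per-radius mean gradient
  magnitude transverse to the line inside an annular region of interest;
  equality is declared when the coefficient of variation of the 12 scores
  drops below 0.03 (the spread measured for a diffraction-limited render).
* **Flip preference**: the Visual Strehl ratio of the two JCC positions;
  **flip equality**: the Pearson similarity of the two rendered dot-pattern
  images reaching τ_eq = 0.995. Both thresholds are session options.

The Visual Strehl ratio is the VSOTF variant: the CSF-weighted volume of
`Re(OTF)` over that of the diffraction-limited OTF. The neural weight is a
simple radially symmetric band-pass, `(f/4) exp(1 - f/4)` cpd truncated at
60 cpd; because VS is a ratio its absolute scale cancels, and the rotation
invariance of pure-cylinder scenes is tested. Published VS variants differ
(VSOTF/VSMTF/VSX); VSOTF was chosen as the most common and the integrand is
isolated in one function so alternatives can be plugged in.

## The procedures

`full_refraction()` chains: an objective starting sphere (the sphere
zeroing the spherical equivalent of the scene's second-order wavefront —
what an autorefractor reports, and the clinically assumed starting point);
fogging with a standing +1.00 D plus top-up until acuity ≥ 0.50 logMAR (the
standing fog is necessary: cylinder blur alone can satisfy the acuity
criterion while a focal line still sits behind the retina, which flips the
dial's sharpest-line geometry); the clock dial (sharpest line → axis via
the rule of 30, then minus cylinder in 0.25 D steps until the line scores
equalize); objective repositioning of the circle of least confusion onto
the retina; JCC axis search (10° then 5° steps toward the preferred flip)
and power search (0.25 D steps, +0.25 D sphere per accumulated -0.50 D
cylinder when `maintain_clc = TRUE`, oscillations bracketed); and sphere
refinement to maximum plus for best acuity. All quantities move in exact
0.25 D quanta (binary fractions, so spherical-equivalent conservation under
the CLC rule is floating-point exact at every half-diopter accumulation and
within 0.125 D between them).

## Example eyes

`make_eye()` generates the study conditions: an `emmetrope`; a `P1_like`
low-order astigmat whose full correction is plano sphere with -0.75 D
cylinder axis 180 (plano is the neutral default; the correcting
sphero-cylinder is a constructor argument); a `P2_like`
irregular-astigmatism eye with
seeded random coefficients over radial orders 3–6 scaled so the
higher-order RMS is exactly 1.44 µm, on top of a fixed moderate second-order
error — only these summary constraints are honoured, the individual
coefficients are synthetic; and `random_loa` eyes (|S| ≤ 3 D, C in [-2, 0]
D, axes on a 5° lattice, 0.25 D quanta) for parameter-recovery batteries.
The generator emulates clean single-wavelength aberrometry: no measurement
noise, no chromatic aberration, no accommodation, no pupil dynamics, no
cone sampling or neural processing — so passing tests demonstrate the
optical/procedural logic, not performance on noisy clinical data.

The multifocal designs are concentric-ring centre-near lenses with +2.00 D
add: CL1 with rings near/intermediate(+1.00 D)/distance, CL2 alternating
near/distance/near. Ring radii are not published numbers; the defaults
split a 3-mm pupil radius at 1.5 and 2.25 mm and are fully overridable.
Through-focus curves add virtual spheres at the pupil plane, so the x-axis
reads directly as object vergence.

## Numerical choices and degenerate inputs

* Retinal-image convolution crops the PSF to the smallest centred kernel
  holding all but 1e-8 of its energy, renormalized, and pads to FFT-friendly
  sizes; mean image intensity is conserved to 1e-6.
* Charts are black-on-white rasters converted to emission (white-on-black)
  for convolution and inverted back, so zero-padding is physically dark
  surround.
* Anamorphic magnification uses inverse-mapped bilinear resampling about
  the image centre with background fill.
* A JCC flip toggles a state flag rather than adding 90° to the axis, so a
  double flip restores the phase bit-exactly.
* Ties in flip preference keep the current state (the clinical end-point);
  A→B→A oscillations in the power search terminate at the bracketed choice,
  which is within one 0.25 D quantum of the optimum.
* Degenerate inputs are rejected with messages rather than propagated:
  up-scaling pupils, lenses whose focal point lands on the pupil plane
  (`1 - d_v F = 0`), contact lenses not covering the pupil, charts larger
  than the convolution guard, non-finite phases.

## Known limitations

Monochromatic 587 nm only; no Stiles–Crawford apodization, photon noise, or
psychometric response modelling — the automated observer is deterministic,
so recovered prescriptions have no test–retest variance. Spectacle
magnification of a stack is computed from the power-vector sum of the stack
rather than the product of per-lens anamorphic maps (identical for aligned
axes, a second-order approximation otherwise). Acuity estimates are a
surrogate: absolute logMAR values depend on the template-matching margin
and should be compared within the simulator, not against clinical charts.
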