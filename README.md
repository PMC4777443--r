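# refractsim

Virtual subjective refraction from ocular wavefront aberrometry.

Subjective refraction — the "which is better, one or two?" routine — finds
the sphero-cylindrical lens `(S, C × α)` that best corrects a patient's
vision. Its classical tests (fogging, the astigmatic clock dial, the
Jackson Cross Cylinder) are hard to teach and hard to study, because only
the patient sees the retinal image. `refractsim` computes that image: it
simulates, for an eye described by its measured wavefront aberrations, what
each chart looks like at every step of the procedure, and runs the
procedures themselves with an automated observer. It is aimed at visual
optics researchers and at optometry instructors who want reproducible,
scriptable refraction scenarios — including ones a trial frame cannot
produce, such as high-order aberrations or multifocal contact lenses.

## The model

An eye's wavefront error is a set of OSA-indexed Zernike coefficients
`c_j` (µm) over a measurement pupil, attached to a reduced schematic eye
(focal length 22.4 mm, index 1.33, λ = 587 nm). The scene phase at the
exit pupil is

```
W_T(x,y) = W_eye + W_lens + W_JCC · S (+ W_CL)
PSF      = | FFT( p(x,y) · exp(−i 2π W_T / λ) ) |²
Im       = O ⊛ PSF
```

with every phoropter lens transposed to the pupil plane
(`F' = F / (1 − d_v F)` per principal meridian) and the paraxial optotype
`O` pre-distorted by the anamorphic spectacle magnification
`SM = 1 / (1 − d_v F)`. Trial lenses use power vectors
`M = S + C/2`, `J0 = −(C/2)cos 2α`, `J45 = −(C/2)sin 2α`, which add under
stacking. Image quality is summarized by the Strehl ratio and the Visual
Strehl ratio (VSOTF: CSF-weighted volume of `Re(OTF)` against the
diffraction-limited OTF); acuity is estimated by template-matching rendered
Snellen Es against diffraction-limited ones.

## Worked example

A low-order astigmat whose full correction is `plano −0.75 × 180`,
refracted automatically at a 2-mm pupil radius:

```r
library(refractsim)

eye <- make_eye("P1_like")            # synthetic example aberrometry
s   <- refraction_session(eye, pupil_radius = 2)

s <- fog(s, initial_add = 1.0)        # fog to >= 0.50 logMAR
s <- clock_dial_procedure(s)
s$results$clock_dial
#> $axis
#> [1] 180
#>
#> $cylinder
#> [1] -0.75
```

The dial stops at −0.75 D of cylinder, axis 180 — the eye's true
correction. The full pipeline (`full_refraction()`) chains fogging, the
dial, the JCC axis and power searches (keeping the circle of least
confusion on the retina: +0.25 D sphere per −0.50 D cylinder), and final
sphere refinement:

```r
z <- make_eye("random_loa", seed = 4)  # +0.50 -2.00 x 10 ground truth
out <- full_refraction(refraction_session(z, pupil_radius = 2))
session_trial(out)
#> +0.50 -2.00 x 10
```

Through-focus evaluation of a centre-near multifocal contact lens on an
aberration-free eye (3-mm pupil radius):

```r
s1 <- refraction_session(make_eye("emmetrope"), pupil_radius = 3,
                         cl = cl1_design(), n_pupil = 256, pad_factor = 4)
curve <- defocus_curve(s1, seq(-3, 1, 0.25))
curve$vs[curve$defocus_D %in% c(-2, -1, 0)]
#> [1] 0.2411 0.2183 0.3406
```

The curve is bimodal (distance and near foci) and retains intermediate
performance through the +1.00 D transition ring; the alternating
near/distance design (`cl2_design()`) collapses to VS ≈ 0.02 at −1 D.

Rendered images (`session_render()`, `render_retinal_image()`),
interferograms and PSFs can be written to PNG with `write_image_png()`. A
command-line wrapper over the same functions is installed at
`inst/cli/refractsim.R` (subcommands `simulate`, `clock-dial`, `jcc`,
`defocus-curve`, `session`, `make-eye`).

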