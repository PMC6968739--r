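---
title: "Digital refocusing and extended depth of field for Fourier ptychographic blood-film imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital refocusing and extended depth of field for Fourier ptychographic blood-film imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fpmtools)
```

## The imaging problem

Fourier ptychographic microscopy (FPM) records a sequence of low-resolution
intensity images under angle-varied LED illumination and stitches their
shifted passbands in frequency space into a single high-resolution complex
field. The synthetic numerical aperture is `NA_syn = NA_obj + NA_illu`,
so a 10x/0.3 objective with illumination out to `NA_illu ~ 0.6` behaves
like a 0.9-NA system for resolution — but also for depth of field. The
classical incoherent DoF,

    DoF = lambda * n / NA^2 + n * e / (M * NA),

drops from roughly 8.4 um for the raw images to roughly 1.3 um for the
reconstruction (`depth_of_field()`), about 15% — a thin blood film of
~3 um thickness no longer fits inside one focal plane. Red-cell membranes
and intracellular malaria parasites (MPs) then focus at different planes,
which is exactly what this package models, simulates, and corrects.

Two thin-sample limits bound the territory. The first-Born condition
`k t dn / 2 << 1` (`born_thickness_coefficient()`) gives coefficients of
about 2 per um for a dry film (sample index 1.40 in air) and 0.5 per um
under oil at 0.63 um. The shifted-spectrum approximation itself holds up
to `h_max = pi / |k_z|_max = lambda / (2 (1 - sqrt(1 - NA_illu^2)))`
(`ou_thickness_limit()`), about 2.7 wavelengths (1.7 um at 632 nm) at
`NA_illu = 0.58`; both calculators are exposed because they anchor every
design choice downstream.

## Forward model and reconstruction

The simulator implements the thin-object model: for illumination
direction cosines `(alpha, beta)` the camera records

    I_i = | iFT[ T(u - alpha/lambda, v - beta/lambda) * P(u, v) ] |^2,

with `T` the object spectrum and `P` the pupil (binary CTF by default,
optionally carrying a Zernike aberration). Spectrum shifts are rounded to
the nearest frequency pixel; camera-grid downsampling is band-limited
(Fourier cropping), which is exact here because the intensity band
`2 NA_obj / lambda` fits the camera Nyquist rate. Optional Poisson shot
noise (photon budget) and Gaussian read noise are off by default; every
random path demands an explicit seed.

`reconstruct()` runs the sequential Gauss-Newton recovery: per frame, the
modelled passband field has its amplitude replaced by the measured
`sqrt(I)` (phase kept), and the object patch — and with EPRY the pupil —
receives the regularised update

    O <- O + conj(P) |P| / (max|P| (|P|^2 + delta_obj)) * dPsi
    P <- P + conj(O) |O| / (max|O| (|O|^2 + delta_pupil)) * dPsi.

The literature states no unique update equations, so these forms are fixed
here and pinned by fixed-point and recovery tests. Defaults: 50
iterations (150 for IPM refocusing, which genuinely needs them),
`delta = 1e-3` both, centre-out frame order by illumination NA with ties
by frame index, convergence when the relative residual change falls below
`1e-4`, pupil magnitude capped at 1.1, and the final spectrum masked to
the synthetic NA disc. No global phase is anchored; comparisons against
truth go through `nrmse_mod_phase()`, which minimises over a global phase
and +/-2 px shifts. A run aborts if the residual grows for three
consecutive iterations above a 1e-12 floor (the floor keeps
machine-precision jitter from tripping it).

Pupil aberrations are summarised by least-squares projection of the pupil
phase onto Noll-normalised Zernike modes (`fit_zernike()`); defocus is
`Z(2,0) = sqrt(3)(2 rho^2 - 1)`, and the normalisation is stated because
a coefficient without one is meaningless.

## Refocusing: PRR and IPM

Post-reconstruction refocusing (PRR) propagates the recovered field with
the angular-spectrum transfer function

    H(u, v) = exp(i (2 pi / lambda) z sqrt(1 - (lambda u)^2 - (lambda v)^2)),

exact for scalar fields; evanescent components are zeroed by default (a
real-exponential decay policy is available). The alternative linear
kernel `exp(i 2 pi z / lambda) exp(-i pi (z / lambda) sqrt((lambda u)^2 +
(lambda v)^2))` delays plane waves linearly in radial frequency — more
phase at low-to-mid angles, less at the largest angles — which can favour
the frequencies where real data keep their signal-to-noise. The printed
form of the linear kernel is typographically ambiguous in its source; the
implemented reading is the dimensionless one above, recorded as
normative. Whether its constant `exp(i 2 pi z / lambda)` factor is kept
is cosmetic for intensity rendering.

Initial pupil modification (IPM) refocuses instead by multiplying the
pupil with the angular-spectrum phase for `-z` and re-running the whole
reconstruction. The two agree closely inside the raw DoF, and both decay
once the sample leaves it; but one IPM plane costs a full reconstruction
(iterations x frames x FFTs on the raw grid) against two FFTs for a PRR
plane — a ratio far beyond 100x, which the package reports as FFT-work
estimates (`cost_flops`) rather than wall-clock, so the comparison
survives hardware changes. Sign convention: positive `z` moves the
virtual focal plane toward the detector; the round-trip and group tests
pin it.

`focal_plan(thickness, dof)` spans the film with a step of `dof / 5` by
default — for a 3 um film at the synthetic DoF this gives at least twelve
planes, the operating plan used throughout.

## The blood-film phantom

`make_blood_film_phantom()` is first-class, tested code: it emits complex
transmittance layers plus an exact truth record, and every quality claim
in this package is measured against it. The rendering aims at a dried,
fixed, Giemsa-stained thin film:

* Cells are flat pancakes (interior optical path ~1.1 um) with a rim
  torus peaking at 2.5 um and a dark absorbing membrane ring (amplitude
  drop 0.45 in air, nearly none under oil, where index matching removes
  the rim contrast). A live-cell biconcave profile was deliberately
  rejected: its interior curvature acts as a microlens of roughly 9 um
  focal length that visibly displaces the apparent focus of intracellular
  objects — real for live cells, wrong for dried smears.
* Phase is `k (1.40 - n_medium) t(x, y)` with sample index 1.40; in air
  the interior sits near 4.4 rad, under oil near -1.1 rad.
* Each infected cell (30% of cells by default, rounded) hosts one
  parasite: a purely absorbing chromatin spot of 1.2 um diameter with a
  fainter cytoplasmic ring, on its own layer at an axial offset drawn
  uniformly from +/-1.5 um. The spot carries no phase: a phase-bearing
  dot defocuses antisymmetrically (dark on one side of focus, bright on
  the other), which biases any amplitude-based focus estimate by
  ~0.5-1 um — a genuine limitation of amplitude-only plane selection that
  the phantom documents rather than hides.
* Layers combine by propagate-multiply (`compose_layered_object()`), the
  standard multi-slice composition, and the exit wave is band-limited to
  the synthetic NA before analysis.

The defaults (20 cells, 600^2 px at 0.1417 um, seed-mandatory placement
with bounded retries) mirror the instrument's operating patch. What the
phantom does not emulate: partial coherence, LED spectra, stain
variability, overlapping-cell stacks, camera noise unless asked for —
so passing tests demonstrate algorithmic correctness under the stated
model, not clinical performance.

## EDoF pipeline and its coherent-imaging corrections

The rendering pipeline (`run_edof_pipeline()`) follows the blood-film
recipe: per-plane raw masks (air: Sobel edges of the least-squares
unwrapped phase OR an adaptive dark-amplitude threshold; oil: binarised
amplitude-or-phase AND Sobel-edge-or), unioned across planes, cleaned by
the 50-px size filter, reflective padding and morphological filling;
clumps are split by removing the band between the closed mask and its
eroded interior plus a matching erosion of the filled mask, then growing
the resulting cores back through the filled mask and cutting along the
grown-label boundaries; components below 12 um^2 (about half a cell) are
dropped. Candidate parasites come from Otsu thresholding inside the
eroded cell footprint on every plane, with three guards the source recipe
leaves implicit but coherent noise-free data require: an upper equivalent
diameter of 2.5 um, a darkness guard, and persistence in at least 40% of
the planes (defocus caustics appear only in a few extreme planes; a true
absorber persists).

Two steps had to be re-derived for coherent fields, and both are worth
stating because they invert incoherent intuition:

* **Membrane focus.** For an absorption-dominant target, the sharpest
  plane maximises edge strength, and `sharpness_rank()` implements
  exactly that ranking (3x3 median filter, total Sobel magnitude, top two
  planes, higher variance wins, ties to lower z). A stained film,
  however, carries several radians of smooth phase: at focus that phase
  is invisible and the gradient energy is *minimal*; off focus it erupts
  into fringes. The pipeline therefore locates its membrane plane at the
  gradient-energy minimum (internal `membrane_plane_rank()`), verified on
  both air and oil phantoms, while `sharpness_rank()` keeps the
  absorption-appropriate rule used for calibration targets and channel
  alignment.
* **Parasite plane selection (air).** The selection rule matches the
  apparent object perimeter to that of a typical ring-stage parasite
  (4 um). Contour-pixel counts on coherent amplitudes are dominated by
  defocus ringing, so the perimeter is measured as the area-equivalent
  circle perimeter `2 sqrt(pi A)` of the candidate's dark footprint, with
  sub-pixel (soft) coverage, a threshold held fixed across the whole
  series — so defocus blur monotonically shallows the object — and a
  lightly smoothed perimeter-versus-z curve whose end planes serve only
  as smoothing support. The oil variant maximises Michelson contrast of
  the candidate against its intracellular surround. Ties go to the plane
  nearest the membrane plane.

The consistency check resets assignments farther than half the film
thickness (3 um default) from the film centre; the centre defaults to the
median of the assignments, but the pipeline anchors it at the membrane
plane, because with few parasites a skewed median wrongly clips honest
extreme-z assignments. Composition takes the membrane plane as base and
replaces each cell's intracellular region by its selected plane with a
1-px feathered boundary; all other pixels are drawn verbatim and the
per-pixel plane index is recorded.

Phase unwrapping is residue-free least squares (a Poisson solve via
mirror-extended FFT) followed by snapping to the nearest 2-pi-congruent
surface, so the output differs from the wrapped input by an exact
multiple of 2 pi everywhere. A quality-guided region-growing unwrapper
was considered and rejected: interpreted-language flood fills are orders
of magnitude too slow for 600^2 x 12-plane series, and the smooth,
residue-free phases produced by this model are exactly the case where the
least-squares solution is already the true one.

On the canonical phantom (seed 1) the full pipeline finds 20/20 cells and
6/6 parasites with no false positives and every parasite within one
0.25 um step of its true plane. Across other seeds, occasional
rim-proximal parasites are missed and ~20% of plane assignments drift
beyond one step — the phantom keeps these failure modes visible, and they
set realistic expectations for harder data.

## Chromatic correction

Colour FPM suffers per-channel focal shifts. `align_channels()` finds the
sharpest plane per channel and reports offsets relative to green; the
default ranking is the absorption-appropriate sharpness rule, with
`method = "membrane"` for phase-bearing films. `color_edof()` shifts each
channel's axial frame by its offset, runs the EDoF pipeline per channel,
and merges the composites with per-channel 0.1-99.9 percentile
normalisation (the merge normalisation is unstated in the source; the
percentile rescale is this package's choice). Channel wavelengths default
to 632/525/470 nm; only the red emission maximum is instrument-specified.

## Numerical and testing choices

Frequencies are cycles/um everywhere (pupil cutoff `NA / lambda`); the
radian convention never crosses a module boundary. All morphology is
8-connective; coordinates are pixel-centred. SSIM uses an 11-px Gaussian
window (sigma 1.5), `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, and the
luminance-omitted variant simply drops the luminance factor while keeping
`C2` — experimental SSIM values against real microscope references are
not reproducible at desk scale and are replaced throughout by these
synthetic-fixture properties. Problem sizes in the test-suite: unit tests
run at 64-360 px grids; the end-to-end checks use the instrument-scale
600^2 patch with 69 LEDs and 50 iterations, a 12-plane 0.25 um focal
series, and 256^2 refocusing studies — sizes chosen to exercise the
operating regime while keeping a full run in minutes on one CPU.

Known limitations: amplitude-based plane selection cannot resolve
phase-dominant inclusions (see above); the thin-object forward model is
used even for the physically layered phantom, so thick-sample multiple
scattering is out of reach by construction; LED positions map to angles
without slide-refraction correction; and the sharpness inversions
documented here mean any gradient-based "autofocus" on coherent
noise-free amplitudes should be treated with suspicion before being
applied to real, partially coherent data.
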