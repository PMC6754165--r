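---
title: "Methods: multi-focus phase-mask design and HiLo sectioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-focus phase-mask design and HiLo sectioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hilomfm)
```

This vignette records the models, numerical conventions and design choices
behind the package, in the spirit of a methods section: what is computed,
under which assumptions, and what the built-in tests do and do not
demonstrate about real instruments.

## 1. Sampled wave optics

A `complex_field` is a sampled complex amplitude with a physical pitch and
wavelength; all lengths are micrometres. Conventions, fixed once and used
everywhere:

* the array origin is the centre sample, index `floor(n/2) + 1`;
* spectra are held in FFT order internally and shifted only for display;
* images are row-major with the origin top-left; physical coordinates map
  pixel centres.

**Lens Fourier transform.** `fourier_lens_transform()` evaluates
`U = 1/(iλf) ∬ E exp(+i2π(ux+vy)/(λf)) dx dy` as a centred DFT
(`fftshift ∘ FFT ∘ ifftshift`, which is exact for the centred sampling
above), with the output pitch rescaled to `λf/(N·pitch)`. With this pitch
the discrete transform is unitary in energy, and the inverse (conjugate
kernel, conjugate prefactor) recovers the input grid exactly; the tests
verify the round trip to 1e-10 and Parseval to 1e-9, and check the forward
transform against a brute-force quadrature of the integral and against the
Airy first-zero radius `1.22 λf / D` of a circular top-hat.

**Fresnel propagation.** `fresnel_propagate()` applies the paraxial kernel
as a frequency-domain transfer function `exp(−iπλΔL|f|²)`. This keeps the
pitch constant — required by the design loop, which propagates forth and
back on a fixed camera-side grid — and is exactly unitary, so the
forward/backward pair composes to the identity by construction. `ΔL = 0`
returns the field unchanged; `|ΔL|` below a configurable floor (default
1e-9 um) falls back to the identity with a message, since the spatial
kernel degenerates. Sampling is checked against the field's *occupied*
bandwidth: the kernel phase must advance by less than π between adjacent
frequency samples up to the largest significant field frequency. A
violation warns rather than errors because the design loop intentionally
uses modest `|ΔL|`, far inside the limit, while diagnostic sweeps (axial
scans of multifocal lenses) legitimately push further with band-limited
fields. Against the closed-form Gaussian-beam law `w(z) = w0√(1+(z/z_R)²)`
the propagator is accurate to well under 1%.

**Axial mapping.** An object-side offset Δl maps to the image side as
`ΔL = M²Δl` (longitudinal magnification), sign preserved. With M = 60 and
Δz = 0.4 um spacing, adjacent image-side planes are 1440 um apart.

## 2. Multiplex plans and the design grid

`plan_from_spacings()` turns spacings d₁…d₈ into cumulative offsets,
anchored either at the first plane or symmetrically (nine planes at 0.4 um
give −1.6 … +1.6 um). Each plane carries a tile assignment on the camera
and a weight; one plane may be the *zero-order pass-through*: the
unmodulated reflection off the SLM cover glass is itself used as the
central, unshifted image, so that plane has weight 0 and is excluded from
the design targets. Which camera tile shows which depth is configuration
data (`tile_rc`, `plane_order`), not something the physics fixes.

The default simulation grid is 512×512 at the SLM's native 8 um pitch with
a 1.8 mm clear-aperture radius. This is a deliberate reduced-aperture
model: the conjugate (camera-side) grid spans `λf/pitch`, and at 512
samples one grid cannot hold both the full 3.81 mm relayed back aperture
and the full 3×3 footprint of 501-pixel (6.5 um) camera tiles — that needs
roughly 700 samples per axis. The reduced aperture preserves every
qualitative property the design metrics probe (tile steering, refocusing,
uniformity, stray light) at a quarter of the cost; passing
`slm_shape = c(1024, 1024), aperture_radius = 3810` reproduces the
full-aperture geometry. Tilt steering is limited by the SLM Nyquist
criterion (π phase per pixel, i.e. offsets up to `λf/(2·pitch)` ≈ 6.9 mm at
8 um); the corner tiles of the default layout sit at 4.6 mm, safely inside,
and a plan that violates the limit is rejected naming the offending tile.

## 3. Weighted global Gerchberg–Saxton

`wggs_optimize()` implements the refinement literally: per iteration,
E_A = E₀e^{iφ}; E_B = F(E_A); for each weighted plane, E_C = T(E_B, ΔL_i),
amplitude replacement E_D = w_i·E_tar,i·e^{i·Arg(E_C)}, E_E = T(E_D, −ΔL_i),
E_F(i) = F⁻¹(E_E); then φ ← Arg(Σ_i E_F(i)). Choices the procedure leaves
open, and how they were resolved:

* **Loop bound.** The iteration counter runs while `n < max_iter`, so
  `max_iter = 1` performs no update and returns the initial phase — a
  useful no-op bound for testing. Default `max_iter = 31` (30 updates),
  chosen because the uniformity metric plateaus well before that on the
  default plan; there is no adaptive stopping, matching the fixed-bound
  structure of the procedure.
* **Weights.** Static weights as printed, normalized to unit total target
  energy. The weighted-GS refinement `w_i ← w_i·⟨a⟩/a_i` (a_i the achieved
  amplitude) is available behind `adaptive_weights = TRUE`.
  Whether the weight belongs inside the amplitude replacement or only in
  the summation is ambiguous in the printed procedure; it is applied inside
  the replacement, as printed.
* **Targets.** The per-plane target amplitude is nowhere specified; here it
  is a focused copy of the aperture field (the diffraction-limited spot)
  shifted to the plane's tile centre and normalized to unit energy. This
  makes the single-plane, on-axis case an exact fixed point of the loop
  (the classical-GS reduction the tests exercise).
* **Initialization.** Deterministic superposition of the per-plane
  lens+tilt phases; an optional seeded Gaussian phase perturbation
  (`init_perturbation`) exists for studies of convergence from poor starts.
* **Quantization.** Real SLMs address discrete levels; `quantize_phase()`
  snaps to k uniform levels in [0, 2π). At 256 levels the per-plane
  energies shift by under 2%.

**Scoring.** `mask_report()` drives the simulator's coherent probe: energy
within tile j's window at plane i's focal distance, for all (i, j). In this
low-NA image-side geometry each channel's light stays within its own tile
at every plane (the defocus blur is tens of um against mm-scale tiles), so
per-channel signal is the diagonal E(i,i) and the package reports a
*conservative* crosstalk figure: all probe energy not delivered into a
designed tile at its designed plane, i.e. ghost orders, spill into wrong
tiles and light outside every window combined. The unmodulated hardware
reflection is not simulated; the reported zero-order fraction is the stray
light landing in the pass-through tile. Hardware efficiencies (SLM
reflectivity, diffraction efficiency) are instrument properties outside the
model. On the default nine-plane design the converged mask delivers ~90% of
the probe energy to its tiles with a relative energy spread of ~13%
(down from ~61% at initialization) and stray energy ~8% of the diffracted
total.

## 4. HiLo reconstruction

The two-component model `I_u = I_in + I_out`, `I_s = S·I_in + I_out` makes
the difference image `I_D = (S−1)·I_in` background-free. Decisions where
the published description is silent:

* **η norm.** The scaling η = |I_u·HP|/|I_D·LP| does not define |·|;
  implemented as the L2 norm over all frequencies excluding DC. Rationale:
  it matches the spectral magnitude of the two channels at the crossover,
  and HP(0) = 0 makes the numerator DC-free anyway, so including DC in the
  denominator would only bias η downward. η is computed per plane (per
  tile): each tile sees different content, and a global η would couple
  tiles through nothing but the camera layout.
* **Low-pass width.** `lp_sigma` is the Gaussian σ in cycles/pixel; the
  default 1/16 puts the effective cutoff near 1/8 of the sampling
  frequency. It must be user-tunable: the right value depends on speckle
  grain and object spectrum.
* **Signed vs rectified difference.** (S−1) is signed, so LP(I_D) can be
  negative; the default uses the signed difference as written and clips the
  fused image at zero (the clipped fraction is logged). The
  `rectify_difference` flag low-passes |I_D| instead — the variance-based
  variant, which is also what the axial-response diagnostics use, since
  with a spectral-norm η the rescaling would otherwise cancel the very
  decay being measured.
* **Boundaries.** Filters are applied with mirror padding of about one
  filter support to suppress wrap-around.
* **Degeneracy.** If the low-passed difference has no energy (no speckle
  modulation), η is undefined; `eta_scale()` errors with guidance and
  `hilo_reconstruct()` falls back to `eta_fixed` with a warning, reducing
  to the clipped high-pass of the uniform image.

## 5. Acquisition arithmetic and the pipeline

`plan_acquisition()` is exact integer arithmetic: stage step `N·Δz`,
positions `⌈depth/(N·Δz)⌉`, sections generated `positions·N`, kept
`round(depth/Δz)` with the excess discarded *from the end of the stack*
(the trailing sections image beyond the specimen), speed-up `N/states`
against one-exposure-per-section widefield, volume rate
`camera rate/states`. `reconstruct_volume()` interleaves sections as
z-index = position·N + plane rank with ranks ordered by ascending Δl;
per-section integral normalization is off by default and available behind a
flag, as a post-processing option rather than part of the method.

## 6. The simulator and what the tests show

The imaging model is incoherent (fluorescence): per-plane rendering
convolves intensities; the coherent path is used only for mask design and
verification, mirroring the SLM's dual role. Specifics:

* **Defocus.** Gaussian blur with σ(z) = σ₀ + k·|z − z_f|, defaults
  σ₀ = 0.15 um and k = 1 per um of defocus — a geometric-cone simplification
  of a high-NA PSF, adequate for exercising background rejection, not for
  resolution claims. Blurs are exact-DC-gain FFT filters (circular
  boundary), so each slice's energy is conserved identically.
* **Speckle.** Fully developed speckle from a random-phase pupil whose
  radius sets the grain (default ~8 px at the sample), normalized to unit
  mean; its intensity histogram passes a KS check against Exp(1). Grain and
  contrast at the sample are not known instrument quantities; they are
  configuration values.
* **Model structure.** By default the speckle multiplies the *blurred
  in-focus image* (`modulate_image`), which makes the two-component model
  hold to machine precision — the regime in which the difference-image
  cancellation is an identity, asserted on every rendered pair. The more
  physical `modulate_object` mode applies speckle to every slice before
  blurring, so contrast washes out smoothly with defocus; the axial
  response measurements use it. Under it the sectioning FWHM of a swept
  thin plane is finite (≈1.2 um at the default low-pass) and narrows as the
  low-pass cutoff rises, while the widefield response is flat.
* **Noise.** Poisson shot noise on expected photons plus Gaussian read
  noise, both off by default so identity tests are exact.
* **Phantoms.** Seeded beads/slab (optionally filaments), with optional
  axial confinement and a minimum lateral bead separation so that per-bead
  depth recovery is well-posed; ground truth is returned alongside.

**Problem sizes.** The shipped tests and the acceptance script design on
the full 512² grid but simulate acquisitions with 64-px tiles, 8 beads and
45 phantom slices — sizes chosen so the whole chain (10 multiplexed frames,
45 HiLo sections) runs in seconds while every pipeline property (section
counts and ordering, per-section background ratios, per-bead depth
recovery) is still exercised end to end. What passing them shows is that
the algorithms are implemented correctly under their own model; they do not
certify performance on real tissue, where the PSF, speckle statistics,
aberrations and chromatic effects all depart from these idealizations.

## 7. Known limitations

Paraxial scalar optics only (no vectorial/high-NA PSF, polarization or
partial coherence); no chromatic-aberration modelling (the instrument-side
mitigation is a bandpass filter, and compensation gratings are out of
scope); no deconvolution or deblurring post-processing; the unmodulated
zero-order reflection is treated as a geometric pass-through, not
simulated; hardware control (SLM driving, stages, cameras, diffusers) is
entirely out of scope.
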