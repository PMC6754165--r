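# hilomfm

Computational stack for **SLM-based multi-focus fluorescence microscopy
(MFM) with HiLo optical sectioning**, written for microscope builders and
computational imaging researchers who want to design, simulate and
reconstruct multi-plane acquisitions without touching hardware.

A multi-focus microscope images several specimen depths *simultaneously*: a
phase mask on a spatial light modulator (SLM) in a Fourier plane of the
emission path splits the fluorescence into N channels, each refocused from a
different depth and steered to its own tile of the camera chip. One exposure
therefore yields N optical planes. Because widefield detection admits
out-of-focus fluorescence, each plane is cleaned with the two-frame HiLo
algorithm, and an axial scan stitches consecutive N-plane volumes into a
deep z-stack.

## What the package computes

**Phase-mask design.** For focal planes at object-side offsets Δl_i
(image-side ΔL_i = M²Δl_i), the mask starts as a superposition of off-axis
Fresnel lenses,

    φ0 = Arg Σ_i exp{ i [ π ΔL_i r² / (λ f²)  −  2π (u_i x + v_i y) / (λ f) ] },

and is refined by a weighted global Gerchberg–Saxton loop: each iteration
propagates E_A = E₀ e^{iφ} through the Fourier lens (U = F(E), with the
1/(iλf) prefactor and the conjugate-plane pitch λf/(N·pitch)), Fresnel-
propagates to every plane's ΔL_i, replaces the amplitude with the weighted
per-tile target w_i·E_tar,i, propagates back, and sets φ ← Arg Σ_i E_F(i).
All propagation uses an FFT transfer-function Fresnel kernel, so energy is
conserved to machine precision and the grid pitch never changes inside the
loop.

**HiLo sectioning.** With a uniform-illumination image I_u = I_in + I_out
and a speckle-illumination image I_s = S·I_in + I_out, the difference
I_D = I_s − I_u = (S−1)·I_in cancels the out-of-focus term exactly. The
sectioned image fuses the two bands,

    I_HiLo = η · LP(I_D) + HP(I_u),     HP = 1 − LP,
    η = ‖F(I_u)·HP‖ / ‖F(I_D)·LP‖   (L2 over frequencies, DC excluded),

with LP a Gaussian low-pass (default cutoff at 1/8 of the sampling
frequency).

**Volume pipeline.** Multiplexed frames are cropped into tiles, sectioned
per plane, and interleaved so section z-index = position·N + plane rank
(ranked by ascending Δl); trailing sections that image beyond the specimen
are discarded. The planner reports the acquisition arithmetic: stage step
N·Δz, positions = ⌈depth/(N·Δz)⌉, speed-up N/states, volume rate =
camera rate / states.

**Simulator.** Seeded 3-D bead/slab phantoms, fully developed speckle (unit
mean, exponential intensity statistics), a linear-in-defocus Gaussian blur
model satisfying the two-component HiLo model exactly, multiplexed frame
rendering with optional Poisson/read noise, and a coherent mask-response
probe used to score designed masks.

## Worked example

```r
library(hilomfm)

# 1. plan: nine planes at 0.4 um over a 16 um depth, two illumination states
acq <- plan_acquisition(depth = 16, dz = 0.4, n_planes = 9,
                        frames_per_position = 2, camera_rate = 200)
acq
#> <acquisition_plan> 9 planes x 5 positions (step 3.6 um, dz 0.4 um)
#>   raw frames 10; sections 45 generated, 40 kept, 5 discarded
#>   speed-up x4.5, volume rate 100 Hz

# 2. design the nine-plane mask on a 512^2 grid (~40 s)
plan <- mfm_default_plan()
mask <- wggs_optimize(plan, gs_config(max_iter = 31))
rep  <- mask_report(mask, plan)
round(c(diffracted = rep$diffracted_fraction,
        uniformity_rsd = rep$uniformity_rsd,
        crosstalk = rep$crosstalk_fraction), 3)
#>     diffracted uniformity_rsd      crosstalk
#>          0.901          0.128          0.075

# 3. simulate a five-position scan of a bead phantom and reconstruct
ph <- make_phantom(shape = c(64, 64, 45), voxel = c(0.108, 0.108, 0.4),
                   beads = list(n = 8, radius = 0.3, intensity = 1,
                                z_range = c(0.8, 15.2), min_separation = 1.5),
                   slab = 0.05, seed = 7)
grid   <- tile_grid(3, 3, tile_px = 64)
frames <- simulate_axial_scan(ph, plan, grid, acq, seed = 11)
vol    <- reconstruct_volume(frames, grid, acq, hilo_params())
vol
#> <volume_stack> 40 sections of 64 x 64 px, dz 0.4 um, pixel NA um
```

The mask report says 90% of the probe energy arrives in the designed tiles
at the designed depths, their energies agree to a 13% relative spread, and
under 10% of the diffracted energy is stray. The reconstructed stack holds
the 40 kept sections; bead depths recovered from it match the phantom's
ground truth to the section, and the empty-region background is below 1% of
the widefield baseline.

A thin command-line front end is installed as `exec/hilo-mfm`
(`plan`, `design`, `simulate`, `reconstruct`), driven by a single YAML
config — see `inst/extdata/example-config.yaml`.

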