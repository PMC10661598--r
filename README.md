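# patwist

Single-shot 3D photoacoustic imaging with a **single-element detector**,
as software: a passive acoustic relay (prism + long fused-silica pipe)
scrambles the pressure wave from every voxel into a distinctive temporal
signature at one transducer, so a single laser shot encodes the whole
volume in one time trace. `patwist` simulates that measurement chain and
reconstructs the 3D image from it.

The package is for researchers in compressive/computational imaging who
want a fully reproducible, desk-scale testbed for calibration-dictionary
photoacoustics: how incoherent the per-voxel codes must be, what the
critical-angle aperture does to coupling, how total-variation
regularization trades fidelity against smoothness, and how calibration
drift degrades reconstruction.

## Model

The single-shot trace is linear in the image,

```
y = K x,     K = [k_1 … k_N],   x ≥ 0,
```

where column `k_i` is the calibrated response of voxel `i`: a
time-of-flight-delayed, band-limited (1 MHz, 84.66% −6 dB bandwidth)
pulse convolved with a voxel-specific pseudorandom scrambling coda,
weighted by the critical-angle aperture coupling
(`sin θc = v_water / v_pipe`, θc = 14.73° for water/fused silica), mixed
laterally to the system's 2.5 mm lateral resolution, and averaged over
two noisy calibration shots. The image is recovered by TwIST (two-step
iterative shrinkage/thresholding) with isotropic 3D total variation:

```
x̂ = argmin_x  ½‖y − Kx‖² + λ Φ_TV(x)
```

See `vignettes/methods.Rmd` for the full model, parameter defaults and
design rationale.

## Worked example

Calibrate a 15 × 15 × 11-voxel volume (7 × 7 × 3 mm at the system's
0.5 / 0.3 mm scan increments, 20 mm in front of the pipe entrance),
image a point target in one simulated shot, and measure the point-spread
resolution:

```r
library(patwist)

params <- acoustic_params()          # 1 MHz, 84.66% bw, 20 MHz sampling
grid   <- default_grid("desk")       # 15 x 15 x 11 voxels
K      <- build_dictionary(grid, params, encoder_config(seed = 7))

target <- point_target(c(0, 0, 21.5), grid)
y      <- synthesize(K, target)      # one noiseless single-shot trace

cfg <- recon_config(lam = 1e-6)
res <- twist_reconstruct(y, K, cfg)
res
#> <recon_result> 200 iterations (max_iter), objective 2.626e-08 -> 1.936e-10

measure_resolution(K, cfg, "lateral")   # mm
#> [1] 1.56234
measure_resolution(K, cfg, "axial")     # mm
#> [1] 0.3000222
```

The lateral width (≈1.6 mm here) is the partially deconvolved 2.5 mm
lateral mixing kernel — at or below the physical system's 2.5 mm — while
the axial response collapses to a single 0.3 mm slice because distinct
depths arrive at distinct times with near-orthogonal codes; axial is
finer than lateral, as the physics requires.

The same pipeline runs from the shell via the thin wrapper in
`inst/cli/patwist`:

```sh
patwist simulate-calibration --grid 7x7x3 --inc 0.5x0.5x0.3 --seed 7 --out K.h5
patwist phantom     --dict K.h5 --type B --depth 1.5 --out scene.h5
patwist forward     --dict K.h5 --phantom scene.h5 --snr 30 --out y.h5
patwist reconstruct --dict K.h5 --signal y.h5 --lam 1e-5 --out xhat.h5
```

Artifacts are HDF5 containers that record the grid, acoustic, encoder
and solver configuration (including seeds) needed to regenerate them.

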