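# dpcct

Simulation and iterative reconstruction of **grating-interferometry
differential phase-contrast CT (DPC-CT)**, end to end and without external
data.

Talbot-Lau grating interferometry measures, per detector element, the
lateral shift of an interference fringe caused by X-ray refraction. For a
specimen with refractive-index decrement δ the fringe phase is

    φ = (2π d₂ / g₂) · ∂/∂x ∫ δ dl,

the *transverse derivative* of the projection. This differential forward
operator makes the tomographic inverse problem much worse conditioned than
ordinary absorption CT, and phase retrieval from noisy stepping curves both
amplifies noise and wraps the phase to (−π, π] at strong edges. The package
implements the full chain a researcher needs to study this problem at desk
scale:

* **Phantoms & geometry** — breast-like piecewise-smooth δ phantoms with a
  paired attenuation map; parallel- and fan-beam 2D scan geometries.
* **Signal simulation & retrieval** — phase-stepping counts
  `I_k = I₀T(1 + V₀D cos(k + Φ₀ − φ))` with Poisson noise, and the Fourier
  retrieval of transmission T, dark-field D and wrapped phase φ.
* **Tomographic operators** — a ray-driven forward / voxel-driven backward
  pair built on Kaiser-Bessel blobs (α = 3, support twice the pixel pitch)
  whose *analytic derivative* is tabulated once and sampled per ray, plus
  the classical ray-sum + finite-difference baseline pair, both as sparse
  linear maps with exact matched adjoints; normal-matrix spectrum analysis
  shows the blob pair is the better-conditioned discretization.
* **Certified denoiser** — a bias-free ReLU CNN trained on noisy
  unregularized iterates with the spectral-norm product regularizer
  `ReLU(Π L(W_l) − (1 − ε))` (power-method norms, λ = 1e-4, ε = 1e-8); the
  shipped weights are certified non-expansive by a converged power method.
* **Reconstruction** — Plug-and-Play L-BFGS (15 data updates per denoising
  step, quasi-Newton memory restarted each outer iteration, stop at the
  estimated noise floor), a PnP gradient-descent control, Hilbert-filter
  FBP, a TV/Chambolle baseline, and FBP + learned post-processing.
* **Evaluation** — PSNR, SSIM, ROI SNR/CNR, the one-gradient-step
  noise-propagation experiment and the spectrum comparison report.

## Worked example

Simulate a noisy scan of a synthetic breast phantom, retrieve the wrapped
DPC sinogram, and compare the two operator discretizations:

```r
library(dpcct)

g       <- scan_geometry("parallel", n_angles = 48, n_det = 47,
                         det_pitch = 0.1, pixel_size = 0.1,
                         image_shape = c(32, 32))
phantom <- make_breast_phantom(c(32, 32), n_inclusions = 3, seed = 7)
op      <- dpc_operator(g, sensitivity = 1)

sim <- simulate_phase_stepping(phantom, g, sensitivity = 1,
                               photons = 120000, seed = 7, op = op)
ret <- retrieve_signals(sim$sample, sim$flat)
phi <- as_dpc_sinogram(ret)

sum(abs(ret$phi - sim$phi_true) > pi)   # 156 wrapped sinogram pixels
estimate_noise_level(sim$flat)      # data-loss noise floor

psnr(fbp_hilbert(phi, sensitivity = 1), phantom$delta)
# 7.04 dB -- analytic FBP on heavily wrapped, noisy data

one_step_experiment(phantom, g, sensitivity = 1, seed = 7)
# one-step PSNR: KB 9.41 dB vs FD 9.23 dB -- the blob operator
# propagates less noise in a single gradient update
```

The sinogram wraps at the phantom's strongest edges (156 of 2,256 pixels
here), which is what makes plain FBP and least-squares fitting fail and a
learned, certified-non-expansive prior worthwhile. Training and plugging in
the denoiser:

```r
phantoms <- lapply(1:50, function(i)
  make_breast_phantom(c(32, 32), 2 + i %% 3, seed = 1000 + i))
pairs   <- generate_training_pairs(phantoms, g, sensitivity = 1,
                                   seed = 1, op = op)
trained <- train_denoiser(pairs, denoiser_config(epochs = 80, seed = 1))
trained$spectral_state$product   # ~0.97: certified non-expansive

rec <- pnp_lbfgs(phi, op, trained,
                 recon_config(k_max = 15,
                              eps_n = estimate_noise_level(sim$flat),
                              max_outer = 12))
psnr(rec$delta_reg, phantom$delta)  # above the TV and FBP baselines
```

The conditioning claim can be checked directly — the normalized spectrum of
the blob pair's normal matrix dominates the finite-difference pair's over
the whole top quartile:

```r
spectrum_report(dpc_operator(g16 <- scan_geometry("parallel", 24, 23, 0.1, 0.1,
                                                  c(16, 16)), sensitivity = 1),
                fd_operator(g16, sensitivity = 1))
#> <spectrum_report> 256 values; KB >= FD on 100% of the top quartile: kb decays slower
```

A thin command-line wrapper over the same functions (subcommands
`simulate`, `reconstruct`, `spectrum`, `one-step`, `evaluate`) ships at
`system.file("cli", "dpcct.R", package = "dpcct")`.

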