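---
title: "Grating-interferometry DPC-CT: models, operators and the certified Plug-and-Play reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grating-interferometry DPC-CT: models, operators and the certified Plug-and-Play reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dpcct)
```

# The measurement model

A Talbot--Lau grating interferometer converts X-ray refraction into a lateral
shift of an interference fringe. For a specimen described by the
refractive-index decrement $\delta$ (with refractive index
$n = 1 - \delta + i\beta$), the wavefront phase advance along a ray is
$\Phi = \frac{2\pi}{\lambda}\int \delta\, dl$, the refraction angle is
$\alpha = \partial_x \int \delta\, dl$ (the transverse derivative of the line
integral), and the fringe phase measured behind the analyzer grating of pitch
$g_2$ at distance $d_2$ is

$$\varphi = \underbrace{\frac{2\pi d_2}{g_2}}_{\text{sensitivity}} \;
\partial_x \!\int \delta\, dl .$$

`interferometer_spec()` stores $(\lambda_x, d_2, g_2)$ and
`gi_sensitivity()` returns the prefactor. Note that the wavelength cancels
when the three relations are composed; the package also accepts a bare
scalar sensitivity, which is the natural parameterization when phantoms are
generated in unit-rescaled $\delta$ (see below).

Phase stepping scans one grating through the fringe period. The detector
counts at step phase $k$ follow

$$I_k = I_0\, T\, \bigl(1 + V_0\, D\, \cos(k + \Phi_0 - \varphi)\bigr),$$

with flat-field intensity $I_0$, visibility $V_0$ and reference phase
$\Phi_0$; $T$ is the transmission (Beer--Lambert on $\mu$), $D$ the
dark-field visibility reduction, and $\varphi$ the differential phase.
`simulate_phase_stepping()` evaluates these means (with uniform step phases
$k_j = 2\pi j/n_{\text{steps}}$, which makes the two-harmonic retrieval
exact) and draws Poisson counts. `retrieve_signals()` inverts the model by
discrete Fourier analysis of the stepping curve: zeroth and first harmonics
of sample and flat stacks give $T$, $D$ and
$\varphi = \mathrm{wrap}(\arg a_1^{\text{flat}} - \arg a_1^{\text{sample}})$.
Retrieval can only observe $\varphi$ modulo $2\pi$ on $(-\pi, \pi]$: where
the true $|\varphi|$ exceeds $\pi$ the sinogram *wraps*, producing the
sign-flip streaks that the reconstruction stage must cope with.

# Forward and backward tomographic operators

The image is parameterized by radially symmetric Kaiser--Bessel blobs

$$w_{kb}(x) = \frac{b\!\left(\alpha_{kb}\pi\sqrt{1 - (x/w)^2}\right)}{b(\alpha_{kb}\pi)},
\qquad b(x) = \sum_{m=0}^{4} \frac{1}{m!\,(m+2)!} \left(\frac{x}{2}\right)^{2m+3},$$

with $\alpha_{kb} = 3$ and support half-width $w$ equal to **twice the pixel
pitch**, so each blob spans several classical pixels. The decisive property
is that the derivative $\partial_x w_{kb}$ exists in closed form: the
forward operator can sample *how much each pixel refracts the ray*
directly, instead of differencing a line-integral projection numerically.
`build_lookup()` tabulates window and derivative once (linear interpolation
between nodes; the node count is forced odd so the center values 1 and 0
are exact table entries).

The **ray-driven forward operator** casts one ray per detector-element
center, takes the signed perpendicular distance $d$ of each in-support
pixel center to the ray, and accumulates
$\text{scale}\cdot\sum \partial_x w_{kb}(d)$. The sign convention is
$d = s_{\text{det}} - s_{\text{voxel}}$ in the rotated frame, which makes
the sum the analytic $\partial_s$ of the blob-smoothed projection (validated
by the simulate/retrieve round trip and the analytic disk oracle). The
**voxel-driven backward operator** projects each pixel center along its
source ray to the detector plane and samples the same derivative lookup at
the detector-plane offsets, magnification-scaled in fan geometry. Both maps
are materialized as sparse matrices, so linearity is structural, rays are
independent, and the `matched` adjoint (the default for reconstruction,
preserving the convex-quadratic data term) is the literal transpose. In
parallel geometry the voxel-driven and matched backprojectors coincide
identically.

**Scale normalization.** An unweighted lattice sum of $\partial_x w_{kb}$
over pixel centers approximates
$\frac{\int w_{kb}}{p^2}\,\partial_s P(s)$ for pixel pitch $p$ and
projection profile $P$. The operator therefore carries
$\text{scale} = \text{sensitivity} \cdot p^2 / \int w_{kb}$, which is what
makes grid refinement consistent: the forward projection of an
(anti-aliased) disk converges to the analytic
$-2\delta s/\sqrt{r^2 - s^2}$ profile as $p \to 0$.

Two discretization facts are worth knowing and are asserted in the tests:

* At exactly axis-aligned angles with matched detector/pixel pitches, the
  transverse pixel offsets collapse onto four coarse nodes of the odd
  kernel, and the quadrature degrades. At generic angles the offsets are
  dense and the operator is accurate; test oracles that compare against
  continuous analytic projections therefore use angle grids offset from the
  axes.
* A *binary* pixelized disk carries $O(p)$ staircase boundary roughness
  whose transverse derivative does not vanish under refinement; the
  analytic-oracle tests use `make_disk_phantom(antialias = TRUE)` (boundary
  pixels carry their area coverage), which removes this artifact of the
  test object rather than of the operator.

The **finite-difference baseline** (`fd_operator()`) is the classical
construction: a triangle-kernel ray-sum projector followed by central
differencing across detector columns divided by the detector pitch. Its
transpose is the exact adjoint.

**Conditioning.** `normal_matrix_spectrum()` materializes $A$ densely
(guarded to at most $64^2$ unknowns; beyond that an iterative top-$k$
method is the right tool) and returns the normalized eigenvalues of
$A^\top A$. The blob-based operator's spectrum decays more slowly than the
finite-difference operator's over the leading indices -- each unknown is
coupled to more data, the Hessian has higher curvature in its principal
directions, and data updates propagate less noise. The package verifies the
domination over the top quartile at $32^2$ and the one-gradient-step PSNR
advantage on ten seeded noisy phantoms. For the one-step experiment the
step is the exact line minimizer $\eta = \|g\|^2/\|Ag\|^2$ of the quadratic
loss: a halving backtracking step would quantize $\eta$ to powers of two
and the comparison would measure where each operator's optimal step falls
relative to that grid rather than noise propagation (with the quantized
policy the comparison even inverts).

# The data-driven regularizer

The denoiser is a **bias-free** stack of $3\times 3$ convolutions with ReLU
between them and no additive constants anywhere, so $f(0) = 0$ holds
bit-exactly and $f$ is positively homogeneous and locally linear: for every
input there is a Jacobian $J(x)$ with $f(x) = J(x)x$ (`jacobian_row()`
exposes the corresponding pixel weight maps). The default desk-scale
architecture is $1\to16\to16\to1$ (about 2,500 weights); depth and width
are configuration, not algorithm.

Non-expansiveness ($\|f(x_1)-f(x_2)\| \le \|x_1-x_2\|$) is enforced through
the composition bound $L(f) \le \prod_l L(W_l)$, penalizing

$$\mathcal{R} = \mathrm{ReLU}\!\left(\prod_l L(W_l) - (1 - \epsilon)\right),
\qquad \epsilon = 10^{-8},$$

added to the per-pixel mean squared denoising error with weight
$\lambda = 10^{-4}$. Each $L(W_l)$ is the spectral norm of the layer *as an
operator on full feature tensors* (padding included), estimated by a
warm-started power method during training and certified with 1000
iterations on the shipped weights; the hinge gradient flows through the
power-iteration singular vectors ($\partial \sigma/\partial K$ is the
kernel-space outer product of the leading left/right singular vectors).
Individual layers may be expansive -- only the product is constrained.

Three training-procedure choices deserve explanation:

* **Noisy iterates as training inputs.** Training pairs are built by
  running 15 unregularized L-BFGS data updates from the *clean* phantom
  against its Poisson-noisy, phase-wrapped sinogram
  (`generate_training_pairs()`). The iterate accumulates exactly the noise
  and wrap streaks the Plug-and-Play denoiser will meet mid-reconstruction
  (on the default conditions the pairs land at roughly 4--7 dB PSNR
  against their clean targets). Plain small-step gradient descent would barely perturb
  the clean start; the quasi-Newton steps are what propagate noise along
  the ill-conditioned directions, matching the role the denoiser has to
  play later.
* **Mean-shift augmentation.** Because the data are differential, pixels
  far from edges converge slowly and the local mean of iterates drifts.
  Each presentation of a pair adds one uniform scalar offset to both
  members (default range: half the clean dynamic range), so denoising
  becomes mean-invariant. The training log and tests check that shifted
  inputs denoise within 1 dB of unshifted ones.
* **Amplitude standardization.** The supervised term scales with the square
  of the image amplitude while the hinge is scale-free, so the balance
  implied by $\lambda = 10^{-4}$ depends on the units of the training
  images. Training standardizes pairs to a fixed reference amplitude
  (`image_scale`, default 0.01 in units of the clean dynamic range) at
  which the hinge dominates the optimizer whenever the product exceeds the
  boundary, reproducing the intended behaviour (the product rides just
  below 1 while the MSE trains in the interior). Because the bias-free
  network is positively homogeneous, the trained map is identical on data
  of any amplitude -- the standardization changes the optimization, never
  the deployed function.

Warm few-iteration norm estimates lag the converged values by about 1% on
clustered convolution spectra, which would let the certified product
equilibrate marginally above 1. Training therefore ends with a
**certification phase**: the same loss is minimized at a tenth of the
learning rate with converged (100-iteration) per-layer estimates until the
1000-iteration certificate is at most 1 (`cert_epochs` caps the phase). On
the default conditions the certified product lands at 0.99--1.00, the
empirical Lipschitz ratio over 1000 random pairs (plus local Jacobian power
iterations) stays below the certificate, and an ablation with
$\lambda = 0$ drives the product well above 1.

# Reconstruction

The variational problem is the convex quadratic
$\min_\delta \tfrac{1}{2}\|A\delta - \varphi\|_2^2$; regularization enters
through the denoiser in a Plug-and-Play loop (`pnp_lbfgs()`):

1. start from the all-zero image (consistent with $f(0)=0$: the zero image
   lies on the clean manifold);
2. run $k_{\max} = 15$ L-BFGS data updates (two-loop recursion, full
   inner-loop memory of 14 pairs, curvature guard
   $s^\top y > 10^{-12}\|s\|\|y\|$, Armijo backtracking from unit step with
   a $1/\|g\|$ first-step heuristic);
3. apply the denoiser once, restart the quasi-Newton memory, and repeat
   from the denoised iterate until
   $\tfrac{1}{2}\|A\delta-\varphi\|^2 < \epsilon_n$ or `max_outer` is hit.

The loop is a meta-algorithm: repeated L-BFGS solves with ever-better
starting points. The stop threshold $\epsilon_n$ is the noise floor of the
data term; `estimate_noise_level()` estimates it from a flat stack by
parametric bootstrap (Poisson-resampling the stack's retrieved harmonic
means and re-retrieving), which matches the ground-truth loss floor within
20% on synthetic scans whenever transmission is near 1 and scales inversely
with photon count. On heavily wrapped data the floor is dominated by the
wrap inconsistencies instead and `max_outer` (default comparable to the
dozen outer iterations the full-scale runs need) governs termination.

The while-condition is evaluated *before* the first inner block, so
$\epsilon_n = \infty$ returns the initial image untouched -- a degenerate
case the tests pin down.

Comparators, structurally parallel to the main loop:

* `pnp_gd()` -- identical outer structure with steepest-descent inner
  updates; on noise-free problems it needs several times more data updates
  to reach the same loss, which is the empirical content of the
  quasi-Newton motivation.
* `fbp_hilbert()` -- the analytic pseudo-inverse. Differential data already
  contain one derivative, so the ramp filter reduces to the imaginary-sign
  (Hilbert) filter $-i\,\mathrm{sign}(\nu)/(2\pi\,\text{sensitivity})$
  applied along the detector axis in the frequency domain (4x zero-padding,
  optional Hann window) before backprojection. With the $w = 2p$ blob
  basis, the reconstruction of a sharp disk is exact in the interior
  (RMSE $\approx 10^{-3}$) while the edge ring carries the basis blur,
  capping disk PSNR near 27 dB -- a property of the basis, not the filter.
* `tv_reconstruct()` -- the classical baseline: the same alternating
  structure with the denoiser replaced by the ROF proximal step, computed
  with Chambolle's dual projection ($\tau = 0.25$), on the
  finite-difference operator pair.
* `postprocess_fbp()` -- FBP followed by one application of the same
  trained network.

On a seeded noisy, wrapped test scan the package verifies the ordering
PSNR(PnP-L-BFGS) > PSNR(TV) > PSNR(FBP) and that the trained pipeline
leaves less wrap-artifact energy than FBP.

# The synthetic data generator

`make_breast_phantom()` emulates the in-silico data the study design needs:
a smooth elliptical adipose-like background (65% of the dynamic range), a
low-frequency texture (4 broad Gaussian bumps, 5% amplitude), and
non-overlapping elliptical inclusions alternating above/below the
background value -- piecewise-smooth images whose support edge is strong
enough to wrap the retrieved phase at the default sensitivity. Attenuation
is tied to $\delta$ by a fixed affine map ($\mu = 0.02\,\delta/\delta_{\max}$
per mm, transmission $\approx 0.9$ at desk scale): it only has to make the
stepping-curve counts realistic, and is never reconstructed. Phantoms are
pure functions of their arguments and seed.

Default study conditions, chosen once: unit-rescaled $\delta \in [0, 1]$
(the physical $10^{-7}$ scale is equivalent through the sensitivity
constant), sensitivity 1 (strongest edges reach $|\varphi| \approx 4.6$,
so wraps are present as in the full-scale sinograms), 5 phase steps,
120,000 flat counts per detector element and step, visibility 0.3,
$32^2$ images with 48-angle parallel-beam geometry for training and
end-to-end runs, $64^2$/90 angles for operator audits, and 50 training
phantoms (40/10 split by phantom, never by patch).

What the generator does **not** emulate: anatomically realistic breast
texture, polychromatic spectra, grating imperfections, detector cross-talk,
the retrieval-variance model of real interferometers, 3D cone-beam
geometry. Passing tests therefore demonstrate the algorithmic claims
(adjointness, conditioning, certification, convergence, ordering) on
controlled synthetic conditions -- not clinical image quality.

# Numerical choices and degenerate inputs

* Lookup tables: 2049 nodes over $[-w, w]$ (odd count, exact center),
  linear interpolation, empirical interpolation error $O(n^{-2})$.
* Dead pixels (zero stepping-curve mean) are flagged, set to neutral
  sentinels ($T = D = 1$, $\varphi = 0$) and excluded from the data term
  via the sinogram mask.
* Curvature pairs with $s^\top y \le 10^{-12}\|s\|\|y\|$ are rejected from
  the L-BFGS memory; a direction that loses descent falls back to
  $-g$; a failed line search ends the inner block.
* An outer iteration that does not decrease the data loss triggers a
  warning and an early stop (expected on wrapped data once the denoiser
  balances the wrap inconsistencies).
* In the method-ordering comparison the TV baseline runs on the same
  Kaiser-Bessel operator as the Plug-and-Play method, so the comparison
  isolates the prior (the classical finite-difference + TV combination is
  additionally penalized on KB-simulated data by its operator model error).
  Its prox weight (0.3 on the default noisy scan) was fixed by a small sweep
  maximizing the *baseline's own* PSNR, so the ordering is tested against
  the strongest classical setting.
* Problem sizes throughout (32^2 reconstructions, 64^2 operator audits,
  50 phantoms, 80 training epochs) are the package's desk-scale defaults;
  every pipeline scales to larger grids through the same configuration
  objects.

# Known limitations

* The voxel-driven fan-beam backprojector is the classical voxel-parallel
  construction and is *not* the exact adjoint off-parallel (the matched
  transpose is, and is the default for reconstruction); the tests report
  its agreement rather than constrain it.
* The certified Lipschitz bound applies to the trained network as shipped;
  retraining with different conditions re-runs the certification phase.
* The Hilbert-filter FBP assumes parallel geometry; fan data must be
  rebinned first (not implemented).
* Convergence of the PnP loop is checked empirically (bounded iterates,
  error-ratio decay, quasi-Newton advantage); no formal proof is attempted.
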