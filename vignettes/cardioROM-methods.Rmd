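---
title: "cardioROM: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardioROM: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the mathematical models in `cardioROM`, the numerical
choices behind them, and the reasoning for decisions that were genuinely open.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The full-order model

The monodomain equation couples a reaction–diffusion PDE for the dimensionless
transmembrane potential $u$ with a pointwise ODE for the recovery variable
$w$ (Aliev–Panfilov kinetics):

$$
\partial_t u - \nabla\cdot(\sigma(x)\,D\,\nabla u) + I_{ion}(u,w) = I_{app}(x,t),
\qquad
\partial_t w + g(u,w) = 0,
$$

with homogeneous Neumann boundary conditions and zero initial data,
$I_{ion} = K u (u-a)(u-1) + u w$ and
$g = (\varepsilon_0 + c_1 w/(c_2+u))(-w - K u(u-b-1))$. Note the sign
convention: the package's `gating_rhs()` returns $g$, and the solver marches
$w^{k+1} = w^k - \Delta t\, g(u^k, w^k)$.

All internal arithmetic is in rescaled variables; $\tilde t = 12.9\,t$ ms and
$\tilde u = 100u - 80$ mV map back to physical units (`to_dimensional()`).
Conductivities are stored exactly as the benchmark definitions print them
(e.g. $12.9\cdot 0.1\ \mathrm{cm^2/ms}$), i.e. as coefficients of the
rescaled-time equation. The stimulus amplitudes are treated as dimensionless
source magnitudes: the benchmark texts attach "mA" to them, but the
nondimensional equation leaves no consistent current unit, so amplitudes are
taken at face value. Stimulus windows are specified in ms and tested against
$\tilde t$.

### Spatial discretization

Bilinear quadrilateral (Q1) elements on the uniform $n_x \times n_y$ point
grid. Q1 on the structured grid reproduces the "$N = n_x n_y$ grid points"
accounting of the benchmark definitions exactly. Element matrices use
$2\times 2$ Gauss quadrature (exact for products of Q1 gradients) with a
per-element constant tensor obtained by averaging the nodal modulation/fiber
fields over the four corners. The mass matrix is lumped (row sums), and the
ionic terms are evaluated nodally ("ionic current interpolation"); together
these make the gating update an exact per-node collocation, which is how the
semi-discrete system is posed. Two structural invariants are tested: the
stiffness annihilates constants (pure Neumann) and the lumped mass sums to
the domain area (partition of unity).

### Time discretization

A one-step, first-order, semi-implicit (IMEX) scheme: diffusion implicit,
reaction explicit, gating first,

$$
w^{k+1} = w^k - \Delta t\, g(u^k, w^k), \qquad
(M/\Delta t + A)\, u^{k+1} = (M/\Delta t) u^k
 - M\,\rho \odot I_{ion}(u^k, w^{k+1}) + M I_{app}(t^k).
$$

The update order (gating first, $w^{k+1}$ inside $I_{ion}$) is one of several
defensible IMEX variants; it is fixed here, documented, and covered by the
self-convergence test, which checks an observed order of accuracy in
$[0.8, 1.2]$. Implicit diffusion removes the parabolic CFL restriction; the
explicit reaction still requires $\Delta t$ small against the upstroke time
scale, which the benchmark steps ($\Delta t = 0.1/12.9$ or $0.2/12.9$)
satisfy. The system matrix is time-independent per parameter instance, so its
sparse Cholesky factorization is computed once and reused at every step. A
NaN/overflow guard aborts with the offending step index.

## 2. Benchmark scenarios

Three parametrized slab scenarios are shipped as presets, with the printed
constants frozen into tests:

* **Ischemic slab** (`build_test1`): $10\,\mathrm{cm}$ square, two parameters
  = scar-center coordinates in $[3.5, 6.5]^2$ cm. The scar enters through the
  smooth modulation $\rho(x;\mu) = 1 - \exp(-((x_1-\mu_1)^4 +
  (x_2-\mu_2)^4)/2\alpha^2)$ with $\alpha = 7$, which multiplies the ionic
  current, and $\sigma = \rho + \sigma_0(1-\rho)$ with $\sigma_0 = 10^{-4}$,
  which multiplies the conductivity tensor. Gaussian stimulus
  $C e^{-\|x\|^2/\beta}$, $C = 100$, $\beta = 0.02\ \mathrm{cm^2}$, on
  $[0, 2]$ ms.
* **S1–S2 re-entry** (`build_test2`): $2\,\mathrm{cm}$ square, S1 activates
  the bottom strip $y \le 0.1$ over $[0,5]$ ms, S2 a disk of radius 0.2 cm at
  $(1, \mu)$ over $[70, 75]$ ms; snapshots only over $[95, 175]$ ms, the
  window in which re-entry exists and differs across $\mu$. Training points
  are uniform in the box, testing points their midpoints.
* **Restitution variability** (`build_test4`): conductivities
  $(\mu_1, \mu_2)$ define $D = \mu_2 I + (\mu_1 - \mu_2) f_0 f_0^T$ and
  $\mu_3$ replaces $c_1$, modulating APD. The printed testing lattice is
  $4^3 = 64$ points while the testing count is given as 16; the package keeps
  `n_test` configurable (default 16, first lattice points in lexicographic
  order) rather than guessing which 16 were used. Since some box corners have
  $\mu_1 < \mu_2$, `conductivity_model(strict = FALSE)` admits the flipped
  ordering while keeping the axial tensor form.

Every preset accepts resolution/epoch overrides; `build_test1_mini()`
(32×32 nodes, 3×3 training lattice, 2×2 testing lattice, 200 snapshot times)
is the desk-scale configuration used throughout the tests. Scenario configs
round-trip losslessly through YAML (`scenario_to_config()` /
`scenario_from_config()`).

### What the generator emulates — and what it does not

The scenarios reproduce the governing equations, parameter boxes and stimulus
protocols of the slab benchmarks: anisotropic conduction, conduction blocks,
re-entrant activation, APD variability. They do not include 3D geometry,
rule-based fiber fields, realistic ionic models (e.g. ten Tusscher–Panfilov),
bidomain effects, or measurement noise — so passing tests demonstrate that
the reduced models capture *this* family of wave dynamics, not that they
transfer to patient-derived anatomies or stiffer ionic kinetics.

## 3. POD-Galerkin + DEIM baseline

POD retains the smallest $n$ with
$\sum_{i\le n}\sigma_i^2 / \sum_i \sigma_i^2 > 1 - \varepsilon_{POD}^2$
(strict inequality, as the criterion is stated). Mode signs are fixed (first
nonzero entry positive) for reproducibility. DEIM builds a second POD basis
from the recorded nonlinear-term snapshots $\rho \odot I_{ion}(u^k, w^k)$ —
recorded during the FOM runs, not recomputed — and selects interpolation
nodes by the standard greedy residual-maximization; the reduced system then
advances the gating variable only at those nodes.

Choices the method statement leaves open, resolved here:

* **Clustering feature space** (local bases): k-means on snapshot columns in
  full state space, k-means++ seeding, fixed seed, empty-cluster re-seeding
  with a retry budget. State space is the natural geometry because the online
  selection rule is nearest centroid to the reconstructed state.
* **Online cluster selection** is evaluated every step, but without touching
  $N$-sized arrays: $\|Vu_n - c_j\|^2 = \|u_n\|^2 - 2 (c_j^T V) u_n +
  \|c_j\|^2$ with $c_j^T V$ precomputed. On a switch the coordinates map
  through the basis cross-Gramian $V_{new}^T V_{old}$, and gating values at
  nodes not shared with the previous cluster come from a lazily maintained
  store of the last values seen at each node (a documented approximation; the
  method statement does not specify switch handling).
* **DEIM tolerance per cluster** defaults to $\varepsilon_{POD}$.
* **Snapshot density**: projection ROMs are built from densely sampled
  trajectories (every few steps), while the DL-ROM trains on the sparser
  uniform sampling. This mirrors the benchmarks' own practice — the linear
  ROM's DEIM space degrades measurably when the nonlinear-term snapshots are
  subsampled too coarsely, which the reproduction test makes visible.

The $\mu$-dependent reduced operators $V^T A(\mu) V$ are assembled per online
instance (no matrix-DEIM; that is out of scope), after which the per-step
cost is independent of $N$.

## 4. DL-ROM

The DL-ROM approximates $u(t;\mu) \approx f_D(\phi_{DF}(t, \mu))$: a DFNN
$\phi_{DF}: \mathbb{R}^{n_\mu+1} \to \mathbb{R}^n$ provides the intrinsic
coordinates and the decoder $f_D$ of a convolutional autoencoder provides the
nonlinear trial manifold. The encoder $f_E$ exists only during training,
where the per-example loss

$$
\mathcal{L} = \tfrac{\omega_h}{2}\,\|u - f_D(\phi_{DF}(t,\mu))\|^2
 + \tfrac{1-\omega_h}{2}\,\|f_E(u) - \phi_{DF}(t,\mu)\|^2
$$

ties the two latent descriptions together. Evaluation never touches the
encoder or any previous time's state — queries are stateless and can be made
at any time instant in any order.

Implementation and protocol choices:

* **Networks and optimizer are implemented in compiled code** (RcppArmadillo):
  convolution via im2col/GEMM with exact transposed-convolution adjoints,
  ELU activations, ADAM with the standard bias corrections. Training is
  single-threaded and bitwise reproducible for a fixed seed; one manifest
  seed drives initialization, the data split and batch shuffling.
* **Default architecture**: 4 conv layers, kernel 5×5, stride 2, channels
  (8, 16, 32, 64), dense to $n$; mirrored decoder; DFNN 4×50, ELU. The exact
  benchmark architecture is not reproduced; this default is consistent with
  the companion-method literature and every piece is overridable via
  `dlrom_architecture()`.
* **Normalization**: global min–max scaling of snapshots to $[0,1]$ and
  per-component min–max scaling of $(t, \mu)$ — unstated in the method
  description; chosen to keep convolution inputs bounded.
* **Padding**: snapshot columns are reshaped to $s\times s$ with
  $s = \lceil\sqrt N\rceil$ and zero-padded; padded cells are masked out of
  the reconstruction loss so the decoder spends no capacity on them.
* **Validation split** is over individual $(t,\mu)$ samples (random, seeded),
  8:2 — the stated proportion without a stated granularity; per-sample keeps
  every parameter instance represented in training, which matters at desk
  scale where instances are few.
* **Early stopping**: "loss does not decrease over $p$ epochs" is read as
  no new strict minimum of the *validation* loss within the patience window;
  the returned weights are the best-validation checkpoint.
* **$\omega_h$** defaults to 0.5 (the loss statement only constrains it to
  $[0,1]$).

### Desk-scale problem sizes

The test suite and acceptance script run two benchmarks, with sizes chosen
once as the package's desk-scale presets:

* **Toy manifold**: $u(t;\mu) = \sin(\pi t)\,\mu\,\phi(x)$ on a 16×16 grid,
  8 training / 4 testing $\mu$, 50 times — an exactly two-parameter solution
  manifold, so $n = 2$ must suffice; a 2-conv-layer network, learning rate
  $10^{-3}$, up to 1000 epochs.
* **Ischemic slab desk scale** (`test1-mini`): $n = 3$ latent dimensions,
  lighter conv stack (4, 8, 16, 32), learning rate $10^{-3}$, batch 40, up to
  400 epochs with patience 80. The larger learning rate and smaller network
  relative to the full-scale defaults match the 30-fold smaller training set
  and coarser images; the full-scale protocol (rate $10^{-4}$, batch 40,
  thousands of epochs) remains the `train_config()` default.

The accuracy comparison at desk scale is qualitative by design: the DL-ROM at
$n = 3$ must beat the POD-Galerkin ROM of equal dimension, reproducing the
accuracy ordering of the full-scale benchmarks, not their headline error
values — those require full grids and GPU-scale training budgets.

## 5. Error indicators and clinical outputs

`eps_rel()` implements the time-averaged relative indicator literally
(squared norms summed under the root, mean over test instances); `eps_k()`
normalizes the per-node absolute error by the time-mean of the truth's
spatial 2-norms; `eps_ks()` uses the 1-norm normalization × 100 exactly as
printed, even though it yields very small percentages on large grids. All
three are zero iff the prediction equals the truth on the evaluated samples.

Activation time is the first upward threshold crossing, linearly interpolated
between samples, in ms; nodes that never cross report `NA`. APD accumulates
the dimensional time above threshold with interpolated partial intervals.
The threshold defaults to $u = 0.5$ (≈ −30 mV): the benchmarks never print
their threshold, so it is configurable.

## 6. Degenerate inputs and tie-breaks

* `gating_rhs()` guards $|c_2 + u| > 10^{-8}$ and errors otherwise.
* `pod_basis(n_fixed = k)` caps $k$ at the numerical rank
  (singular values $> 10^{-14}\sigma_1$); DEIM rejects a singular
  $P^T\Phi$.
* k-means: an empty cluster triggers re-seeding (up to 5 attempts).
* `prepare_dataset()` rejects constant snapshot matrices and constant input
  components (min–max scaling would divide by zero).
* Snapshot-window membership uses a relative $10^{-9}$ tolerance so that
  window endpoints expressed in ms select the same steps regardless of
  floating-point round-trips of $\Delta t$.
* Queries outside the training box warn (and extrapolate) rather than error.

## 7. Known limitations

* 2D structured grids only; no unstructured meshes, 3D geometries or
  rule-based fiber fields, hence the left-ventricle benchmark is not covered.
* The explicit reaction term limits $\Delta t$; no adaptivity.
* On coarse desk-scale grids the stimulus-driven nodes can transiently
  overshoot the excited state during current injection; the free-running AP
  stays in the physiological band (this is tested).
* POD-Galerkin accuracy is sensitive to the density of the recorded
  nonlinear-term snapshots; very coarse snapshot strides degrade DEIM before
  they degrade the state basis.
* Training times reported by the CLI are informational; wall-clock
  comparisons between the surrogates are hardware-dependent and are not part
  of the test surface.
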