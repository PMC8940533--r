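---
title: "Gaussian process classification on triangulated surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian process classification on triangulated surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Computational models of atrial fibrillation are interrogated by pacing
them from a site on the atrial surface and recording whether a sustained
arrhythmia is induced. The *inducibility map* is the boolean field over
the surface answering that question everywhere; its area fraction, the
*inducibility*, is the summary used to compare ablation strategies. Each
label costs a full electrophysiology simulation, so only a few dozen
pacing sites can be afforded. `surfgpc` learns the whole map from those
few labels with a probabilistic classifier that lives directly on the
triangulated surface, optionally fusing a cheap low-resolution simulator
with an expensive high-resolution one.

Nothing in the package is specific to cardiac models: it applies to any
binary field observed at vertices of a triangulated 2-manifold.

## The model

**Latent-function classification.** A zero-mean Gaussian process
$f \sim \mathcal{GP}(0, k)$ on the surface $S$ is pushed through the
logistic sigmoid, $\pi(x) = \sigma(f(x))$, and binary labels are
Bernoulli draws with probability $\pi(x_i)$.

**A Matérn kernel that respects the geometry.** Euclidean kernels
evaluated on 3-D coordinates ignore the topology (two points close in
space can be far along the wall), and substituting geodesic distance
into the Matérn formula does not in general produce a positive
semi-definite kernel. Instead the kernel is defined spectrally: with
$\{(\lambda_i, \psi_i)\}$ the Neumann eigenpairs of the Laplace-Beltrami
operator on $S$,

$$k(x, x') = \frac{\eta^2}{C} \sum_{i < N_{\mathrm{eig}}}
  (\kappa^2 + \lambda_i)^{-\nu - d/2}\, \psi_i(x)\, \psi_i(x'),
  \qquad \kappa^2 = \frac{2\nu}{\ell^2},\; d = 2,$$

the covariance of the fractional stochastic PDE
$(\kappa^2 - \Delta)^{\nu/2 + d/4} u = \mathcal{W}$. On flat geometry far
from boundaries this reduces to the classical Matérn covariance with
smoothness $\nu$ and length scale $\ell$; the test suite verifies the
$\nu = 3/2$ closed form to within 5% on a flat patch. We deliberately
use $\kappa^2 = 2\nu/\ell^2$ (the standard SPDE-Matérn correspondence)
so that $\ell$ *is* the Matérn length scale; writing $1/\ell^2$ in its
place, which some presentations do, silently rescales $\ell$ by
$\sqrt{2\nu}$.

The eigenpairs are computed once per mesh from linear finite elements:
stiffness $A$ (cotangent Laplacian) and consistent mass $M$ assembled
per triangle, then the generalized problem $A v = \lambda M v$. The
basis is mass-orthonormal, eigenvector signs are fixed (largest-magnitude
entry positive) so results are reproducible, and the decomposition can
be cached to disk keyed by a mesh checksum.

**The normalizing constant $C$.** The reference formulation leaves $C$
unspecified. We fix it so that the vertex-area-weighted average of
$k(x,x)$ over the mesh equals $\eta^2$ exactly, which makes $\eta$ the
marginal standard deviation of the field: $C = \frac{1}{|S|}\sum_i q_i
(\kappa^2+\lambda_i)^{-\nu-d/2}$ with $q_i$ the lumped-quadrature norms
of the eigenfunctions ($q_i \approx 1$). A consequence worth knowing: on
a mesh *with boundary* the Neumann eigenfunctions are inflated along the
boundary, so marginal variances at interior points sit somewhat below
$\eta^2$ — correlations are unaffected. $C$ depends on $\ell$ and is
recomputed for every posterior draw.

**Geometry normalization.** Meshes are rescaled by the largest per-axis
coordinate standard deviation (`normalize_geometry()`), so the same
length-scale priors are meaningful across anatomies; $\ell$ is always
quoted in these normalized units.

**Priors and inference.** Following the reference analysis: $\eta \sim
\mathrm{HalfNormal}(10^4)$, $\ell \sim \mathrm{Gamma}(1,1)$ in the
single-fidelity model; $\nu$ is fixed at $3/2$, never inferred; the
truncation default is $N_{\mathrm{eig}} = 1000$, clamped to the basis.
The latent function is parametrized non-centrally through its spectral
weights $w_i \sim N(0,1)$, $f(x) = \sqrt{\eta^2/C}\,\sum_i w_i
(\kappa^2+\lambda_i)^{-\nu/2-d/4}\psi_i(x)$, so no covariance
factorization is ever needed during sampling. Inference is by the
No-U-Turn sampler — implemented in the package, since no Hamiltonian
Monte Carlo engine is available as an R dependency here — with
dual-averaging step-size adaptation toward a 0.9 acceptance target,
windowed diagonal mass-matrix estimation, and divergence monitoring
(a warning is raised above 10% divergent transitions). Defaults: 500
warmup iterations (discarded), 500 retained samples, one chain.

**A caution on the amplitude prior.** With noise-free thresholded
labels the Bernoulli likelihood saturates once $|f| \gtrsim 10$, so it
contains no information about $\eta$ beyond that point. Under the
reference HalfNormal($10^4$) prior the posterior for $\eta$ is then a
wide plateau: chains wander over $\eta \in [10^3, 10^4]$, probability
maps saturate to $\{0,1\}$, and posterior summaries become poorly
reproducible across chains even though decision boundaries are stable.
The package keeps $10^4$ as the default (`inference_config(eta_scale=)`)
but the test suite, benchmarks, and the acceptance script run with
`eta_scale = 10`, which caps the plateau without affecting which side of
$0.5$ any probability falls on. Users fitting real label sets are
advised to do the same.

**Prediction.** For each posterior draw $(\eta_s, \ell_s, w_s)$ the
standard conditioning equations give
$\mu_s(x^*) = k_s(x^*, X) K_s^{-1} f_s$ and $\Sigma_s(x^*) =
k_s(x^*,x^*) - k_s(x^*,X) K_s^{-1} k_s(X,x^*)$, with jitter
$10^{-6}\eta_s^2$ on the diagonal of $K_s$. Means and variances are then
*averaged across draws*, latent values are sampled from
$N(\hat\mu, \hat\Sigma)$ (diagonal), and class probabilities are the
sigmoid of those samples, summarized by their mean and central 90%
interval. Averaging covariances across draws rather than pooling the
full mixture is statistically unconventional (it discards
between-draw variance of $\mu_s$), but it is the procedure of the
reference analysis and is implemented as such. Hard labels use the 0.5
threshold. At observed vertices the conditional mean reproduces the
latent draw exactly (up to jitter), which the tests exploit as an
oracle: in a *full* eigenbasis both the conditioning route and the
direct spectral expansion are exact at data sites and must agree to
$10^{-6}$.

## Multi-fidelity fusion

Two correlated label sources (coarse and fine simulators) are coupled
autoregressively: $f_H(x) = \rho\, f_L(x) + \delta(x)$ with independent
manifold Matérn priors on $f_L$ and the discrepancy $\delta$, giving the
block joint covariance
$K = \begin{pmatrix} K_{LL} & \rho K_{LH} \\ \rho K_{LH}^\top &
\rho^2 K_{HH}^{(L)} + K_{HH}^{(H)}\end{pmatrix}$. Priors:
$\eta_L, \eta_H \sim \mathrm{HalfNormal}(10^4)$, $\ell_L, \ell_H \sim
\mathrm{Gamma}(2,2)$, $\rho \sim N(0, 10)$. Note the deliberate
asymmetry kept from the reference: the single-fidelity model uses
$\mathrm{Gamma}(1,1)$ for $\ell$, the multi-fidelity one
$\mathrm{Gamma}(2,2)$. Low-fidelity labels are Bernoulli in
$\sigma(f_L)$, high-fidelity ones in $\sigma(f_H)$; prediction of the
high-fidelity class probability conditions on the entire joint dataset
through $K$. Both fidelities live on the single classification mesh; a
site may carry one label of each fidelity.

## Geodesics, designs, baselines, acquisition

*Heat-method geodesics*: one backward-Euler heat step
$(M + tA)u = u_0$ with $t = (\text{mean edge length})^2$, per-triangle
gradient normalization, and a Poisson solve recover distance; both
operators are prefactored, so a distance field costs two triangular
solves. Accuracy is a few percent (the tests bound flat-strip error at
2% and near-antipodal sphere error at 3%), and symmetry holds only
approximately — the solver is an approximation, not an exact polyhedral
geodesic.

*Farthest-point designs*: the first vertex is drawn uniformly (seeded),
each next vertex maximizes the minimum geodesic distance to the chosen
set, ties broken by lowest index. Designs are nested by construction.

*Geodesic nearest neighbor*: the baseline classifier labels a query by
its geodesically closest labeled vertex (one distance field per labeled
site).

*Active learning*: candidates are all mesh vertices except boundary
vertices (whose Neumann variance is artificially high) and
already-labeled sites; the next site is
$\arg\min |\hat\mu(x)| / \hat\Sigma(x)$ — division by the *variance*,
not the standard deviation, exactly as the criterion is stated in the
reference. One site is acquired per retraining round.

## The synthetic benchmark

`generate_labels()` draws a prior field and thresholds it at zero
(equivalently, rounds $\sigma(f)$; a field value of exactly zero maps to
label 1 — a measure-zero convention). `generate_two_fidelity()` builds
correlated pairs $f_H = \rho f_L + \delta$ and can calibrate the
discrepancy amplitude by bisection so the *expected* label agreement —
computed exactly per vertex from the Gaussian orthant probability
$\tfrac12 + \arcsin(r)/\pi$ — hits a target such as 0.82, the agreement
level observed between coarse and fine atrial models. What the generator
emulates is the spatial statistics of inducibility maps (zero-mean
Matérn fields at length scales 0.2–1.0, $\eta = 1$, $\nu = 3/2$) and the
imperfect low/high-fidelity correlation; what it does not emulate is any
physiology — fibrosis geometry, class imbalance induced by ablation,
spatially varying noise. Passing benchmarks therefore demonstrates the
statistical machinery, not clinical validity.

`run_benchmark()` reproduces the comparison protocol: per replicate
field, the nearest-neighbor and fixed-design GP classifiers share an
identical farthest-point design; the active-learning variant shares only
its first 20 points; the multi-fidelity variant additionally receives a
low-fidelity label set. The evaluation metric is balanced accuracy
(mean of sensitivity and specificity), evaluated over all mesh
vertices by default (training sites can be excluded with a flag; for a
truth single-class degenerate case the recall of the present class is
returned with a warning). Replicate seeds derive from a master seed by
fixed offsets recorded in the output table.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, on one CPU in a few
tens of minutes: analytic FEM checks on single triangles, spheres
(icosphere refinements 1–4) and flat grids; kernel oracles with a
500-mode basis on an 841-vertex patch; inference checks on a 162-vertex
sphere with 80 eigenpairs and 300–400 NUTS draws; and the classifier
comparison on a 2,562-vertex sphere with 150 eigenpairs, 3 replicate
fields per length scale, and training sizes 20–100. The benchmark
sphere refinement is chosen so that a 100-point design labels ~4% of
vertices, the sampling density of the reference atrial study; on much
coarser meshes the nearest-neighbor baseline saturates and the
comparison is uninformative. The active-learning comparison runs to a
40-label budget, inside the 20–70 range where acquisition matters most.

Other numerical choices: consistent (not lumped) element mass by
default, with `lump = TRUE` available (the heat-method solver uses the
lumped mass, as is customary); degenerate triangles rejected below
$10^{-12}$ of the mean area; meshes with multiple connected components
rejected (the multiplicity of $\lambda = 0$ would otherwise exceed one);
the dense whitened eigen-solver is the default (deterministic; exact
LAPACK), with a shift-invert Lanczos path via RSpectra for large
meshes; eigenvalues clamped at zero when negative within tolerance;
ties everywhere broken by lowest vertex index.

## File conventions

Label and field CSVs use comma separation, a header row, and **0-based
vertex indices on disk** (matching the mesh file formats OFF/PLY/VTK/STL
that the readers accept); in-memory R structures are 1-based and the
readers/writers shift. YAML configuration keys mirror
`inference_config()` argument names exactly. Every command-line run
writes a JSON manifest with seeds, configuration and mesh/basis
checksums; a cached eigenbasis is refused if its mesh checksum does not
match.

## Known limitations

- Volumetric (tetrahedral) domains and curved elements are out of scope;
  the classifier operates on a mid-wall surface mesh.
- The heat-method geodesics are approximate; designs and NN baselines
  inherit that error (a few percent).
- Exactly two fidelity levels; no input-dependent $\rho(x)$ and no
  cost-aware choice of which fidelity to query (acquisition labels the
  high-fidelity source only, and combining the acquisition rule with the
  multi-fidelity posterior, while supported, is untested territory).
- MCMC reproducibility is statistical, not bitwise, across different
  seeds; with the reference amplitude prior and separable labels the
  amplitude is only weakly identified (see above).
- Under a deterministic labeling oracle, re-labeling an already-labeled
  site is uninformative, so acquired sites are removed from the
  candidate pool.
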