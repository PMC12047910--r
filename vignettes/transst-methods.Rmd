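---
title: "Transfer-learning spatial clustering: models, choices, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer-learning spatial clustering: models, choices, and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `transst`, the
tunable parameters that matter, the design decisions that were
genuinely open, and what the package's simulation-based validation
does and does not establish.

## The three-step model

**Step 1 — supervised probabilistic dimension reduction.** The labeled
source expression matrix $X_{src} \in \mathbb{R}^{n_1 \times p}$ is
modeled as a factor model with class-conditional factor priors:

$$x_i = W_0 u_i + \epsilon_i, \qquad \epsilon_i \sim N(0, \Lambda),
\qquad u_i \mid z_i = k \sim N(\mu_k, \Sigma_k),$$

with $W_0 \in \mathbb{R}^{p\times q}$, $\Lambda$ diagonal, and the
class labels $z_i$ known. `fit_pldr()` maximizes the marginal
likelihood by EM. Because every ingredient is Gaussian, both steps are
closed-form: the E-step conditions $u_i$ on $x_i$ within its class
(posterior covariance $(W_0^\top\Lambda^{-1}W_0 + \Sigma_k^{-1})^{-1}$),
and the M-step updates $W_0$, $\Lambda$, $\mu_k$, $\Sigma_k$ from the
posterior first and second moments. The likelihood is monotone along
the trace, which the test suite asserts at tolerance $10^{-8}$.

The loading is only identified up to an invertible $q \times q$
transform. After convergence we rotate so $W_0^\top\Lambda^{-1}W_0$ is
diagonal with decreasing entries and fix column signs by the
largest-magnitude loading entry — a standard factor-analysis
convention that makes refits comparable. No orthogonality constraint
is imposed during the iterations.

**Step 2 — adaptive transfer.** On the unlabeled target
$X_{tgt} \in \mathbb{R}^{n_0\times p}$, `fit_transfer()` minimizes

$$\sum_{i=1}^{n_0}\|x_{tgt,i} - W v_i\|_2^2
  + \lambda \|W - \hat W_0\|_F^2$$

by alternating exact least squares from $W = \hat W_0$; each step is
the exact coordinate minimizer, so the objective never increases.
$\lambda = 0$ recovers unpenalized rank-$q$ factorization (the
Eckart–Young optimum, asserted against an SVD oracle); a dominating
$\lambda$ pins $W$ at $\hat W_0$ and reduces $V$ to the least-squares
projection of the target onto the source loading's span.

$\lambda$ is chosen by the two-fold scheme of `select_lambda()`: rows
are shuffled and split in half; each fold's fitted loading is used to
reconstruct the *other* fold and the residual Frobenius errors are
summed. "Reconstruct" needed a concrete meaning for held-out rows that
have no fitted factors: we project them onto the span of the fold's
loading by least squares, the only label-free choice. Ties are broken
toward the larger $\lambda$ (more transfer).

**Step 3 — spatially smoothed mixture clustering.** The target
factors carry a Gaussian mixture likelihood and the labels a Potts
Markov-random-field prior over a k-nearest-neighbor graph on the spot
coordinates:

$$f(v_i \mid z_i = k) = N(\mu_k, \Sigma_k), \qquad
f(z) \propto \exp\Big\{-\tfrac12 \sum_i \sum_{i'\in N_i}
\beta(1 - I\{z_i = z_{i'}\})\Big\}.$$

`fit_spgmm()` uses ICM-EM: iterated-conditional-modes label updates
$z_i \leftarrow \arg\max_k [\log N(v_i;\mu_k,\Sigma_k) -
\beta\,\#\{i'\in N_i: z_{i'}\neq k\}]$ alternating with moment
M-steps, the deterministic hard-label scheme used throughout this
family of spatial clustering methods. The $\tfrac12$ in the joint
density cancels in the conditional because a symmetric graph counts
each pair twice, so conditional scores use the unhalved disagreement
count. At $\beta = 0$ the procedure is exactly classification
(hard-EM) GMM with equal component weights, which the tests assert
label-for-label against an independent R implementation.

$\beta$ is selected over a grid in $[0,1]$ (default step 0.1) by the
conditional pseudo-likelihood — the Potts normalizing constant is
intractable, and "the likelihood" had to be pinned down; the
pseudo-likelihood is the standard surrogate and is what we report and
maximize. All $\beta$ values start from one shared k-means++
initialization so the line search is paired.

## Parameters and defaults

| parameter | default | notes |
|---|---|---|
| `q` (latent dimension) | 15 in the pipeline | the working dimension used across methods in this literature; the simulator uses 10 |
| `k` (spatial neighbors) | 5 | Euclidean kNN on coordinates, union-symmetrized; ties toward the lower row index |
| `lambda` | two-fold CV | default grid $\{0, 0.01, 0.1, 1, 10, 100\}\cdot n_0 p/(\|\hat W_0\|_F^2+1)$, scale-aware so penalty and data terms are comparable across sizes |
| `beta_grid` | $0, 0.1, \dots, 1$ | granularity of the line search |
| `n_hvg` | 2000 | highly-variable-gene cut, log-scale variance ranking |
| `n_restarts` | 3 (pipeline), 1 (direct call) | clustering restarts; winner by pseudo-likelihood |
| K selection | BIC-type | $-2\,\mathrm{pLL} + \log(n_0)\,[Kq + Kq(q+1)/2]$, ties toward smaller K; the criterion function is pluggable |

The K-selection rule deserves emphasis: it is a declared stand-in
(a BIC-type penalty on the pseudo-likelihood), not a claim about any
particular published criterion, and `select_K(criterion = ...)`
accepts alternatives.

## Preprocessing

`preprocess()` follows the standard scRNA-seq recipe: library-size
normalization to the median total count, `log1p`, selection of the
`n_hvg` genes with the largest log-scale variance (variance ranking
uses 10 significant digits so floating-point noise cannot reorder
ties), then per-gene centering and unit scaling. Zero-variance genes
are dropped with a warning; rows with zero totals are an error.
Multiple source samples are normalized **separately** and then
concatenated (`align_and_combine_sources()`); whether to normalize
jointly was an open choice, and separate-then-concatenate keeps each
sample's library-size structure intact. Genes a source lacks are
zero-filled rather than dropped so the loading keeps the full target
gene dimension; the zero-filled names are recorded on the result.

## What the simulator emulates — and what it does not

`simulate_dataset()` reproduces the benchmark design the package is
validated on: Potts-distributed labels on a lattice (rook adjacency,
Gibbs-sampled; the sampler is checked against exact enumeration on a
2×2 lattice), cluster-conditional Gaussian factors
$u\mid z{=}k \sim N(\mathrm{effect\_size}\cdot e_k, I_q)$, an
orthonormal loading, residual noise $\epsilon \sim N(0,
\mathrm{resid\_sd}^2 I)$ in source and target, and optional extra
target noise $e \cdot N(0,1)$.

Two generator choices were genuinely open:

* **Marker structure.** The benchmark stipulates that genes 1, 2, 3
  and 4–10 uniquely determine clusters 1–4. We embed this in the
  loading matrix: column $k$ is the normalized indicator of cluster
  $k$'s marker genes and $\mu_k = \mathrm{effect\_size}\cdot e_k$, so
  cluster $k$ elevates exactly its own marker genes while the data
  remain an exact factors-times-loading product. The alternative —
  adding marker shifts in gene space after the matrix product — makes
  the true signal rank $q + K$ while every method fits rank $q$; that
  hands target-only PCA an adaptive advantage over any transferred
  loading and inverts the method ordering the benchmark is designed
  to exhibit. The in-loading construction is also the literal reading
  of "multiply [the factors] by a factor loading matrix, which
  results in the gene expression matrix".
* **Residual noise.** `resid_sd = 0.5` puts the per-gene signal
  fraction in the range typical of log-normalized expression data
  (noise comparable to per-gene signal); without any residual term
  the target would be exactly low-rank and target-only PCA would be
  unbeatable by construction.

Defaults (`effect_size = 3`, 30×30 lattice, $n_1 = 2500$, $p = 200$,
$q = 10$, $\beta_{true} = 1$) place the tandem PCA baseline in a
weak-recovery regime with clear headroom, so the orderings the test
suite asserts — spatial smoothing helps over $\beta=0$, transfer
helps over target-only PCA factors, and the margins shrink as target
noise grows — are informative rather than saturated.

What passing these tests does **not** show about real data: the
simulator draws Gaussian factors and Gaussian noise (no count-level
overdispersion, zero inflation, or library-size variation), uses a
regular lattice (no irregular spot geometries or tissue boundaries),
gives source and target identical generative parameters (no batch
effects or platform shift), and marks clusters with disjoint gene
sets. Performance on real tissues with distribution shift between
source and target is outside what the suite can certify.

## Numerical choices

* **EM termination.** Relative log-likelihood change below `tol`
  (default $10^{-6}$), capped at `max_iter`. When a numerically null
  update dips the computed log-likelihood by less than
  $10^{-9}(|\ell|+1)$ — below what double precision can resolve for
  an exact-EM step — the update is reverted and convergence declared,
  keeping the reported trace monotone without masking real
  regressions.
* **Degeneracy guards.** $\Lambda$ entries floored at $10^{-6}$;
  covariance matrices ridge-repaired with $10^{-6} I$ whenever the
  smallest eigenvalue falls below $10^{-8}$; near-singular Gram
  matrices in the ALS steps get an $10^{-8} I$ ridge with a warning.
  Empty mixture components are re-seeded at the point with the lowest
  maximum responsibility.
* **Factor orientation.** The ALS factor basis is arbitrary up to an
  invertible transform; the mixture likelihood is equivariant to it
  but the k-means++ initialization is not. The pipeline therefore
  rotates factors to principal axes (`canonicalize_factors()`) before
  clustering, which makes results independent of the incidental basis
  and well-conditioned for the seeding geometry.
* **Tie-breaking.** ICM label ties keep the smaller class index;
  kNN distance ties keep the lower row index; $\lambda$ CV ties take
  the larger $\lambda$; K-selection ties take the smaller K. All are
  deterministic given the seed.
* **Seeds.** The pipeline derives per-stage seeds as
  `seed + 1 .. seed + 4` so stages can be re-run in isolation; two
  runs with the same config are byte-identical on disk.

## Scope of the validation and known limitations

The test suite runs at desk scale: EM monotonicity on $n_1 = 1000,
p = 50$ instances; subspace recovery at $n_1 = 5000, p = 20$;
transfer limits on a $500 \times 100$ matrix; the paired clustering
comparisons on 30×30 lattices with 20 replicates; sampler exactness
at $10^5$ chains on the 2×2 lattice. The scenario presets
(`scenario_config("s1")` through `"s4"`, up to $n_0 = 20000$,
$n_1 = 10000$, $p = 200$) generate the larger benchmark sizes but are
not exercised by default.

Known limitations: ICM is a greedy optimizer and lands in local
optima — restarts damp but do not remove the variance (this is why
the replication-invariance of K-selection can fail: different data
sizes give the initializer different RNG streams and hence different
local optima, not different criteria). The two-fold $\lambda$ CV
measures reconstruction, not clustering quality; when the prior
loading is uninformative *and* the target is noise-dominated, the
held-out-error gradient at $\lambda = 0$ has replicate-random sign,
so tiny penalties may be selected — harmless, since tiny penalties
barely move $W$. The pseudo-likelihood used for $\beta$ and K is a
surrogate, not the intractable exact likelihood. No missing-data
handling inside EM, no sparse loadings, no count-level models.
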