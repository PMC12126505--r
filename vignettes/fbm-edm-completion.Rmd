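---
title: "Completing distance matrices of fractional Brownian trajectories"
author: "fbmedm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completing distance matrices of fractional Brownian trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbmedm)
```

## The problem

A configuration of $n$ points $x_1,\dots,x_n \in \mathbb{R}^D$ defines a
Euclidean distance matrix (EDM) of squared pairwise distances
$a_{ij} = \lVert x_i - x_j\rVert^2$: a symmetric, hollow, non-negative
matrix whose entries obey the triangle inequality
$\sqrt{a_{ij}} \le \sqrt{a_{ik}} + \sqrt{a_{kj}}$ and whose rank is
$\min(n, D+2)$ for points in general position. An EDM with a known subset
of entries — encoded by a symmetric binary mask $B$ with $b_{ij}=1$ where
the distance is measured, zero diagonal, and missing ratio
$\mu = 2m/(n(n-1))$ — arises whenever distances are measured imperfectly.
The motivating case is chromatin tracing: multiplexed FISH microscopy
reports the 3-D position of each 30 kb genomic bin in each cell, a locus
that fails to image removes an entire row and column of that cell's
distance matrix, and downstream single-cell analyses then confront partial
EDMs at substantial sparsity.

This package treats partial EDMs as corrupted images and completes them
with (i) classical methods — nuclear-norm relaxation, direct coordinate
optimization, nearest-neighbour fill, database search, ensemble mean — and
(ii) conditional sampling from a denoising diffusion prior trained on an
ensemble of synthetic EDMs with the right statistics. The synthetic
ensemble is fractional Brownian motion (fBm): a Gaussian process with
$\langle B_H(t)B_H(t')\rangle = \tfrac12(t^{2H} + t'^{2H} - |t-t'|^{2H})$
whose Hurst exponent $H$ sets the memory of the increments and the
mean-squared displacement $\langle r^2(s)\rangle = a^2 s^{2H}$. Chromatin
without cohesin-mediated loops shows fractal statistics corresponding to
$H = 1/3$; $H = 1/2$ is Brownian, $H = 2/3$ superdiffusive.

## When is a completion unique?

If the partial graph defined by $B$ is (generically) rigid in
$\mathbb{R}^D$, the completion is unique and instance-level evaluation
(RMSE against the held-back truth) is meaningful. `rigidity_test()`
implements a greedy sufficient certificate: seed with a clique of at least
$D+1$ vertices, then repeatedly absorb the external vertex with the most
links to the absorbed set, requiring at least $D+1$ links — enough links
to pin the new vertex's coordinates uniquely. The certificate is
*sufficient, not necessary*: a `FALSE` report means "not certified", and a
mask's missing ratio alone is not informative (two cliques glued at a
vertex have many constraints per vertex yet flex). Exact maximum-clique
search being NP-hard, the seed is found by degree-ordered greedy expansion
from 32 starting vertices; any clique of size $\ge D+1$ is a valid seed,
larger seeds only help, and absorption is attempted from every candidate
seed before giving up. Ties in link count break to the lowest vertex
index, for determinism. The test suite validates every certificate against
an independent oracle — the rank of the bar-and-joint rigidity matrix at
random generic coordinates, which must equal $3n-6$.

## Synthetic data: what the generator emulates

`sample_fbm()` draws each coordinate component as an independent discrete
fBm by Davies–Harte circulant embedding (exact in distribution; a
non-positive embedding — possible at extreme $H$ with short series —
falls back to exact Cholesky sampling with a warning). Per-component
variance is $a^2 s^{2H}/D$, so the $D$-dimensional displacement follows
the Gaussian propagator
$P(r\,|\,s) = (D / 2\pi a^2 s^{2H})^{D/2} \exp(-D r^2 / 2 a^2 s^{2H})$ and
the rescaled distance $r/\langle r^2(s)\rangle^{1/2}$ is Maxwell
distributed — both properties are asserted by the tests
(`maxwell_collapse()` checks the KS statistic against
$P(\chi^2_3 \le 3u^2)$ using one pair per matrix so the samples are
independent under the null).

Benchmark corruption is Bernoulli: each upper-triangle entry is dropped
independently with probability $\mu$, mirrored to the lower triangle.
FISH-style corruption masks whole rows/columns (`rowcol_mask()`). A note
on arithmetic: masking $k$ of $n$ loci gives
$\mu = 1 - \binom{n-k}{2}/\binom{n}{2}$, so 15 masked loci of 64 give
$\mu = 0.4167$ and 25 of 64 give $\mu = 0.63$; a per-cell sparsity of 0.29
sometimes quoted for 15 missing loci is not consistent with pair counting
at $n = 64$, and this package reports only the pair-counting value.

`synth_fish_fixture()` emulates a chromatin-tracing cohort: per-cell fBm
trajectories at $H = 1/3$ with a typical neighbouring-locus displacement
of `scale_nm = 300` nm (the magnitude seen between adjacent 30 kb bins in
imaging data of this kind), with per-cell whole-locus dropout whose count
law is configurable. It does **not** emulate localization noise,
locus-dependent detection efficiency, chromatin loops (cohesin present),
or cell-to-cell scale heterogeneity — passing tests therefore demonstrate
correctness of the pipeline and the ranking of methods under the fractal
null model, not performance on any particular experimental dataset.

## The diffusion prior

The forward process follows the standard variance-preserving chain with a
linear schedule $\beta_t \in [10^{-4}, 0.02]$, $T = 1000$, $\beta_0 = 0$,
under which $\bar\alpha_T < 10^{-3}$; sampling uses a respaced
subsequence (`respace()` preserves the forward marginals exactly), with
150 steps for unconditional generation and 200 for inpainting by default —
both configurable, as the two operating points trade speed for fidelity.

The noise predictor is deliberately *not* a deep network. The package
partitions the chain into 16 bins of equal width in noise magnitude
$\sqrt{1-\bar\alpha_t}$ and gives each bin an affine map
$\hat\epsilon = W_k x_t + b_k$. For a data distribution that is exactly
Gaussian the optimal denoiser *is* affine in $x_t$, and fBm EDM ensembles
at desk scale are close enough to jointly Gaussian that this architecture
reproduces the ensemble's scaling and supports all four conditional
samplers, while training in seconds on one CPU. Because the objective is
then an exact least-squares problem in the ensemble's first two moments,
`train_denoiser()` first solves the per-bin normal equations
($\bar\Sigma_k W_k = \bar s_k I$ with
$\Sigma_t = \bar\alpha_t C + (1-\bar\alpha_t)I$ averaged over the bin, $C$
the empirical image covariance) and then refines with minibatch Adam; the
loss history starts from the evaluated loss of the untrained predictor.
This two-stage scheme was adopted after pure from-zero SGD at desk-scale
budgets left the sampler visibly underfit. The trade-offs of the affine
class are real: it cannot capture non-Gaussian features (the $\chi^2$-like
marginals of squared distances), so generated matrices match the ensemble
in mean and covariance — hence in scaling exponent and gyration radius —
but not in higher moments. Intensity normalization maps raw squared
distances affinely onto $[-1, 1]$ with the scale set at the ensemble's
99.9th-percentile entry (clipping above during training only): squared
distances at large contour separation have a heavy right tail that would
otherwise compress the short-range structure into a sliver of the model
range. The map is recorded with the model and exactly invertible.

## Conditional sampling

Four samplers share one trained prior:

* **DDPM inpainting** — at each step the known pixels are re-noised from
  the measurements at the next step's level and merged with the reverse
  step's unknown pixels through the mask.
* **RePaint** — the same step wrapped in an inner (denoise, re-noise)
  loop, `repaint_loops = 10` by default; with one loop it consumes the
  identical noise stream and is bit-equal to DDPM inpainting (a tested
  contract made possible by a fixed RNG consumption order per step:
  known-pixel noise first, then reverse-step noise, then — only inside
  RePaint — the re-noising draw).
* **DDRM** — operates on the unscaled ladder $\sigma_t =
  \sqrt{(1-\bar\alpha_t)/\bar\alpha_t}$ derived from the same schedule,
  with the DDIM-style update
  $x_{t-1} = \hat x_0 + \sqrt{1-\eta^2}\,\sigma_{t-1}(x_t - \hat
  x_0)/\sigma_t + \eta \sigma_{t-1}\epsilon$ on unknown coordinates and
  the measured values driving the known ones. All stochastic terms carry
  the factor $\eta$, so $\eta = 0$ is fully deterministic. The sampler
  default is $\eta = 0.85$, a common operating point for diverse
  restoration in this method family.
* **DDNM** — replaces the known pixels of the $x_0$-estimate by the
  measurements at every step ($B \odot x_{0|t} = B \odot y$ exactly; the
  deviation trace is recorded and identically zero), then takes the
  standard posterior step, with a time-travel loop of
  `travel = c(3, 3)` by default.

Outputs pass through `project_edm()` (denormalize, symmetrize, clamp
negatives, zero the diagonal) and known entries are restored bit-exactly
in raw units afterwards, so preservation holds at the double-precision
level for every method.

One design choice deserves emphasis: the FISH imputation protocol
(`impute_and_score()`) runs DDRM at $\eta = 0$ by default, unlike the
sampler's own default. Imputation is scored by RMSE against held-out
measurements, and the expected squared error of a *sample* from the
posterior exceeds that of the posterior mean by the posterior variance;
at desk scale the injected variance of the stochastic variant is large
enough to erase the method's margin over the nearest-neighbour baseline,
while the deterministic DDIM limit — the best point estimate the sampler
family offers — retains it. Users wanting diverse imputations rather than
point estimates can set `ddrm_eta` near 1.

## Classical baselines and numerical choices

* **FISTA** solves $\min_A \lVert B \odot (A - \tilde A)\rVert_F^2 +
  \beta\lVert A\rVert_*$ by accelerated singular-value soft-thresholding
  with known entries re-imposed each iterate. The regularization follows
  a geometric continuation $\beta_k = \beta_0\, 0.7^{\lfloor k/50\rfloor}$
  from $\beta_0 = 0.1\,\sigma_{\max}(A^0)$, advancing immediately when the
  loss plateaus; iteration stops once $\beta$ reaches its floor
  ($10^{-6}\beta_0$) and the relative loss change falls below
  `stop_ratio = 1e-7`, so the continuation cannot be cut short by an
  early plateau. A monotone acceptance guard (keep the previous iterate if
  the objective would rise, momentum restarted at each continuation stage)
  makes the recorded loss trace non-increasing by construction without
  affecting the convergence guarantees. In the rigid regime this drives
  the missing-entry RMSE below $10^{-2}$ in normalized units — the convex
  relaxation recovers the unique completion.
* **Trajectory optimization** runs Adam (learning rate 0.01) on $n \times
  3$ coordinates against the masked squared-error loss, warm-started from
  the classical-MDS realization of the nearest-neighbour fill — a random
  start frequently lands in reflection-branch local minima, the warm start
  does not. Its output is the exact EDM of the optimized coordinates
  (rank 5 by construction); `impose_known = TRUE` trades that exactness
  for bit-exact preservation.
* **Nearest-neighbour fill** uses Chebyshev index distance with ties
  averaged — the corruption pattern is isotropic in index space, and the
  tie rule makes the fill deterministic.
* **Database search** scores candidates by the masked Frobenius
  discrepancy and fills unknowns from the argmin; the batched variant
  evaluates all query-candidate pairs with dense BLAS products over
  flattened upper triangles, the only practical route at
  protocol scale ($2\times10^4$ database entries, hundreds of queries).
* **Ensemble mean** averages each unknown entry over cohort members that
  know it, falling back to the nearest-neighbour fill for entries known
  nowhere.

Rank decisions use a relative threshold of $10^{-8}\sigma_{\max}$
throughout. `rank_fraction()` implements the ratio
$\sqrt{\sum_{i\le r}\lambda_i^2}/\sqrt{\sum_i \lambda_i^2}$ of singular
values. Degenerate inputs are handled explicitly: masks with no known
entries are rejected by the completion methods, `realize()` flags inputs
whose Gram spectrum has material negative mass, and the Fréchet distance
regularizes the covariances diagonally (and flags it) if the matrix
square root fails.

## Scale of the shipped experiments

Everything the package asserts about itself is recomputed at test time at
desk scale, chosen to keep the whole suite within a coffee break on one
CPU: priors are trained at $n = 16$ with $M$ between $2\times10^3$ and
$4\times10^3$ images; the database-search benchmark runs the full
protocol ($n = 64$, $M = 2\times10^4$ database entries, 500 queries,
$\mu = 0.25$); scaling checks use $M = 5000$ ensembles at $n = 64$; the
chromatin protocol uses 80 synthetic cells of 16 loci. Full-scale
training ($n = 64$, $M = 2\times10^5$, deep priors) is out of desk reach
and the corresponding published numbers are treated as reference points,
not test targets. The Fréchet ensemble metric ships with a deterministic
analytic embedding (diagonal-band means plus leading singular values);
adapters around pretrained convolutional features can be plugged in via
`fid_embedding()`, but absolute FID magnitudes are embedding-specific and
are not comparison targets here. Stochastic summary metrics are reported
with percentile bootstrap intervals (1000 resamples by default), the
estimator of choice when no distributional form is available.

## A worked example

```{r example, eval = FALSE}
library(fbmedm)

schedule <- make_schedule()
train <- sample_fbm_edms(fbm_spec(0.5, 16, count = 2000, seed = 1))
prior <- train_denoiser(train, schedule, seed = 2)

truth <- sample_fbm_edms(fbm_spec(0.5, 16, count = 1, seed = 3))[[1]]
mask <- bernoulli_mask(16, mu = 0.25, seed = 4)
partial <- corrupt(truth, mask)

rigidity_test(mask)$rigid             # is the completion unique?
fista <- fista_complete(partial)
ddrm <- inpaint_ddrm(prior, partial, schedule, n_steps = 200, seed = 5)

nrm <- prior$normalizer
rmse_missing(normalize_edm(nrm, fista$completed),
             normalize_edm(nrm, truth), mask)
rmse_missing(normalize_edm(nrm, ddrm$completed),
             normalize_edm(nrm, truth), mask)
```

## Known limitations

* Known distances are assumed exact; measurement noise on the *observed*
  entries is not modelled (the natural extension would relax the hard
  merge of known pixels to a noise-weighted one).
* The affine prior matches second-order statistics only; rank sharpness
  and higher-moment features of generated matrices are weaker than a deep
  prior would give.
* Matrices larger than the trained size are not tiled or fine-tuned;
  completion runs at the trained $n$.
* Chromatin with active loop extrusion is not fractal; the $H = 1/3$
  prior applies to cohesin-depleted conditions only.
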