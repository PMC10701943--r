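---
title: "Empirical Bayes batch correction: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical Bayes batch correction: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batchEB)
```

## The problem

Expression datasets assembled from several experimental runs carry
systematic technical differences — batch effects — that shift both the
mean and the variance of each gene within a batch. If uncorrected, these
shifts masquerade as biology. `batchEB` implements the two standard
empirical Bayes correctors for this problem: a location–scale model for
log-scale (approximately normal) matrices, and a negative binomial model
with quantile matching for raw sequencing counts.

The choice between them is a distributional question, not a preference.
RMA-processed microarray intensities are log2-transformed and close to
normal; raw RNA-Seq counts are overdispersed counts and should *not* be
log-transformed or normalized first — the count model consumes them
directly, and library size is handled inside the model as an offset. It
is the user's responsibility to check which regime their data are in.

## Normal model

For gene $g$, sample $j$ in batch $i$:

$$y_{gij} = \alpha_g + X_j \beta_g + \gamma_{gi} + \delta_{gi}\,
\varepsilon_{gij}, \qquad \varepsilon_{gij} \sim N(0, 1)$$

$\alpha_g$ is the gene's baseline, $X_j$ an optional numeric covariate
vector (biology to preserve), $\gamma_{gi}$ the additive and
$\delta^2_{gi}$ the multiplicative batch effect.

**Standardization.** Each gene is fit by least squares against the full
design (one indicator per batch, no intercept, plus covariates).
$\hat\alpha_g$ is the batch-size-weighted average of the batch
coefficients, which enforces $\sum_i (n_i/N)\,\hat\gamma_{gi} = 0$; the
pooled variance uses denominator $N$
($\hat\sigma^2_g = \tfrac1N \sum (y - \hat y)^2$), while the within-batch
variances of the standardized residuals
$z_{gij} = (y_{gij} - \hat\alpha_g - X_j\hat\beta_g)/\hat\sigma_g$ use
$n_i - 1$. These denominator conventions keep small worked examples
closed-form and match the established moment definitions for this model
family. Batch effect estimates are taken on the standardized scale:
$\hat\gamma_{gi}$ is the batch mean of $z$, $\hat\delta^2_{gi}$ its
within-batch variance.

**Empirical Bayes shrinkage.** With thousands of genes and often few
samples per batch, the per-gene estimates are noisy. They are shrunk
toward cross-gene priors whose hyperparameters are estimated by method of
moments per batch: a normal prior
$\gamma_{gi} \sim N(\bar\gamma_i, \tau^2_i)$ and an inverse-gamma prior on
$\delta^2_{gi}$ with shape $\lambda_i = (m^2 + 2s^2)/s^2$ and scale
$\theta_i = (m s^2 + m^3)/s^2$, where $m$ and $s^2$ are the across-gene
mean and variance of $\hat\delta^2$ (this inverse-gamma has mean $m$ and
variance $s^2$). Two posterior variants are provided:

- *Parametric*: the coupled conditional-posterior updates
  $$\gamma^* = \frac{n\tau^2\hat\gamma + \delta^{2*}\bar\gamma}
  {n\tau^2 + \delta^{2*}}, \qquad
  \delta^{2*} = \frac{\theta + \tfrac12\sum_j (z_{gij} - \gamma^*)^2}
  {n/2 + \lambda - 1}$$
  are iterated from $(\hat\gamma, \hat\delta^2)$ until the maximum
  relative change of both falls below `tol` (default $10^{-4}$, cap 1000
  iterations — matching the magnitude of the defaults in the established
  tools for this model, and cheap to tighten). $n$ is the gene's
  non-missing sample count in the batch.
- *Non-parametric*: gene $g$'s posterior is the likelihood-weighted
  average of all other genes' estimates, with weights
  $\prod_{j \in i} N(z_{gij};\, \hat\gamma_{g'i}, \hat\delta^2_{g'i})$.
  No prior form is assumed; it is slower ($O(G^2)$) but robust to
  non-normal effect distributions. Weights are accumulated in log space
  with max-subtraction, so products over many samples cannot underflow;
  if every donor weight still underflows the gene falls back to its own
  estimates with a warning.

**Adjustment.** $y^*_{gij} = \hat\sigma_g (z_{gij} - \gamma^*_{gi}) /
\delta^*_{gi} + \hat\alpha_g + X_j\hat\beta_g$. Entries whose gene–batch
posterior is exactly the identity transform ($\gamma^* = 0$,
$\delta^{2*} = 1$) are returned untouched, so the no-effect limit
round-trips the input bit-exactly rather than accumulating two rounding
errors through the division and multiplication by $\hat\sigma_g$.

## Count model

$$y_{gij} \sim \mathrm{NB}(\mu_{gij}, \phi_{gi}), \qquad
\log \mu_{gij} = \alpha_g + X_j\beta_g + \gamma_{gi} + o_j, \qquad
\mathrm{Var}(y) = \mu + \phi\mu^2$$

with offsets $o_j = \log(\text{column sum})$ — the simplest depth model,
chosen deliberately: no normalization factors are computed, and users who
want TMM-like scaling can pre-scale the offsets themselves. A consequence
worth spelling out: the corrector preserves each sample's library size,
so when a one-sided batch fold change inflates a batch's column sums, the
*raw* per-gene batch mean ratio after correction equals the depth ratio,
not 1. Residual batch effect should therefore be assessed on
depth-normalized values (the package's tests do exactly that); downstream
pipelines normalize depth anyway.

**Dispersion estimation.** The model family leaves the estimator of
$\phi_{gi}$ open; we use the Cox–Reid adjusted profile likelihood (APL),
the standard choice for NB GLMs, maximized natively: for each batch, the
per-gene APL (NB log-likelihood at the IRLS-fitted mean minus
$\tfrac12\log\det X^TWX$) is evaluated on a 40-point log-spaced grid over
$[10^{-6}, 10]$, vectorized across genes. The batch-common dispersion
maximizes the summed APL, refined by golden-section search
(`stats::optimize`) between the bracketing grid points; gene-wise
dispersions take the per-gene grid argmax refined by parabolic
interpolation in log-dispersion (grid spacing is ~1.3×, so the
interpolated maximum is well within estimation noise). This
grid-plus-refinement scheme was chosen over per-gene golden-section
because every grid evaluation is a single vectorized fit of all genes —
orders of magnitude faster in R with identical objective. Gene-wise
estimation needs $n_i > p_{cov} + 2$ samples; smaller batches use the
common value. A batch whose profile is maximized at the lower bound is
treated as Poisson ($\phi = 0$, with a warning), and $\phi = 0$ entries
use Poisson distribution functions throughout.

**GLM fitting.** Per-gene IRLS with weights $\mu/(1 + \phi\mu)$, run
simultaneously for all genes against the shared design (the per-gene
normal-equation blocks are assembled by matrix products; only the final
$p \times p$ solves loop). Initialization regresses
$\log(y + 0.1) - o_j$ on the design, which is finite in the presence of
zeros; convergence is a relative deviance change below $10^{-8}$ (cap
100); fitted means are clamped to $[10^{-8}, 10^{12}]$ to keep weights
finite. Genes whose fit diverges fall back to moment coefficients
(log batch mean minus mean offset) with a warning.

**Quantile matching.** Counts are moved from the batch distribution
$\mathrm{NB}(\mu_{gij}, \phi_{gi})$ to the batch-free one, whose
$\log$-mean replaces the batch coefficients by their batch-size-weighted
average and whose dispersion is the same weighted average of
$\phi_{gi}$. The per-entry map is fixed, edge rules included, and must
stay bit-stable:

- $y \le 1$: returned unchanged;
- otherwise $p = F_{\text{batch}}(y - 1)$; if $|p - 1| < 10^{-4}$ the
  value sits so deep in the tail that the inverse map is numerically
  meaningless — returned unchanged;
- otherwise $y^* = 1 + Q_{\text{free}}(p)$, with $Q$ the smallest
  integer whose CDF reaches $p$.

When the batch and batch-free distributions coincide the map is the
identity, exactly — outputs are always non-negative integers, and the
whole pipeline is deterministic (no randomness anywhere). The tail guard
means the map is monotone in $y$ on the adjusted region but can step
down where pass-through begins; this is inherent to any bounded-tail
rule and affects only entries with $p > 1 - 10^{-4}$.

## Reference batches and mean-only mode

With `ref_batch` set, both correctors return the reference batch's
samples bit-identical to the input and adjust all other batches toward
it. In the normal model the standardization itself is re-parametrized:
$\hat\alpha_g$ is the reference batch's coefficient and
$\hat\sigma^2_g$ is pooled over reference residuals only — the
reference's scale defines the target scale. (Whether the pooled variance
should use all batches or the reference only is genuinely open; we chose
reference-only, which makes the reference's distribution the fixed
point of the transform.) In the count model the batch-free mean uses the
reference coefficient and the reference dispersion.

`mean_only = TRUE` corrects the additive effect only: $\delta^{2*}
\equiv 1$ and $\gamma^*$ is the one-step posterior mean with unit
variance, computed with the batch's actual observation count $n_i$. One
widely used implementation fixes $n = 1$ in this formula, shrinking much
harder; we use $n_i$ because it is the actual conditional posterior mean
under the stated prior, and document the difference rather than
reproduce it. Mean-only is also the only coherent semantics for
singleton batches (a one-sample batch has no variance to correct), so
batches of size 1 are accepted in the normal model only under mean-only.

## Degenerate inputs and numerical choices

- Genes constant across all samples (zero pooled variance) cannot be
  standardized; they bypass correction unchanged, with a warning. Count
  genes that are all-zero everywhere likewise pass through.
- Confounding is detected by numerical rank of the combined design:
  singular values below $10^{-8}$ times the largest are treated as zero.
  A covariate collinear with batch is an error, not a silent drop.
- If the across-gene variance of $\hat\delta^2$ is zero the
  inverse-gamma moments are undefined; variance shrinkage is skipped
  ($\delta^{2*} = \hat\delta^2$) while location shrinkage proceeds.
- Missing values are allowed in the normal model only (the count model
  has no missing-data semantics): they are ignored in every moment,
  $n_i$ is replaced by the gene's observed count, and they stay missing
  in the output.
- Batch labels are opaque strings ordered by first appearance, and
  covariates must arrive numerically encoded — categorical expansion is
  the caller's job, which keeps rank checking unambiguous.

## The synthetic generator

`simulate_microarray()` draws exactly from the normal model above:
baselines $\alpha_g \sim N(8, 2)$ (a typical log2-intensity range),
additive effects with standard deviation `gamma_spread` satisfying the
weighted zero-sum constraint, and variance multipliers
$\delta^2_{gi} \sim \text{InvGamma}(\texttt{delta\_shape},
\texttt{delta\_shape} - 1)$ with mean 1. The additive effects are drawn
freely for batches $2..k$ with batch 1 solving the constraint; naive
recentring of i.i.d. draws would shrink the realized spread below
`gamma_spread` (by $\sqrt2$ for two equal batches) and silently weaken
every downstream recovery test. `simulate_counts()` draws NB counts with
log-normal base means (median ≈ 50 counts), a designated random subset
of genes carrying the batch fold change, uniform library-size factors,
and an optional balanced binary covariate entering on the log scale. One
integer seed drives each generator call, so datasets are
bit-reproducible.

What the generator does *not* emulate: gene–gene correlation, platform-
or probe-specific noise, outlier samples, and confounded designs.
Passing tests on these simulations therefore demonstrate correctness of
the estimation machinery under the stated models — not robustness to
real-data pathologies outside them.

## Validation design

The test suite pairs every non-trivial computation with an independent
oracle: hand-derived closed forms for standardization, hyperpriors and
the first parametric iteration; a deliberately naive double-loop
re-implementation of the non-parametric posterior (agreement to
$10^{-10}$); a linear CDF-scan oracle for the quantile map; the
established `sva` implementations of the normal-model corrector as an
external cross-check (all modes but mean-only, see above); and
simulation-recovery checks at moderate sizes — 1000 genes × 2×20 samples
for the normal model, 2000 genes × 2×15 for counts, 150–200 samples per
gene for dispersion recovery — sizes chosen to make sampling noise small
relative to the asserted bands while keeping the suite fast. One caveat
surfaced by this design: after *in-sample* correction the per-gene batch
means are equalized almost exactly, so post-correction two-sample tests
reject far *below* the nominal rate (a share near 0, not 0.05). That is
over-homogenization, shared by the established implementations, and
worth knowing when interpreting post-correction hypothesis tests.

## Limitations

- The normal model assumes the input is on a scale where residuals are
  roughly Gaussian; it will not complain about raw-scale input.
- Covariate effects are linear on the modeled scale, shared across
  batches, and must not be confounded with batch.
- The count model's batch-free dispersion is a batch-size-weighted
  average of per-batch dispersions — a pooling choice, not an estimate
  of a batch-free dispersion.
- Gene-by-gene numeric parity with other count-model implementations is
  not guaranteed: the dispersion estimator is not part of the model
  family's specification, and different estimators yield slightly
  different fitted distributions (the validation surface is
  simulation-based recovery instead).
- No surrogate-variable estimation, no single-cell containers, no
  normalization-factor computation.
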