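# batchEB

Empirical Bayes batch effect correction for high-throughput expression
data, in R. When samples profiled in different runs, labs or platforms are
merged, systematic technical shifts ("batch effects") can dwarf the
biology. `batchEB` removes them with two complementary correctors:

- **`combat_norm()`** — for approximately normal, log-scale matrices
  (RMA-normalized microarray intensities, log-transformed abundances).
  Location–scale model per gene *g*, sample *j*, batch *i*:

  *y<sub>gij</sub>* = α<sub>g</sub> + X<sub>j</sub>β<sub>g</sub> +
  γ<sub>gi</sub> + δ<sub>gi</sub>ε<sub>gij</sub>,  ε ~ N(0, 1)

  with α<sub>g</sub> the gene baseline, X<sub>j</sub> optional covariates,
  γ<sub>gi</sub> the additive and δ²<sub>gi</sub> the multiplicative batch
  effect. Per-gene batch effects are estimated on standardized data and
  shrunk across genes with empirical Bayes priors — a parametric
  normal/inverse-gamma scheme (fast) or a non-parametric
  likelihood-weighted scheme (no prior-form assumption) — then the fitted
  transform is inverted with the shrunk effects.

- **`combat_seq()`** — for raw RNA-Seq counts, no preprocessing needed.
  Negative binomial GLM per gene with log link and library-size offsets:

  log μ<sub>gij</sub> = α<sub>g</sub> + X<sub>j</sub>β<sub>g</sub> +
  γ<sub>gi</sub>,  Var(y<sub>gij</sub>) = μ<sub>gij</sub> +
  φ<sub>gi</sub>μ²<sub>gij</sub>

  Dispersions φ<sub>gi</sub> are estimated per batch by Cox–Reid adjusted
  profile likelihood. Each count is then mapped from its batch-specific NB
  distribution to the batch-free one by quantile matching, producing
  adjusted **integer** counts.

Both correctors support covariates (biological signal to preserve), a
reference batch (its samples pass through bit-identically and everything
else is adjusted toward it), and — for the normal model — a mean-only mode
and tolerance of missing values. A synthetic-data generator
(`simulate_microarray()`, `simulate_counts()`) with known injected batch
structure, residual-batch-effect diagnostics (`batch_f_statistics()`,
`relative_difference_summary()`), TSV/CSV readers/writers and a CLI
(`exec/batcheb`, or `run_cli()`) round out the package.

## Worked example

```r
library(batchEB)

## log-scale expression: 500 genes, 2 batches of 10, additive effects of
## spread 1 and inverse-gamma(4) variance multipliers
sim <- simulate_microarray(n_genes = 500, batch_sizes = c(10, 10),
                           gamma_spread = 1, delta_shape = 4, seed = 1)
corrected <- combat_norm(sim$matrix, sim$design, method = "parametric")
median(batch_f_statistics(sim$matrix, sim$design))   # 12.47
median(batch_f_statistics(corrected, sim$design))    # 0.046
```

The per-gene one-way F statistic contrasts between-batch to within-batch
variance: a median of 12.5 before correction means the injected batch
effect dominates; 0.05 after means batch means are equalized (in-sample
correction is conservative, so F falls below the null expectation of ≈ 1).

```r
## raw counts: 500 genes, 2 batches of 8, 2x fold change on half the genes
simc <- simulate_counts(n_genes = 500, batch_sizes = c(8, 8),
                        fold_change = 2, phi_true = 0.3, seed = 2)
adj <- combat_seq(simc$matrix, simc$design)

cpm <- function(m) sweep(m, 2, colSums(m), "/")
i2 <- simc$design$batch == "batch2"
ratio <- function(m) rowMeans(cpm(m)[, i2]) / rowMeans(cpm(m)[, !i2])
median(ratio(simc$matrix)[simc$truth$affected])  # 1.35  (batch effect visible)
median(ratio(adj), na.rm = TRUE)                 # 0.998 (removed)
```

Ratios are computed on depth-normalized counts because the corrector, by
design, preserves each sample's library size. The two posterior variants
of the normal model agree closely on the same input:

```r
np <- combat_norm(sim$matrix, sim$design, method = "nonparametric")
relative_difference_summary(corrected, np)
#> mean relative difference: -0.00016064 (95% CI [-0.0204374, 0.0150943])
#> relative squared error:   5.91903e-05
#> entries used: 10000 (excluded: 0)
```

From the shell:

```sh
exec/batcheb norm --input expr.tsv --batch batches.tsv --output corrected.tsv
exec/batcheb seq  --input counts.tsv --batch batches.tsv --output adjusted.tsv
```

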