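# Forward simulation of the two generative models, with the injected
# batch/covariate structure returned as ground truth. One integer seed
# drives all draws, so a given call is bit-reproducible.

sim_labels <- function(batch_sizes) {
  if (length(batch_sizes) < 2L)
    stop_batchEB("batchEB_single_batch_error", "need >= 2 batches")
  if (any(batch_sizes < 1L))
    stop_batchEB("batchEB_value_error", "batch sizes must be >= 1")
  rep(paste0("batch", seq_along(batch_sizes)), times = batch_sizes)
}

# balanced binary covariate, alternating within each batch so it is never
# confounded with batch
sim_covariate <- function(batch_sizes) {
  unlist(lapply(batch_sizes, function(n) rep_len(c(0, 1), n)))
}

#' Simulate a microarray-like log-scale expression matrix with batch effects
#'
#' Draws from the additive location-scale model: per-gene baselines
#' `alpha_g ~ N(8, 2)` (log2-intensity scale), additive batch effects
#' `gamma_gi ~ N(0, gamma_spread^2)` recentred so their batch-size-weighted
#' mean is zero per gene, multiplicative batch effects
#' `delta2_gi ~ InvGamma(delta_shape, delta_shape - 1)` (mean 1; smaller
#' `delta_shape` = heavier variance heterogeneity), and
#' `y = alpha + X beta + gamma + delta * eps` with standard normal noise.
#' An optional balanced binary covariate carries effect `beta_true`.
#'
#' @param n_genes number of genes.
#' @param batch_sizes integer vector of per-batch sample counts (>= 2
#'   batches).
#' @param gamma_spread standard deviation of the additive batch effects
#'   (log2 units); 0 disables them.
#' @param delta_shape inverse-gamma shape for the variance multipliers;
#'   must exceed 1. `Inf` fixes all multipliers at 1.
#' @param beta_true optional covariate effect (scalar, log2 units); when
#'   given, a balanced binary covariate is included.
#' @param seed integer seed; same seed, same dataset.
#' @return list with `matrix` (genes x samples), `design`
#'   ([batch_design()]) and `truth` (class `"sim_truth"`: `gamma_true`,
#'   `delta2_true`, `beta_true`, `covariate`, `seed`).
#' @export
simulate_microarray <- function(n_genes, batch_sizes, gamma_spread = 1,
                                delta_shape = 4, beta_true = NULL,
                                seed = 1L) {
  if (gamma_spread < 0)
    stop_batchEB("batchEB_value_error", "gamma_spread must be >= 0")
  if (delta_shape <= 1)
    stop_batchEB("batchEB_value_error", "delta_shape must exceed 1")
  set.seed(seed)
  labels <- sim_labels(batch_sizes)
  N <- length(labels)
  k <- length(batch_sizes)
  w <- batch_sizes / N
  gene_ids <- paste0("g", seq_len(n_genes))
  sample_ids <- paste0("s", seq_len(N))

  alpha <- stats::rnorm(n_genes, 8, 2)
  # free draws for batches 2..k; batch 1 solves the weighted zero-sum
  # constraint, so non-first batches have sd exactly gamma_spread
  gamma_free <- matrix(stats::rnorm(n_genes * (k - 1L), 0, gamma_spread),
                       n_genes, k - 1L)
  gamma <- cbind(-(gamma_free %*% w[-1L]) / w[1L], gamma_free)
  delta2 <- if (is.finite(delta_shape))
    matrix(1 / stats::rgamma(n_genes * k, shape = delta_shape,
                             rate = delta_shape - 1), n_genes, k)
  else matrix(1, n_genes, k)

  cov_mat <- NULL
  xb <- 0
  if (!is.null(beta_true)) {
    xc <- sim_covariate(batch_sizes)
    cov_mat <- matrix(xc, ncol = 1, dimnames = list(sample_ids, "cov1"))
    xb <- outer(rep(beta_true, n_genes), xc)
  }

  bidx <- rep(seq_len(k), times = batch_sizes)
  eps <- matrix(stats::rnorm(n_genes * N), n_genes, N)
  y <- alpha + xb + gamma[, bidx, drop = FALSE] +
    sqrt(delta2[, bidx, drop = FALSE]) * eps
  dimnames(y) <- list(gene_ids, sample_ids)

  bd <- batch_design(labels, sample_ids = sample_ids, covariates = cov_mat)
  truth <- structure(list(gamma_true = gamma, delta2_true = delta2,
                          beta_true = beta_true,
                          covariate = if (is.null(cov_mat)) NULL else cov_mat[, 1L],
                          seed = seed),
                     class = "sim_truth")
  list(matrix = y, design = bd, truth = truth)
}

#' Simulate an RNA-Seq count matrix with batch effects
#'
#' Draws counts from the NB model `Var = mu + phi mu^2`: per-gene base
#' means are log-normal, a designated random subset of genes has its mean
#' multiplied by `fold_change` in every batch after the first, per-sample
#' library-size factors are uniform on `lib_size_range`, and an optional
#' balanced binary covariate multiplies the mean by `exp(beta_true)`.
#' `phi_true = 0` gives Poisson counts.
#'
#' @param n_genes number of genes.
#' @param batch_sizes integer vector of per-batch sample counts.
#' @param fold_change multiplicative batch effect on the mean (> 0)
#'   applied to affected genes in batches after the first.
#' @param frac_affected fraction of genes carrying the batch fold change.
#' @param phi_true NB dispersion, scalar or per-gene vector (>= 0).
#' @param lib_size_range range of multiplicative library-size factors.
#' @param base_meanlog,base_sdlog log-normal parameters of the per-gene
#'   base means.
#' @param beta_true optional covariate effect on the log scale.
#' @param seed integer seed.
#' @return list with `matrix` (integer counts), `design` and `truth`
#'   (`fold_true` genes x batches, `phi_true`, `beta_true`, `affected`,
#'   `lib_factors`, `covariate`, `seed`).
#' @export
simulate_counts <- function(n_genes, batch_sizes, fold_change = 2,
                            frac_affected = 0.5, phi_true = 0.3,
                            lib_size_range = c(0.7, 1.3),
                            base_meanlog = log(50), base_sdlog = 1,
                            beta_true = NULL, seed = 1L) {
  if (fold_change <= 0)
    stop_batchEB("batchEB_value_error", "fold_change must be > 0")
  if (any(phi_true < 0))
    stop_batchEB("batchEB_value_error", "phi_true must be >= 0")
  set.seed(seed)
  labels <- sim_labels(batch_sizes)
  N <- length(labels)
  k <- length(batch_sizes)
  gene_ids <- paste0("g", seq_len(n_genes))
  sample_ids <- paste0("s", seq_len(N))
  phi <- rep_len(phi_true, n_genes)

  base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  affected <- sort(sample.int(n_genes, round(frac_affected * n_genes)))
  fold <- matrix(1, n_genes, k)
  if (k > 1L) fold[affected, 2:k] <- fold_change

  lib <- stats::runif(N, lib_size_range[1L], lib_size_range[2L])
  cov_mat <- NULL
  covfold <- 1
  if (!is.null(beta_true)) {
    xc <- sim_covariate(batch_sizes)
    cov_mat <- matrix(xc, ncol = 1, dimnames = list(sample_ids, "cov1"))
    covfold <- exp(outer(rep(beta_true, n_genes), xc))
  }

  bidx <- rep(seq_len(k), times = batch_sizes)
  mu <- base * fold[, bidx, drop = FALSE] * covfold *
    matrix(lib, n_genes, N, byrow = TRUE)
  y <- matrix(0L, n_genes, N, dimnames = list(gene_ids, sample_ids))
  pois <- phi == 0
  if (any(pois))
    y[pois, ] <- stats::rpois(sum(pois) * N, mu[pois, , drop = FALSE])
  if (any(!pois))
    y[!pois, ] <- stats::rnbinom(sum(!pois) * N,
                                 size = 1 / phi[!pois],
                                 mu = mu[!pois, , drop = FALSE])
  bd <- batch_design(labels, sample_ids = sample_ids, covariates = cov_mat)
  truth <- structure(list(fold_true = fold, phi_true = phi,
                          beta_true = beta_true, affected = affected,
                          lib_factors = lib,
                          covariate = if (is.null(cov_mat)) NULL else cov_mat[, 1L],
                          seed = seed),
                     class = "sim_truth")
  list(matrix = y, design = bd, truth = truth)
}
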