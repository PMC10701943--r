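# Location-scale empirical Bayes correction for log-scale expression.
#
# Model: y_gij = alpha_g + X_j beta_g + gamma_gi + delta_gi * eps_gij,
# eps ~ N(0, 1). Per-gene batch effects (gamma, delta^2) are estimated on
# standardized data and shrunk across genes with empirical Bayes priors
# (normal prior on gamma, inverse-gamma on delta^2), then the fitted
# location-scale transform is inverted with the shrunk effects.

#' Standardize an expression matrix against its batch/covariate design
#'
#' Per-gene least-squares fit of the full design (batch indicators plus
#' covariates), producing the standardized residual matrix and the
#' per-batch location/scale estimates that feed the empirical Bayes step.
#'
#' The gene-wise baseline `alpha` is the batch-size-weighted average of the
#' batch coefficients, so the estimated additive effects satisfy
#' `sum_i (n_i/N) gamma_hat_gi = 0`. The pooled variance `sigma2` uses
#' denominator N; the within-batch variances of the standardized data use
#' denominator `n_i - 1`. With a reference batch set, `alpha` is the
#' reference batch's coefficient and `sigma2` is pooled over reference
#' residuals only, so `gamma_hat` is measured relative to the reference.
#'
#' Genes with zero pooled variance (constant after the fit) are flagged in
#' `retained` and bypass correction; missing values are ignored in all
#' moments and propagate to the output.
#'
#' @param x genes x samples numeric matrix of log-scale expression.
#' @param design design matrix from [validate_and_build_design()].
#' @return an object of class `"normal_fit"` with elements `alpha`, `beta`,
#'   `gamma_hat` (genes x batches, standardized scale), `sigma2`, `z`
#'   (standardized matrix), `delta2_hat` (genes x batches), `stand_mean`
#'   (genes x samples fitted batch-free mean), `n_obs` (non-missing counts
#'   per gene x batch), `retained`, and the design metadata.
#' @export
fit_standardization <- function(x, design) {
  bd <- attr(design, "batch_design")
  k <- attr(design, "n_batches")
  G <- nrow(x)
  N <- ncol(x)
  p <- ncol(design)

  # per-gene least squares; vectorized for complete genes, looped otherwise
  B <- matrix(NA_real_, G, p)
  complete <- !apply(is.na(x), 1L, any)
  if (any(complete)) {
    XtXinv <- solve(crossprod(design))
    B[complete, ] <- x[complete, , drop = FALSE] %*% design %*% XtXinv
  }
  if (any(!complete)) {
    for (g in which(!complete)) {
      obs <- !is.na(x[g, ])
      if (sum(obs) <= p) {
        B[g, ] <- NA_real_  # unidentifiable; gene dropped below
      } else {
        B[g, ] <- stats::lm.fit(design[obs, , drop = FALSE], x[g, obs])$coefficients
      }
    }
  }
  batch_coef <- B[, seq_len(k), drop = FALSE]
  beta <- if (p > k) B[, (k + 1L):p, drop = FALSE] else
    matrix(0, G, 0)

  w <- bd$sizes / N
  alpha <- if (is.null(bd$ref_batch)) drop(batch_coef %*% w) else
    batch_coef[, match(bd$ref_batch, bd$batches)]

  cov_part <- if (ncol(beta) > 0)
    beta %*% t(design[, (k + 1L):p, drop = FALSE]) else
    matrix(0, G, N)
  stand_mean <- alpha + cov_part                      # genes x samples

  resid <- x - B %*% t(design)
  if (is.null(bd$ref_batch)) {
    nobs_tot <- rowSums(!is.na(x))
    sigma2 <- rowSums(resid^2, na.rm = TRUE) / nobs_tot
  } else {
    ref_cols <- bd$batch == bd$ref_batch
    rr <- resid[, ref_cols, drop = FALSE]
    sigma2 <- rowSums(rr^2, na.rm = TRUE) / rowSums(!is.na(rr))
  }

  retained <- is.finite(sigma2) & sigma2 > .Machine$double.eps

  z <- (x - stand_mean) / sqrt(sigma2)
  z[!retained, ] <- NA_real_

  gamma_hat <- matrix(NA_real_, G, k, dimnames = list(rownames(x), bd$batches))
  delta2_hat <- gamma_hat
  n_obs <- matrix(0L, G, k, dimnames = dimnames(gamma_hat))
  for (i in seq_len(k)) {
    zi <- z[, bd$batch == bd$batches[i], drop = FALSE]
    ni <- rowSums(!is.na(zi))
    gm <- rowSums(zi, na.rm = TRUE) / ni
    gamma_hat[, i] <- gm
    delta2_hat[, i] <- rowSums((zi - gm)^2, na.rm = TRUE) / (ni - 1L)
    n_obs[, i] <- ni
  }

  # a gene also needs at least one observed value in every batch
  retained <- retained & rowSums(n_obs == 0L) == 0L
  if (any(!retained))
    warn_batchEB("batchEB_degenerate_gene_warning",
                 "%d gene(s) constant or unidentifiable; passed through unadjusted (first: %s)",
                 sum(!retained),
                 rownames(x)[which(!retained)[1L]] %||% which(!retained)[1L])

  structure(list(alpha = alpha, beta = beta, gamma_hat = gamma_hat,
                 sigma2 = sigma2, z = z, delta2_hat = delta2_hat,
                 stand_mean = stand_mean, n_obs = n_obs,
                 retained = retained, bd = bd, design = design),
            class = "normal_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Method-of-moments empirical Bayes hyperpriors
#'
#' Estimates, per batch, the normal prior on the additive effects
#' (`gamma_bar`, `tau2`) and the inverse-gamma prior on the standardized
#' within-batch variances (`lambda` shape, `theta` scale) by matching
#' moments across retained genes: with `m = mean(delta2_hat)` and
#' `s2 = var(delta2_hat)`, `lambda = (m^2 + 2 s2)/s2` and
#' `theta = (m s2 + m^3)/s2` (the inverse-gamma with these parameters has
#' mean `m` and variance `s2`).
#'
#' When the across-gene variance of `delta2_hat` is zero the inverse-gamma
#' moments are undefined; the batch is flagged `degenerate` (variance
#' shrinkage is skipped downstream, location shrinkage still applies).
#'
#' @param fit a [fit_standardization()] result.
#' @return an object of class `"eb_hyperpriors"`: per-batch vectors
#'   `gamma_bar`, `tau2`, `lambda`, `theta`, and logical `degenerate`.
#' @export
estimate_hyperpriors <- function(fit) {
  keep <- fit$retained
  if (sum(keep) < 2L)
    stop_batchEB("batchEB_eb_degenerate_error",
                 "need >= 2 retained genes to estimate hyperpriors")
  gh <- fit$gamma_hat[keep, , drop = FALSE]
  dh <- fit$delta2_hat[keep, , drop = FALSE]
  gamma_bar <- colMeans(gh)
  tau2 <- apply(gh, 2L, stats::var)
  m <- colMeans(dh)
  s2 <- apply(dh, 2L, stats::var)
  degenerate <- !is.finite(s2) | s2 <= 0
  lambda <- ifelse(degenerate, NA_real_, (m^2 + 2 * s2) / s2)
  theta <- ifelse(degenerate, NA_real_, (m * s2 + m^3) / s2)
  if (any(degenerate))
    warn_batchEB("batchEB_eb_degenerate_warning",
                 "across-gene variance of delta2_hat is zero in batch(es) %s; variance shrinkage skipped there",
                 paste(fit$bd$batches[degenerate], collapse = ", "))
  structure(list(gamma_bar = gamma_bar, tau2 = tau2,
                 lambda = lambda, theta = theta, degenerate = degenerate,
                 batches = fit$bd$batches),
            class = "eb_hyperpriors")
}

# posterior mean of gamma given a fixed variance d
post_gamma <- function(n, tau2, gamma_hat, d, gamma_bar)
  (n * tau2 * gamma_hat + d * gamma_bar) / (n * tau2 + d)

#' Parametric empirical Bayes posteriors
#'
#' Iterates, per gene and batch, the coupled conditional-posterior updates
#' \deqn{\gamma^* = \frac{n \tau^2 \hat\gamma + \delta^{2*} \bar\gamma}
#'                       {n \tau^2 + \delta^{2*}}, \qquad
#'       \delta^{2*} = \frac{\theta + \tfrac12 \sum_j (z_{gij}-\gamma^*)^2}
#'                          {n/2 + \lambda - 1}}
#' from `(gamma_hat, delta2_hat)` to a fixed point, stopping when the
#' maximum relative change of both quantities falls below `tol`. `n` is the
#' number of non-missing values of the gene in the batch.
#'
#' @param fit a [fit_standardization()] result.
#' @param priors an [estimate_hyperpriors()] result.
#' @param tol relative convergence tolerance (default 1e-4).
#' @param max_iter iteration cap; hitting it raises a convergence warning
#'   and returns the last iterate.
#' @param mean_only if TRUE, variances are not shrunk or corrected:
#'   `delta2_star` is identically 1 and `gamma_star` is the one-step
#'   posterior mean with unit variance.
#' @return an object of class `"eb_posterior"`: `gamma_star`, `delta2_star`
#'   (genes x batches) and `iterations`.
#' @export
parametric_posterior <- function(fit, priors, tol = 1e-4, max_iter = 1000L,
                                 mean_only = FALSE) {
  keep <- fit$retained
  k <- length(fit$bd$batches)
  G <- nrow(fit$gamma_hat)
  gamma_star <- matrix(NA_real_, G, k, dimnames = dimnames(fit$gamma_hat))
  delta2_star <- gamma_star
  iterations <- matrix(0L, G, k, dimnames = dimnames(fit$gamma_hat))

  for (i in seq_len(k)) {
    n <- fit$n_obs[keep, i]
    g_hat <- fit$gamma_hat[keep, i]
    d_hat <- fit$delta2_hat[keep, i]
    gb <- priors$gamma_bar[i]; t2 <- priors$tau2[i]
    if (mean_only) {
      gamma_star[keep, i] <- post_gamma(n, t2, g_hat, 1, gb)
      delta2_star[keep, i] <- 1
      iterations[keep, i] <- 1L
      next
    }
    if (priors$degenerate[i]) {
      gamma_star[keep, i] <- post_gamma(n, t2, g_hat, d_hat, gb)
      delta2_star[keep, i] <- d_hat
      iterations[keep, i] <- 1L
      next
    }
    la <- priors$lambda[i]; th <- priors$theta[i]
    zi <- fit$z[keep, fit$bd$batch == fit$bd$batches[i], drop = FALSE]
    S1 <- rowSums(zi, na.rm = TRUE)
    S2 <- rowSums(zi^2, na.rm = TRUE)
    g_old <- g_hat; d_old <- d_hat
    it_done <- rep(NA_integer_, length(g_hat))
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- post_gamma(n, t2, g_hat, d_old, gb)
      ssq <- S2 - 2 * g_new * S1 + n * g_new^2
      d_new <- (th + 0.5 * ssq) / (n / 2 + la - 1)
      change <- pmax(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                     abs(d_new - d_old) / pmax(d_old, 1e-12))
      it_done[is.na(it_done) & change < tol] <- it
      g_old <- g_new; d_old <- d_new
      if (max(change) < tol) break
      if (it >= max_iter) {
        warn_batchEB("batchEB_convergence_warning",
                     "parametric posterior hit max_iter = %d in batch %s (max rel change %.3g)",
                     max_iter, fit$bd$batches[i], max(change))
        break
      }
    }
    it_done[is.na(it_done)] <- it
    gamma_star[keep, i] <- g_old
    delta2_star[keep, i] <- d_old
    iterations[keep, i] <- it_done
  }
  structure(list(gamma_star = gamma_star, delta2_star = delta2_star,
                 iterations = iterations),
            class = "eb_posterior")
}

#' Non-parametric empirical Bayes posteriors
#'
#' Monte Carlo posterior over the other genes' estimates: for gene `g` in
#' batch `i`, every other retained gene `g'` is weighted by the likelihood
#' of `g`'s standardized values under `N(gamma_hat_g'i, delta2_hat_g'i)`,
#' and `(gamma_star, delta2_star)` are the weight-normalized averages of
#' the donors' `(gamma_hat, delta2_hat)`. Weights are accumulated in log
#' space with max-subtraction; no prior form is assumed. Missing samples
#' are skipped in the likelihood product.
#'
#' @inheritParams parametric_posterior
#' @return an object of class `"eb_posterior"` (`iterations` is `NULL`).
#' @export
nonparametric_posterior <- function(fit, mean_only = FALSE) {
  keep <- fit$retained
  if (sum(keep) < 2L)
    stop_batchEB("batchEB_eb_degenerate_error",
                 "need >= 2 retained genes for the non-parametric posterior")
  k <- length(fit$bd$batches)
  G <- nrow(fit$gamma_hat)
  gamma_star <- matrix(NA_real_, G, k, dimnames = dimnames(fit$gamma_hat))
  delta2_star <- gamma_star

  for (i in seq_len(k)) {
    zi <- fit$z[keep, fit$bd$batch == fit$bd$batches[i], drop = FALSE]
    n <- rowSums(!is.na(zi))
    S1 <- rowSums(zi, na.rm = TRUE)
    S2 <- rowSums(zi^2, na.rm = TRUE)
    gam <- fit$gamma_hat[keep, i]
    del <- if (mean_only) rep(1, sum(keep)) else fit$delta2_hat[keep, i]
    # logW[g, g'] = sum_{j in batch} log N(z_gj; gam_g', del_g')
    logW <- -0.5 * outer(n, log(2 * pi * del)) -
      outer(S2, 1 / (2 * del)) +
      outer(S1, gam / del) -
      outer(n, gam^2 / (2 * del))
    diag(logW) <- -Inf
    mx <- apply(logW, 1L, max)
    bad <- !is.finite(mx)
    if (any(bad))
      warn_batchEB("batchEB_underflow_warning",
                   "all donor weights underflow for %d gene(s) in batch %s; using own estimates",
                   sum(bad), fit$bd$batches[i])
    W <- exp(logW - mx)
    W[bad, ] <- 0
    sw <- rowSums(W)
    gs <- drop(W %*% gam) / sw
    ds <- drop(W %*% del) / sw
    gs[bad] <- gam[bad]; ds[bad] <- del[bad]
    gamma_star[keep, i] <- gs
    delta2_star[keep, i] <- if (mean_only) 1 else ds
  }
  structure(list(gamma_star = gamma_star, delta2_star = delta2_star,
                 iterations = NULL),
            class = "eb_posterior")
}

#' Invert the standardization with shrunk batch effects
#'
#' Applies `y* = (sigma_g / delta*_gi) (z_gij - gamma*_gi) + alpha_g +
#' X_j beta_g`. Entries whose gene-batch posterior is exactly the identity
#' transform (`gamma* = 0`, `delta2* = 1`) are returned unchanged, so a
#' forced-identity posterior round-trips the input bit-exactly. Constant
#' (non-retained) genes pass through; missing values stay missing; with a
#' reference batch set its samples are returned identical to the input.
#'
#' @param fit a [fit_standardization()] result.
#' @param post an `"eb_posterior"` object.
#' @param x the original input matrix (source of pass-through values).
#' @return corrected matrix, same shape and dimnames as `x`.
#' @export
apply_adjustment <- function(fit, post, x) {
  bd <- fit$bd
  out <- x
  keep <- fit$retained
  if (any(keep)) {
    sig <- sqrt(fit$sigma2[keep])
    for (i in seq_along(bd$batches)) {
      cols <- bd$batch == bd$batches[i]
      gs <- post$gamma_star[keep, i]
      ds <- sqrt(post$delta2_star[keep, i])
      adj <- sig * (fit$z[keep, cols, drop = FALSE] - gs) / ds +
        fit$stand_mean[keep, cols, drop = FALSE]
      ident <- gs == 0 & ds == 1     # exact identity transform
      if (any(ident)) adj[ident, ] <- x[keep, cols, drop = FALSE][ident, ]
      out[keep, cols] <- adj
    }
  }
  if (!is.null(bd$ref_batch))
    out[, bd$batch == bd$ref_batch] <- x[, bd$batch == bd$ref_batch]
  out
}

#' Empirical Bayes batch correction for log-scale expression
#'
#' Full location-scale correction pipeline: standardization, empirical
#' Bayes hyperprior estimation across genes, parametric or non-parametric
#' posterior shrinkage of the per-gene batch effects, and inversion of the
#' fitted transform. Assumes approximately normal input (e.g. RMA/log2
#' microarray intensities, log-transformed abundances) — check your data's
#' distribution; raw counts belong in [combat_seq()] instead.
#'
#' @param x genes x samples numeric matrix of log-scale expression values.
#'   Missing values are tolerated and propagated.
#' @param batch a [batch_design()], or a vector of per-sample batch labels.
#' @param covariates optional samples x p numeric covariate matrix (ignored
#'   when `batch` is already a `batch_design` carrying covariates).
#' @param method `"parametric"` (iterated normal/inverse-gamma posteriors;
#'   fast) or `"nonparametric"` (likelihood-weighted donor averaging; no
#'   prior-form assumption, slower).
#' @param mean_only correct only the additive batch effect, leaving
#'   per-batch variances untouched. Required if any batch has one sample.
#' @param ref_batch optional reference batch: its samples are returned
#'   unchanged and all other batches are adjusted toward it.
#' @param tol,max_iter convergence controls for the parametric iteration.
#' @return corrected matrix, same dimensions and dimnames as `x`.
#' @examples
#' sim <- simulate_microarray(n_genes = 50, batch_sizes = c(5, 5),
#'                            gamma_spread = 1, delta_shape = 4, seed = 1)
#' corrected <- combat_norm(sim$matrix, sim$design)
#' @export
combat_norm <- function(x, batch, covariates = NULL,
                        method = c("parametric", "nonparametric"),
                        mean_only = FALSE, ref_batch = NULL,
                        tol = 1e-4, max_iter = 1000L) {
  method <- match.arg(method)
  bd <- if (inherits(batch, "batch_design")) batch else
    batch_design(batch, sample_ids = colnames(x) %||% names(batch),
                 covariates = covariates, ref_batch = ref_batch)
  if (!is.null(ref_batch) && is.null(bd$ref_batch))
    bd$ref_batch <- as.character(ref_batch)
  design <- validate_and_build_design(x, bd, mode = "normal",
                                      mean_only = mean_only)
  fit <- fit_standardization(x, design)
  if (mean_only) fit$delta2_hat[] <- 1
  post <- if (method == "parametric") {
    priors <- estimate_hyperpriors(fit)
    parametric_posterior(fit, priors, tol = tol, max_iter = max_iter,
                         mean_only = mean_only)
  } else {
    nonparametric_posterior(fit, mean_only = mean_only)
  }
  apply_adjustment(fit, post, x)
}
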