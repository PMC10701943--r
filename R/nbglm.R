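# Negative binomial GLM machinery for the count corrector: log link,
# per-sample log-library-size offsets, NB variance mu + phi mu^2.
# IRLS is vectorized across genes (shared design, gene-specific weights);
# dispersions maximize the Cox-Reid adjusted profile likelihood.

MU_FLOOR <- 1e-8
MU_CEIL <- 1e12

# Expand phi (scalar | per-gene vector | G x n matrix) to a G x n matrix.
expand_phi <- function(phi, G, n) {
  if (is.matrix(phi)) {
    stopifnot(nrow(phi) == G, ncol(phi) == n)
    phi
  } else if (length(phi) == 1L) {
    matrix(phi, G, n)
  } else {
    stopifnot(length(phi) == G)
    matrix(phi, G, n)
  }
}

# NB log likelihood, elementwise phi; phi == 0 entries use Poisson.
nb_loglik_rows <- function(Y, MU, PHI) {
  ll <- matrix(0, nrow(Y), ncol(Y))
  pois <- PHI == 0
  if (any(pois))
    ll[pois] <- stats::dpois(Y[pois], MU[pois], log = TRUE)
  if (any(!pois))
    ll[!pois] <- stats::dnbinom(Y[!pois], size = 1 / PHI[!pois],
                                mu = MU[!pois], log = TRUE)
  rowSums(ll)
}

# Per-gene NB deviance at fixed dispersion (Poisson limit at phi == 0).
nb_deviance_rows <- function(Y, MU, PHI) {
  t1 <- ifelse(Y > 0, Y * log(Y / MU), 0)
  pois <- PHI == 0
  t2 <- matrix(0, nrow(Y), ncol(Y))
  t2[pois] <- -(Y[pois] - MU[pois])
  if (any(!pois))
    t2[!pois] <- -(Y[!pois] + 1 / PHI[!pois]) *
      log((1 + PHI[!pois] * Y[!pois]) / (1 + PHI[!pois] * MU[!pois]))
  2 * rowSums(t1 + t2)
}

# Weighted least-squares solve of the IRLS normal equations for all genes
# at once. W, Z are G x n; X is n x p. Returns G x p coefficients.
solve_wls <- function(W, Z, X) {
  p <- ncol(X)
  G <- nrow(W)
  if (p == 1L) {
    a <- W %*% (X[, 1L]^2)
    b <- (W * Z) %*% X[, 1L]
    return(cbind(drop(b / a)))
  }
  M <- array(NA_real_, c(G, p, p))
  for (a in seq_len(p))
    for (b in a:p) {
      v <- drop(W %*% (X[, a] * X[, b]))
      M[, a, b] <- v
      M[, b, a] <- v
    }
  V <- (W * Z) %*% X
  if (p == 2L) {
    det <- M[, 1, 1] * M[, 2, 2] - M[, 1, 2]^2
    return(cbind((M[, 2, 2] * V[, 1] - M[, 1, 2] * V[, 2]) / det,
                 (M[, 1, 1] * V[, 2] - M[, 1, 2] * V[, 1]) / det))
  }
  B <- matrix(NA_real_, G, p)
  for (g in seq_len(G)) {
    B[g, ] <- tryCatch(solve(M[g, , ], V[g, ]),
                       error = function(e) rep(NA_real_, p))
  }
  B
}

# log det(X' W X) per gene, for the Cox-Reid adjustment.
logdet_xtwx <- function(W, X) {
  p <- ncol(X)
  G <- nrow(W)
  if (p == 1L) return(log(drop(W %*% (X[, 1L]^2))))
  M <- array(NA_real_, c(G, p, p))
  for (a in seq_len(p))
    for (b in a:p) {
      v <- drop(W %*% (X[, a] * X[, b]))
      M[, a, b] <- v
      M[, b, a] <- v
    }
  if (p == 2L)
    return(log(M[, 1, 1] * M[, 2, 2] - M[, 1, 2]^2))
  vapply(seq_len(G), function(g) determinant(M[g, , ])$modulus[1L], 0)
}

# Moment fallback coefficients: per design column, log of the weighted
# mean count (offset-corrected); covariate-style columns get 0.
mom_coefficients <- function(Y, X, offset) {
  p <- ncol(X)
  B <- matrix(0, nrow(Y), p)
  for (a in seq_len(p)) {
    xa <- X[, a]
    if (all(xa %in% c(0, 1)) && sum(xa) > 0) {
      cols <- xa == 1
      B[, a] <- log(pmax(rowMeans(Y[, cols, drop = FALSE]), 0.5)) -
        mean(offset[cols])
    }
  }
  B
}

# IRLS for all genes simultaneously at fixed dispersion(s).
# Y: G x n counts, X: n x p design, offset: length n, phi: scalar/vector/matrix.
nb_irls <- function(Y, X, offset, phi, tol = 1e-8, max_iter = 100L,
                    warn_divergence = TRUE) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  PHI <- expand_phi(phi, G, n)
  OFF <- matrix(offset, G, n, byrow = TRUE)
  # init: OLS of log(counts + 0.1) - offset on the design
  r <- log(Y + 0.1) - OFF
  B <- r %*% X %*% solve(crossprod(X))
  dev_old <- NULL
  for (it in seq_len(max_iter)) {
    eta <- B %*% t(X) + OFF
    MU <- pmin(pmax(exp(eta), MU_FLOOR), MU_CEIL)
    W <- MU / (1 + PHI * MU)
    Z <- (eta - OFF) + (Y - MU) / MU
    B_new <- solve_wls(W, Z, X)
    bad <- !is.finite(rowSums(B_new))
    if (any(bad)) B_new[bad, ] <- B[bad, , drop = FALSE]
    B <- B_new
    eta <- B %*% t(X) + OFF
    MU <- pmin(pmax(exp(eta), MU_FLOOR), MU_CEIL)
    dev <- nb_deviance_rows(Y, MU, PHI)
    if (!is.null(dev_old)) {
      delta <- abs(dev - dev_old) / (abs(dev_old) + 0.1)
      delta <- delta[is.finite(delta)]
      if (length(delta) && max(delta) < tol) {
        dev_old <- dev
        break
      }
    }
    dev_old <- dev
  }
  diverged <- !is.finite(rowSums(B)) | !is.finite(dev_old)
  if (any(diverged)) {
    if (warn_divergence)
      warn_batchEB("batchEB_irls_divergence_warning",
                   "IRLS diverged for %d gene(s); using moment coefficients",
                   sum(diverged))
    Bm <- mom_coefficients(Y, X, offset)
    B[diverged, ] <- Bm[diverged, , drop = FALSE]
    eta <- B %*% t(X) + OFF
    MU <- pmin(pmax(exp(eta), MU_FLOOR), MU_CEIL)
  }
  list(coefficients = B, mu = MU, diverged = diverged, phi = PHI)
}

# Cox-Reid adjusted profile log-likelihood per gene at dispersion phi
# (scalar or per-gene). Refits the mean model at this phi.
cr_apl <- function(Y, X, offset, phi) {
  fit <- nb_irls(Y, X, offset, phi, warn_divergence = FALSE)
  W <- fit$mu / (1 + fit$phi * fit$mu)
  nb_loglik_rows(Y, fit$mu, fit$phi) - 0.5 * logdet_xtwx(W, X)
}

PHI_LOWER <- 1e-6
PHI_UPPER <- 10

#' Estimate negative binomial dispersions per batch
#'
#' For each batch, maximizes the Cox-Reid adjusted profile likelihood
#' (APL) of a within-batch intercept + covariates model, with log
#' library-size offsets. A batch-common dispersion is found by profiling
#' the summed APL on a log-spaced grid over `[1e-6, 10]` followed by
#' golden-section refinement; gene-wise dispersions maximize the per-gene
#' APL on the same grid with parabolic refinement in log-dispersion.
#' Gene-wise estimation is used only when the batch has more samples than
#' covariate columns plus 2; smaller batches fall back to the common
#' value. A batch whose common APL is maximized at the lower bound is
#' treated as Poisson (dispersion 0, with a warning).
#'
#' @param counts genes x samples matrix of non-negative integers.
#' @param bd a [batch_design()] (covariates, if any, enter the
#'   within-batch mean model).
#' @param offsets optional per-sample log offsets; default
#'   `log(colSums(counts))`.
#' @param grid_size number of grid points for the APL profile.
#' @return an object of class `"dispersion_estimates"`: `genewise`
#'   (genes x batches), `common` (per batch), `method_used` (per batch,
#'   `"genewise"` or `"common"`).
#' @export
estimate_dispersions <- function(counts, bd, offsets = NULL, grid_size = 40L) {
  if (is.null(offsets)) offsets <- log(colSums(counts))
  G <- nrow(counts)
  k <- length(bd$batches)
  genewise <- matrix(NA_real_, G, k, dimnames = list(rownames(counts), bd$batches))
  common <- stats::setNames(rep(NA_real_, k), bd$batches)
  method_used <- stats::setNames(rep("common", k), bd$batches)
  p_cov <- if (is.null(bd$covariates)) 0L else ncol(bd$covariates)
  grid <- exp(seq(log(PHI_LOWER), log(PHI_UPPER), length.out = grid_size))

  for (i in seq_len(k)) {
    cols <- bd$batch == bd$batches[i]
    ni <- sum(cols)
    if (ni < 2L)
      stop_batchEB("batchEB_single_sample_batch_error",
                   "dispersion estimation needs >= 2 samples in batch %s",
                   bd$batches[i])
    Yi <- counts[, cols, drop = FALSE]
    Xi <- cbind(intercept = rep(1, ni),
                if (!is.null(bd$covariates))
                  bd$covariates[cols, , drop = FALSE])
    # drop within-batch constant covariate columns (absorbed by intercept)
    if (ncol(Xi) > 1L) {
      keep_col <- c(TRUE, apply(Xi[, -1L, drop = FALSE], 2L,
                                function(v) stats::sd(v) > 0))
      Xi <- Xi[, keep_col, drop = FALSE]
    }
    offi <- offsets[cols]

    apl <- vapply(grid, function(ph) cr_apl(Yi, Xi, offi, ph),
                  numeric(G))                       # G x grid_size
    apl <- matrix(apl, nrow = G)
    total <- colSums(apl)

    # common: golden-section refinement around the grid maximum
    jmax <- which.max(total)
    if (jmax == 1L) {
      common[i] <- 0
      warn_batchEB("batchEB_poisson_fallback_warning",
                   "common dispersion for batch %s maximized at the lower bound; using Poisson (0)",
                   bd$batches[i])
    } else {
      lo <- grid[max(jmax - 1L, 1L)]
      hi <- grid[min(jmax + 1L, grid_size)]
      opt <- stats::optimize(function(lp) sum(cr_apl(Yi, Xi, offi, exp(lp))),
                             interval = log(c(lo, hi)), maximum = TRUE,
                             tol = 1e-4)
      common[i] <- exp(opt$maximum)
    }

    if (ni > p_cov + 2L) {
      method_used[i] <- "genewise"
      jg <- max.col(apl, ties.method = "first")
      lg <- log(grid)
      h <- lg[2L] - lg[1L]
      phig <- numeric(G)
      interior <- jg > 1L & jg < grid_size
      at_lower <- jg == 1L
      at_upper <- jg == grid_size
      if (any(interior)) {
        idx <- which(interior)
        f0 <- apl[cbind(idx, jg[idx] - 1L)]
        f1 <- apl[cbind(idx, jg[idx])]
        f2 <- apl[cbind(idx, jg[idx] + 1L)]
        den <- f0 - 2 * f1 + f2
        shift <- ifelse(abs(den) > 1e-12, 0.5 * h * (f0 - f2) / den, 0)
        shift <- pmin(pmax(shift, -h), h)
        phig[idx] <- exp(lg[jg[idx]] + shift)
      }
      phig[at_lower] <- 0
      phig[at_upper] <- PHI_UPPER
      genewise[, i] <- phig
    } else {
      genewise[, i] <- common[i]
    }
  }
  structure(list(genewise = genewise, common = common,
                 method_used = method_used),
            class = "dispersion_estimates")
}

#' Fit per-gene negative binomial GLMs at fixed dispersions
#'
#' Iteratively reweighted least squares with log link, NB variance
#' `mu + phi mu^2` and per-sample log-library-size offsets, run for all
#' genes against the shared batch/covariate design. Each sample's
#' dispersion is its batch's gene-wise estimate. Convergence is declared
#' when the relative deviance change drops below 1e-8 (at most 100
#' iterations); genes whose fit diverges fall back to moment coefficients
#' with a warning.
#'
#' @param counts genes x samples matrix of non-negative integers.
#' @param design design matrix from [validate_and_build_design()].
#' @param dispersions a [estimate_dispersions()] result.
#' @param offsets optional per-sample log offsets; default
#'   `log(colSums(counts))`.
#' @return an object of class `"nb_fit"`: `coefficients` (genes x design
#'   columns), `offsets`, `fitted_mu` (genes x samples), `phi`
#'   (genes x samples), `diverged`, plus the design metadata.
#' @export
fit_nb_glm <- function(counts, design, dispersions, offsets = NULL) {
  bd <- attr(design, "batch_design")
  if (is.null(offsets)) offsets <- log(colSums(counts))
  if (any(!is.finite(offsets)))
    stop_batchEB("batchEB_value_error",
                 "sample(s) with zero library size: %s",
                 paste(bd$sample_ids[!is.finite(offsets)], collapse = ", "))
  PHI <- dispersions$genewise[, as.integer(bd$batch), drop = FALSE]
  fit <- nb_irls(counts, design, offsets, PHI)
  structure(list(coefficients = fit$coefficients, offsets = offsets,
                 fitted_mu = fit$mu, phi = fit$phi,
                 diverged = fit$diverged, bd = bd, design = design),
            class = "nb_fit")
}
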