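make_fit <- function(z, bd, gamma_hat, delta2_hat, n_obs = NULL,
                     sigma2 = NULL, alpha = NULL) {
  G <- nrow(gamma_hat)
  structure(list(alpha = alpha %||% rep(0, G),
                 beta = matrix(0, G, 0),
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 sigma2 = sigma2 %||% rep(1, G), z = z,
                 stand_mean = matrix(0, G, ncol(z)),
                 n_obs = n_obs %||%
                   matrix(rep(as.integer(bd$sizes), each = G), G,
                          length(bd$batches)),
                 retained = rep(TRUE, G), bd = bd, design = NULL),
            class = "normal_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("standardization matches the closed-form least-squares toy", {
  x <- matrix(c(0, 2, 4, 6), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  bd <- batch_design(c("A", "A", "B", "B"), sample_ids = colnames(x))
  X <- validate_and_build_design(x, bd, "normal")
  fit <- fit_standardization(x, X)
  expect_equal(unname(fit$alpha), 3)
  expect_equal(unname(fit$gamma_hat[1, ]), c(-2, 2))
  expect_equal(unname(fit$sigma2), 1)
  expect_equal(unname(fit$z[1, ]), c(-3, -1, 1, 3))
  expect_equal(unname(fit$delta2_hat[1, ]), c(2, 2))
  # batch-size-weighted constraint on gamma_hat
  w <- bd$sizes / 4
  expect_lt(abs(sum(fit$gamma_hat[1, ] * w)), 1e-8)
})

test_that("identical batches give zero estimated batch effects", {
  base <- matrix(rnorm(20, 8), 5, 4)
  x <- cbind(base, base)
  colnames(x) <- paste0("s", 1:8); rownames(x) <- paste0("g", 1:5)
  bd <- batch_design(rep(c("A", "B"), each = 4), sample_ids = colnames(x))
  fit <- fit_standardization(x, validate_and_build_design(x, bd, "normal"))
  expect_equal(max(abs(fit$gamma_hat)), 0, tolerance = 1e-10)
})

test_that("reference-batch standardization re-parametrizes around the reference", {
  set.seed(3)
  x <- matrix(rnorm(40, 8), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  x[, 5:8] <- x[, 5:8] + 2
  bd <- batch_design(rep(c("A", "B"), each = 4), sample_ids = colnames(x),
                     ref_batch = "A")
  fit <- fit_standardization(x, validate_and_build_design(x, bd, "normal"))
  # oracle: direct least squares with A as baseline
  a_coef <- rowMeans(x[, 1:4])
  expect_equal(unname(fit$alpha), unname(a_coef))
  resA <- x[, 1:4] - a_coef
  expect_equal(unname(fit$sigma2), unname(rowMeans(resA^2)))
  expect_equal(unname(fit$gamma_hat[, "A"]), rep(0, 5), tolerance = 1e-10)
})

test_that("hyperprior moment matching reproduces two-point closed forms", {
  bd <- batch_design(c("A", "A", "B", "B"), sample_ids = paste0("s", 1:4))
  gh <- matrix(c(-0.5, 0.5, -0.5, 0.5), 2, 2)
  dh <- matrix(c(1, 3, 1, 3), 2, 2)
  fit <- make_fit(matrix(0, 2, 4), bd, gh, dh)
  pr <- estimate_hyperpriors(fit)
  expect_equal(unname(pr$gamma_bar), c(0, 0))
  expect_equal(unname(pr$tau2), c(0.5, 0.5))
  # delta2 over genes = (1, 3): m = 2, s2 = 2 -> lambda = 4, theta = 6;
  # InvGamma(4, 6) indeed has mean 6/3 = 2 and variance 36/(9*2) = 2
  expect_equal(unname(pr$lambda), c(4, 4))
  expect_equal(unname(pr$theta), c(6, 6))

  fit0 <- make_fit(matrix(0, 2, 4), bd, matrix(0.7, 2, 2), dh)
  pr0 <- estimate_hyperpriors(fit0)
  expect_equal(unname(pr0$gamma_bar), c(0.7, 0.7))
  expect_equal(unname(pr0$tau2), c(0, 0))
  post <- parametric_posterior(fit0, pr0)
  expect_equal(unname(post$gamma_star[, 1]), c(0.7, 0.7))  # zero-variance prior collapses
})

test_that("parametric updates reproduce the hand-computed first iteration", {
  bd <- batch_design(c("A", "A", "B", "B"), sample_ids = paste0("s", 1:4))
  z <- matrix(c(1, 3, -1, 1), 1, 4)
  fit <- make_fit(z, bd, gamma_hat = matrix(c(2, 0), 1, 2),
                  delta2_hat = matrix(c(2, 2), 1, 2))
  pr <- structure(list(gamma_bar = c(0, 0), tau2 = c(1, 1),
                       lambda = c(3, 3), theta = c(2, 2),
                       degenerate = c(FALSE, FALSE), batches = c("A", "B")),
                  class = "eb_hyperpriors")
  expect_warning(   # one convergence warning per batch at max_iter = 1
    expect_warning(parametric_posterior(fit, pr, max_iter = 1L),
                   class = "batchEB_convergence_warning"),
    class = "batchEB_convergence_warning")
  post <- suppressWarnings(parametric_posterior(fit, pr, max_iter = 1L))
  expect_equal(post$gamma_star[1, 1], 1)          # (2*1*2 + 2*0)/(2*1 + 2)
  expect_equal(post$delta2_star[1, 1], 4 / 3)     # (2 + 0.5*4)/(1 + 3 - 1)
})

test_that("parametric posterior is a fixed point of its update equations", {
  sim <- simulate_microarray(200, c(8, 8), gamma_spread = 1, delta_shape = 4,
                             seed = 11)
  fit <- fit_standardization(sim$matrix,
                             validate_and_build_design(sim$matrix, sim$design,
                                                       "normal"))
  pr <- estimate_hyperpriors(fit)
  tol <- 1e-4
  post <- parametric_posterior(fit, pr, tol = tol)
  for (i in 1:2) {
    cols <- sim$design$batch == sim$design$batches[i]
    n <- fit$n_obs[, i]
    g <- post$gamma_star[, i]; d <- post$delta2_star[, i]
    g_next <- (n * pr$tau2[i] * fit$gamma_hat[, i] + d * pr$gamma_bar[i]) /
      (n * pr$tau2[i] + d)
    ssq <- rowSums((fit$z[, cols] - g_next)^2)
    d_next <- (pr$theta[i] + 0.5 * ssq) / (n / 2 + pr$lambda[i] - 1)
    expect_lt(max(abs(g_next - g) / pmax(abs(g), 1e-12)), tol)
    expect_lt(max(abs(d_next - d) / d), tol)
  }
  # tau2 -> Inf limit: no shrinkage of the location
  pr_inf <- pr; pr_inf$tau2 <- c(1e12, 1e12)
  post_inf <- parametric_posterior(fit, pr_inf)
  expect_equal(post_inf$gamma_star, fit$gamma_hat, tolerance = 1e-6)
})

test_that("nonparametric posterior equals the brute-force double loop", {
  sim <- simulate_microarray(50, c(5, 5, 5), gamma_spread = 1,
                             delta_shape = 4, seed = 21)
  fit <- fit_standardization(sim$matrix,
                             validate_and_build_design(sim$matrix, sim$design,
                                                       "normal"))
  post <- nonparametric_posterior(fit)
  for (i in 1:3) {
    cols <- sim$design$batch == sim$design$batches[i]
    bf <- bf_nonparametric(fit$z[, cols], fit$gamma_hat[, i],
                           fit$delta2_hat[, i])
    expect_lt(max(abs(post$gamma_star[, i] - bf$gamma_star)), 1e-10)
    expect_lt(max(abs(post$delta2_star[, i] - bf$delta2_star)), 1e-10)
  }
})

test_that("nonparametric edge cases: two genes swap, identical genes fix", {
  bd <- batch_design(c("A", "A", "B", "B"), sample_ids = paste0("s", 1:4))
  z <- matrix(c(0.1, -0.1, 0.2, -0.2, 0.3, -0.3, 0.1, -0.1), 2, 4)
  gh <- matrix(c(0.5, -0.5, 0.2, -0.2), 2, 2)
  dh <- matrix(c(1.2, 0.8, 1.1, 0.9), 2, 2)
  post <- nonparametric_posterior(make_fit(z, bd, gh, dh))
  expect_equal(post$gamma_star[1, ], gh[2, ])   # single donor: each takes the other
  expect_equal(post$gamma_star[2, ], gh[1, ])
  expect_equal(post$delta2_star[1, ], dh[2, ])

  ghc <- matrix(0.4, 3, 2); dhc <- matrix(1.3, 3, 2)
  zc <- matrix(rnorm(12), 3, 4)
  postc <- nonparametric_posterior(make_fit(zc, bd, ghc, dhc))
  expect_equal(postc$gamma_star, ghc)
  expect_equal(postc$delta2_star, dhc)
})

test_that("identity posteriors round-trip the input bit-exactly", {
  set.seed(7)
  x <- matrix(rnorm(60, 8, 2), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  bd <- batch_design(rep(c("A", "B"), each = 5), sample_ids = colnames(x))
  fit <- fit_standardization(x, validate_and_build_design(x, bd, "normal"))
  post <- structure(list(gamma_star = matrix(0, 6, 2),
                         delta2_star = matrix(1, 6, 2)),
                    class = "eb_posterior")
  expect_identical(apply_adjustment(fit, post, x), x)
})

test_that("plugging the estimates back in equalizes batch means", {
  x <- matrix(c(0, 2, 4, 6), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  bd <- batch_design(c("A", "A", "B", "B"), sample_ids = colnames(x))
  fit <- fit_standardization(x, validate_and_build_design(x, bd, "normal"))
  post <- structure(list(gamma_star = fit$gamma_hat,
                         delta2_star = fit$delta2_hat),
                    class = "eb_posterior")
  y <- apply_adjustment(fit, post, x)
  expect_equal(mean(y[1, 1:2]), 3)
  expect_equal(mean(y[1, 3:4]), 3)
})

test_that("full pipeline removes batch effects; mean_only leaves variances", {
  sim <- simulate_microarray(300, c(10, 10), gamma_spread = 1.5,
                             delta_shape = 3, seed = 13)
  out <- combat_norm(sim$matrix, sim$design)
  f_before <- batch_f_statistics(sim$matrix, sim$design)
  f_after <- batch_f_statistics(out, sim$design)
  expect_lt(median(f_after), 0.5)
  expect_gt(median(f_before), median(f_after))

  mo <- suppressWarnings(combat_norm(sim$matrix, sim$design, mean_only = TRUE))
  i2 <- sim$design$batch == "batch2"
  v_in <- apply(sim$matrix[, i2], 1, var)
  v_out <- apply(mo[, i2], 1, var)
  expect_equal(v_out, v_in, tolerance = 1e-10)   # only shifted
  m1 <- rowMeans(mo[, !i2]); m2 <- rowMeans(mo[, i2])
  expect_lt(median(abs(m1 - m2)), 0.15)

  expect_error(combat_norm(sim$matrix, rep("A", 20)),
               class = "batchEB_single_batch_error")
})

test_that("constant genes pass through with a warning; NAs propagate", {
  sim <- simulate_microarray(40, c(5, 5), gamma_spread = 1, delta_shape = 4,
                             seed = 17)
  x <- sim$matrix
  x[3, ] <- 5
  x[8, 2] <- NA
  expect_warning(combat_norm(x, sim$design),
                 class = "batchEB_degenerate_gene_warning")
  out <- suppressWarnings(combat_norm(x, sim$design))
  expect_identical(out[3, ], x[3, ])
  expect_true(is.na(out[8, 2]))
  expect_false(anyNA(out[-8, ]))
})

test_that("reference-batch samples pass through bit-exactly", {
  sim <- simulate_microarray(50, c(6, 6), gamma_spread = 1, delta_shape = 4,
                             seed = 19)
  refA <- combat_norm(sim$matrix, sim$design, ref_batch = "batch1")
  i1 <- sim$design$batch == "batch1"
  expect_identical(refA[, i1], sim$matrix[, i1])
  expect_false(identical(refA[, !i1], sim$matrix[, !i1]))
})

test_that("all modes agree with the independent reference implementation", {
  suppressMessages(requireNamespace("sva"))
  sim <- simulate_microarray(120, c(7, 9), gamma_spread = 1, delta_shape = 4,
                             seed = 23)
  x <- sim$matrix
  b <- as.character(sim$design$batch)
  quiet_ref <- function(...) {
    out <- NULL
    invisible(utils::capture.output(out <- sva::ComBat(...)))
    out
  }
  expect_equal(combat_norm(x, sim$design), quiet_ref(x, batch = b),
               tolerance = 1e-5)
  expect_equal(combat_norm(x, sim$design, method = "nonparametric"),
               quiet_ref(x, batch = b, par.prior = FALSE),
               tolerance = 1e-10)
  expect_equal(combat_norm(x, sim$design, ref_batch = "batch2"),
               quiet_ref(x, batch = b, ref.batch = "batch2"),
               tolerance = 1e-5)
  simc <- simulate_microarray(80, c(6, 6), gamma_spread = 1, delta_shape = 4,
                              beta_true = 1.2, seed = 29)
  expect_equal(combat_norm(simc$matrix, simc$design),
               quiet_ref(simc$matrix, batch = as.character(simc$design$batch),
                         mod = cbind(1, simc$design$covariates)),
               tolerance = 1e-5)
})
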