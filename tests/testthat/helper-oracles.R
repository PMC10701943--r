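# Independent brute-force oracles, deliberately written as plain double
# loops / linear scans so they share no code path with the vectorized
# implementations they check.

# Non-parametric EB posterior for one batch: direct product-of-densities
# weights, no log-space tricks.
bf_nonparametric <- function(z_batch, gamma_hat, delta2_hat) {
  G <- nrow(z_batch)
  gs <- numeric(G)
  ds <- numeric(G)
  for (g in seq_len(G)) {
    w <- numeric(G)
    for (gp in seq_len(G)) {
      if (gp == g) next
      zi <- z_batch[g, ]
      zi <- zi[!is.na(zi)]
      w[gp] <- prod(stats::dnorm(zi, mean = gamma_hat[gp],
                                 sd = sqrt(delta2_hat[gp])))
    }
    w <- w / sum(w)
    gs[g] <- sum(w * gamma_hat)
    ds[g] <- sum(w * delta2_hat)
  }
  list(gamma_star = gs, delta2_star = ds)
}

# Smallest integer k with NB/Poisson CDF(k) >= p, by linear scan of the pmf.
bf_nb_quantile <- function(p, mu, phi, kmax = 100000L) {
  cdf <- 0
  for (k in 0:kmax) {
    cdf <- cdf + if (phi == 0) stats::dpois(k, mu) else
      stats::dnbinom(k, size = 1 / phi, mu = mu)
    if (cdf >= p) return(k)
  }
  stop("bf_nb_quantile: scan exhausted")
}

# Quantile-map oracle per entry, following the documented edge rules.
bf_match_one <- function(y, mu_b, phi_b, mu_f, phi_f) {
  if (y <= 1) return(y)
  p <- if (phi_b == 0) stats::ppois(y - 1, mu_b) else
    stats::pnbinom(y - 1, size = 1 / phi_b, mu = mu_b)
  if (abs(p - 1) < 1e-4) return(y)
  1 + bf_nb_quantile(p, mu_f, phi_f)
}

# Small deterministic expression fixture with visible batch structure.
toy_expression <- function(G = 6, seed = 99) {
  set.seed(seed)
  n <- 8
  x <- matrix(rnorm(G * n, 8, 1), G, n,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  x[, 5:8] <- x[, 5:8] + 1.5
  bd <- batch_design(rep(c("A", "B"), each = 4), sample_ids = colnames(x))
  list(x = x, bd = bd)
}
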