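# Validation metrics: entrywise relative differences between two corrected
# matrices, and per-gene one-way F statistics quantifying residual batch
# effects.

#' Summarize entrywise relative differences between two matrices
#'
#' Computes `(a - b) / b` over entries where `b` is nonzero (and neither
#' entry is missing) and reports the mean, the empirical 2.5% / 97.5%
#' percentiles, and the relative squared error
#' `sum((a - b)^2) / sum(b^2)`. Entries excluded because `b = 0` or a
#' value is missing are counted in `n_excluded`. The interval is a
#' percentile summary of the per-entry differences, not a standard error
#' on the mean.
#'
#' @param a,b numeric matrices of identical shape (and dimnames, if set).
#' @return an object of class `"diff_summary"`: `mean_rel_diff`,
#'   `ci95_low`, `ci95_high`, `relative_squared_error`, `n_used`,
#'   `n_excluded`.
#' @export
relative_difference_summary <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop_batchEB("batchEB_shape_mismatch_error",
                 "matrices differ in shape: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b))
  if (!is.null(dimnames(a)) && !is.null(dimnames(b)) &&
      !identical(dimnames(a), dimnames(b)))
    stop_batchEB("batchEB_shape_mismatch_error", "matrix dimnames disagree")
  ok <- !is.na(a) & !is.na(b) & b != 0
  d <- (a[ok] - b[ok]) / b[ok]
  qs <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  structure(list(mean_rel_diff = mean(d),
                 ci95_low = qs[1L], ci95_high = qs[2L],
                 relative_squared_error = sum((a[ok] - b[ok])^2) / sum(b[ok]^2),
                 n_used = sum(ok), n_excluded = sum(!ok)),
            class = "diff_summary")
}

#' @export
print.diff_summary <- function(x, ...) {
  cat(sprintf("mean relative difference: %.6g (95%% CI [%.6g, %.6g])\n",
              x$mean_rel_diff, x$ci95_low, x$ci95_high))
  cat(sprintf("relative squared error:   %.6g\n", x$relative_squared_error))
  cat(sprintf("entries used: %d (excluded: %d)\n", x$n_used, x$n_excluded))
  invisible(x)
}

#' Per-gene one-way F statistics for residual batch effects
#'
#' Between/within variance ratio of each gene's values across batches
#' with the usual degrees of freedom (`k - 1`, `N - k`). Large values
#' before correction and near-1 values after indicate the additive batch
#' effect was removed. Genes with zero within-batch variance get `Inf`
#' (with a warning); missing values are ignored per gene.
#'
#' @param x genes x samples numeric matrix.
#' @param bd a [batch_design()] with >= 2 samples per batch.
#' @return named numeric vector of per-gene F statistics.
#' @export
batch_f_statistics <- function(x, bd) {
  bd <- reorder_design(bd, colnames(x) %||% bd$sample_ids)
  if (any(bd$sizes < 2L))
    stop_batchEB("batchEB_single_sample_batch_error",
                 "F statistics need >= 2 samples per batch")
  k <- length(bd$batches)
  obs <- !is.na(x)
  n_tot <- rowSums(obs)
  grand <- rowSums(x, na.rm = TRUE) / n_tot
  ssb <- 0
  ssw <- 0
  for (i in seq_len(k)) {
    xi <- x[, bd$batch == bd$batches[i], drop = FALSE]
    ni <- rowSums(!is.na(xi))
    mi <- rowSums(xi, na.rm = TRUE) / ni
    ssb <- ssb + ni * (mi - grand)^2
    ssw <- ssw + rowSums((xi - mi)^2, na.rm = TRUE)
  }
  f <- (ssb / (k - 1)) / (ssw / (n_tot - k))
  if (any(ssw == 0))
    warn_batchEB("batchEB_degenerate_gene_warning",
                 "%d gene(s) with zero within-batch variance; F = Inf",
                 sum(ssw == 0))
  stats::setNames(f, rownames(x))
}
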