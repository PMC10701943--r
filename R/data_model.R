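#' Describe the batch structure of a set of samples
#'
#' Bundles per-sample batch labels, optional numeric covariates and an
#' optional reference batch into the design object consumed by
#' [combat_norm()] and [combat_seq()].
#'
#' Batch labels are treated as opaque strings; the batch order used
#' everywhere downstream (columns of parameter tables, design indicator
#' columns) is the order of first appearance in `batch`. Covariates must
#' already be numerically encoded (expand categorical covariates to
#' indicator columns yourself); do not include an intercept column.
#'
#' @param batch character (or coercible) vector of batch labels, one per
#'   sample. Names, if present, are taken as sample ids.
#' @param sample_ids sample identifiers; defaults to `names(batch)`.
#' @param covariates optional numeric matrix or data frame (samples x p) of
#'   covariates, rows in the same order as `batch` (or rownames matching
#'   `sample_ids`). No intercept column.
#' @param ref_batch optional label of a reference batch whose samples are
#'   left untouched by correction.
#' @return an object of class `"batch_design"`: a list with elements
#'   `batch` (factor, levels in first-appearance order), `sample_ids`,
#'   `batches`, `sizes` (named per-batch sample counts), `covariates`
#'   (numeric matrix or NULL) and `ref_batch`.
#' @examples
#' bd <- batch_design(c("A", "A", "B", "B"),
#'                    sample_ids = paste0("s", 1:4))
#' bd$sizes
#' @export
batch_design <- function(batch, sample_ids = names(batch),
                         covariates = NULL, ref_batch = NULL) {
  batch <- as.character(batch)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_along(batch))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(batch))
    stop_batchEB("batchEB_shape_mismatch_error",
                 "%d batch labels but %d sample ids",
                 length(batch), length(sample_ids))
  if (anyDuplicated(sample_ids))
    stop_batchEB("batchEB_shape_mismatch_error",
                 "duplicated sample ids: %s",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(batch))
    stop_batchEB("batchEB_value_error", "missing batch labels")
  levels <- unique(batch)            # first-appearance order
  if (length(levels) < 2L)
    stop_batchEB("batchEB_single_batch_error",
                 "at least 2 distinct batches are required (got %d)",
                 length(levels))
  f <- factor(batch, levels = levels)
  if (!is.null(ref_batch)) {
    ref_batch <- as.character(ref_batch)
    if (!ref_batch %in% levels)
      stop_batchEB("batchEB_value_error",
                   "ref_batch '%s' is not one of the batch labels", ref_batch)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(batch))
      stop_batchEB("batchEB_shape_mismatch_error",
                   "covariates have %d rows but there are %d samples",
                   nrow(covariates), length(batch))
    if (!is.numeric(covariates))
      stop_batchEB("batchEB_value_error",
                   "covariates must be numeric (encode categories yourself)")
    if (anyNA(covariates) || any(!is.finite(covariates)))
      stop_batchEB("batchEB_value_error", "covariates contain NA/Inf")
    if (!is.null(rownames(covariates)) &&
        !identical(rownames(covariates), sample_ids)) {
      if (!setequal(rownames(covariates), sample_ids))
        stop_batchEB("batchEB_shape_mismatch_error",
                     "covariate rownames do not match sample ids")
      covariates <- covariates[sample_ids, , drop = FALSE]
    }
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  }
  structure(list(batch = f,
                 sample_ids = sample_ids,
                 batches = levels,
                 sizes = stats::setNames(as.integer(table(f)[levels]), levels),
                 covariates = covariates,
                 ref_batch = ref_batch),
            class = "batch_design")
}

#' @export
print.batch_design <- function(x, ...) {
  cat("batch_design:", length(x$sample_ids), "samples,",
      length(x$batches), "batches\n")
  print(x$sizes)
  if (!is.null(x$covariates))
    cat("covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  if (!is.null(x$ref_batch)) cat("reference batch:", x$ref_batch, "\n")
  invisible(x)
}

# Reorder a batch_design to a given sample order (ids must match as sets).
reorder_design <- function(bd, sample_ids) {
  if (identical(bd$sample_ids, sample_ids)) return(bd)
  missing_in_bd <- setdiff(sample_ids, bd$sample_ids)
  extra_in_bd <- setdiff(bd$sample_ids, sample_ids)
  if (length(missing_in_bd) || length(extra_in_bd))
    stop_batchEB("batchEB_shape_mismatch_error",
                 "sample ids disagree between matrix and batch design%s%s",
                 if (length(missing_in_bd))
                   paste0("; missing from design: ",
                          paste(missing_in_bd, collapse = ", ")) else "",
                 if (length(extra_in_bd))
                   paste0("; absent from matrix: ",
                          paste(extra_in_bd, collapse = ", ")) else "")
  idx <- match(sample_ids, bd$sample_ids)
  batch_design(as.character(bd$batch)[idx], sample_ids = sample_ids,
               covariates = if (is.null(bd$covariates)) NULL else
                 bd$covariates[idx, , drop = FALSE],
               ref_batch = bd$ref_batch)
}

# Numerical column rank with the tolerance used for confounding checks:
# singular values > 1e-8 * largest.
numeric_rank <- function(X) {
  if (ncol(X) == 0L) return(0L)
  d <- svd(X, nu = 0, nv = 0)$d
  sum(d > 1e-8 * d[1L])
}

#' Validate inputs and build the batch/covariate design matrix
#'
#' Checks a genes x samples matrix against a [batch_design()], reorders the
#' design to the matrix's column order, enforces the mode-specific input
#' contract, and returns the model matrix used by both correctors: one
#' indicator column per batch (no global intercept) followed by the
#' covariate columns.
#'
#' @param x genes x samples numeric matrix. In `"count"` mode entries must
#'   be non-negative integers with no missing values; in `"normal"` mode
#'   missing values are allowed (never infinite).
#' @param bd a [batch_design()].
#' @param mode `"normal"` (log-scale expression) or `"count"` (raw counts).
#' @param mean_only logical; in normal mode, permits singleton batches
#'   (their variance is never used by a mean-only correction).
#' @return the design matrix with attributes `batch_design` (the reordered
#'   [batch_design()]) and `n_batches`.
#' @export
validate_and_build_design <- function(x, bd, mode = c("normal", "count"),
                                      mean_only = FALSE) {
  mode <- match.arg(mode)
  if (!is.matrix(x) || !is.numeric(x))
    stop_batchEB("batchEB_value_error", "x must be a numeric matrix")
  if (ncol(x) < 2L)
    stop_batchEB("batchEB_shape_mismatch_error", "at least 2 samples required")
  if (anyDuplicated(rownames(x)))
    stop_batchEB("batchEB_shape_mismatch_error", "duplicated gene ids")
  if (anyDuplicated(colnames(x)))
    stop_batchEB("batchEB_shape_mismatch_error", "duplicated sample ids")
  if (!inherits(bd, "batch_design"))
    stop_batchEB("batchEB_value_error", "bd must be a batch_design")
  ids <- colnames(x)
  if (is.null(ids)) {
    if (ncol(x) != length(bd$sample_ids))
      stop_batchEB("batchEB_shape_mismatch_error",
                   "matrix has %d samples, design has %d",
                   ncol(x), length(bd$sample_ids))
    ids <- bd$sample_ids
  }
  bd <- reorder_design(bd, ids)

  if (mode == "count") {
    if (anyNA(x))
      stop_batchEB("batchEB_value_error", "count matrix contains missing values")
    bad <- which(x < 0 | x != floor(x) | !is.finite(x))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(x))
      stop_batchEB("batchEB_value_error",
                   "counts must be non-negative integers; first offender at gene %d, sample %d (value %g)",
                   rc[1L], rc[2L], x[bad[1L]])
    }
    if (any(bd$sizes < 2L))
      stop_batchEB("batchEB_single_sample_batch_error",
                   "count correction needs >= 2 samples per batch; offending: %s",
                   paste(names(bd$sizes)[bd$sizes < 2L], collapse = ", "))
  } else {
    if (any(is.infinite(x)))
      stop_batchEB("batchEB_value_error", "expression matrix contains Inf")
    if (any(bd$sizes < 2L) && !mean_only)
      stop_batchEB("batchEB_single_sample_batch_error",
                   "batch(es) with a single sample (%s) require mean_only = TRUE",
                   paste(names(bd$sizes)[bd$sizes < 2L], collapse = ", "))
  }

  ind <- stats::model.matrix(~ 0 + bd$batch)
  colnames(ind) <- paste0("batch_", bd$batches)
  X <- if (is.null(bd$covariates)) ind else cbind(ind, bd$covariates)
  rownames(X) <- bd$sample_ids
  if (numeric_rank(X) < ncol(X))
    stop_batchEB("batchEB_confounded_design_error",
                 "design is rank-deficient: a covariate is confounded with batch")
  attr(X, "batch_design") <- bd
  attr(X, "n_batches") <- length(bd$batches)
  X
}
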