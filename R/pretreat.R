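#' Standard normal variate (row-wise) transformation
#'
#' Transforms each fingerprint row to zero mean and unit variance using the
#' population standard deviation (divisor `n`, not `n - 1`). SNV is
#' idempotent on non-degenerate rows; a constant row has no variance to
#' standardize and raises a degenerate-row error naming the sample.
#'
#' @param fm a [fingerprint_matrix].
#' @return The transformed [fingerprint_matrix].
#' @export
snv_rows <- function(fm) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  if (ncol(fm$values) < 2L) hs_stop_invalid("rows need more than one feature")
  m <- rowMeans(fm$values)
  s <- sqrt(rowMeans((fm$values - m)^2))
  if (any(s == 0))
    hs_stop(sprintf("sample '%s' has zero variance; SNV is undefined",
                    fm$sample_ids[which(s == 0)[1L]]), "degenerate_row")
  fm$values <- (fm$values - m) / s
  fm
}

#' Savitzky-Golay derivative per wavelength block
#'
#' Applies a Savitzky-Golay derivative filter to each row, independently
#' within each wavelength channel's block of columns (never across block
#' boundaries). The derivative is taken with respect to retention time in
#' minutes, using the block's time spacing. Output dimensions are unchanged.
#'
#' @param fm a [fingerprint_matrix] from [unfold_cube()].
#' @param order derivative order, 1 or 2.
#' @param window odd filter window length (points), `> polyorder`.
#' @param polyorder polynomial order of the fit, `>= order`.
#' @return The differentiated [fingerprint_matrix].
#' @export
derivative_rows <- function(fm, order, window = 15L, polyorder = 2L) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  if (!order %in% 1:2) hs_stop_invalid("order must be 1 or 2")
  if (window %% 2L == 0L) hs_stop_invalid("window must be odd")
  if (!(window > polyorder && polyorder >= order))
    hs_stop_invalid("need window > polyorder >= order")

  w <- unique(fm$feature_map$wavelength)
  out <- fm$values
  for (wl in w) {
    cols <- which(fm$feature_map$wavelength == wl)
    if (window > length(cols))
      hs_stop_invalid(sprintf("window (%d) exceeds the %d-point block at %g nm",
                              window, length(cols), wl))
    dt <- diff(fm$feature_map$time[cols])
    ts <- dt[1L]
    for (i in seq_len(nrow(out)))
      out[i, cols] <- signal::sgolayfilt(fm$values[i, cols], p = polyorder,
                                         n = window, m = order, ts = ts)
  }
  fm$values <- out
  fm
}

#' Column autoscaling fitted on the training set
#'
#' Centers and scales columns using training-set statistics only (mean and
#' sample standard deviation). Zero-variance training columns are scaled by 1
#' and flagged. When `apply_to` is supplied it is transformed with the stored
#' training state; the test set never contributes statistics.
#'
#' @param train a [fingerprint_matrix] to fit (and, by default, transform).
#' @param apply_to optional [fingerprint_matrix] to transform with the fitted
#'   state instead of `train`.
#' @return A list with elements `matrix` (the transformed
#'   [fingerprint_matrix]) and `state` (class `scaling_state`: `column_means`,
#'   `column_sds`, `flagged` column indices, `fitted_on`).
#' @export
autoscale <- function(train, apply_to = NULL) {
  stopifnot(inherits(train, "fingerprint_matrix"))
  if (nrow(train$values) == 0L) hs_stop_invalid("training matrix is empty")
  mu <- colMeans(train$values)
  sdv <- apply(train$values, 2L, stats::sd)
  flagged <- which(sdv == 0)
  sdv[flagged] <- 1
  state <- structure(list(column_means = mu, column_sds = sdv,
                          flagged = flagged, fitted_on = nrow(train$values)),
                     class = "scaling_state")
  target <- if (is.null(apply_to)) train else apply_to
  list(matrix = apply_scaling(state, target), state = state)
}

#' Apply a fitted scaling state to a fingerprint matrix
#'
#' @param state a `scaling_state` from [autoscale()].
#' @param fm a [fingerprint_matrix] with the same feature count.
#' @return The transformed [fingerprint_matrix].
#' @export
apply_scaling <- function(state, fm) {
  stopifnot(inherits(state, "scaling_state"), inherits(fm, "fingerprint_matrix"))
  if (ncol(fm$values) != length(state$column_means))
    hs_stop_invalid("feature count does not match the fitted scaling state")
  fm$values <- sweep(sweep(fm$values, 2L, state$column_means), 2L,
                     state$column_sds, "/")
  fm
}
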