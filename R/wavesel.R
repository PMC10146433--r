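#' Correlation map between DAD wavelength channels
#'
#' Computes the Pearson correlation between the time traces of every pair of
#' wavelength channels of a single injection (the reference plant's record in
#' the screening workflow). Zero-variance channels are flagged and receive
#' coefficient 0 off the diagonal. The per-channel total signal (sum of
#' absorbance over time) is stored for use as the seeding criterion of
#' [select_orthogonal_wavelengths()].
#'
#' @param record a one-sample [dad_cube], or a numeric matrix
#'   (wavelengths x time points).
#' @param wavelengths wavelengths in nm when `record` is a bare matrix;
#'   ignored for a cube.
#' @return An object of class `channel_correlation_map` with elements
#'   `coefficients` (symmetric, unit diagonal), `wavelengths`,
#'   `channel_signal` and `zero_variance` (flagged wavelengths).
#' @export
channel_correlation_map <- function(record, wavelengths = NULL) {
  if (inherits(record, "dad_cube")) {
    if (dim(record$values)[1L] != 1L)
      hs_stop_invalid("record must hold exactly one sample")
    wavelengths <- record$wavelengths
    x <- record$values[1L, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)   # single channel
  } else {
    x <- as.matrix(record)
    if (is.null(wavelengths)) wavelengths <- seq_len(nrow(x))
  }
  if (ncol(x) < 2L)
    hs_stop_invalid("at least 2 time points per channel are required")
  sds <- apply(x, 1L, stats::sd)
  flat <- sds == 0
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[flat, ] <- 0; cc[, flat] <- 0
  diag(cc) <- 1
  structure(list(coefficients = cc,
                 wavelengths = as.numeric(wavelengths),
                 channel_signal = rowSums(x),
                 channel_range = apply(x, 1L, max) - apply(x, 1L, min),
                 zero_variance = as.numeric(wavelengths)[flat]),
            class = "channel_correlation_map")
}

#' @export
print.channel_correlation_map <- function(x, ...) {
  cat(sprintf("<channel_correlation_map> %d channels (%g-%g nm)",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  if (length(x$zero_variance))
    cat(sprintf("; %d zero-variance", length(x$zero_variance)))
  cat("\n")
  invisible(x)
}

#' Select a small set of mutually uncorrelated wavelengths
#'
#' Greedy deterministic selection of up to `max_k` channels whose pairwise
#' absolute correlations all fall below `cutoff`: the channel with maximal
#' total signal seeds the set, then the channel whose largest absolute
#' correlation to the current selection is smallest is added repeatedly,
#' stopping when that value reaches the cutoff or `max_k` channels are
#' chosen. Ties are broken toward the lower wavelength. Absolute correlation
#' is used because anti-correlated channels carry the same fingerprint
#' information as correlated ones. Zero-variance (flagged) channels are never
#' candidates, and neither are near-signal-free channels — a channel whose
#' dynamic range falls below `min_signal_frac` of the seed channel's sees
#' essentially detector noise, which correlates with nothing and would
#' otherwise always be picked as "orthogonal" despite carrying no
#' fingerprint (the selection is meant to stay inside the absorbing region
#' of the spectrum). If every other channel correlates with the seed above
#' the cutoff, the seed alone is returned with a warning.
#'
#' @param map a [channel_correlation_map].
#' @param cutoff pairwise absolute-correlation cutoff in (0, 1].
#' @param max_k maximum number of wavelengths to select.
#' @param min_signal_frac minimum channel dynamic range as a fraction of the
#'   seed channel's; 0 disables the floor (also disabled for maps lacking
#'   range information).
#' @return Numeric vector of selected wavelengths (nm) in selection order,
#'   with attribute `stop_reason` (`"cutoff"`, `"max_k"` or `"exhausted"`).
#' @export
select_orthogonal_wavelengths <- function(map, cutoff = 0.95, max_k = 5L,
                                          min_signal_frac = 0.05) {
  stopifnot(inherits(map, "channel_correlation_map"))
  if (!(cutoff > 0 && cutoff <= 1)) hs_stop_invalid("cutoff must lie in (0, 1]")
  if (!is_count(max_k)) hs_stop_invalid("max_k must be >= 1")

  w <- map$wavelengths
  r <- abs(map$coefficients)
  candidates <- setdiff(seq_along(w), match(map$zero_variance, w))
  if (!length(candidates)) hs_stop_invalid("all channels are zero-variance")
  if (min_signal_frac > 0 && !is.null(map$channel_range)) {
    sig <- map$channel_signal[candidates]
    seed0 <- candidates[sig == max(sig)][1L]
    keep <- map$channel_range[candidates] >=
      min_signal_frac * map$channel_range[seed0]
    candidates <- candidates[keep]
  }

  sig <- map$channel_signal[candidates]
  seed_pool <- candidates[sig == max(sig)]
  sel <- seed_pool[which.min(w[seed_pool])]       # tie: lower wavelength
  reason <- "exhausted"
  while (length(sel) < max_k) {
    rest <- setdiff(candidates, sel)
    if (!length(rest)) break
    worst <- apply(r[rest, sel, drop = FALSE], 1L, max)
    best <- min(worst)
    if (best >= cutoff) { reason <- "cutoff"; break }
    pool <- rest[worst == best]
    sel <- c(sel, pool[which.min(w[pool])])
  }
  if (length(sel) == max_k) reason <- "max_k"
  if (length(sel) == 1L && reason == "cutoff")
    hs_warn(sprintf("all channels correlate above %.2f with the seed (%g nm); returning the seed alone",
                    cutoff, w[sel]), "selection_degenerate")
  structure(w[sel], stop_reason = reason)
}
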