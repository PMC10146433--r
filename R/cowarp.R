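#' COW warping parameters
#'
#' @param segment_length segment length in time points, `>= 3`.
#' @param slack maximum stretch/compression of a segment in points,
#'   `1 <= slack < segment_length`.
#' @return An object of class `warp_spec`.
#' @export
warp_spec <- function(segment_length, slack) {
  if (!is_count(segment_length) || segment_length < 3L)
    hs_stop_invalid("segment_length must be an integer >= 3")
  if (!is_count(slack) || slack >= segment_length)
    hs_stop_invalid("slack must be an integer in [1, segment_length)")
  structure(list(segment_length = as.integer(segment_length),
                 slack = as.integer(slack)),
            class = "warp_spec")
}

#' @export
print.warp_spec <- function(x, ...) {
  cat(sprintf("<warp_spec> segment %d points, slack %d\n",
              x$segment_length, x$slack))
  invisible(x)
}

#' Choose the alignment target among a set of chromatograms
#'
#' Returns the index of the trace with the highest mean Pearson correlation to
#' all other traces; ties go to the lowest index. Zero-variance traces
#' correlate 0 with everything.
#'
#' @param traces numeric matrix, one chromatogram per row, or a list of
#'   equal-length numeric vectors.
#' @return Integer row index of the target profile.
#' @export
select_target_profile <- function(traces) {
  if (is.list(traces)) {
    len <- lengths(traces)
    if (length(unique(len)) != 1L)
      hs_stop_invalid("traces must all have the same length")
    traces <- do.call(rbind, traces)
  }
  traces <- as.matrix(traces)
  if (nrow(traces) < 2L) hs_stop_invalid("at least 2 traces are required")
  cc <- suppressWarnings(stats::cor(t(traces)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- NA
  means <- rowMeans(cc, na.rm = TRUE)
  unname(which.max(means))                    # ties: lowest index
}

#' Warp one chromatogram onto a target by correlation-optimized warping
#'
#' The target axis is divided into contiguous segments of
#' `spec$segment_length` points (the final segment absorbs the remainder;
#' first and last nodes are pinned). Each sample segment may be stretched or
#' compressed by at most `spec$slack` points, so boundary `b` can deviate from
#' its proportional position by up to `b * slack` cumulatively. Sample
#' segments are linearly interpolated onto their target segments, and dynamic
#' programming returns the node path that globally maximizes the sum of
#' per-segment Pearson correlations (zero-variance segments contribute 0).
#'
#' @param sample,target numeric chromatogram vectors, each at least twice the
#'   segment length.
#' @param spec a [warp_spec].
#' @return An object of class `cow_warp`: `node_positions` (1-based indices in
#'   the sample trace, one per segment boundary), `warped` (the sample on the
#'   target grid), `score` (summed per-segment correlation) and
#'   `segment_scores`.
#' @export
cow_warp <- function(sample, target, spec) {
  stopifnot(inherits(spec, "warp_spec"))
  sample <- as.numeric(sample); target <- as.numeric(target)
  if (length(sample) < 2L * spec$segment_length ||
      length(target) < 2L * spec$segment_length)
    hs_stop_invalid("both traces must have at least 2 x segment_length points")
  res <- tryCatch(
    cow_dp_cpp(sample, target, spec$segment_length, spec$slack),
    error = function(e) hs_stop_invalid(conditionMessage(e)))
  structure(list(node_positions = res$nodes + 1L,
                 warped = res$warped,
                 score = res$score,
                 segment_scores = res$segment_scores,
                 spec = spec),
            class = "cow_warp")
}

#' @export
print.cow_warp <- function(x, ...) {
  cat(sprintf("<cow_warp> %d segments, score %.4f (mean r %.4f)\n",
              length(x$segment_scores), x$score,
              x$score / length(x$segment_scores)))
  invisible(x)
}

#' Grid search for COW parameters
#'
#' Evaluates every admissible (segment length, slack) pair on the grid and
#' returns the one maximizing the mean Pearson correlation of the warped
#' traces to the target; ties go to the smaller segment length, then the
#' smaller slack. The default grid spans segment lengths 10-50 (step 5) and
#' slacks 1-5.
#'
#' @param traces numeric matrix of chromatograms (one per row).
#' @param target_index row index of the alignment target; `NULL` selects it
#'   via [select_target_profile()].
#' @param segment_grid candidate segment lengths.
#' @param slack_grid candidate slacks.
#' @return The winning [warp_spec], with attributes `score` (mean warped
#'   correlation) and `grid` (data.frame of all evaluated cells).
#' @export
optimize_warp_params <- function(traces, target_index = NULL,
                                 segment_grid = seq(10L, 50L, by = 5L),
                                 slack_grid = 1:5) {
  traces <- as.matrix(traces)
  if (!length(segment_grid) || !length(slack_grid))
    hs_stop_invalid("parameter grids must be non-empty")
  if (is.null(target_index)) target_index <- select_target_profile(traces)
  target <- traces[target_index, ]

  rows <- list(); best <- -Inf; best_spec <- NULL
  for (L in sort(segment_grid)) for (s in sort(slack_grid)) {
    if (s >= L || L < 3L || ncol(traces) < 2L * L) next
    spec <- warp_spec(L, s)
    ok <- TRUE
    rs <- vapply(seq_len(nrow(traces)), function(i) {
      wr <- tryCatch(cow_warp(traces[i, ], target, spec), error = function(e) NULL)
      if (is.null(wr)) { ok <<- FALSE; return(NA_real_) }
      r <- suppressWarnings(stats::cor(wr$warped, target))
      if (is.finite(r)) r else 0
    }, numeric(1L))
    if (!ok) next
    m <- mean(rs)
    rows[[length(rows) + 1L]] <- data.frame(segment_length = L, slack = s,
                                            mean_correlation = m)
    if (m > best + 1e-9) { best <- m; best_spec <- spec }   # ties keep earlier cell
  }
  if (is.null(best_spec))
    hs_stop_invalid("no admissible (segment, slack) pair for these traces")
  structure(best_spec, score = best, grid = do.call(rbind, rows))
}

#' Align every channel of a data cube by COW
#'
#' For each wavelength channel independently, the target trace is chosen by
#' [select_target_profile()] over that channel's sample traces and every
#' sample's trace is replaced by its [cow_warp()] result. Dimensions are
#' unchanged. The per-channel target indices/ids, target traces, spec and
#' scores are recorded in the `warp_log` attribute (and reused verbatim when
#' screening new samples).
#'
#' @param cube a (cropped) [dad_cube].
#' @param spec a [warp_spec] applied to every channel, or a list of one
#'   [warp_spec] per channel.
#' @return The aligned [dad_cube] with attribute `warp_log`.
#' @export
align_cube <- function(cube, spec) {
  stopifnot(inherits(cube, "dad_cube"))
  d <- dim(cube$values)
  n <- d[1L]; W <- d[2L]
  specs <- if (inherits(spec, "warp_spec")) rep(list(spec), W) else spec
  if (length(specs) != W)
    hs_stop_invalid("need one warp_spec, or one per wavelength channel")

  out <- cube$values
  log <- vector("list", W)
  for (j in seq_len(W)) {
    traces <- matrix(cube$values[, j, ], nrow = n)
    ti <- select_target_profile(traces)
    target <- traces[ti, ]
    scores <- numeric(n)
    for (i in seq_len(n)) {
      wr <- cow_warp(traces[i, ], target, specs[[j]])
      out[i, j, ] <- wr$warped
      scores[i] <- wr$score
    }
    log[[j]] <- list(wavelength = cube$wavelengths[j],
                     target_index = ti,
                     target_id = cube$sample_ids[ti],
                     target_trace = target,
                     spec = specs[[j]],
                     scores = scores)
  }
  res <- dad_cube(out, cube$sample_ids, cube$wavelengths, cube$times, cube$labels)
  attr(res, "warp_log") <- log
  res
}
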