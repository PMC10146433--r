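#' Three-way LC-DAD data cube
#'
#' Container for diode-array-detection data: an absorbance array indexed
#' (sample, wavelength, time) with labelled axes and optional integer class
#' labels per sample. Wavelengths are in nm, times in minutes; both axes must
#' be strictly increasing and the array must be free of missing values.
#'
#' @param values numeric array of absorbances, dim `c(n_samples, n_wavelengths,
#'   n_times)`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param wavelengths numeric vector of detection wavelengths (nm), strictly
#'   increasing.
#' @param times numeric vector of retention times (minutes), strictly
#'   increasing.
#' @param labels optional integer class codes, one per sample.
#' @return An object of class `dad_cube`.
#' @export
dad_cube <- function(values, sample_ids, wavelengths, times, labels = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    hs_stop_invalid("'values' must be a 3-way array (sample x wavelength x time)")
  d <- dim(values)
  if (length(sample_ids) != d[1L])
    hs_stop_invalid("length(sample_ids) does not match dim(values)[1]")
  if (length(wavelengths) != d[2L])
    hs_stop_invalid("length(wavelengths) does not match dim(values)[2]")
  if (length(times) != d[3L])
    hs_stop_invalid("length(times) does not match dim(values)[3]")
  if (anyDuplicated(sample_ids))
    hs_stop_invalid("sample_ids must be unique")
  if (d[2L] > 1L && any(diff(wavelengths) <= 0))
    hs_stop_invalid("wavelengths must be strictly increasing")
  if (d[3L] > 1L && any(diff(times) <= 0))
    hs_stop_invalid("times must be strictly increasing")
  if (anyNA(values) || !all(is.finite(values)))
    hs_stop_invalid("values must be finite and free of missing entries")
  if (!is.null(labels)) {
    if (length(labels) != d[1L])
      hs_stop_invalid("labels must have one entry per sample")
    labels <- as.integer(labels)
  }
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 wavelengths = as.numeric(wavelengths),
                 times = as.numeric(times),
                 labels = labels),
            class = "dad_cube")
}

#' @export
print.dad_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dad_cube> %d samples x %d wavelengths x %d time points\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  wavelengths: %g-%g nm; time: %g-%g min\n",
              min(x$wavelengths), max(x$wavelengths),
              min(x$times), max(x$times)))
  if (!is.null(x$labels))
    cat("  labels:", paste(sprintf("%d (n=%d)", as.integer(names(table(x$labels))),
                                   as.integer(table(x$labels))), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.dad_cube <- function(x) dim(x$values)

#' Unfolded fingerprint matrix
#'
#' Two-way (sample x feature) representation of a [dad_cube], columns ordered
#' wavelength-major: all time points of the first wavelength channel, then the
#' second, and so on. `feature_map` records the (wavelength, time) coordinate
#' behind each column.
#'
#' @param values numeric matrix (samples x features).
#' @param feature_map data.frame with columns `wavelength`, `time`, one row per
#'   matrix column.
#' @param sample_ids character vector of row identifiers.
#' @param labels optional integer class codes per row.
#' @return An object of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(values, feature_map, sample_ids, labels = NULL) {
  if (!is.matrix(values)) hs_stop_invalid("'values' must be a matrix")
  if (nrow(feature_map) != ncol(values))
    hs_stop_invalid("feature_map must have one row per column of values")
  if (length(sample_ids) != nrow(values))
    hs_stop_invalid("sample_ids must have one entry per row")
  if (!is.null(labels)) {
    if (length(labels) != nrow(values))
      hs_stop_invalid("labels must have one entry per row")
    labels <- as.integer(labels)
  }
  structure(list(values = values,
                 feature_map = feature_map,
                 sample_ids = as.character(sample_ids),
                 labels = labels),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d samples x %d features (%d wavelengths x %d time points)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$feature_map$wavelength)),
              length(unique(x$feature_map$time))))
  invisible(x)
}

#' @export
dim.fingerprint_matrix <- function(x) dim(x$values)

#' Crop a cube to a retention-time window
#'
#' Retains exactly the time points `t` with `start <= t <= end` (closed
#' interval, with a small numeric tolerance for grid arithmetic). The default
#' fingerprint window 1.5-6.6 min on a 0.05 s grid keeps 6121 points.
#'
#' @param cube a [dad_cube].
#' @param start,end window limits in minutes, `start < end`.
#' @param tol absolute tolerance (minutes) applied at the window edges.
#' @return A [dad_cube] restricted to the window; other axes unchanged.
#' @export
crop_time_window <- function(cube, start, end, tol = 1e-9) {
  stopifnot(inherits(cube, "dad_cube"))
  if (!is.numeric(start) || !is.numeric(end) || start >= end)
    hs_stop_invalid("'start' must be smaller than 'end'")
  keep <- cube$times >= start - tol & cube$times <= end + tol
  if (!any(keep))
    hs_stop(sprintf("time window [%g, %g] does not overlap the time axis [%g, %g]",
                    start, end, min(cube$times), max(cube$times)),
            "empty_selection")
  dad_cube(cube$values[, , keep, drop = FALSE],
           cube$sample_ids, cube$wavelengths, cube$times[keep], cube$labels)
}

#' Subset a cube to a set of wavelength channels
#'
#' @param cube a [dad_cube].
#' @param wavelengths wavelengths (nm) to retain; each must be present on the
#'   cube's wavelength axis (within `tol`).
#' @param tol matching tolerance in nm.
#' @return A [dad_cube] with the selected channels, in increasing order.
#' @export
subset_wavelengths <- function(cube, wavelengths, tol = 1e-9) {
  stopifnot(inherits(cube, "dad_cube"))
  wavelengths <- sort(unique(as.numeric(wavelengths)))
  idx <- vapply(wavelengths, function(w) {
    j <- which(abs(cube$wavelengths - w) <= tol)
    if (length(j) != 1L)
      hs_stop_invalid(sprintf("wavelength %g nm is not on the cube's wavelength axis", w))
    j
  }, integer(1L))
  dad_cube(cube$values[, idx, , drop = FALSE],
           cube$sample_ids, cube$wavelengths[idx], cube$times, cube$labels)
}

#' Unfold a data cube into a fingerprint matrix
#'
#' Row `i` of the result is sample `i`'s channels concatenated wavelength-major
#' (all time points of the first wavelength, then the second, ...), so that
#' `matrix[i, (j - 1) * T + k] == cube[i, j, k]` for `T` time points.
#'
#' @param cube a [dad_cube].
#' @return A [fingerprint_matrix] with `n_wavelengths * n_times` columns.
#' @export
unfold_cube <- function(cube) {
  stopifnot(inherits(cube, "dad_cube"))
  d <- dim(cube$values)
  if (any(d == 0L)) hs_stop_invalid("cannot unfold an empty cube")
  n <- d[1L]; W <- d[2L]; T <- d[3L]
  # aperm to (sample, time, wavelength) then flatten: column index runs time
  # fastest within wavelength, wavelength-major overall.
  m <- matrix(aperm(cube$values, c(1L, 3L, 2L)), nrow = n, ncol = W * T)
  fmap <- data.frame(wavelength = rep(cube$wavelengths, each = T),
                     time = rep(cube$times, times = W))
  fingerprint_matrix(m, fmap, cube$sample_ids, cube$labels)
}

#' Refold a fingerprint matrix back into a data cube
#'
#' Inverse of [unfold_cube()]; requires the feature map to describe a complete
#' wavelength x time grid in wavelength-major order.
#'
#' @param fm a [fingerprint_matrix] produced by [unfold_cube()].
#' @return The [dad_cube] whose unfolding is `fm`.
#' @export
refold_matrix <- function(fm) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  w <- unique(fm$feature_map$wavelength)
  t <- unique(fm$feature_map$time)
  W <- length(w); T <- length(t); n <- nrow(fm$values)
  if (ncol(fm$values) != W * T ||
      !identical(fm$feature_map$wavelength, rep(w, each = T)) ||
      !isTRUE(all.equal(fm$feature_map$time, rep(t, times = W))))
    hs_stop_invalid("feature_map is not a wavelength-major grid; cannot refold")
  arr <- aperm(array(fm$values, dim = c(n, T, W)), c(1L, 3L, 2L))
  dad_cube(arr, fm$sample_ids, w, t, fm$labels)
}

# ---- long-format CSV interchange ------------------------------------------

#' Write a data cube to long-format CSV
#'
#' One row per cell with mandatory header
#' `sample_id,label,wavelength_nm,time_min,absorbance_au`, rows sorted by
#' (sample_id, wavelength, time). This is the interchange format used by the
#' command-line stages. Reading a written file restores values, axes, ids and
#' labels exactly; note that samples are stored in lexicographic id order, so
#' the sample ordering round-trips whenever ids already sort naturally (all
#' ids produced by [simulate_study()] do).
#'
#' @param cube a [dad_cube].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "dad_cube"))
  d <- dim(cube$values)
  n <- d[1L]; W <- d[2L]; T <- d[3L]
  labs <- if (is.null(cube$labels)) rep(NA_integer_, n) else cube$labels
  dt <- data.table::data.table(
    sample_id = rep(cube$sample_ids, each = W * T),
    label = rep(labs, each = W * T),
    wavelength_nm = rep(rep(cube$wavelengths, each = T), times = n),
    time_min = rep(cube$times, times = W * n),
    absorbance_au = as.vector(aperm(cube$values, c(3L, 2L, 1L))))
  data.table::setorder(dt, sample_id, wavelength_nm, time_min)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a data cube from long-format CSV
#'
#' Validates the dialect written by [write_cube()]: every sample must carry
#' the complete wavelength x time grid exactly once; axes must be strictly
#' increasing. Violations raise a format error naming the offending sample or
#' row.
#'
#' @param path input file path.
#' @return A [dad_cube]; samples appear in file order.
#' @export
read_cube <- function(path) {
  dt <- data.table::fread(path, colClasses = list(
    character = "sample_id", numeric = c("wavelength_nm", "time_min", "absorbance_au")))
  req <- c("sample_id", "label", "wavelength_nm", "time_min", "absorbance_au")
  if (!all(req %in% names(dt)))
    hs_stop(sprintf("missing required columns: %s",
                    paste(setdiff(req, names(dt)), collapse = ", ")), "format_error")
  if (nrow(dt) == 0L) hs_stop("file contains no data rows", "format_error")
  if (anyNA(dt$absorbance_au) || anyNA(dt$wavelength_nm) || anyNA(dt$time_min))
    hs_stop(sprintf("missing value first seen at data row %d",
                    which(is.na(dt$absorbance_au) | is.na(dt$wavelength_nm) |
                          is.na(dt$time_min))[1L]), "format_error")
  dup <- duplicated(dt[, c("sample_id", "wavelength_nm", "time_min")])
  if (any(dup))
    hs_stop(sprintf("duplicate (sample, wavelength, time) key at data row %d",
                    which(dup)[1L]), "format_error")

  ids <- unique(dt$sample_id)                    # file order
  w <- sort(unique(dt$wavelength_nm))
  t <- sort(unique(dt$time_min))
  W <- length(w); T <- length(t)
  cnt <- table(dt$sample_id)
  bad <- names(cnt)[cnt != W * T]
  if (length(bad))
    hs_stop(sprintf("sample '%s' has %d of the %d grid cells (%d wavelengths x %d time points)",
                    bad[1L], as.integer(cnt[bad[1L]]), W * T, W, T), "format_error")

  # labels: constant per sample, all-NA means unlabelled
  lab_tab <- unique(dt[, c("sample_id", "label")])
  if (anyDuplicated(lab_tab$sample_id))
    hs_stop(sprintf("sample '%s' carries more than one label",
                    lab_tab$sample_id[duplicated(lab_tab$sample_id)][1L]), "format_error")
  labs <- lab_tab$label[match(ids, lab_tab$sample_id)]
  if (all(is.na(labs))) labs <- NULL
  else if (anyNA(labs))
    hs_stop("labels must be present for all samples or none", "format_error")

  o <- order(match(dt$sample_id, ids), dt$wavelength_nm, dt$time_min)
  arr <- aperm(array(dt$absorbance_au[o], dim = c(T, W, length(ids))), c(3L, 2L, 1L))
  dad_cube(arr, ids, w, t, labs)
}
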