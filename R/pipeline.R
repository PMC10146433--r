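#' Train screening models on simulated studies
#'
#' End-to-end training workflow, executed in fixed stage order per model:
#' wavelength selection (correlation map of the pure reference record on the
#' full wavelength grid) -> fingerprint-window crop -> per-channel COW
#' alignment -> unfolding -> optional pretreatment -> duplex split ->
#' stratified cross-validation for the factor count -> PLS-DA fit -> external
#' test-set validation. Binary models are trained one per requested plant on
#' that plant's own wavelength set; the multiclass model pools every plant's
#' trituration block and uses the wavelength set of `multiclass_wavelengths_of`.
#'
#' Study cubes are simulated on the selected wavelength grid (the full
#' 200-400 nm cube is only ever generated for the single reference record, as
#' in the laboratory workflow where only the reference standard's whole cube
#' is inspected).
#'
#' @param library profile list from [build_plant_library()].
#' @param config a [sim_config]; its seed drives every stochastic stage.
#' @param design `"binary"`, `"multiclass"` or `"both"`.
#' @param plants plant names to train binary models for (default: all plants
#'   in the library).
#' @param window fingerprint retention window in minutes.
#' @param cutoff,max_k wavelength-selection parameters.
#' @param spec a [warp_spec] used for every channel; set `optimize = TRUE` to
#'   grid-search (segment 10-50, slack 1-5) per model instead.
#' @param optimize logical; grid-search COW parameters.
#' @param test_fraction duplex validation fraction.
#' @param folds,max_factors cross-validation settings.
#' @param snv,derivative,autoscale optional pretreatments applied between
#'   unfolding and splitting (`derivative` is `NULL` or
#'   `list(order, window, polyorder)`); all off by default.
#' @param multiclass_wavelengths_of plant whose wavelength set the multiclass
#'   model uses (default: first trained plant).
#' @return An object of class `screening_bundle`: per-model entries holding
#'   the selected wavelengths, warp log (targets, specs, scores), duplex
#'   split, cross-validation table, fitted model, scaling state (if any) and
#'   train/test [evaluate()] reports.
#' @export
train_screening_models <- function(library, config = sim_config(),
                                   design = c("binary", "multiclass", "both"),
                                   plants = NULL,
                                   window = c(1.5, 6.6),
                                   cutoff = 0.95, max_k = 5L,
                                   spec = warp_spec(35L, 3L), optimize = FALSE,
                                   test_fraction = 0.25,
                                   folds = 10L, max_factors = 30L,
                                   snv = FALSE, derivative = NULL,
                                   autoscale = FALSE,
                                   multiclass_wavelengths_of = NULL) {
  design <- match.arg(design)
  types <- vapply(library, `[[`, character(1L), "type")
  all_plants <- names(library)[types == "plant"]
  if (is.null(plants)) plants <- all_plants
  if (!all(plants %in% all_plants))
    hs_stop_invalid("unknown plant name in 'plants'")

  pretreat_cfg <- list(snv = snv, derivative = derivative, autoscale = autoscale)
  bundle <- list(binary = list(), multiclass = NULL,
                 window = window, config = config, pretreat = pretreat_cfg)

  wl_sets <- lapply(seq_along(plants), function(i) {
    select_plant_wavelengths(library[[plants[i]]], config,
                             seed = config$seed + i * 1009L,
                             window = window, cutoff = cutoff, max_k = max_k)
  })
  names(wl_sets) <- plants

  if (design %in% c("binary", "both")) {
    for (i in seq_along(plants)) {
      p <- plants[i]
      study_cfg <- config
      study_cfg$wavelength_grid <- sort(wl_sets[[p]])
      study_cfg$seed <- config$seed + i * 7919L
      study <- simulate_study(library, p, "binary", study_cfg)
      bundle$binary[[p]] <- fit_one_model(study, window, spec, optimize,
                                          test_fraction, folds, max_factors,
                                          "binary", pretreat_cfg,
                                          cv_seed = study_cfg$seed,
                                          wavelengths = sort(wl_sets[[p]]))
    }
  }
  if (design %in% c("multiclass", "both")) {
    wp <- if (is.null(multiclass_wavelengths_of)) plants[1L] else multiclass_wavelengths_of
    study_cfg <- config
    study_cfg$wavelength_grid <- sort(wl_sets[[wp]])
    study_cfg$seed <- config$seed + 104729L
    study <- simulate_study(library, NULL, "multiclass", study_cfg)
    bundle$multiclass <- fit_one_model(study, window, spec, optimize,
                                       test_fraction, folds, max_factors,
                                       "multiclass", pretreat_cfg,
                                       cv_seed = study_cfg$seed,
                                       wavelengths = sort(wl_sets[[wp]]))
    bundle$multiclass$wavelengths_of <- wp
  }
  structure(bundle, class = "screening_bundle")
}

# wavelength selection for one plant from its pure reference record
select_plant_wavelengths <- function(profile, config, seed, window,
                                     cutoff = 0.95, max_k = 5L) {
  ref <- simulate_dad_record(list(profile), 1, config, jitter = 0, seed = seed,
                             sample_id = paste0("ref_", profile$name))
  map <- channel_correlation_map(ref)
  as.numeric(select_orthogonal_wavelengths(map, cutoff, max_k))
}

# shared per-model stages: crop -> align -> unfold -> pretreat -> split ->
# CV -> fit -> external validation
fit_one_model <- function(study, window, spec, optimize, test_fraction,
                          folds, max_factors, coding, pretreat_cfg, cv_seed,
                          wavelengths) {
  cropped <- crop_time_window(study, window[1L], window[2L])
  if (optimize) {
    traces <- matrix(cropped$values[, 1L, ], nrow = dim(cropped$values)[1L])
    spec <- optimize_warp_params(traces)
    attr(spec, "grid") <- NULL
  }
  aligned <- align_cube(cropped, spec)
  fm <- unfold_cube(aligned)
  fm <- apply_pretreat(fm, pretreat_cfg)

  sp <- duplex_split(fm, test_fraction)
  tr <- fm$values[sp$calibration_idx, , drop = FALSE]
  te <- fm$values[sp$validation_idx, , drop = FALSE]
  tr_lab <- fm$labels[sp$calibration_idx]
  te_lab <- fm$labels[sp$validation_idx]

  scale_state <- NULL
  if (isTRUE(pretreat_cfg$autoscale)) {
    tr_fm <- fingerprint_matrix(tr, fm$feature_map, sp$calibration_ids, tr_lab)
    te_fm <- fingerprint_matrix(te, fm$feature_map, sp$validation_ids, te_lab)
    fitted <- autoscale(tr_fm)
    tr <- fitted$matrix$values
    scale_state <- fitted$state
    te <- apply_scaling(scale_state, te_fm)$values
  }

  mf <- min(max_factors, nrow(tr) - ceiling(nrow(tr) / folds) - 1L, ncol(tr))
  cv <- cross_validate_lv(tr, tr_lab, coding, folds, mf, seed = cv_seed)
  model <- fit_plsda(tr, tr_lab, cv$n_factors, coding)
  train_report <- evaluate(tr_lab, predict_classes(model, tr), sp$calibration_ids)
  test_report <- evaluate(te_lab, predict_classes(model, te), sp$validation_ids)

  list(wavelengths = wavelengths,
       warp = attr(aligned, "warp_log"),
       spec = spec,
       split = sp,
       cv = cv,
       model = model,
       scale_state = scale_state,
       train_report = train_report,
       test_report = test_report)
}

# pretreatments applied to the whole unfolded matrix (autoscale is handled
# split-aware in fit_one_model / screen_samples)
apply_pretreat <- function(fm, cfg) {
  if (!is.null(cfg$derivative))
    fm <- derivative_rows(fm, cfg$derivative$order,
                          cfg$derivative$window %||% 15L,
                          cfg$derivative$polyorder %||% 2L)
  if (isTRUE(cfg$snv)) fm <- snv_rows(fm)
  fm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.screening_bundle <- function(x, ...) {
  cat("<screening_bundle>\n")
  for (p in names(x$binary))
    cat(sprintf("  binary %-10s wavelengths %s | %d LVs | test ccr %d%%\n", p,
                paste(x$binary[[p]]$wavelengths, collapse = "/"),
                x$binary[[p]]$model$n_factors,
                x$binary[[p]]$test_report$ccr_display))
  if (!is.null(x$multiclass))
    cat(sprintf("  multiclass (wavelengths of %s) | %d LVs | test ccr %d%%\n",
                x$multiclass$wavelengths_of, x$multiclass$model$n_factors,
                x$multiclass$test_report$ccr_display))
  invisible(x)
}

#' Screen new samples with a trained bundle
#'
#' New injections are processed with the train-time state only: cropped to
#' the bundle's fingerprint window, warped channel by channel against the
#' stored COW targets with the stored specs, unfolded, pretreated with the
#' stored scaling state, and classified by every binary model and (when
#' present) the multiclass model. Binary verdicts are independent, so a
#' sample may screen positive for several plants; the multiclass model
#' assigns exactly one class.
#'
#' @param bundle a [train_screening_models()] result.
#' @param samples a [dad_cube] of new injections sharing the wavelength grids
#'   of the bundle's models (extra channels are allowed and subset away).
#' @return A data.frame (class `screening_report`) with one row per sample:
#'   `sample_id`, one logical verdict column per binary model
#'   (`positive_<plant>`) with its predicted code (`code_<plant>`; codes
#'   below the 1.5 midpoint read positive), and `multiclass_class` when a
#'   multiclass model is present. Model provenance is attached as attribute
#'   `provenance`.
#' @export
screen_samples <- function(bundle, samples) {
  stopifnot(inherits(bundle, "screening_bundle"), inherits(samples, "dad_cube"))
  out <- data.frame(sample_id = samples$sample_ids, stringsAsFactors = FALSE)

  predict_with <- function(entry, coding) {
    missing <- setdiff(entry$wavelengths, samples$wavelengths)
    if (length(missing))
      hs_stop_invalid(sprintf("samples lack model wavelengths: %s nm",
                              paste(missing, collapse = ", ")))
    sub <- subset_wavelengths(samples, entry$wavelengths)
    sub <- crop_time_window(sub, bundle$window[1L], bundle$window[2L])
    if (length(sub$times) != length(entry$warp[[1L]]$target_trace))
      hs_stop_invalid("sample time grid does not match the training grid")
    d <- dim(sub$values)
    for (j in seq_len(d[2L])) {
      lw <- entry$warp[[j]]
      for (i in seq_len(d[1L]))
        sub$values[i, j, ] <- cow_warp(sub$values[i, j, ], lw$target_trace,
                                       lw$spec)$warped
    }
    fm <- unfold_cube(sub)
    fm <- apply_pretreat(fm, bundle$pretreat)
    if (!is.null(entry$scale_state)) fm <- apply_scaling(entry$scale_state, fm)
    list(classes = predict_classes(entry$model, fm),
         codes = predict_codes(entry$model, fm))
  }

  for (p in names(bundle$binary)) {
    pr <- predict_with(bundle$binary[[p]], "binary")
    out[[paste0("positive_", p)]] <- pr$classes == 1L
    out[[paste0("code_", p)]] <- pr$codes[, 1L]
  }
  if (!is.null(bundle$multiclass))
    out$multiclass_class <- predict_with(bundle$multiclass, "multiclass")$classes

  attr(out, "provenance") <- list(
    binary_models = names(bundle$binary),
    wavelength_sets = lapply(bundle$binary, `[[`, "wavelengths"),
    window = bundle$window)
  class(out) <- c("screening_report", "data.frame")
  out
}

#' Compare multiwavelength and single-wavelength (254 nm) screening
#'
#' Trains twin binary models for one plant on (a) its selected orthogonal
#' wavelength set and (b) the classical 254 nm channel alone, from the same
#' simulated study, the same COW alignment, and the same duplex assignment
#' (computed on the multiwavelength unfolded matrix, so both arms share the
#' identical calibration/validation partition), and reports both external
#' test ccr%.
#'
#' @param library profile list from [build_plant_library()].
#' @param plant plant name.
#' @param config a [sim_config] whose wavelength grid includes 254 nm.
#' @inheritParams train_screening_models
#' @return A data.frame with one row per arm: `strategy`, `n_wavelengths`,
#'   `n_features`, `n_factors`, `test_ccr`.
#' @export
compare_channel_strategies <- function(library, plant, config = sim_config(),
                                       window = c(1.5, 6.6),
                                       cutoff = 0.95, max_k = 5L,
                                       spec = warp_spec(35L, 3L),
                                       test_fraction = 0.25,
                                       folds = 10L, max_factors = 30L) {
  if (!any(abs(config$wavelength_grid - 254) < 1e-9))
    hs_stop_invalid("wavelength grid must include 254 nm")
  wl <- select_plant_wavelengths(library[[plant]], config,
                                 seed = config$seed + 1009L, window = window,
                                 cutoff = cutoff, max_k = max_k)
  grid <- sort(unique(c(wl, 254)))
  study_cfg <- config
  study_cfg$wavelength_grid <- grid
  study_cfg$seed <- config$seed + 7919L
  study <- simulate_study(library, plant, "binary", study_cfg)
  cropped <- crop_time_window(study, window[1L], window[2L])
  aligned <- align_cube(cropped, spec)

  arm <- function(wavelengths, split = NULL) {
    sub <- subset_wavelengths(aligned, wavelengths)
    fm <- unfold_cube(sub)
    sp <- if (is.null(split)) duplex_split(fm, test_fraction) else split
    tr <- fm$values[sp$calibration_idx, , drop = FALSE]
    te <- fm$values[sp$validation_idx, , drop = FALSE]
    mf <- min(max_factors, nrow(tr) - ceiling(nrow(tr) / folds) - 1L, ncol(tr))
    cv <- cross_validate_lv(tr, fm$labels[sp$calibration_idx], "binary",
                            folds, mf, seed = study_cfg$seed)
    model <- fit_plsda(tr, fm$labels[sp$calibration_idx], cv$n_factors, "binary")
    rep <- evaluate(fm$labels[sp$validation_idx], predict_classes(model, te))
    list(split = sp, n_features = ncol(fm$values), n_factors = model$n_factors,
         test_ccr = rep$ccr)
  }

  multi <- arm(sort(wl))
  single <- arm(254, split = multi$split)
  data.frame(strategy = c("multiwavelength", "254nm"),
             n_wavelengths = c(length(wl), 1L),
             n_features = c(multi$n_features, single$n_features),
             n_factors = c(multi$n_factors, single$n_factors),
             test_ccr = c(multi$test_ccr, single$test_ccr))
}
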