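#' Simulation configuration for synthetic LC-DAD studies
#'
#' Holds the study design and instrument model for the synthetic generator:
#' number of blank botanical matrices, spike ratios of the reference plant in
#' the triturations, wavelength and time grids, and the disturbance model
#' (retention-time jitter, detector noise, baseline drift). Defaults reproduce
#' the spiked-trituration design: 11 matrices (one a lactose stand-in) x 5
#' spike ratios 1/20, 1/15, 1/10, 1/5, 1/2 (i.e. the reference plant makes up
#' 5-50% of the mixture mass), DAD grid 200-400 nm at 1 nm, 8 min runs sampled
#' every 0.05 s.
#'
#' @param n_matrices number of blank botanical matrices.
#' @param spike_ratios mass fractions of the reference plant in the
#'   triturations, each in (0, 1).
#' @param wavelength_grid detection wavelengths in nm, strictly increasing.
#' @param time_grid retention-time grid in minutes, strictly increasing.
#' @param rt_jitter_sd standard deviation (minutes) of the per-injection
#'   global retention shift.
#' @param noise_sd standard deviation (AU) of i.i.d. Gaussian detector noise.
#' @param baseline_drift_amp amplitude (AU) of the slow quadratic baseline
#'   drift.
#' @param seed integer seed; a fixed seed makes every generated cube
#'   bit-identical across runs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_matrices = 11L,
                       spike_ratios = c(1/20, 1/15, 1/10, 1/5, 1/2),
                       wavelength_grid = seq(200, 400, by = 1),
                       time_grid = (0:9600) / 1200,
                       rt_jitter_sd = 0.02,
                       noise_sd = 0.002,
                       baseline_drift_amp = 0.01,
                       seed = 1L) {
  if (!is_count(n_matrices)) hs_stop_invalid("n_matrices must be a positive count")
  if (!length(spike_ratios) || any(spike_ratios <= 0) || any(spike_ratios >= 1))
    hs_stop_invalid("spike_ratios must all lie in (0, 1)")
  if (length(wavelength_grid) < 1L || any(diff(wavelength_grid) <= 0))
    hs_stop_invalid("wavelength_grid must be strictly increasing")
  if (length(time_grid) < 2L || any(diff(time_grid) <= 0))
    hs_stop_invalid("time_grid must be strictly increasing")
  if (rt_jitter_sd < 0 || noise_sd < 0 || baseline_drift_amp < 0)
    hs_stop_invalid("disturbance magnitudes must be non-negative")
  if (!is_count(seed, positive = FALSE)) hs_stop_invalid("seed must be an integer")
  structure(list(n_matrices = as.integer(n_matrices),
                 spike_ratios = as.numeric(spike_ratios),
                 wavelength_grid = as.numeric(wavelength_grid),
                 time_grid = as.numeric(time_grid),
                 rt_jitter_sd = rt_jitter_sd,
                 noise_sd = noise_sd,
                 baseline_drift_amp = baseline_drift_amp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Chromatographic peak of one compound
#'
#' A Gaussian peak along retention time with a UV spectrum modelled as a
#' non-negative sum of Gaussians in wavelength. The peak's contribution to
#' absorbance is `amplitude * exp(-(t - rt)^2 / (2 * sigma_t^2)) * s(lambda)`
#' with `s` the spectral factor.
#'
#' @param retention_center peak apex position, minutes.
#' @param retention_width Gaussian sigma along time, minutes, `> 0`.
#' @param amplitude peak height at the spectral maximum, AU, `>= 0`.
#' @param spectrum_centers Gaussian centers of the UV spectrum, nm.
#' @param spectrum_widths Gaussian sigmas of the UV spectrum, nm, all `> 0`.
#' @param spectrum_weights non-negative weights of the spectral Gaussians.
#' @return An object of class `compound_peak`.
#' @export
compound_peak <- function(retention_center, retention_width, amplitude,
                          spectrum_centers, spectrum_widths, spectrum_weights) {
  if (retention_width <= 0) hs_stop_invalid("retention_width must be > 0")
  if (amplitude < 0) hs_stop_invalid("amplitude must be >= 0")
  if (any(spectrum_widths <= 0)) hs_stop_invalid("spectrum_widths must all be > 0")
  if (length(spectrum_centers) != length(spectrum_widths) ||
      length(spectrum_centers) != length(spectrum_weights))
    hs_stop_invalid("spectrum fields must have equal length")
  structure(list(retention_center = retention_center,
                 retention_width = retention_width,
                 amplitude = amplitude,
                 spectrum_centers = as.numeric(spectrum_centers),
                 spectrum_widths = as.numeric(spectrum_widths),
                 spectrum_weights = as.numeric(spectrum_weights)),
            class = "compound_peak")
}

#' Constituent profile of a plant or blank matrix
#'
#' @param name unique identifier within a library.
#' @param peaks list of [compound_peak] objects, at least one.
#' @param type `"plant"` (reference plant) or `"matrix"` (blank botanical
#'   matrix / diluent).
#' @return An object of class `plant_profile`.
#' @export
plant_profile <- function(name, peaks, type = c("plant", "matrix")) {
  type <- match.arg(type)
  if (!length(peaks)) hs_stop_invalid("a profile needs at least one peak")
  if (!all(vapply(peaks, inherits, logical(1L), "compound_peak")))
    hs_stop_invalid("peaks must be compound_peak objects")
  structure(list(name = as.character(name), peaks = peaks, type = type),
            class = "plant_profile")
}

# spectral factor of one peak on a wavelength grid
peak_spectrum <- function(peak, wavelengths) {
  s <- numeric(length(wavelengths))
  for (g in seq_along(peak$spectrum_centers))
    s <- s + peak$spectrum_weights[g] *
      exp(-(wavelengths - peak$spectrum_centers[g])^2 /
            (2 * peak$spectrum_widths[g]^2))
  s
}

#' Generate a deterministic library of plant and matrix profiles
#'
#' Builds `n_plants` reference-plant profiles and `n_matrices` blank-matrix
#' profiles. Botanical supplements share much of their chemistry, so all
#' matrix profiles draw from a common pool of 12 ubiquitous constituents
#' (each matrix carries each common compound with probability 0.7, at a
#' matrix-specific amplitude factor of 0.5-1.5); plants carry common
#' compounds with probability 0.3. On top of the shared chemistry every
#' matrix has 2 and every plant 4 distinctive peaks. A matrix's second
#' distinctive peak co-elutes with a randomly chosen plant non-signature
#' peak with probability 0.6 (same retention slot, independent spectrum) —
#' the single-wavelength ambiguity that motivates multiwavelength
#' fingerprints in the first place.
#'
#' Separability is guaranteed by construction: distinctive retention centers
#' sit on a global slot grid of 0.10 min spacing assigned without
#' replacement, with at most 0.015 min of placement jitter and peak sigmas
#' of 0.015-0.024 min, so any plant's distinctive peaks are farther than
#' twice the largest peak width from every peak of every matrix. Each plant's
#' signature peak lies inside the 1.5-6.6 min fingerprint window and its
#' spectral maximum is at least `180 / (n_profiles - 1)` nm (about 13 nm at
#' the default library size) from every other profile's signature maximum.
#' The first matrix is a lactose stand-in with near-zero UV absorbance and
#' no common constituents.
#'
#' @param n_plants number of reference plants, `>= 1`.
#' @param n_matrices number of blank matrices, `>= 1`.
#' @param seed integer seed; fixed seed gives an identical library.
#' @return A list of `n_plants + n_matrices` [plant_profile] objects (plants
#'   first), named by profile.
#' @export
build_plant_library <- function(n_plants, n_matrices, seed = 1L) {
  if (!is_count(n_plants) || !is_count(n_matrices))
    hs_stop_invalid("n_plants and n_matrices must be positive counts")
  set.seed(as.integer(seed))

  n_prof <- n_plants + n_matrices
  n_common <- 12L
  n_distinct <- c(rep(4L, n_plants), rep(2L, n_matrices))
  slot_centers <- seq(0.35, 7.65, by = 0.10)
  if (n_common + sum(n_distinct) > length(slot_centers))
    hs_stop_invalid("library too large for the retention window (not enough peak slots)")

  in_window <- which(slot_centers >= 1.6 & slot_centers <= 6.5)
  # signature slots: one in-window slot per profile
  sig_slots <- sample(in_window, n_prof)
  free <- sample(setdiff(seq_along(slot_centers), sig_slots))
  common_slots <- free[seq_len(n_common)]
  free <- free[-seq_len(n_common)]

  # the shared constituent pool: fixed retention and spectrum, per-profile amplitude
  common_pool <- lapply(seq_len(n_common), function(g) list(
    rt = slot_centers[common_slots[g]] + runif(1, -0.015, 0.015),
    width = runif(1, 0.015, 0.024),
    amp = runif(1, 0.2, 0.8),
    centers = runif(sample(1:2, 1L), 210, 390),
    widths = NULL))
  common_pool <- lapply(common_pool, function(cp) {
    cp$widths <- runif(length(cp$centers), 8, 15)
    cp$weights <- c(1, runif(length(cp$centers) - 1L, 0.2, 0.5))
    cp
  })

  # signature spectral maxima: evenly spaced, shuffled; documents the minimum
  # spectral distance 180 / (n_prof - 1) nm between signature peaks
  base_lambda <- if (n_prof == 1L) 300 else sample(seq(210, 390, length.out = n_prof))

  lib <- vector("list", n_prof)
  k <- 0L
  plant_nonsig_slots <- integer(0)
  for (i in seq_len(n_prof)) {
    is_plant <- i <= n_plants
    name <- if (is_plant) sprintf("plant%02d", i) else
      sprintf("matrix%02d", i - n_plants)
    lactose <- !is_plant && i == n_plants + 1L       # near-flat UV stand-in
    slots <- c(sig_slots[i], free[k + seq_len(n_distinct[i] - 1L)])
    k <- k + n_distinct[i] - 1L
    if (is_plant) {
      plant_nonsig_slots <- c(plant_nonsig_slots, slots[-1L])
    } else if (length(plant_nonsig_slots) && length(slots) > 1L) {
      # co-elution: non-signature matrix peaks land on a plant peak's slot
      co <- which(runif(length(slots) - 1L) < 0.6) + 1L
      slots[co] <- sample(plant_nonsig_slots, length(co), replace = TRUE)
    }
    peaks <- vector("list", length(slots))
    for (j in seq_along(slots)) {
      rt <- slot_centers[slots[j]] + runif(1, -0.015, 0.015)
      sig <- j == 1L
      amp <- if (lactose) 0.002 else runif(1, 0.3, 1.0)
      lam <- if (sig) base_lambda[i] else runif(1, 210, 390)
      n_g <- if (sig) 2L else sample(1:2, 1L)
      centers <- c(lam, runif(n_g - 1L, 210, 390))
      peaks[[j]] <- compound_peak(
        retention_center = rt,
        retention_width = runif(1, 0.015, 0.024),
        amplitude = amp,
        spectrum_centers = centers,
        spectrum_widths = runif(n_g, 8, 15),
        spectrum_weights = c(1, runif(n_g - 1L, 0.2, 0.5)))
    }
    if (!lactose) {
      p_carry <- if (is_plant) 0.3 else 0.7
      carry <- runif(n_common) < p_carry
      for (g in which(carry)) {
        cp <- common_pool[[g]]
        peaks[[length(peaks) + 1L]] <- compound_peak(
          retention_center = cp$rt,
          retention_width = cp$width,
          amplitude = cp$amp * runif(1, 0.5, 1.5),
          spectrum_centers = cp$centers,
          spectrum_widths = cp$widths,
          spectrum_weights = cp$weights)
      }
    }
    lib[[i]] <- plant_profile(name, peaks, if (is_plant) "plant" else "matrix")
  }
  names(lib) <- vapply(lib, `[[`, character(1L), "name")
  lib
}

#' Simulate one DAD injection of a mixture
#'
#' Beer-Lambert additive mixing: the absorbance surface is the mass-fraction
#' weighted sum of each profile's peak contributions, plus a slow quadratic
#' baseline drift shared by all wavelength channels and i.i.d. Gaussian
#' detector noise. Mass fractions must be non-negative and sum to at most 1;
#' any remainder is blank diluent contributing only baseline. With zero noise
#' the record is exactly linear in the mass fractions (for a fixed seed, which
#' fixes the baseline).
#'
#' @param profiles list of [plant_profile] objects in the mixture.
#' @param fractions numeric mass fractions, one per profile.
#' @param config a [sim_config]; supplies the grids and disturbance model.
#' @param jitter global retention-time shift (minutes) applied to every peak
#'   of this injection.
#' @param seed integer seed for the baseline coefficients and noise.
#' @param sample_id identifier for the record.
#' @param label optional integer class code.
#' @return A one-sample [dad_cube] on `config`'s grids.
#' @export
simulate_dad_record <- function(profiles, fractions, config, jitter = 0,
                                seed = 1L, sample_id = "sample1", label = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(profiles) != length(fractions))
    hs_stop_invalid("one mass fraction per profile is required")
  if (any(fractions < 0)) hs_stop_invalid("mass fractions must be non-negative")
  if (sum(fractions) > 1 + 1e-12) hs_stop_invalid("mass fractions must sum to at most 1")

  w <- config$wavelength_grid
  t <- config$time_grid
  set.seed(as.integer(seed))
  cb <- runif(3, -1, 1)                          # baseline polynomial coefficients
  u <- t / max(t)
  baseline <- config$baseline_drift_amp * (cb[1] + cb[2] * u + cb[3] * u^2)

  vals <- matrix(rep(baseline, each = length(w)), nrow = length(w))
  for (i in seq_along(profiles)) {
    if (fractions[i] == 0) next
    for (pk in profiles[[i]]$peaks) {
      g_t <- exp(-(t - pk$retention_center - jitter)^2 / (2 * pk$retention_width^2))
      s_w <- peak_spectrum(pk, w)
      vals <- vals + (pk$amplitude * fractions[i]) * outer(s_w, g_t)
    }
  }
  if (config$noise_sd > 0)
    vals <- vals + rnorm(length(vals), sd = config$noise_sd)

  dad_cube(array(vals, dim = c(1L, length(w), length(t))),
           sample_id, w, t, if (is.null(label)) NULL else label)
}

#' Simulate a complete screening study
#'
#' Reproduces the spiked-trituration study design. The binary design for one
#' target plant yields `n_matrices * length(spike_ratios)` triturations (each
#' blank matrix spiked with the target at each ratio), one blank injection per
#' matrix, and one pure reference injection: 67 records at the defaults, 56 of
#' class 1 (contains the target) and 11 of class 2 (blank). The multiclass
#' design pools the trituration blocks of every plant with the blanks and one
#' reference per plant (235 records at the defaults with 4 plants); classes
#' 1..n_plants code the plants, class `n_plants + 1` the blanks. Each record
#' receives an independent retention jitter and noise realization; the whole
#' study is bit-reproducible from `config$seed`.
#'
#' @param library profile list from [build_plant_library()].
#' @param target_plant name of the target plant (binary design; ignored for
#'   multiclass).
#' @param design `"binary"` or `"multiclass"`.
#' @param config a [sim_config].
#' @return A labelled [dad_cube].
#' @export
simulate_study <- function(library, target_plant = NULL,
                           design = c("binary", "multiclass"), config = sim_config()) {
  design <- match.arg(design)
  stopifnot(inherits(config, "sim_config"))
  types <- vapply(library, `[[`, character(1L), "type")
  plants <- library[types == "plant"]
  matrices <- library[types == "matrix"]
  if (length(matrices) < config$n_matrices)
    hs_stop_invalid(sprintf("library has %d matrices but the design needs %d",
                            length(matrices), config$n_matrices))
  matrices <- matrices[seq_len(config$n_matrices)]
  if (design == "binary") {
    if (is.null(target_plant) || !target_plant %in% names(plants))
      hs_stop_invalid("target_plant must name a plant profile in the library")
    plants <- plants[target_plant]
  } else if (length(plants) < 2L) {
    hs_stop_invalid("multiclass design needs at least two plants in the library")
  }

  ratios <- config$spike_ratios
  recipes <- list()
  add <- function(id, label, profs, fracs)
    recipes[[length(recipes) + 1L]] <<- list(id = id, label = label,
                                             profs = profs, fracs = fracs)
  for (pi in seq_along(plants)) {
    p <- plants[[pi]]
    for (mi in seq_along(matrices))
      for (ri in seq_along(ratios))
        add(sprintf("trit_%s_m%02d_r%02d", p$name, mi, ri), pi,
            list(p, matrices[[mi]]), c(ratios[ri], 1 - ratios[ri]))
  }
  blank_class <- length(plants) + 1L
  for (mi in seq_along(matrices))
    add(sprintf("zblank_m%02d", mi), if (design == "binary") 2L else blank_class,
        matrices[mi], 1)
  for (pi in seq_along(plants))
    add(sprintf("zref_%s", plants[[pi]]$name), pi, plants[pi], 1)

  n <- length(recipes)
  set.seed(config$seed)
  jitters <- rnorm(n, 0, config$rt_jitter_sd)
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n)

  W <- length(config$wavelength_grid); T <- length(config$time_grid)
  vals <- array(NA_real_, dim = c(n, W, T))
  for (i in seq_len(n)) {
    r <- recipes[[i]]
    rec <- simulate_dad_record(r$profs, r$fracs, config, jitter = jitters[i],
                               seed = rec_seeds[i], sample_id = r$id)
    vals[i, , ] <- rec$values[1L, , ]
  }
  dad_cube(vals,
           vapply(recipes, `[[`, character(1L), "id"),
           config$wavelength_grid, config$time_grid,
           vapply(recipes, `[[`, integer(1L), "label"))
}
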