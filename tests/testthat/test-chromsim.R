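test_that("library bookkeeping: counts, unique names, seed determinism", {
  lib <- build_plant_library(4, 11, seed = 1)
  expect_length(lib, 15L)
  expect_false(anyDuplicated(names(lib)) > 0)
  expect_identical(sum(vapply(lib, `[[`, character(1), "type") == "plant"), 4L)

  expect_identical(build_plant_library(1, 1, seed = 7),
                   build_plant_library(1, 1, seed = 7))
  expect_error(build_plant_library(0, 5), class = "herbscreen_invalid_argument")
  expect_error(build_plant_library(3, -1), class = "herbscreen_invalid_argument")
})

test_that("every plant has an in-window distinguishing peak, by exhaustive scan", {
  lib <- build_plant_library(4, 11, seed = 1)
  plants <- lib[vapply(lib, `[[`, character(1), "type") == "plant"]
  matrices <- lib[vapply(lib, `[[`, character(1), "type") == "matrix"]
  rt <- function(p) vapply(p$peaks, `[[`, numeric(1), "retention_center")
  wd <- function(p) vapply(p$peaks, `[[`, numeric(1), "retention_width")
  for (p in plants) {
    expect_true(any(rt(p) >= 1.5 & rt(p) <= 6.6))
    for (m in matrices) {
      lim <- 2 * max(c(wd(p), wd(m)))
      # at least one plant peak farther than 2x the largest width from every
      # matrix peak
      dist_ok <- vapply(rt(p), function(r) all(abs(r - rt(m)) > lim), logical(1))
      expect_true(any(dist_ok))
    }
  }
})

test_that("single-peak record peaks at its retention center and spectral maximum", {
  pk <- compound_peak(3, 0.05, 1, spectrum_centers = 300, spectrum_widths = 10,
                      spectrum_weights = 1)
  prof <- plant_profile("p", list(pk), "plant")
  cfg <- small_config(noise_sd = 0, baseline_drift_amp = 0, rt_jitter_sd = 0)
  rec <- simulate_dad_record(list(prof), 1, cfg, jitter = 0, seed = 3)
  lam_max <- which.min(abs(cfg$wavelength_grid - 300))
  expect_equal(cfg$time_grid[which.max(rec$values[1, lam_max, ])], 3)
  expect_equal(cfg$wavelength_grid[which.max(rec$values[1, , which.max(rec$values[1, lam_max, ])])],
               300)
})

test_that("empty profile list gives a baseline-only record", {
  cfg <- small_config(noise_sd = 0)
  rec <- simulate_dad_record(list(), numeric(0), cfg, seed = 11)
  # baseline is wavelength-independent: all channel rows identical
  expect_equal(max(abs(sweep(rec$values[1, , ], 2, rec$values[1, 1, ]))), 0)
  cfg0 <- small_config(noise_sd = 0, baseline_drift_amp = 0)
  rec0 <- simulate_dad_record(list(), numeric(0), cfg0, seed = 11)
  expect_equal(max(abs(rec0$values)), 0)
})

test_that("zero-noise mixtures are exactly linear in mass fractions", {
  lib <- build_plant_library(2, 2, seed = 5)
  cfg <- small_config(noise_sd = 0)
  ab <- simulate_dad_record(lib[c(1, 3)], c(0.3, 0.7), cfg, seed = 9)
  a <- simulate_dad_record(lib[1], 1, cfg, seed = 9)
  b <- simulate_dad_record(lib[3], 1, cfg, seed = 9)
  # mixture record = 0.3 A + 0.7 B pointwise (fractions sum to 1, shared baseline)
  expect_equal(ab$values, 0.3 * a$values + 0.7 * b$values, tolerance = 1e-12)
  expect_error(simulate_dad_record(lib[1], -0.1, cfg),
               class = "herbscreen_invalid_argument")
  expect_error(simulate_dad_record(lib[c(1, 3)], c(0.8, 0.5), cfg),
               class = "herbscreen_invalid_argument")
})

test_that("binary study design: 67 records, 56 positive, 11 blank, 55-record block", {
  lib <- build_plant_library(4, 11, seed = 1)
  cfg <- small_config(seed = 2)
  st <- simulate_study(lib, "plant01", "binary", cfg)
  expect_identical(dim(st$values)[1], 67L)
  expect_identical(sum(st$labels == 1L), 56L)
  expect_identical(sum(st$labels == 2L), 11L)
  expect_identical(sum(startsWith(st$sample_ids, "trit_")), 55L)

  # record count follows the design for other configurations too
  cfg2 <- small_config(seed = 2, n_matrices = 4L, spike_ratios = c(0.1, 0.3))
  st2 <- simulate_study(build_plant_library(1, 4, seed = 3), "plant01", "binary", cfg2)
  expect_identical(dim(st2$values)[1], 4L * 2L + 4L + 1L)
})

test_that("multiclass study design: 235 records, labels 1-5", {
  lib <- build_plant_library(4, 11, seed = 1)
  st <- simulate_study(lib, NULL, "multiclass", small_config(seed = 4))
  expect_identical(dim(st$values)[1], 235L)
  expect_identical(as.integer(table(st$labels)), c(56L, 56L, 56L, 56L, 11L))
  # per plant the trituration block has 55 records
  for (p in sprintf("plant%02d", 1:4))
    expect_identical(sum(startsWith(st$sample_ids, paste0("trit_", p))), 55L)
})

test_that("fixed seed reproduces a study bit for bit", {
  lib <- build_plant_library(2, 11, seed = 1)
  cfg <- small_config(seed = 17)
  expect_identical(simulate_study(lib, "plant01", "binary", cfg),
                   simulate_study(lib, "plant01", "binary", cfg))
})

test_that("study generation validates its library", {
  lib <- build_plant_library(2, 3, seed = 1)
  expect_error(simulate_study(lib, "plant01", "binary", small_config()),
               class = "herbscreen_invalid_argument")  # needs 11 matrices
  expect_error(simulate_study(lib, "nope", "binary",
                              small_config(n_matrices = 3L)),
               class = "herbscreen_invalid_argument")
})
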