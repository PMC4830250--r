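test_that("ellipsoid phantom: closed form, convergence, degeneracy", {
  p <- make_ellipsoid_phantom(c(30, 20, 15), spacing = 1, thickness = 3)
  expect_equal(p$true_volume_mL, 4 / 3 * pi * 30 * 20 * 15 / 1000)
  expect_error(make_ellipsoid_phantom(c(0.3, 10, 10), spacing = 0.5),
               "degenerate")
  # planimetry converges: error at halved spacing at most the coarse error
  planim <- function(ph) {
    s <- edhvol:::.measure_series(ph$mask, ph$spacing, ph$thickness)
    planimetry_volume(s)
  }
  sph_c <- make_ellipsoid_phantom(c(14, 14, 14), spacing = 1, thickness = 4)
  sph_f <- make_ellipsoid_phantom(c(14, 14, 14), spacing = 0.5, thickness = 2)
  err_c <- abs(planim(sph_c) - sph_c$true_volume_mL) / sph_c$true_volume_mL
  err_f <- abs(planim(sph_f) - sph_f$true_volume_mL) / sph_f$true_volume_mL
  expect_lt(err_f, 0.02)
  expect_lt(err_f, err_c + 1e-12)
})

test_that("lens phantom: closed form, limits, grid oracle agreement", {
  # d = 0 reduces to the full sphere
  p0 <- make_lens_phantom(20, 0, spacing = 1, thickness = 2)
  expect_equal(p0$true_volume_mL, 4 / 3 * pi * 20^3 / 1000)
  expect_error(make_lens_phantom(20, 40), "2R")
  # volume vanishes as d approaches 2R
  v <- function(R, d) pi * (4 * R + d) * (2 * R - d)^2 / 12 / 1000
  expect_lt(v(20, 39.9), 0.01 * v(20, 0))
  # closed form against the voxel-count oracle
  p <- make_lens_phantom(40, 60, spacing = 0.5, thickness = 2)
  s <- edhvol:::.measure_series(p$mask, p$spacing, p$thickness)
  expect_equal(planimetry_volume(s), p$true_volume_mL, tolerance = 0.02)
})

test_that("irregular phantom: identity at amplitude 0, determinism, volume bounds", {
  base <- make_ellipsoid_phantom(c(16, 12, 9), spacing = 1, thickness = 3)
  irr0 <- make_irregular_phantom(c(16, 12, 9), amplitude = 0, seed = 5,
                                 spacing = 1, thickness = 3)
  expect_identical(irr0$mask, base$mask)
  expect_equal(irr0$true_volume_mL, base$true_volume_mL)
  a <- make_irregular_phantom(c(16, 12, 9), amplitude = 0.2, seed = 7,
                              spacing = 1.5, thickness = 3)
  b <- make_irregular_phantom(c(16, 12, 9), amplitude = 0.2, seed = 7,
                              spacing = 1.5, thickness = 3)
  expect_identical(a$mask, b$mask)
  expect_gt(a$true_volume_mL, 0.5 * base$true_volume_mL)
  expect_lt(a$true_volume_mL, 2 * base$true_volume_mL)
  # oracle volume tracks the phantom's own voxel count reasonably
  s <- edhvol:::.measure_series(a$mask, a$spacing, a$thickness)
  expect_equal(planimetry_volume(s), a$true_volume_mL, tolerance = 0.1)
  expect_error(make_irregular_phantom(c(10, 10, 10), amplitude = 1.2),
               "amplitude")
})

test_that("simulate_cohort: determinism, truth recording, estimator property", {
  ph <- simulate_cohort(6, seed = 42, spacing_range = c(1.2, 1.5),
                        thickness_choices = c(3, 4))
  ph2 <- simulate_cohort(6, seed = 42, spacing_range = c(1.2, 1.5),
                         thickness_choices = c(3, 4))
  expect_length(ph, 6L)
  expect_identical(vapply(ph, function(p) p$true_volume_mL, numeric(1)),
                   vapply(ph2, function(p) p$true_volume_mL, numeric(1)))
  expect_true(all(vapply(ph, function(p) p$true_volume_mL, numeric(1)) >= 3))
  expect_error(simulate_cohort(0), "at least 1")
  # all-ellipsoid cohort at fine depth: variation-1 estimates cluster
  # near the analytic 3/pi ratio of truth
  ell <- simulate_cohort(3, seed = 7,
                         shape_probs = c(ellipsoid = 1, lens = 0, irregular = 0),
                         mean_mL = 15, sd_mL = 5,
                         spacing_range = c(0.5, 0.6),
                         thickness_choices = 1)
  ratios <- vapply(ell, function(p) {
    rec <- measure_case(p$mask, p$spacing, p$thickness)
    rec$estimates_mL[["1"]] / p$true_volume_mL
  }, numeric(1))
  expect_true(all(abs(ratios / (3 / pi) - 1) < 0.08))
})

test_that("study fixture loads, checks, and satisfies its identities", {
  fx <- load_study_fixture()
  expect_equal(nrow(fx), 53L)
  expect_equal(fx$planimetry[fx$case_id == 4], 3.22)
  expect_equal(fx$v2p[fx$case_id == 34], 238.46)
  expect_equal(fx$p_A1B1C0, 2 * fx$v1)
  # definitional identities: traditional = half product; primed columns
  # equal their formula applied to the reconstructed product within
  # double printed rounding (0.65 * 0.01 + 0.005)
  expect_equal(fx$v1, 0.5 * fx$p_A1B1C0)
  expect_lt(max(abs(0.37 * fx$p_A1B1C0 - 0.75 - fx$v1p)), 0.012)
  expect_lt(max(abs(0.65 * fx$p_A1B1C1 - 1.04 - fx$v2p)), 0.012)
  expect_lt(max(abs(0.39 * fx$p_A2B2C0 - 0.04 - fx$v3p)), 0.012)
  expect_lt(max(abs(0.65 * fx$p_A2B2C1 - 0.17 - fx$v4p)), 0.012)
  # corrupted file is rejected
  tmp <- tempfile(fileext = ".csv")
  lines <- readLines(system.file("extdata", "tedh_cohort.csv",
                                 package = "edhvol"))
  lines[3] <- sub("9.85", "9.86", lines[3])
  writeLines(lines, tmp)
  expect_error(load_study_fixture(tmp), "checksum")
})
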