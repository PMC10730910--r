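test_that("design templates produce the documented profile shapes", {
  mono <- generate_lens_profile(lens_design_spec("monofocal", base_power_D = -3))
  expect_length(mono$radii_mm, 141L)
  expect_true(all(mono$powers_D == -3))
  cn <- generate_lens_profile(lens_design_spec(
    "center_near", base_power_D = 0, addition_D = 2.5,
    zone_boundaries_mm = 1.5, transition_width_mm = 0))
  expect_true(all(cn$powers_D[cn$radii_mm < 1.5] == 2.5))
  expect_true(all(cn$powers_D[cn$radii_mm >= 1.5] == 0))
  cd <- generate_lens_profile(lens_design_spec(
    "center_distance", base_power_D = 0, addition_D = 2.5,
    zone_boundaries_mm = 1.5, transition_width_mm = 0))
  expect_equal(cd$powers_D, 2.5 - cn$powers_D)
  asp <- generate_lens_profile(lens_design_spec(
    "aspheric", base_power_D = 0, addition_D = 2))
  expect_equal(asp$powers_D[1], 2)
  expect_equal(asp$powers_D[141], 0)
  expect_true(all(diff(asp$powers_D) < 0))
  bif <- generate_lens_profile(lens_design_spec(
    "concentric_bifocal", base_power_D = 0, addition_D = 2,
    zone_boundaries_mm = c(1, 2, 3), transition_width_mm = 0))
  expect_equal(bif$powers_D[bif$radii_mm < 1][1], 0)
  expect_equal(bif$powers_D[bif$radii_mm >= 1 & bif$radii_mm < 2][1], 2)
  expect_equal(bif$powers_D[bif$radii_mm >= 2 & bif$radii_mm < 3][1], 0)
  expect_equal(bif$powers_D[141], 2)
  expect_error(generate_lens_profile(lens_design_spec("quadrifocal")),
               "valid designs")
})

test_that("noisy profiles are deterministic given the seed", {
  spec <- lens_design_spec("center_near", addition_D = 2, noise_sd_D = 0.05,
                           seed = 42)
  p1 <- generate_lens_profile(spec)
  p2 <- generate_lens_profile(spec)
  expect_identical(p1$powers_D, p2$powers_D)
  spec2 <- spec
  spec2$seed <- 43
  expect_false(identical(generate_lens_profile(spec2)$powers_D, p1$powers_D))
})

test_that("generated profiles round-trip through the profile reader", {
  spec <- lens_design_spec("aspheric", base_power_D = -6, addition_D = 3,
                           noise_sd_D = 0.05, seed = 7)
  p <- generate_lens_profile(spec)
  path <- tempfile(fileext = ".csv")
  write_profile(p, path)
  p2 <- read_profile(path)
  expect_equal(p2$radii_mm, p$radii_mm, tolerance = 1e-9)
  expect_equal(p2$powers_D, p$powers_D, tolerance = 1e-8)
  expect_equal(p2$meta$base_power_D, -6)
})

test_that("eye populations respect bounds, scales, and determinism", {
  spec <- eye_population_spec(n_eyes = 65, seed = 11)
  eyes <- generate_eye_population(spec)
  expect_length(eyes, 65L)
  pupils <- vapply(eyes, function(e) e$pupil_diameter_mm, numeric(1))
  expect_true(all(pupils >= 2.45 & pupils <= 6.27))
  eyes2 <- generate_eye_population(spec)
  expect_identical(lapply(eyes, function(e) e$zernikes$coeffs),
                   lapply(eyes2, function(e) e$zernikes$coeffs))
  clean <- generate_eye_population(eye_population_spec(
    n_eyes = 3, coeff_scales_um = c(`2` = 0, `3` = 0, `4` = 0, `5` = 0,
                                    `6` = 0), sa_mean_um = 0, seed = 1))
  expect_true(all(vapply(clean, function(e) all(e$zernikes$coeffs == 0),
                         logical(1))))
})

test_that("population moments match the generating scales at n = 1000", {
  spec <- eye_population_spec(n_eyes = 1000, seed = 99)
  eyes <- generate_eye_population(spec)
  cf <- t(vapply(eyes, function(e) e$zernikes$coeffs, numeric(28)))
  # per-order SDs, pooled over the zero-mean modes of each order
  for (ord in 2:5) {
    js <- setdiff(as.character(Filter(function(j) osa_nm(j)[["n"]] == ord,
                                      0:27)), "12")
    pooled <- sd(as.vector(cf[, js]))
    scale <- spec$coeff_scales_um[[as.character(ord)]]
    expect_lt(abs(pooled - scale) / scale, 0.15)
  }
  expect_lt(abs(mean(cf[, "12"]) - spec$sa_mean_um), 0.005)
  expect_lt(abs(sd(cf[, "24"]) - spec$coeff_scales_um[["6"]]) /
              spec$coeff_scales_um[["6"]], 0.1)
  pupils <- vapply(eyes, function(e) e$pupil_diameter_mm, numeric(1))
  expect_equal(range(pupils), c(2.45, 6.27), tolerance = 0.05)
})

test_that("equivalent-sphere injection lands in the defocus term", {
  eyes <- generate_eye_population(eye_population_spec(
    n_eyes = 2, coeff_scales_um = c(`2` = 0, `3` = 0, `4` = 0, `5` = 0,
                                    `6` = 0), sa_mean_um = 0,
    equiv_sphere_D = -0.75, seed = 5))
  for (e in eyes) {
    expect_equal(e$zernikes$coeffs[["4"]],
                 defocus_coeff_from_diopters(-0.75,
                                             e$pupil_diameter_mm / 2))
    expect_true(all(e$zernikes$coeffs[names(e$zernikes$coeffs) != "4"] == 0))
  }
})

test_that("the study batch has 12 designs x 3 bases plus controls", {
  b <- generate_study_batch(seed = 3, n_eyes = 65)
  expect_length(b$designs, 12L)
  expect_length(b$profiles, 36L)
  expect_length(b$eyes, 65L)
  expect_equal(b$monofocal$meta$design, "monofocal")
  bases <- vapply(b$profiles, function(p) p$meta$base_power_D, numeric(1))
  expect_equal(sort(unique(bases)), c(-6, -3, 1))
  expect_equal(sum(bases == -3), 12L)
  b2 <- generate_study_batch(seed = 3, n_eyes = 65)
  expect_identical(lapply(b$profiles, `[[`, "powers_D"),
                   lapply(b2$profiles, `[[`, "powers_D"))
})
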