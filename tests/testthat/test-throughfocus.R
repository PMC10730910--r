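test_that("the default vergence grid has 193 samples, step 0.03125, and 0 D", {
  v <- default_vergence_grid()
  expect_length(v, 193L)
  expect_equal(v[1], -1)
  expect_equal(v[193], 5)
  expect_true(all(diff(v) == 6 / 192))
  expect_identical(v[33], 0)  # 0-based index 32
})

test_that("the compiled sweep reproduces the reference VSOTF evaluation", {
  g <- grid_spec(64)
  asm <- combine_with_eye(
    make_flat_lens(5),
    eye_record(zernike_coefficients(c(`4` = 0.3, `12` = 0.06), 2.06),
               4.12, "hoa"), g)
  vg <- seq(-1, 3, by = 1)
  cv <- through_focus(asm, vg)
  R <- asm$aperture_radius_mm
  geo <- segwave:::pupil_geometry(g, R)
  ref <- vapply(vg, function(d) {
    opd <- asm$wavefront$opd
    c20 <- defocus_coeff_from_diopters(-d, R)
    opd[geo$mask] <- opd[geo$mask] +
      c20 * sqrt(3) * (2 * pmin(geo$rho_mm[geo$mask] / R, 1)^2 - 1)
    vsotf(wavefront_map(opd, R, g))
  }, numeric(1))
  expect_equal(cv$values, ref, tolerance = 1e-12)
})

test_that("a clean eye on a flat lens peaks at zero with even symmetry", {
  g <- grid_spec(128)
  asm <- combine_with_eye(make_flat_lens(5), make_clean_eye(4.12), g)
  vg <- seq(-1, 1, by = 0.25)
  cv <- through_focus(asm, vg)
  expect_equal(peak_performance(cv)$vergence_D, 0)
  expect_equal(cv$values, rev(cv$values), tolerance = 1e-6)  # defocus parity
})

test_that("a pure defocus eye shifts the peak by its equivalent power", {
  g <- grid_spec(128)
  # eye whose defocus term is the +0.50 D spherical equivalent
  eye <- eye_record(zernike_coefficients(
    c(`4` = defocus_coeff_from_diopters(0.5, 2.06)), 2.06), 4.12, "es")
  asm <- combine_with_eye(make_flat_lens(5), eye, g)
  cv <- through_focus(asm)
  expect_equal(peak_performance(cv)$vergence_D, 0.5, tolerance = 6 / 192)
  sh <- equivalent_sphere_shift(cv)
  expect_equal(sh, -0.5, tolerance = 6 / 192)
  # re-evaluating with the shift centres the peak at 0.00 D
  cv2 <- through_focus(asm, shift_D = sh)
  expect_lte(abs(peak_performance(cv2)$vergence_D), 6 / 192)
})

test_that("injected defocus demand is recovered across the grid", {
  g <- grid_spec(128)
  flat <- make_flat_lens(5)
  for (es in c(-0.75, -0.25, 0.40625, 0.9)) {
    eye <- eye_record(zernike_coefficients(
      c(`4` = defocus_coeff_from_diopters(es, 2.5)), 2.5), 5, "es")
    cv <- through_focus(combine_with_eye(flat, eye, g))
    expect_equal(peak_performance(cv)$vergence_D, es, tolerance = 6 / 192)
  }
})

test_that("metric arithmetic matches the literal definitions", {
  v <- default_vergence_grid()
  ones <- through_focus_curve(v, rep(1, 193))
  expect_equal(as.numeric(area_under_curve(ones)), 193)
  expect_equal(range_above_threshold(ones), 6)
  half <- through_focus_curve(v, rep(0.5, 193))
  expect_equal(as.numeric(area_under_curve(half)), 96.5)
  zeros <- through_focus_curve(v, rep(0, 193))
  expect_equal(as.numeric(area_under_curve(zeros)), 0)
  expect_equal(range_above_threshold(zeros), 0)
  # 96 samples strictly above threshold
  vals <- c(rep(1, 96), rep(0.1, 97))
  expect_equal(range_above_threshold(through_focus_curve(v, vals)),
               96 * 6 / 193)
  # samples exactly at the threshold do not count
  at <- through_focus_curve(v, rep(0.12, 193))
  expect_equal(range_above_threshold(at), 0)
})

test_that("range above threshold is monotone in the curve and the threshold", {
  v <- default_vergence_grid()
  base_vals <- pmax(0, 0.8 - 0.2 * abs(v - 1))
  cv <- through_focus_curve(v, base_vals)
  up <- through_focus_curve(v, pmin(base_vals + 0.05, 1))
  expect_gte(range_above_threshold(up), range_above_threshold(cv))
  expect_gte(range_above_threshold(cv, 0.05), range_above_threshold(cv, 0.12))
})

test_that("metrics are invariant to reversing a symmetric curve", {
  v <- default_vergence_grid()
  sym <- exp(-(v - 2)^2)  # symmetric about +2 on the grid
  cv <- through_focus_curve(v, sym)
  rv <- through_focus_curve(v, rev(sym))
  expect_equal(as.numeric(area_under_curve(cv)), as.numeric(area_under_curve(rv)))
  expect_equal(range_above_threshold(cv), range_above_threshold(rv))
  expect_equal(peak_performance(cv)$peak, peak_performance(rv)$peak)
})

test_that("peak ties break toward the smallest absolute vergence", {
  v <- default_vergence_grid()
  const <- through_focus_curve(v, rep(0.7, 193))
  pk <- peak_performance(const)
  expect_equal(pk$vergence_D, 0)
  expect_equal(pk$peak, 0.7)
  expect_equal(equivalent_sphere_shift(const), 0)
})

test_that("normalization reports percentages of the monofocal reference", {
  v <- default_vergence_grid()
  ref <- metrics_report(through_focus_curve(v, pmax(0.5 - 0.1 * abs(v), 0.13)))
  m <- metrics_report(through_focus_curve(v, pmax(0.5 - 0.1 * abs(v), 0.13)),
                      reference = ref)
  expect_equal(m$normalized$area_pct, 100)
  expect_equal(m$normalized$range_pct, 100)
  expect_equal(m$normalized$peak_pct, 100)
  scaled <- through_focus_curve(v, 0.78 * pmax(0.5 - 0.1 * abs(v), 0.13))
  m2 <- metrics_report(scaled, reference = ref)
  expect_equal(m2$normalized$peak_pct, 78)
  zero_ref <- metrics_report(through_focus_curve(v, rep(0.05, 193)))
  expect_error(normalize_to_monofocal(m, zero_ref), "positive")
})

test_that("curves round-trip through delimited text", {
  v <- default_vergence_grid()
  cv <- through_focus_curve(v, pmax(0.4 - 0.05 * abs(v - 1), 0.01),
                            meta = list(lens = "demo", eye_id = "e1",
                                        shift_D = -0.25))
  path <- tempfile(fileext = ".csv")
  write_curve(cv, path)
  cv2 <- read_curve(path)
  expect_equal(cv2$values, cv$values, tolerance = 1e-9)
  expect_equal(cv2$meta$shift_D, -0.25)
  expect_equal(cv2$meta$lens, "demo")
})
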