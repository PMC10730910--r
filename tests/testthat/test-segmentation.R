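test_that("annular masks partition the pupil disk exactly", {
  g <- grid_spec(128)
  pupil <- segwave:::pupil_geometry(g, 2)$mask + 0L
  for (n in c(1L, 2L, 7L, 141L)) {
    total <- Reduce(`+`, lapply(0:(n - 1), function(l)
      annular_mask(l, n, 2, g)$indicator))
    expect_identical(total, pupil)
  }
})

test_that("two-zone masks split at the half radius", {
  g <- grid_spec(128)
  geo <- segwave:::pupil_geometry(g, 2)
  m0 <- annular_mask(0, 2, 2, g)$indicator
  m1 <- annular_mask(1, 2, 2, g)$indicator
  expect_true(all(geo$rho_mm[m0 == 1] < 1))
  expect_true(all(geo$rho_mm[m1 == 1] >= 1 & geo$rho_mm[m1 == 1] <= 2))
  expect_error(annular_mask(2, 2, 2, g), "zone index")
})

test_that("constant profiles reduce to the monofocal wavefront pixel-exactly", {
  g <- grid_spec(128)
  const <- sagittal_profile(seq(0, 5, by = 1 / 28), rep(2, 141),
                            meta = list(lens = "const2"))
  mono_map <- defocus_wavefront(2, 4, g)$opd
  for (n in c(1L, 5L, 141L)) {
    asm <- build_multifocal_wavefront(const, 2, n, g)
    expect_identical(asm$wavefront$opd, mono_map)
  }
})

test_that("two-zone assemblies equal their constituent defocus maps per zone", {
  g <- grid_spec(128)
  r <- seq(0, 2, by = 1 / 28)
  p <- sagittal_profile(r, ifelse(r < 1, 0, 2))
  asm <- build_multifocal_wavefront(p, 2, 2, g)
  w0 <- defocus_wavefront(0, 4, g)$opd
  w2 <- defocus_wavefront(2, 4, g)$opd
  m0 <- annular_mask(0, 2, 2, g)$indicator == 1
  m1 <- annular_mask(1, 2, 2, g)$indicator == 1
  expect_identical(asm$wavefront$opd[m0], w0[m0])
  expect_identical(asm$wavefront$opd[m1], w2[m1])
})

test_that("zone count defaults to the samples inside the aperture", {
  g <- grid_spec(128)
  p <- sagittal_profile(seq(0, 5, by = 1 / 28), rep(0, 141))
  asm <- build_multifocal_wavefront(p, 2, grid = g)
  expect_identical(asm$n_zones, sum(p$radii_mm <= 2))
  expect_error(build_multifocal_wavefront(p, 6, grid = g), "combine_with_eye")
})

test_that("the min-aperture rule picks the smaller of pupil and lens radius", {
  g <- grid_spec(64)
  lens <- make_flat_lens(5)
  big_eye <- make_clean_eye(6.27)
  expect_equal(combine_with_eye(lens, big_eye, g)$aperture_radius_mm, 3.135)
  small_lens <- make_flat_lens(1.5)
  expect_equal(combine_with_eye(small_lens, big_eye, g)$aperture_radius_mm, 1.5)
})

test_that("an aberration-free eye adds nothing to the lens wavefront", {
  g <- grid_spec(64)
  r <- seq(0, 5, by = 1 / 14)
  p <- sagittal_profile(r, 1 + 0.5 * sin(r))
  asm_eye <- combine_with_eye(p, make_clean_eye(4.12), g)
  asm_lens <- build_multifocal_wavefront(p, 2.06, asm_eye$n_zones, g)
  expect_equal(asm_eye$wavefront$opd, asm_lens$wavefront$opd, tolerance = 1e-12)
})

test_that("eye superposition is additive, also for asymmetric aberrations", {
  g <- grid_spec(64)
  r <- seq(0, 5, by = 1 / 14)
  p <- sagittal_profile(r, ifelse(r < 1.5, 2, 0))
  cf <- c(`3` = 0.15, `7` = -0.1, `12` = 0.08)  # astig., coma, SA
  eye <- eye_record(zernike_coefficients(cf, 2.5), 5, "hoa")
  asm <- combine_with_eye(p, eye, g)
  R <- asm$aperture_radius_mm
  lens_part <- build_multifocal_wavefront(p, R, asm$n_zones, g)$wavefront$opd
  geo <- segwave:::pupil_geometry(g, R)
  eye_part <- matrix(NA_real_, 64, 64)
  eye_part[geo$mask] <- segwave:::zernike_sum(
    eye$zernikes, geo$rho_mm[geo$mask] / 2.5, geo$theta[geo$mask])
  expect_equal(asm$wavefront$opd, lens_part + eye_part, tolerance = 1e-12)
})

test_that("a defocus-only eye on a flat lens gives the cropped eye defocus map", {
  g <- grid_spec(64)
  eye <- eye_record(zernike_coefficients(c(`4` = 0.5), 2.06), 4.12, "defoc")
  asm <- combine_with_eye(make_flat_lens(5), eye, g)
  expected <- wavefront_from_coeffs(eye$zernikes, g)$opd
  expect_equal(asm$wavefront$opd, expected, tolerance = 1e-12)
})

test_that("assembly OPD exports carry metadata and the full matrix", {
  g <- grid_spec(64)
  asm <- build_multifocal_wavefront(make_flat_lens(5, 1.5), 2, 3, g)
  path <- tempfile(fileext = ".csv")
  write_assembly_opd(asm, path)
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)]
  expect_true(any(grepl("aperture_radius_mm=2", meta)))
  expect_true(any(grepl("n_zones=3", meta)))
  mat <- as.matrix(read.csv(text = lines[!grepl("^#", lines)],
                            header = FALSE))
  expect_equal(dim(mat), c(64L, 64L))
  expect_equal(unname(mat), unname(asm$wavefront$opd), tolerance = 1e-9)
})

test_that("shrinking the aperture shrinks the physical wavefront support", {
  g <- grid_spec(64)
  p <- make_flat_lens(5, 1)
  support_mm <- function(R) {
    asm <- build_multifocal_wavefront(p, R, 1, g)
    geo <- segwave:::pupil_geometry(g, R)
    max(geo$rho_mm[!is.na(asm$wavefront$opd)])
  }
  expect_lt(support_mm(1.5), support_mm(2.5))
  expect_equal(support_mm(2.5), 2.5, tolerance = 0.05)
})
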