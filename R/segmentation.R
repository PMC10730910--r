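# Zone membership of every pixel: annulus l of n covers physical radius
# [R l / n, R (l + 1) / n), the last zone closed at R.  Computing the index
# as floor(rho / R * n), clamped to n - 1, makes the zones pairwise disjoint
# and their union exactly the pupil disk, so spatial overlap cannot occur by
# construction.  Pixels outside the pupil get NA.
zone_index_map <- function(geo, n_zones) {
  z <- matrix(NA_integer_, nrow(geo$rho_mm), ncol(geo$rho_mm))
  z[geo$mask] <- pmin(
    as.integer(floor(geo$rho_mm[geo$mask] / geo$aperture_radius_mm * n_zones)),
    n_zones - 1L)
  z
}

#' Binary annular mask for one radial zone
#'
#' The masking function selecting annulus `l` out of `n` equal-width zones of
#' the aperture `[0, R]`: 1 where the pixel-centre radius falls in
#' `[R l / n, R (l + 1) / n)` (last zone closed at `R`), 0 elsewhere.  For a
#' fixed `(n, R, grid)` the masks partition the pupil disk exactly.  `n = 1`
#' yields the full pupil disk (the monofocal case).
#'
#' @param l Zone index, `0 <= l <= n - 1`.
#' @param n Zone count, `n >= 1`.
#' @param R_mm Aperture radius, mm.
#' @param grid A [grid_spec()].
#' @return An object of class `annular_mask` with a 0/1 `indicator` matrix.
#' @export
annular_mask <- function(l, n, R_mm, grid) {
  if (n < 1 || n != round(n)) fail_validation("zone count n must be a positive integer")
  if (l < 0 || l > n - 1 || l != round(l))
    fail_validation("zone index l must satisfy 0 <= l <= n - 1")
  geo <- pupil_geometry(grid, R_mm)
  z <- zone_index_map(geo, n)
  ind <- matrix(0L, grid$matrix_size, grid$matrix_size)
  ind[!is.na(z) & z == l] <- 1L
  structure(list(indicator = ind, l = as.integer(l), n = as.integer(n),
                 aperture_radius_mm = R_mm, grid = grid),
            class = "annular_mask")
}

new_multifocal_assembly <- function(wavefront, zone_powers_D, n_zones,
                                    aperture_radius_mm, profile, eye = NULL) {
  structure(list(wavefront = wavefront, zone_powers_D = zone_powers_D,
                 n_zones = n_zones, aperture_radius_mm = aperture_radius_mm,
                 profile = profile, eye = eye),
            class = "multifocal_assembly")
}

#' @export
print.multifocal_assembly <- function(x, ...) {
  cat(sprintf(
    "<multifocal_assembly> %s: %d zone(s) over R = %.3f mm%s; zone power %.2f to %.2f D\n",
    x$profile$meta$lens %||% "lens", x$n_zones, x$aperture_radius_mm,
    if (is.null(x$eye)) "" else sprintf(" + eye %s", x$eye$eye_id),
    min(x$zone_powers_D), max(x$zone_powers_D)))
  invisible(x)
}

#' Assemble a segmented multifocal wavefront from a sagittal profile
#'
#' Builds the multifocal lens wavefront by summing, over `n` annular zones,
#' the monofocal defocus wavefront of each zone's sagittal power restricted
#' to that zone's annulus.  Each zone power is converted to a defocus
#' coefficient over the full aperture ([defocus_coeff_from_diopters()]) and
#' masked by the zone's annulus; no piston matching is applied between zones,
#' so the OPD steps at zone boundaries are part of the model.
#'
#' @param p A [sagittal_profile()] (base correction already removed if the
#'   multifocal structure alone is of interest).
#' @param aperture_radius_mm Aperture radius; must not exceed the measured
#'   lens radius.
#' @param n Zone count; default `NULL` uses one zone per profile sample
#'   inside the aperture.
#' @param grid A [grid_spec()].
#' @return A `multifocal_assembly` whose `wavefront` is a [wavefront_map()].
#' @export
build_multifocal_wavefront <- function(p, aperture_radius_mm, n = NULL,
                                       grid = grid_spec()) {
  stopifnot(inherits(p, "sagittal_profile"))
  if (aperture_radius_mm > max(p$radii_mm) * (1 + 1e-9))
    fail_validation(paste0(
      "aperture radius %.3f mm exceeds the measured lens radius %.3f mm; ",
      "use combine_with_eye, which clamps to min(pupil, lens) radius"),
      aperture_radius_mm, max(p$radii_mm))
  if (is.null(n)) n <- max(1L, sum(p$radii_mm <= aperture_radius_mm * (1 + 1e-12)))
  n <- as.integer(n)
  zone_powers <- vapply(0:(n - 1L), function(l)
    power_at_annulus(p, l, n, aperture_radius_mm), numeric(1))
  c20 <- defocus_coeff_from_diopters(zone_powers, aperture_radius_mm)
  geo <- pupil_geometry(grid, aperture_radius_mm)
  z <- zone_index_map(geo, n)
  z20 <- sqrt(3) * (2 * pmin(geo$rho_mm / aperture_radius_mm, 1)^2 - 1)
  opd <- matrix(NA_real_, grid$matrix_size, grid$matrix_size)
  opd[geo$mask] <- c20[z[geo$mask] + 1L] * z20[geo$mask]
  new_multifocal_assembly(wavefront_map(opd, aperture_radius_mm, grid),
                          zone_powers, n, aperture_radius_mm, p)
}

#' Export an assembled wavefront as a flat OPD matrix
#'
#' Writes the OPD matrix (micrometres, `NA` outside the pupil) as
#' comma-separated text preceded by `#` metadata lines recording the
#' aperture radius, zone count, zone powers, grid and wavelength, for
#' debugging and plotting outside R.
#'
#' @param asm A `multifocal_assembly`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_opd <- function(asm, path) {
  stopifnot(inherits(asm, "multifocal_assembly"))
  con <- file(path, "w")
  on.exit(close(con))
  g <- asm$wavefront$grid
  writeLines(c(
    sprintf("# lens=%s", asm$profile$meta$lens %||% "lens"),
    sprintf("# aperture_radius_mm=%.6g", asm$aperture_radius_mm),
    sprintf("# n_zones=%d", asm$n_zones),
    sprintf("# zone_powers_D=%s",
            paste(formatC(asm$zone_powers_D, digits = 6, format = "g"),
                  collapse = ";")),
    sprintf("# matrix_size=%d", g$matrix_size),
    sprintf("# pupil_fill=%.6g", g$pupil_fill),
    sprintf("# wavelength_nm=%.6g", g$wavelength_nm)), con)
  write.table(asm$wavefront$opd, con, sep = ",", row.names = FALSE,
              col.names = FALSE, na = "NA")
  invisible(path)
}

#' Superpose a lens profile and an eye's aberrations
#'
#' Combines the segmented lens wavefront with the eye's higher-order
#' aberrations by wavefront superposition in the pupil plane.  The
#' computation aperture is `R = min(pupil radius, measured lens radius)`; the
#' eye wavefront is synthesized from its Zernike coefficients over the eye's
#' own measurement pupil and spatially cropped to `R` (no coefficient
#' rescaling), then added to the segmented lens wavefront.
#'
#' @param p A [sagittal_profile()].
#' @param eye An [eye_record()].
#' @param grid A [grid_spec()].
#' @param n Zone count for the lens segmentation; default one zone per
#'   profile sample inside the aperture.
#' @return A `multifocal_assembly` with the eye attached.
#' @export
combine_with_eye <- function(p, eye, grid = grid_spec(), n = NULL) {
  stopifnot(inherits(p, "sagittal_profile"), inherits(eye, "eye_record"))
  R <- min(eye$pupil_diameter_mm / 2, max(p$radii_mm))
  asm <- build_multifocal_wavefront(p, R, n, grid)
  geo <- pupil_geometry(grid, R)
  r_eye <- eye$zernikes$pupil_radius_mm
  eye_opd <- zernike_sum(eye$zernikes,
                         pmin(geo$rho_mm[geo$mask] / r_eye, 1),
                         geo$theta[geo$mask])
  opd <- asm$wavefront$opd
  opd[geo$mask] <- opd[geo$mask] + eye_opd
  new_multifocal_assembly(wavefront_map(opd, R, grid),
                          asm$zone_powers_D, asm$n_zones, R, p, eye)
}
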