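#' OSA single index from radial order and azimuthal frequency
#'
#' @param n Radial order (non-negative integer).
#' @param m Azimuthal frequency, `|m| <= n`, `n - |m|` even.
#' @return The OSA/ANSI single index `j = (n (n + 2) + m) / 2`.
#' @export
osa_index <- function(n, m) {
  check_nm(n, m)
  as.integer((n * (n + 2) + m) / 2)
}

#' Radial order and azimuthal frequency from an OSA single index
#'
#' @param j OSA/ANSI single index (non-negative integer).
#' @return Integer vector `c(n, m)`.
#' @export
osa_nm <- function(j) {
  if (length(j) != 1L || is.na(j) || j < 0 || j != round(j))
    fail_validation("OSA index must be a single non-negative integer")
  n <- as.integer(ceiling((-3 + sqrt(9 + 8 * j)) / 2))
  m <- as.integer(2 * j - n * (n + 2))
  c(n = n, m = m)
}

check_nm <- function(n, m) {
  if (length(n) != 1L || length(m) != 1L || is.na(n) || is.na(m) ||
      n != round(n) || m != round(m) || n < 0 || abs(m) > n ||
      (n - abs(m)) %% 2 != 0)
    fail_validation("invalid Zernike index (n = %s, m = %s)", n, m)
  invisible(NULL)
}

#' Evaluate an orthonormal (OSA/ANSI) Zernike polynomial
#'
#' Uses the OSA/ANSI normalization, under which the polynomials are
#' orthonormal over the unit disk: the RMS contribution of a mode equals its
#' coefficient.
#'
#' @param n Radial order.
#' @param m Azimuthal frequency (negative for sine terms).
#' @param rho Normalized radius in `[0, 1]` (vectorized).
#' @param theta Azimuthal angle in radians (vectorized, recycled with `rho`).
#' @return Polynomial values, dimensionless.
#' @examples
#' zernike_value(2, 0, 0, 0)   # defocus at the pupil centre: -sqrt(3)
#' @export
zernike_value <- function(n, m, rho, theta) {
  check_nm(n, m)
  if (any(rho < 0 | rho > 1 + 1e-12, na.rm = TRUE))
    fail_validation("rho must lie in [0, 1]")
  am <- abs(m)
  k <- 0:((n - am) / 2)
  coef <- (-1)^k * factorial(n - k) /
    (factorial(k) * factorial((n + am) / 2 - k) * factorial((n - am) / 2 - k))
  radial <- drop(outer(rho, n - 2 * k, `^`) %*% coef)
  norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(am * theta) else 1
  norm * radial * ang
}

#' Zernike coefficient set
#'
#' OSA-indexed Zernike coefficients (micrometres) together with the pupil
#' radius over which the expansion is defined.
#'
#' @param coeffs Numeric vector of coefficients in micrometres.  Either named
#'   by OSA single index (`"0"`, `"1"`, ...) or unnamed, in which case the
#'   indices `0, 1, ...` are assumed.
#' @param pupil_radius_mm Pupil radius of the expansion, mm.
#' @param max_order Highest admissible radial order (default 6, covering the
#'   terms used in ocular emulation).
#' @return An object of class `zernike_coefficients`.
#' @export
zernike_coefficients <- function(coeffs, pupil_radius_mm, max_order = 6L) {
  if (!is.numeric(coeffs)) fail_validation("coeffs must be numeric")
  if (is.null(names(coeffs))) names(coeffs) <- as.character(seq_along(coeffs) - 1L)
  idx <- suppressWarnings(as.integer(names(coeffs)))
  if (any(is.na(idx)) || any(idx < 0) || anyDuplicated(idx))
    fail_validation("coefficient names must be distinct non-negative OSA indices")
  if (any(!is.finite(coeffs))) fail_validation("coefficients must be finite")
  for (j in idx) {
    nm <- osa_nm(j)
    if (nm[["n"]] > max_order)
      fail_validation("OSA index %d exceeds maximum radial order %d", j, max_order)
  }
  if (!is.numeric(pupil_radius_mm) || length(pupil_radius_mm) != 1L ||
      pupil_radius_mm <= 0)
    fail_validation("pupil_radius_mm must be positive")
  structure(list(coeffs = coeffs[order(idx)], pupil_radius_mm = pupil_radius_mm),
            class = "zernike_coefficients")
}

#' @export
print.zernike_coefficients <- function(x, ...) {
  nz <- x$coeffs[x$coeffs != 0]
  cat(sprintf("<zernike_coefficients> pupil radius %.3f mm, %d non-zero term(s)\n",
              x$pupil_radius_mm, length(nz)))
  if (length(nz)) print(round(nz, 4))
  invisible(x)
}

# Sum of coefficient-weighted Zernike modes at given normalized radii/angles.
zernike_sum <- function(z, rho_norm, theta) {
  out <- numeric(length(rho_norm))
  cf <- z$coeffs[z$coeffs != 0]
  for (nm in names(cf)) {
    id <- osa_nm(as.integer(nm))
    out <- out + cf[[nm]] * zernike_value(id[["n"]], id[["m"]], rho_norm, theta)
  }
  out
}

#' Synthesize a wavefront map from Zernike coefficients
#'
#' Evaluates `OPD(x, y) = sum_j c_j Z_j(rho, theta)` at every pixel whose
#' centre falls inside the pupil; pixels outside are `NA`.
#'
#' @param z A [zernike_coefficients()].
#' @param grid A [grid_spec()].
#' @return A [wavefront_map()] with the pupil radius of `z`.
#' @export
wavefront_from_coeffs <- function(z, grid) {
  stopifnot(inherits(z, "zernike_coefficients"))
  geo <- pupil_geometry(grid, z$pupil_radius_mm)
  opd <- matrix(NA_real_, grid$matrix_size, grid$matrix_size)
  m <- geo$mask
  opd[m] <- zernike_sum(z, pmin(geo$rho_mm[m] / z$pupil_radius_mm, 1),
                        geo$theta[m])
  wavefront_map(opd, z$pupil_radius_mm, grid)
}

#' Defocus coefficient equivalent to a spherical power
#'
#' Converts a spherical power (diopters, refraction sign convention) into the
#' OSA defocus coefficient `c(2, 0)` over a given pupil radius:
#' `c = -P r^2 / (4 sqrt(3))`.  With `P` in diopters and `r` in millimetres
#' the result is in micrometres.  Positive power maps to negative defocus
#' (myopic-defocus convention); the inverse is the standard spherical
#' equivalent formula `M = -4 sqrt(3) c / r^2`.
#'
#' @param power_D Spherical power in diopters (vectorized).
#' @param pupil_radius_mm Pupil radius in millimetres.
#' @return Defocus coefficient(s) in micrometres.
#' @examples
#' defocus_coeff_from_diopters(1, 3)   # ~ -1.299 um
#' @export
defocus_coeff_from_diopters <- function(power_D, pupil_radius_mm) {
  if (!is.numeric(pupil_radius_mm) || pupil_radius_mm <= 0)
    fail_validation("pupil_radius_mm must be positive")
  -power_D * pupil_radius_mm^2 / (4 * sqrt(3))
}

#' Spherical power equivalent to a defocus coefficient
#'
#' Inverse of [defocus_coeff_from_diopters()].
#'
#' @param c20_um Defocus coefficient in micrometres.
#' @param pupil_radius_mm Pupil radius in millimetres.
#' @return Power in diopters.
#' @export
diopters_from_defocus_coeff <- function(c20_um, pupil_radius_mm) {
  if (!is.numeric(pupil_radius_mm) || pupil_radius_mm <= 0)
    fail_validation("pupil_radius_mm must be positive")
  -c20_um * 4 * sqrt(3) / pupil_radius_mm^2
}

#' Read a Zernike coefficient table
#'
#' Reads a comma-separated table with either a `osa_index` column or `n` and
#' `m` columns, plus a `coeff_um` column.  The pupil diameter is carried in a
#' commented metadata line `# pupil_diameter_mm=...`.
#'
#' @param path Path to the file.
#' @return A [zernike_coefficients()].
#' @export
read_zernike_table <- function(path) {
  parsed <- read_commented_csv(path)
  df <- parsed$data
  if (is.null(parsed$meta$pupil_diameter_mm))
    fail_validation("missing '# pupil_diameter_mm=' metadata line in %s", path)
  d <- as.numeric(parsed$meta$pupil_diameter_mm)
  if (!all(c("coeff_um") %in% names(df)))
    fail_validation("Zernike table must have a coeff_um column")
  j <- if ("osa_index" %in% names(df)) {
    as.integer(df$osa_index)
  } else if (all(c("n", "m") %in% names(df))) {
    mapply(osa_index, df$n, df$m)
  } else {
    fail_validation("Zernike table needs an osa_index column or n and m columns")
  }
  cf <- as.numeric(df$coeff_um)
  names(cf) <- as.character(j)
  zernike_coefficients(cf, d / 2)
}

#' Write a Zernike coefficient table
#'
#' Counterpart of [read_zernike_table()].
#'
#' @param z A [zernike_coefficients()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zernike_table <- function(z, path) {
  stopifnot(inherits(z, "zernike_coefficients"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pupil_diameter_mm=%.6g", 2 * z$pupil_radius_mm), con)
  writeLines("osa_index,coeff_um", con)
  writeLines(sprintf("%s,%.10g", names(z$coeffs), z$coeffs), con)
  invisible(path)
}
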