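#' Simulation grid specification
#'
#' Describes the square sampling grid on which wavefronts, pupils and
#' transfer functions are computed.  The pupil disk spans `pupil_fill` of the
#' grid side, leaving zero padding around it; `pupil_fill <= 0.5` guarantees
#' that the pupil autocorrelation (the OTF support) fits in the grid without
#' wrap-around.
#'
#' @param matrix_size Pixels per grid side; even, at least 64. Default 512.
#' @param pupil_fill Fraction of the grid side spanned by the pupil diameter,
#'   in (0, 1]. Default 0.25, i.e. four-fold padding.
#' @param wavelength_nm Design wavelength in nanometres. Default 555 nm
#'   (photopic peak).
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(128)
#' @export
grid_spec <- function(matrix_size = 512L, pupil_fill = 0.25,
                      wavelength_nm = 555) {
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) != 1L || is.na(matrix_size) || matrix_size < 64L ||
      matrix_size %% 2L != 0L)
    fail_validation("matrix_size must be a single even integer >= 64")
  if (!is.numeric(pupil_fill) || length(pupil_fill) != 1L ||
      pupil_fill <= 0 || pupil_fill > 1)
    fail_validation("pupil_fill must lie in (0, 1]")
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1L ||
      wavelength_nm <= 0)
    fail_validation("wavelength_nm must be a positive number")
  structure(list(matrix_size = matrix_size, pupil_fill = pupil_fill,
                 wavelength_nm = wavelength_nm),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, pupil fill %.3g, wavelength %g nm\n",
              x$matrix_size, x$matrix_size, x$pupil_fill, x$wavelength_nm))
  invisible(x)
}

# Pixel-centre geometry of a circular aperture of radius R (mm) on a grid.
# The DC pixel (index N/2 + 1) sits exactly at the aperture centre, matching
# the FFT origin convention.  A pixel belongs to the pupil iff its centre lies
# at radius <= R (tiny tolerance absorbs floating-point edge cases).
pupil_geometry <- function(grid, aperture_radius_mm) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.numeric(aperture_radius_mm) || aperture_radius_mm <= 0)
    fail_validation("aperture radius must be positive")
  n <- grid$matrix_size
  dx <- 2 * aperture_radius_mm / (grid$pupil_fill * n)
  x <- (seq_len(n) - 1 - n / 2) * dx
  X <- matrix(x, n, n)
  Y <- matrix(x, n, n, byrow = TRUE)
  rho <- sqrt(X^2 + Y^2)
  list(x = x, rho_mm = rho, theta = atan2(Y, X),
       mask = rho <= aperture_radius_mm * (1 + 1e-12),
       dx_mm = dx, aperture_radius_mm = aperture_radius_mm)
}

#' Wavefront map
#'
#' A wavefront as optical path difference (OPD, micrometres) sampled on a
#' square grid over a circular pupil; pixels outside the pupil are `NA`.
#'
#' @param opd Square numeric matrix of OPD values in micrometres, `NA`
#'   outside the pupil.
#' @param pupil_radius_mm Pupil radius over which the map is defined, mm.
#' @param grid A [grid_spec()].
#' @return An object of class `wavefront_map`.
#' @export
wavefront_map <- function(opd, pupil_radius_mm, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(opd) || nrow(opd) != ncol(opd) ||
      nrow(opd) != grid$matrix_size)
    fail_validation("opd must be a square matrix matching the grid size")
  if (!is.numeric(pupil_radius_mm) || pupil_radius_mm <= 0)
    fail_validation("pupil_radius_mm must be positive")
  inside <- !is.na(opd)
  if (any(!is.finite(opd[inside])))
    fail_validation("OPD values inside the pupil must be finite")
  structure(list(opd = opd, pupil_radius_mm = pupil_radius_mm, grid = grid),
            class = "wavefront_map")
}

#' @export
print.wavefront_map <- function(x, ...) {
  cat(sprintf(
    "<wavefront_map> pupil radius %.3f mm on %d px grid; RMS %.4f um\n",
    x$pupil_radius_mm, x$grid$matrix_size, wavefront_rms(x)))
  invisible(x)
}

#' Root-mean-square OPD of a wavefront over its pupil
#'
#' @param w A [wavefront_map()].
#' @return RMS OPD in micrometres.
#' @export
wavefront_rms <- function(w) {
  stopifnot(inherits(w, "wavefront_map"))
  v <- w$opd[!is.na(w$opd)]
  sqrt(mean(v^2))
}
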