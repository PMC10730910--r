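#' Generalized pupil function of a wavefront
#'
#' `P(x, y) = A(x, y) exp(i 2 pi OPD(x, y) / lambda)` with uniform amplitude
#' `A` equal to the pupil indicator.
#'
#' @param w A [wavefront_map()].
#' @param wavelength_nm Wavelength; defaults to the grid's wavelength.
#' @return A complex matrix, zero outside the pupil.
#' @export
generalized_pupil <- function(w, wavelength_nm = w$grid$wavelength_nm) {
  stopifnot(inherits(w, "wavefront_map"))
  lam_um <- wavelength_nm / 1000
  opd <- w$opd
  outside <- is.na(opd)
  opd[outside] <- 0
  p <- exp(2i * pi * opd / lam_um)
  p[outside] <- 0 + 0i
  p
}

# Signed FFT-order frequencies (0, 1, ..., N/2 - 1, -N/2, ..., -1) * d_freq.
fft_frequencies <- function(n, d_freq) {
  (((seq_len(n) - 1 + n / 2) %% n) - n / 2) * d_freq
}

# Frequency increment of the OTF grid in cycles/degree: one pixel of pupil
# shift corresponds to dx / lambda cycles per radian of visual angle.
otf_freq_step_cpd <- function(pupil_diameter_mm, grid) {
  dx_um <- pupil_diameter_mm * 1000 / (grid$pupil_fill * grid$matrix_size)
  dx_um / (grid$wavelength_nm / 1000) * pi / 180
}

#' Optical transfer function of a generalized pupil
#'
#' Computes `PSF = |FFT(P)|^2` and the OTF as the normalized inverse FFT of
#' the PSF (equivalently, the normalized autocorrelation of the pupil), along
#' with the diffraction-limited OTF of the same aperture (zero phase) through
#' the identical numerical path.  Frequency axes are calibrated in
#' cycles/degree of visual angle from the pupil sampling pitch and
#' wavelength.  Matrices are returned in unshifted FFT order; `fx`/`fy` carry
#' the signed frequency of each row/column.
#'
#' @param pupil Complex pupil array from [generalized_pupil()].
#' @param grid The [grid_spec()] the pupil was sampled on (`pupil_fill` must
#'   not exceed 0.5, otherwise the pupil autocorrelation wraps around).
#' @param pupil_diameter_mm Physical pupil diameter, mm.
#' @return An object of class `otf_grid` with elements `otf` (complex,
#'   `otf[1, 1] == 1`), `dl` (real diffraction-limited OTF), `fx`, `fy`,
#'   `d_freq_cpd`, and `cutoff_cpd` (the incoherent cutoff of the aperture).
#' @export
compute_otf <- function(pupil, grid, pupil_diameter_mm) {
  stopifnot(inherits(grid, "grid_spec"))
  if (grid$pupil_fill > 0.5)
    fail_validation(paste0(
      "pupil_fill = %.3g > 0.5: the pupil autocorrelation would wrap around ",
      "the grid (aliasing); use a more padded grid"), grid$pupil_fill)
  if (!is.complex(pupil)) pupil <- pupil + 0i
  psf <- Mod(stats::fft(pupil))^2
  otf_raw <- stats::fft(psf, inverse = TRUE)
  otf <- otf_raw / Re(otf_raw[1, 1])
  dl_raw <- stats::fft(Mod(stats::fft(Mod(pupil)))^2, inverse = TRUE)
  dl <- Re(dl_raw / Re(dl_raw[1, 1]))
  d_freq <- otf_freq_step_cpd(pupil_diameter_mm, grid)
  f <- fft_frequencies(grid$matrix_size, d_freq)
  structure(list(otf = otf, dl = dl, fx = f, fy = f, d_freq_cpd = d_freq,
                 cutoff_cpd = pupil_diameter_mm * 1000 /
                   (grid$wavelength_nm / 1000) * pi / 180,
                 grid = grid, pupil_diameter_mm = pupil_diameter_mm),
            class = "otf_grid")
}

#' Analytic diffraction-limited OTF of a circular aperture
#'
#' The classical "chat" function
#' `H(s) = (2 / pi) (acos(s) - s sqrt(1 - s^2))` with `s = f / f_c`, zero
#' beyond the incoherent cutoff `f_c = D / lambda`.
#'
#' @param f_cpd Spatial frequency, cycles/degree (vectorized).
#' @param pupil_diameter_mm Aperture diameter, mm.
#' @param wavelength_nm Wavelength, nm.
#' @return OTF values in `[0, 1]`.
#' @export
diffraction_limited_otf <- function(f_cpd, pupil_diameter_mm, wavelength_nm) {
  fc <- pupil_diameter_mm * 1000 / (wavelength_nm / 1000) * pi / 180
  s <- pmin(abs(f_cpd) / fc, 1)
  (2 / pi) * (acos(s) - s * sqrt(1 - s^2))
}

#' Parameters of the neural contrast sensitivity function
#'
#' A truncated log-parabola: sensitivity follows a Gaussian in
#' `log2(frequency)` around the peak, and is floored at `floor_frac` of the
#' peak below it (the neural pathway loses little sensitivity at low spatial
#' frequencies once optics are bypassed).  The absolute `gain` cancels in the
#' VSOTF ratio; it is kept so exported CSF grids carry interpretable units.
#'
#' @param gain Peak sensitivity (arbitrary units). Default 500.
#' @param peak_cpd Peak frequency, cycles/degree. Default 4.
#' @param bandwidth_oct Gaussian SD in octaves. Default 1.4.
#' @param floor_frac Low-frequency floor as a fraction of peak. Default 0.8.
#' @return An object of class `csf_params`.
#' @export
csf_params <- function(gain = 500, peak_cpd = 4, bandwidth_oct = 1.4,
                       floor_frac = 0.8) {
  if (gain <= 0 || peak_cpd <= 0 || bandwidth_oct <= 0 ||
      floor_frac < 0 || floor_frac > 1)
    fail_validation("invalid CSF parameters")
  structure(list(gain = gain, peak_cpd = peak_cpd,
                 bandwidth_oct = bandwidth_oct, floor_frac = floor_frac),
            class = "csf_params")
}

#' Neural contrast sensitivity at given spatial frequencies
#'
#' @param f_cpd Spatial frequencies, cycles/degree (non-negative).
#' @param params A [csf_params()].
#' @return Non-negative sensitivities; monotone non-increasing beyond the
#'   peak frequency.
#' @export
neural_csf <- function(f_cpd, params = csf_params()) {
  if (any(f_cpd < 0)) fail_validation("spatial frequency must be non-negative")
  s <- rep(params$floor_frac, length(f_cpd))
  pos <- f_cpd > 0
  lp <- exp(-(log2(f_cpd[pos] / params$peak_cpd))^2 /
              (2 * params$bandwidth_oct^2))
  below <- f_cpd[pos] < params$peak_cpd
  lp[below] <- pmax(lp[below], params$floor_frac)
  s[pos] <- lp
  dim(s) <- dim(f_cpd)
  params$gain * s
}

# CSF-weighted quadrature weights over the frequency disk |f| <= cutoff, in
# unshifted FFT order.  Shared by the reference vsotf() and the compiled
# through-focus sweep.
csf_weight_matrix <- function(grid, pupil_diameter_mm, csf, cutoff_cpd) {
  d_freq <- otf_freq_step_cpd(pupil_diameter_mm, grid)
  f <- fft_frequencies(grid$matrix_size, d_freq)
  if (max(f) < cutoff_cpd)
    fail_validation(paste0(
      "frequency grid reaches only %.1f cyc/deg but the metric integrates to ",
      "%.1f; enlarge matrix_size or reduce pupil_fill"), max(f), cutoff_cpd)
  fr <- sqrt(outer(f^2, f^2, `+`))
  w <- neural_csf(fr, csf)
  w[fr > cutoff_cpd] <- 0
  list(weights = w, d_freq_cpd = d_freq)
}

#' Visual Strehl ratio in the frequency domain (VSOTF)
#'
#' Ratio of the CSF-weighted integral of `|Re(OTF)|` to the CSF-weighted
#' integral of the diffraction-limited OTF of the same aperture, both taken
#' over the spatial-frequency disk up to `cutoff_cpd` (Cartesian quadrature
#' on the OTF grid; the area element cancels in the ratio).
#'
#' @param w A [wavefront_map()].
#' @param csf A [csf_params()]; the overall gain cancels.
#' @param cutoff_cpd Upper integration frequency, cycles/degree. Default 60
#'   (decimal acuity 2.0).
#' @return A dimensionless ratio in `(0, 1]`; 1 for an aberration-free pupil.
#' @export
vsotf <- function(w, csf = csf_params(), cutoff_cpd = 60) {
  stopifnot(inherits(w, "wavefront_map"))
  grid <- w$grid
  d_mm <- 2 * w$pupil_radius_mm
  wm <- csf_weight_matrix(grid, d_mm, csf, cutoff_cpd)$weights
  og <- compute_otf(generalized_pupil(w), grid, d_mm)
  sum(wm * abs(Re(og$otf))) / sum(wm * og$dl)
}
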