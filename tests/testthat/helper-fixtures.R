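# Shared fixtures and independent oracles, built in code at test time.

make_clean_eye <- function(pupil_diameter_mm = 4.12, id = "clean") {
  eye_record(zernike_coefficients(rep(0, 28), pupil_diameter_mm / 2),
             pupil_diameter_mm, id)
}

make_flat_lens <- function(max_radius_mm = 5, power_D = 0) {
  sagittal_profile(c(0, max_radius_mm), c(power_D, power_D),
                   meta = list(lens = sprintf("flat_%g", power_D)))
}

# Direct circular autocorrelation of the pupil, normalized at zero shift —
# the O(N^4) oracle for the FFT-based OTF.
oracle_otf_direct <- function(pupil) {
  n <- nrow(pupil)
  otf <- matrix(0 + 0i, n, n)
  idx <- 0:(n - 1)
  for (u in idx) for (v in idx) {
    shifted <- pupil[((idx - u) %% n) + 1, ((idx - v) %% n) + 1]
    otf[u + 1, v + 1] <- sum(pupil * Conj(shifted))
  }
  otf / Re(otf[1, 1])
}

# CSF-weighted frequency quadrature written out from first principles,
# independent of csf_weight_matrix().
oracle_vsotf <- function(w, csf = csf_params(), cutoff = 60) {
  g <- w$grid
  n <- g$matrix_size
  p <- generalized_pupil(w)
  otf <- oracle_otf_direct(p)
  dl <- oracle_otf_direct(Mod(p) + 0i)
  dx_um <- 2 * w$pupil_radius_mm * 1000 / (g$pupil_fill * n)
  dnu <- dx_um / (g$wavelength_nm / 1000) * pi / 180
  f <- (((0:(n - 1) + n / 2) %% n) - n / 2) * dnu
  fr <- sqrt(outer(f^2, f^2, "+"))
  wt <- neural_csf(fr, csf)
  wt[fr > cutoff] <- 0
  sum(wt * abs(Re(otf))) / sum(wt * Re(dl))
}

# Defocus-only wavefront of a given power over a given pupil.
defocus_wavefront <- function(power_D, pupil_diameter_mm, grid) {
  r <- pupil_diameter_mm / 2
  z <- zernike_coefficients(
    c(`4` = defocus_coeff_from_diopters(power_D, r)), r)
  wavefront_from_coeffs(z, grid)
}

write_temp_profile <- function(lines) {
  path <- withr_local_tempfile()
  writeLines(lines, path)
  path
}

# minimal local tempfile helper (cleaned up by R's tempdir teardown)
withr_local_tempfile <- function() tempfile(fileext = ".csv")
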