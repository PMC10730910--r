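#' Default through-focus vergence grid
#'
#' 193 equally spaced defocus-demand samples spanning -1.00 to +5.00 D
#' inclusive (step 6/192 = 0.03125 D), guaranteeing that 0.00 D is sampled
#' exactly.
#'
#' @return Numeric vector of length 193.
#' @export
default_vergence_grid <- function() {
  -1 + (0:192) * (6 / 192)
}

DEFAULT_RANGE_WEIGHT_D <- 6 / 193

is_default_grid <- function(v) {
  length(v) == 193L && abs(v[1] + 1) < 1e-9 && abs(v[193] - 5) < 1e-9 &&
    max(abs(diff(v) - 6 / 192)) < 1e-9
}

#' Through-focus VSOTF curve
#'
#' Container for VSOTF values over a vergence (defocus-demand) grid.
#'
#' @param vergences_D Strictly increasing vergence samples, diopters.
#' @param values VSOTF at each sample.
#' @param meta Named list of metadata (lens label, eye id, applied shift, ...).
#' @return An object of class `through_focus_curve`.
#' @export
through_focus_curve <- function(vergences_D, values, meta = list()) {
  if (length(vergences_D) != length(values) || length(values) < 1L)
    fail_validation("vergences and values must be non-empty and congruent")
  if (any(diff(vergences_D) <= 0))
    fail_validation("vergences must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1 + 1e-6))
    fail_validation("VSOTF values must be finite and lie in [0, 1]")
  structure(list(vergences_D = vergences_D, values = values, meta = meta),
            class = "through_focus_curve")
}

#' @export
print.through_focus_curve <- function(x, ...) {
  pk <- peak_performance(x)
  cat(sprintf(
    "<through_focus_curve> %s%s: %d samples on [%.2f, %.2f] D; peak %.3f at %+.3f D\n",
    x$meta$lens %||% "curve",
    if (is.null(x$meta$eye_id)) "" else sprintf(" / eye %s", x$meta$eye_id),
    length(x$values), min(x$vergences_D), max(x$vergences_D),
    pk$peak, pk$vergence_D))
  invisible(x)
}

#' @export
plot.through_focus_curve <- function(x, threshold = 0.12, ...) {
  graphics::plot(x$vergences_D, x$values, type = "l",
                 xlab = "Defocus demand (D)", ylab = "VSOTF",
                 ylim = c(0, 1), ...)
  graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}

#' Through-focus VSOTF sweep of a multifocal assembly
#'
#' Evaluates the VSOTF of `W_T + w(d)` for every vergence `d` of the grid,
#' where `w(d)` is the defocus wavefront of the demanded object vergence over
#' the assembly aperture.  The vergence axis follows the clinical
#' defocus-curve convention: positive `d` is near demand (an object at
#' vergence `-d`), so a lens zone with sagittal power `+A` peaks near
#' `d = +A`.  An equivalent-sphere `shift_D` is applied as extra defocus in
#' every evaluation (true optical re-evaluation, not curve interpolation).
#'
#' @param assembly A `multifocal_assembly` from
#'   [build_multifocal_wavefront()] or [combine_with_eye()].
#' @param vergences_D Vergence grid; default [default_vergence_grid()].
#' @param csf A [csf_params()].
#' @param shift_D Equivalent-sphere shift to apply, diopters. Default 0.
#' @param cutoff_cpd Upper integration frequency of the metric. Default 60.
#' @return A [through_focus_curve()].
#' @export
through_focus <- function(assembly, vergences_D = default_vergence_grid(),
                          csf = csf_params(), shift_D = 0, cutoff_cpd = 60) {
  stopifnot(inherits(assembly, "multifocal_assembly"))
  w <- assembly$wavefront
  grid <- w$grid
  R <- assembly$aperture_radius_mm
  geo <- pupil_geometry(grid, R)
  opd <- w$opd
  opd[is.na(opd)] <- 0
  defu <- sqrt(3) * (2 * pmin(geo$rho_mm / R, 1)^2 - 1)
  defu[!geo$mask] <- 0
  # demanded vergence d and shift enter as one combined defocus coefficient
  c20 <- defocus_coeff_from_diopters(shift_D - vergences_D, R)
  wm <- csf_weight_matrix(grid, 2 * R, csf, cutoff_cpd)
  n <- grid$matrix_size
  r_keep <- min(floor(cutoff_cpd / wm$d_freq_cpd) + 1, n / 2 - 1)
  keep <- c(1:(r_keep + 1), (n - r_keep + 1):n)
  vals <- as.numeric(cpp_vsotf_sweep(opd, defu, geo$mask + 0, c20,
                          grid$wavelength_nm / 1000,
                          wm$weights[keep, , drop = FALSE],
                          as.integer(keep - 1L)))
  through_focus_curve(vergences_D, pmin(pmax(vals, 0), 1 + 1e-9),
                      meta = list(
                        lens = assembly$profile$meta$lens,
                        eye_id = if (is.null(assembly$eye)) NULL
                                 else assembly$eye$eye_id,
                        shift_D = shift_D,
                        aperture_radius_mm = R))
}

tie_broken_argmax <- function(curve) {
  mx <- max(curve$values)
  cand <- which(curve$values == mx)
  cand[which.min(abs(curve$vergences_D[cand]))]
}

#' Equivalent-sphere shift from a monofocal through-focus curve
#'
#' The shift that moves the curve's maximum to 0.00 D vergence:
#' `-vergence(argmax)`, with ties broken toward the smallest absolute
#' vergence.  Determined once per eye on the monofocal reference lens and
#' then applied uniformly to every lens evaluated on that eye.
#'
#' @param monofocal_curve A [through_focus_curve()].
#' @return Shift in diopters.
#' @export
equivalent_sphere_shift <- function(monofocal_curve) {
  stopifnot(inherits(monofocal_curve, "through_focus_curve"))
  -monofocal_curve$vergences_D[tie_broken_argmax(monofocal_curve)]
}

#' Area under a through-focus VSOTF curve
#'
#' The plain sum of the VSOTF samples (dimensionless).  A step-weighted
#' variant (`sum * 6/193` D) is attached as attribute `weighted_D`.
#'
#' @param curve A [through_focus_curve()].
#' @return The sum, with attribute `weighted_D`.
#' @export
area_under_curve <- function(curve) {
  stopifnot(inherits(curve, "through_focus_curve"))
  if (!is_default_grid(curve$vergences_D))
    warning("curve is not on the default 193-sample grid; ",
            "area computed as the literal sample sum")
  structure(sum(curve$values),
            weighted_D = sum(curve$values) * DEFAULT_RANGE_WEIGHT_D)
}

#' Through-focus range above a VSOTF threshold
#'
#' Counts the samples whose VSOTF strictly exceeds the threshold and weights
#' each by 6/193 D (samples exactly at the threshold contribute nothing).
#' The default threshold 0.12 corresponds to logMAR 0.20 visual acuity.
#'
#' @param curve A [through_focus_curve()].
#' @param threshold VSOTF threshold. Default 0.12.
#' @return Range in diopters.
#' @export
range_above_threshold <- function(curve, threshold = 0.12) {
  stopifnot(inherits(curve, "through_focus_curve"))
  wt <- if (is_default_grid(curve$vergences_D)) DEFAULT_RANGE_WEIGHT_D
        else stats::median(diff(curve$vergences_D))
  sum(curve$values > threshold) * wt
}

#' Peak performance of a through-focus curve
#'
#' @param curve A [through_focus_curve()].
#' @return List with `peak` (maximum VSOTF) and `vergence_D` (its location;
#'   ties broken toward the smallest absolute vergence).
#' @export
peak_performance <- function(curve) {
  stopifnot(inherits(curve, "through_focus_curve"))
  i <- tie_broken_argmax(curve)
  list(peak = curve$values[i], vergence_D = curve$vergences_D[i])
}

#' Through-focus comparison metrics of a curve
#'
#' Computes the three lens-comparison metrics — area under the through-focus
#' VSOTF, range above threshold, and peak performance — and optionally
#' normalizes them against a monofocal reference report.
#'
#' @param curve A [through_focus_curve()].
#' @param threshold VSOTF threshold for the range metric. Default 0.12.
#' @param reference Optional `metrics_report` of the monofocal reference; if
#'   given, normalized percentages are attached.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(curve, threshold = 0.12, reference = NULL) {
  a <- area_under_curve(curve)
  pk <- peak_performance(curve)
  rep <- structure(list(area = as.numeric(a),
                        area_weighted_D = attr(a, "weighted_D"),
                        range_D = range_above_threshold(curve, threshold),
                        peak = pk$peak, peak_location_D = pk$vergence_D,
                        threshold = threshold, normalized = NULL,
                        meta = curve$meta),
                   class = "metrics_report")
  if (!is.null(reference)) rep <- normalize_to_monofocal(rep, reference)
  rep
}

#' Normalize a metrics report against a monofocal reference
#'
#' Expresses area, range and peak as percentages of the reference values
#' (100 x metric / reference metric).
#'
#' @param m A `metrics_report`.
#' @param ref The monofocal reference `metrics_report`.
#' @return `m` with a `normalized` list (`area_pct`, `range_pct`,
#'   `peak_pct`).
#' @export
normalize_to_monofocal <- function(m, ref) {
  stopifnot(inherits(m, "metrics_report"), inherits(ref, "metrics_report"))
  if (ref$area <= 0 || ref$range_D <= 0 || ref$peak <= 0)
    fail_validation("monofocal reference metrics must all be positive for normalization")
  m$normalized <- list(area_pct = 100 * m$area / ref$area,
                       range_pct = 100 * m$range_D / ref$range_D,
                       peak_pct = 100 * m$peak / ref$peak)
  m
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> %s%s\n  area %.2f (%.3f D-weighted), range > %.2f: %.3f D, peak %.3f at %+.3f D\n",
    x$meta$lens %||% "curve",
    if (is.null(x$meta$eye_id)) "" else sprintf(" / eye %s", x$meta$eye_id),
    x$area, x$area_weighted_D, x$threshold, x$range_D, x$peak,
    x$peak_location_D))
  if (!is.null(x$normalized))
    cat(sprintf("  vs monofocal: area %.1f%%, range %.1f%%, peak %.1f%%\n",
                x$normalized$area_pct, x$normalized$range_pct,
                x$normalized$peak_pct))
  invisible(x)
}

#' Write a through-focus curve as delimited text
#'
#' @param curve A [through_focus_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "through_focus_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("lens", "eye_id", "shift_D", "aperture_radius_mm")) {
    if (!is.null(curve$meta[[k]]))
      writeLines(sprintf("# %s=%s", k, format(curve$meta[[k]], digits = 10)), con)
  }
  writeLines("vergence_D,vsotf", con)
  writeLines(sprintf("%s,%s",
                     formatC(curve$vergences_D, digits = 10, format = "g"),
                     formatC(curve$values, digits = 10, format = "g")), con)
  invisible(path)
}

#' Read a through-focus curve written by [write_curve()]
#'
#' @param path Path to the curve file.
#' @return A [through_focus_curve()].
#' @export
read_curve <- function(path) {
  parsed <- read_commented_csv(path)
  df <- parsed$data
  if (!all(c("vergence_D", "vsotf") %in% names(df)))
    fail_validation("curve file must have columns vergence_D, vsotf")
  meta <- parsed$meta
  for (k in c("shift_D", "aperture_radius_mm"))
    if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(meta[[k]])
  through_focus_curve(as.numeric(df$vergence_D), as.numeric(df$vsotf), meta)
}

#' Write a metrics report as JSON
#'
#' @param m A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(m, path) {
  stopifnot(inherits(m, "metrics_report"))
  jsonlite::write_json(unclass(m), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
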