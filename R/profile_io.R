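# Shared reader for the package's delimited-text dialect: comma-separated,
# "." decimal separator, "#"-prefixed "key=value" metadata lines, mandatory
# header row.  NIMO-class exports vary between installations; a single
# canonical dialect is safer than dialect sniffing.
read_commented_csv <- function(path) {
  if (!file.exists(path)) fail_validation("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      kv <- strsplit(body, "=", fixed = TRUE)[[1]]
      meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  keep <- !is_meta & nzchar(trimws(lines))
  if (sum(keep) < 1L) fail_validation("no data rows in %s", path)
  df <- read.csv(text = paste(lines[keep], collapse = "\n"),
                 header = TRUE, stringsAsFactors = FALSE)
  list(data = df, meta = meta, line_numbers = which(keep)[-1])
}

#' Sagittal power profile of a lens
#'
#' Radial samples of the sagittal (axial) power of a lens, as produced by
#' phase-shifting Schlieren metrology: a radial coordinate in millimetres
#' (0 at the lens centre) and the local power in diopters.
#'
#' @param radii_mm Strictly increasing radial coordinates, mm, first >= 0.
#' @param powers_D Sagittal power at each radius, diopters.
#' @param meta Optional named list of metadata (lens label, nominal base
#'   power, nominal addition, ...).
#' @return An object of class `sagittal_profile`.
#' @export
sagittal_profile <- function(radii_mm, powers_D, meta = list()) {
  if (!is.numeric(radii_mm) || !is.numeric(powers_D))
    fail_validation("radii and powers must be numeric")
  if (length(radii_mm) != length(powers_D))
    fail_validation("radii and powers must have equal length")
  if (length(radii_mm) < 2L)
    fail_validation("a profile needs at least 2 samples")
  if (any(!is.finite(radii_mm)) || any(!is.finite(powers_D)))
    fail_validation("profile samples must be finite")
  if (radii_mm[1] < 0) fail_validation("radii must start at or above 0")
  if (any(diff(radii_mm) <= 0))
    fail_validation("radii must be strictly increasing (duplicate or unsorted radius)")
  meta$sampling_per_mm <- meta$sampling_per_mm %||%
    ((length(radii_mm) - 1) / diff(range(radii_mm)))
  structure(list(radii_mm = radii_mm, powers_D = powers_D, meta = meta),
            class = "sagittal_profile")
}

#' @export
print.sagittal_profile <- function(x, ...) {
  cat(sprintf(
    "<sagittal_profile> %s: %d samples over %.2f-%.2f mm, power %.2f to %.2f D\n",
    x$meta$lens %||% "unnamed lens", length(x$radii_mm),
    min(x$radii_mm), max(x$radii_mm), min(x$powers_D), max(x$powers_D)))
  invisible(x)
}

#' Read a sagittal power profile from delimited text
#'
#' Expects comma-separated columns `radius_mm` and `power_D` after optional
#' `#`-prefixed metadata lines (`# lens=`, `# base_power_D=`,
#' `# addition_D=`).  Rows are sorted by radius; duplicate radii are
#' rejected.
#'
#' @param path Path to the profile file.
#' @return A [sagittal_profile()].
#' @examples
#' read_profile(system.file("extdata", "example_center_near.csv",
#'                          package = "segwave"))
#' @export
read_profile <- function(path) {
  parsed <- read_commented_csv(path)
  df <- parsed$data
  if (!all(c("radius_mm", "power_D") %in% names(df)))
    fail_validation("profile %s must have columns radius_mm, power_D", path)
  r <- suppressWarnings(as.numeric(df$radius_mm))
  p <- suppressWarnings(as.numeric(df$power_D))
  bad <- which(is.na(r) | is.na(p))
  if (length(bad))
    fail_validation("non-numeric profile row at line %d of %s",
                    parsed$line_numbers[bad[1]], path)
  o <- order(r)
  meta <- parsed$meta
  for (k in c("base_power_D", "addition_D")) {
    if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(meta[[k]])
  }
  sagittal_profile(r[o], p[o], meta)
}

#' Write a sagittal power profile as delimited text
#'
#' @param p A [sagittal_profile()].
#' @param path Output path.
#' @param digits Significant digits used for the numeric columns.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path, digits = 10) {
  stopifnot(inherits(p, "sagittal_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("lens", "base_power_D", "addition_D")) {
    if (!is.null(p$meta[[k]]))
      writeLines(sprintf("# %s=%s", k, format(p$meta[[k]], digits = digits)), con)
  }
  writeLines("radius_mm,power_D", con)
  writeLines(sprintf("%s,%s",
                     formatC(p$radii_mm, digits = digits, format = "g"),
                     formatC(p$powers_D, digits = digits, format = "g")), con)
  invisible(path)
}

#' Remove the base (distance) correction from a profile
#'
#' Subtracts the nominal distance prescription from every sample so that only
#' the multifocal structure of the profile remains; the removal is recorded
#' in the metadata.
#'
#' @param p A [sagittal_profile()].
#' @param base_D Base power to remove, diopters.
#' @return A [sagittal_profile()] with `powers_D - base_D`.
#' @export
remove_base_power <- function(p, base_D) {
  stopifnot(inherits(p, "sagittal_profile"))
  if (!is.numeric(base_D) || length(base_D) != 1L || !is.finite(base_D))
    fail_validation("base_D must be a single finite number")
  meta <- p$meta
  meta$base_removed_D <- (meta$base_removed_D %||% 0) + base_D
  sagittal_profile(p$radii_mm, p$powers_D - base_D, meta)
}

#' Representative power of one annular zone of a profile
#'
#' Returns the power assigned to zone `l` of `n` equal-width annuli covering
#' the aperture `[0, R]`: the mean of the profile samples whose radius falls
#' in `[R l / n, R (l + 1) / n)` (last zone closed at `R`), or, if the
#' annulus contains no sample, the linear interpolation of the profile at the
#' annulus midpoint.
#'
#' @param p A [sagittal_profile()].
#' @param l Zone index, `0 <= l <= n - 1`.
#' @param n Zone count, `n >= 1`.
#' @param R_mm Aperture radius, must not exceed the measured radius (clamp
#'   via the min-aperture rule first if it does).
#' @return Zone power in diopters.
#' @export
power_at_annulus <- function(p, l, n, R_mm) {
  stopifnot(inherits(p, "sagittal_profile"))
  if (n < 1 || n != round(n)) fail_validation("zone count n must be a positive integer")
  if (l < 0 || l > n - 1 || l != round(l))
    fail_validation("zone index l must satisfy 0 <= l <= n - 1")
  if (R_mm > max(p$radii_mm) * (1 + 1e-9))
    fail_validation(paste0(
      "aperture radius %.3f mm exceeds the measured lens radius %.3f mm; ",
      "clamp it with the min-aperture rule (see combine_with_eye)"),
      R_mm, max(p$radii_mm))
  lo <- R_mm * l / n
  hi <- R_mm * (l + 1) / n
  sel <- if (l == n - 1) p$radii_mm >= lo & p$radii_mm <= hi * (1 + 1e-12)
         else p$radii_mm >= lo & p$radii_mm < hi
  if (any(sel)) return(mean(p$powers_D[sel]))
  approx(p$radii_mm, p$powers_D, xout = (lo + hi) / 2, rule = 2)$y
}

#' Single-eye aberration record
#'
#' @param zernikes A [zernike_coefficients()] describing the eye's wavefront
#'   over its measurement pupil.
#' @param pupil_diameter_mm Pupil diameter at measurement, mm.
#' @param eye_id Label.
#' @return An object of class `eye_record`.
#' @export
eye_record <- function(zernikes, pupil_diameter_mm, eye_id = "eye") {
  stopifnot(inherits(zernikes, "zernike_coefficients"))
  if (!is.numeric(pupil_diameter_mm) || length(pupil_diameter_mm) != 1L ||
      pupil_diameter_mm <= 0)
    fail_validation("pupil_diameter_mm must be positive")
  if (abs(zernikes$pupil_radius_mm - pupil_diameter_mm / 2) > 1e-9)
    fail_validation("zernike pupil radius must equal half the pupil diameter")
  structure(list(zernikes = zernikes, pupil_diameter_mm = pupil_diameter_mm,
                 eye_id = as.character(eye_id)),
            class = "eye_record")
}

#' @export
print.eye_record <- function(x, ...) {
  cat(sprintf("<eye_record> %s: pupil %.2f mm, %d non-zero Zernike term(s)\n",
              x$eye_id, x$pupil_diameter_mm, sum(x$zernikes$coeffs != 0)))
  invisible(x)
}

#' Read a table of per-eye Zernike coefficients
#'
#' Expects comma-separated columns `eye_id`, `pupil_diameter_mm`, then
#' OSA-indexed coefficient columns `z0 ... z27` (micrometres).  Missing
#' coefficient columns are treated as zero.
#'
#' @param path Path to the table.
#' @return A list of [eye_record()] objects.
#' @examples
#' eyes <- read_eye_table(system.file("extdata", "example_eyes.csv",
#'                                    package = "segwave"))
#' eyes[[1]]
#' @export
read_eye_table <- function(path) {
  parsed <- read_commented_csv(path)
  df <- parsed$data
  if (!all(c("eye_id", "pupil_diameter_mm") %in% names(df)))
    fail_validation("eye table must have columns eye_id, pupil_diameter_mm")
  zcols <- grep("^z[0-9]+$", names(df), value = TRUE)
  lapply(seq_len(nrow(df)), function(i) {
    d <- as.numeric(df$pupil_diameter_mm[i])
    if (!is.finite(d) || d <= 0)
      fail_validation("non-positive pupil diameter for eye %s", df$eye_id[i])
    cf <- rep(0, 28L)
    names(cf) <- as.character(0:27)
    for (zc in zcols) {
      j <- sub("^z", "", zc)
      cf[[j]] <- as.numeric(df[[zc]][i])
    }
    eye_record(zernike_coefficients(cf, d / 2), d, df$eye_id[i])
  })
}

#' Write a table of per-eye Zernike coefficients
#'
#' Counterpart of [read_eye_table()]; writes all 28 OSA coefficients through
#' order 6.
#'
#' @param eyes List of [eye_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eye_table <- function(eyes, path) {
  rows <- vapply(eyes, function(e) {
    cf <- rep(0, 28L)
    names(cf) <- as.character(0:27)
    cf[names(e$zernikes$coeffs)] <- e$zernikes$coeffs
    paste(c(e$eye_id, formatC(e$pupil_diameter_mm, digits = 10, format = "g"),
            formatC(cf, digits = 10, format = "g")), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("eye_id", "pupil_diameter_mm", paste0("z", 0:27)),
                     collapse = ","), rows), path)
  invisible(path)
}
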