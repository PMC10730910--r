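#' Run configuration
#'
#' Bundles every tunable constant of a simulation run.  The `fast` profile
#' drops the grid to 128 x 128 pixels and caps the zone count, for
#' continuous-integration and desk-scale runs.
#'
#' @param matrix_size Grid side in pixels. Default 512.
#' @param pupil_fill Fraction of the grid side spanned by the pupil. Default
#'   0.25.
#' @param wavelength_nm Wavelength, nm. Default 555.
#' @param csf A [csf_params()].
#' @param threshold VSOTF threshold of the range metric, in (0, 1). Default
#'   0.12.
#' @param cutoff_cpd Upper integration frequency, cycles/degree. Default 60.
#' @param vergences_D Through-focus grid. Default [default_vergence_grid()].
#' @param n_zones Zone-count cap (`NULL` = one zone per profile sample).
#' @param seed Seed for synthetic generation. Default 1.
#' @param fast If `TRUE`, use the reduced-resolution profile (matrix 128,
#'   zone count capped at 64).
#' @return An object of class `run_config`.
#' @export
run_config <- function(matrix_size = 512L, pupil_fill = 0.25,
                       wavelength_nm = 555, csf = csf_params(),
                       threshold = 0.12, cutoff_cpd = 60,
                       vergences_D = default_vergence_grid(), n_zones = NULL,
                       seed = 1L, fast = FALSE) {
  if (threshold <= 0 || threshold >= 1)
    fail_validation("threshold must lie in (0, 1)")
  if (isTRUE(fast)) {
    matrix_size <- 128L
    n_zones <- min(n_zones %||% 64L, 64L)
  }
  structure(list(grid = grid_spec(matrix_size, pupil_fill, wavelength_nm),
                 csf = csf, threshold = threshold, cutoff_cpd = cutoff_cpd,
                 vergences_D = vergences_D, n_zones = n_zones,
                 seed = as.integer(seed), fast = isTRUE(fast)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Any key omitted from the file keeps its [run_config()] default.
#' Recognized keys: `matrix_size`, `pupil_fill`, `wavelength_nm`,
#' `threshold`, `cutoff_cpd`, `n_zones`, `seed`, `fast`, and a nested `csf`
#' block (`gain`, `peak_cpd`, `bandwidth_oct`, `floor_frac`).
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) fail_validation("config file not found: %s", path)
  y <- yaml::read_yaml(path) %||% list()
  csf <- do.call(csf_params, y$csf %||% list())
  args <- y[intersect(names(y), c("matrix_size", "pupil_fill",
                                  "wavelength_nm", "threshold", "cutoff_cpd",
                                  "n_zones", "seed", "fast"))]
  do.call(run_config, c(args, list(csf = csf)))
}

#' Write a study-scale synthetic fixture set to disk
#'
#' Generates a [generate_study_batch()] and writes the 36 multifocal profile
#' files, the monofocal control, the eye table and a JSON manifest recording
#' the seed and file list.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param n_eyes Number of eyes. Default 65.
#' @return Invisibly, the manifest as a list.
#' @export
simulate_fixtures <- function(out_dir, seed = 1L, n_eyes = 65L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  batch <- generate_study_batch(seed, n_eyes)
  files <- character(0)
  for (nm in names(batch$profiles)) {
    f <- file.path(out_dir, paste0("profile_", nm, ".csv"))
    write_profile(batch$profiles[[nm]], f)
    files <- c(files, basename(f))
  }
  mono_f <- file.path(out_dir, "profile_monofocal.csv")
  write_profile(batch$monofocal, mono_f)
  eye_f <- file.path(out_dir, "eyes.csv")
  write_eye_table(batch$eyes, eye_f)
  manifest <- list(seed = seed, n_eyes = n_eyes,
                   n_multifocal_profiles = length(batch$profiles),
                   profiles = files, monofocal = basename(mono_f),
                   eye_table = basename(eye_f))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Base-correction removal driven by profile metadata; a no-op when no base
# is recorded or it was already removed.
strip_base <- function(p) {
  b <- p$meta$base_power_D %||% 0
  already <- p$meta$base_removed_D %||% 0
  if (b == 0 || already != 0) return(p)
  remove_base_power(p, b)
}

#' Evaluate a set of lens profiles against a population of eyes
#'
#' The full pipeline: for every eye, the monofocal reference lens is swept
#' through focus to determine the eye's equivalent-sphere shift (the shift
#' that centres the monofocal peak at 0.00 D); the monofocal curve is then
#' re-evaluated with that shift, and every multifocal profile is swept with
#' the same shift applied.  Base corrections recorded in the profile
#' metadata are removed before any computation, so the comparison isolates
#' the multifocal structure of each profile.  The effective aperture chosen
#' per (lens, eye) pair is the min of pupil and measured lens radius and is
#' recorded in each curve's metadata.
#'
#' @param profiles List of [sagittal_profile()]s (multifocal lenses).
#' @param eyes List of [eye_record()]s.
#' @param config A [run_config()].
#' @param monofocal Monofocal reference [sagittal_profile()]; `NULL` builds
#'   an ideal flat 0 D control over the first profile's measured radius.
#' @param keep_curves Keep all curves in the result (default `TRUE`).
#' @param progress Print one line per eye.
#' @return A list of class `batch_result`: `results` (one row per lens-eye
#'   pair with raw and monofocal-normalized metrics), `monofocal_results`,
#'   `curves`, `monofocal_curves`, `shifts`, `config`.
#' @export
evaluate_batch <- function(profiles, eyes, config = run_config(),
                           monofocal = NULL, keep_curves = TRUE,
                           progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(profiles, "sagittal_profile")) profiles <- list(profiles)
  if (inherits(eyes, "eye_record")) eyes <- list(eyes)
  if (!length(profiles) || !length(eyes))
    fail_validation("need at least one profile and one eye")
  profiles <- lapply(profiles, strip_base)
  if (is.null(monofocal)) {
    rmax <- max(profiles[[1]]$radii_mm)
    monofocal <- sagittal_profile(c(0, rmax), c(0, 0),
                                  meta = list(lens = "monofocal"))
  } else {
    monofocal <- strip_base(monofocal)
  }
  lens_names <- names(profiles) %||%
    vapply(profiles, function(p) p$meta$lens %||% "lens", character(1))
  rows <- list()
  mono_rows <- list()
  curves <- list()
  mono_curves <- list()
  shifts <- numeric(length(eyes))
  for (i in seq_along(eyes)) {
    eye <- eyes[[i]]
    mono_asm <- combine_with_eye(monofocal, eye, config$grid, config$n_zones)
    pre <- through_focus(mono_asm, config$vergences_D, config$csf,
                         shift_D = 0, cutoff_cpd = config$cutoff_cpd)
    sh <- equivalent_sphere_shift(pre)
    shifts[i] <- sh
    mono_curve <- through_focus(mono_asm, config$vergences_D, config$csf,
                                shift_D = sh, cutoff_cpd = config$cutoff_cpd)
    mono_rep <- metrics_report(mono_curve, config$threshold)
    mono_rows[[i]] <- data.frame(
      eye_id = eye$eye_id, pupil_diameter_mm = eye$pupil_diameter_mm,
      shift_D = sh, area = mono_rep$area, range_D = mono_rep$range_D,
      peak = mono_rep$peak, peak_location_D = mono_rep$peak_location_D,
      stringsAsFactors = FALSE)
    if (keep_curves) mono_curves[[eye$eye_id]] <- mono_curve
    for (k in seq_along(profiles)) {
      asm <- combine_with_eye(profiles[[k]], eye, config$grid, config$n_zones)
      cv <- through_focus(asm, config$vergences_D, config$csf,
                          shift_D = sh, cutoff_cpd = config$cutoff_cpd)
      rep <- metrics_report(cv, config$threshold, reference = mono_rep)
      rows[[length(rows) + 1L]] <- data.frame(
        lens = lens_names[k], eye_id = eye$eye_id,
        pupil_diameter_mm = eye$pupil_diameter_mm,
        aperture_radius_mm = asm$aperture_radius_mm, shift_D = sh,
        area = rep$area, range_D = rep$range_D, peak = rep$peak,
        peak_location_D = rep$peak_location_D,
        norm_area_pct = rep$normalized$area_pct,
        norm_range_pct = rep$normalized$range_pct,
        norm_peak_pct = rep$normalized$peak_pct,
        stringsAsFactors = FALSE)
      if (keep_curves)
        curves[[paste(lens_names[k], eye$eye_id, sep = "|")]] <- cv
    }
    if (progress)
      message(sprintf("eye %s (%d/%d): shift %+0.3f D",
                      eye$eye_id, i, length(eyes), sh))
  }
  structure(list(results = do.call(rbind, rows),
                 monofocal_results = do.call(rbind, mono_rows),
                 curves = curves, monofocal_curves = mono_curves,
                 shifts = shifts, config = config),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf(
    "<batch_result> %d multifocal curve(s) (%d lens(es) x %d eye(s)) + %d monofocal reference curve(s)\n",
    nrow(x$results), length(unique(x$results$lens)),
    nrow(x$monofocal_results), nrow(x$monofocal_results)))
  invisible(x)
}

#' Summarize a batch evaluation
#'
#' Per-lens means and SDs of the three comparison metrics across eyes, with
#' monofocal-normalized percentages (mean lens metric over mean monofocal
#' metric), plus a per-eye table of mean performance against pupil size.
#'
#' @param batch A `batch_result` from [evaluate_batch()].
#' @return A list with data frames `lens_summary` (the monofocal reference
#'   is the first row, at 100 percent by construction) and `eye_summary`.
#' @export
summarize_batch <- function(batch) {
  stopifnot(inherits(batch, "batch_result"))
  res <- batch$results
  mono <- batch$monofocal_results
  mono_mean <- c(area = mean(mono$area), range_D = mean(mono$range_D),
                 peak = mean(mono$peak))
  per_lens <- lapply(split(res, factor(res$lens, levels = unique(res$lens))),
                     function(d) {
    data.frame(lens = d$lens[1], n_eyes = nrow(d),
               area_mean = mean(d$area), area_sd = sd(d$area),
               range_mean_D = mean(d$range_D), range_sd_D = sd(d$range_D),
               peak_mean = mean(d$peak), peak_sd = sd(d$peak),
               norm_area_pct = 100 * mean(d$area) / mono_mean[["area"]],
               norm_range_pct = 100 * mean(d$range_D) / mono_mean[["range_D"]],
               norm_peak_pct = 100 * mean(d$peak) / mono_mean[["peak"]],
               stringsAsFactors = FALSE)
  })
  mono_row <- data.frame(lens = "monofocal", n_eyes = nrow(mono),
                         area_mean = mono_mean[["area"]], area_sd = sd(mono$area),
                         range_mean_D = mono_mean[["range_D"]],
                         range_sd_D = sd(mono$range_D),
                         peak_mean = mono_mean[["peak"]], peak_sd = sd(mono$peak),
                         norm_area_pct = 100, norm_range_pct = 100,
                         norm_peak_pct = 100, stringsAsFactors = FALSE)
  lens_summary <- rbind(mono_row, do.call(rbind, per_lens))
  rownames(lens_summary) <- NULL
  per_eye <- lapply(split(res, res$eye_id), function(d) {
    data.frame(eye_id = d$eye_id[1],
               pupil_diameter_mm = d$pupil_diameter_mm[1],
               area_mean = mean(d$area), range_mean_D = mean(d$range_D),
               peak_mean = mean(d$peak), stringsAsFactors = FALSE)
  })
  eye_summary <- do.call(rbind, per_eye)
  eye_summary <- eye_summary[order(eye_summary$eye_id), ]
  rownames(eye_summary) <- NULL
  list(lens_summary = lens_summary, eye_summary = eye_summary)
}
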