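# All generator randomness flows through an explicit seed and restores the
# caller's RNG state afterwards; no hidden global state survives a call.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

LENS_DESIGNS <- c("monofocal", "center_near", "center_distance",
                  "aspheric", "concentric_bifocal")

#' Synthetic lens design specification
#'
#' Describes one of five sagittal-power morphologies observed in commercial
#' multifocal contact lenses: a constant monofocal profile, centre-near and
#' centre-distance designs (near addition inside or outside a boundary, with
#' a raised-cosine transition), an aspheric design with a monotone power ramp
#' from `base + addition` at the centre to `base` at the edge, and a
#' concentric bifocal with alternating base/near rings.
#'
#' @param design One of `"monofocal"`, `"center_near"`, `"center_distance"`,
#'   `"aspheric"`, `"concentric_bifocal"`.
#' @param base_power_D Distance prescription, diopters.
#' @param addition_D Near addition, diopters (>= 0).
#' @param zone_boundaries_mm Radial boundaries, mm, inside `(0, max_radius)`.
#'   Default 1.5 mm for centre designs, `c(1.25, 2.25, 3.25)` for the
#'   bifocal.
#' @param transition_width_mm Width of the raised-cosine transition at each
#'   boundary, mm. Default 0.25.
#' @param max_radius_mm Measured lens radius. Default 5 mm.
#' @param sampling_per_mm Radial sampling density. Default 28 points/mm, the
#'   nominal density of phase-shifting Schlieren metrology.
#' @param noise_sd_D SD of additive Gaussian measurement noise, D. Default 0.
#' @param label Lens label; defaults to the design name.
#' @param seed Seed for the noise draw; `NULL` uses the current RNG state.
#' @return An object of class `lens_design_spec`.
#' @export
lens_design_spec <- function(design, base_power_D = 0, addition_D = 0,
                             zone_boundaries_mm = NULL,
                             transition_width_mm = 0.25, max_radius_mm = 5,
                             sampling_per_mm = 28, noise_sd_D = 0,
                             label = design, seed = NULL) {
  if (!design %in% LENS_DESIGNS)
    fail_validation("unknown design '%s'; valid designs: %s",
                    design, paste(LENS_DESIGNS, collapse = ", "))
  if (addition_D < 0) fail_validation("addition_D must be >= 0")
  if (sampling_per_mm <= 0) fail_validation("sampling_per_mm must be positive")
  if (max_radius_mm <= 0) fail_validation("max_radius_mm must be positive")
  if (is.null(zone_boundaries_mm))
    zone_boundaries_mm <- if (design == "concentric_bifocal")
      c(1.25, 2.25, 3.25) else 1.5
  if (any(zone_boundaries_mm <= 0 | zone_boundaries_mm >= max_radius_mm))
    fail_validation("zone boundaries must lie inside (0, max_radius)")
  if (any(diff(zone_boundaries_mm) <= 0))
    fail_validation("zone boundaries must be strictly increasing")
  structure(list(design = design, base_power_D = base_power_D,
                 addition_D = addition_D,
                 zone_boundaries_mm = zone_boundaries_mm,
                 transition_width_mm = transition_width_mm,
                 max_radius_mm = max_radius_mm,
                 sampling_per_mm = sampling_per_mm,
                 noise_sd_D = noise_sd_D, label = label, seed = seed),
            class = "lens_design_spec")
}

# Raised-cosine step from 1 (rho << b) to 0 (rho >> b) over width t.
# t = 0 degenerates to the sharp step: 1 for rho < b, 0 for rho >= b.
cosine_ramp_down <- function(rho, b, t) {
  if (t <= 0) return(as.numeric(rho < b))
  out <- numeric(length(rho))
  out[rho <= b - t / 2] <- 1
  mid <- rho > b - t / 2 & rho < b + t / 2
  out[mid] <- 0.5 * (1 + cos(pi * (rho[mid] - b + t / 2) / t))
  out
}

#' Generate a synthetic sagittal power profile
#'
#' Deterministic given the spec's seed; see [lens_design_spec()] for the
#' design templates.
#'
#' @param spec A [lens_design_spec()].
#' @return A [sagittal_profile()].
#' @export
generate_lens_profile <- function(spec) {
  stopifnot(inherits(spec, "lens_design_spec"))
  r <- seq(0, spec$max_radius_mm, by = 1 / spec$sampling_per_mm)
  b1 <- spec$zone_boundaries_mm[1]
  t <- spec$transition_width_mm
  near_frac <- switch(spec$design,
    monofocal = numeric(length(r)),
    center_near = cosine_ramp_down(r, b1, t),
    center_distance = 1 - cosine_ramp_down(r, b1, t),
    aspheric = 1 - (r / spec$max_radius_mm)^2,
    concentric_bifocal = {
      s <- numeric(length(r))
      sign <- 1
      for (b in spec$zone_boundaries_mm) {
        s <- s + sign * (1 - cosine_ramp_down(r, b, t))
        sign <- -sign
      }
      pmin(pmax(s, 0), 1)
    })
  p <- spec$base_power_D + spec$addition_D * near_frac
  if (spec$noise_sd_D > 0)
    p <- p + with_seed(spec$seed, rnorm(length(p), 0, spec$noise_sd_D))
  sagittal_profile(r, p, meta = list(
    lens = spec$label, base_power_D = spec$base_power_D,
    addition_D = spec$addition_D, design = spec$design,
    sampling_per_mm = spec$sampling_per_mm))
}

#' Synthetic eye-population specification
#'
#' Parameters of a stand-in population of ocular wavefronts: pupil diameters
#' drawn uniformly over the stated range, and independent zero-mean Gaussian
#' Zernike coefficients with order-decaying scales over radial orders 2-5
#' plus sixth-order spherical aberration.  Fourth-order spherical aberration
#' gets a positive population mean, the dominant systematic feature of adult
#' eyes.  An equivalent-sphere refraction can be injected explicitly for
#' shift-recovery experiments.
#'
#' @param n_eyes Number of eyes. Default 65.
#' @param pupil_range_mm Pupil-diameter range, mm. Default `c(2.45, 6.27)`.
#' @param coeff_scales_um Named per-order coefficient SDs in micrometres over
#'   the measurement pupil, for orders `"2"` through `"6"`.
#' @param sa_mean_um Population mean of `c(4, 0)`, micrometres. Default 0.05.
#' @param equiv_sphere_D Optional equivalent-sphere refraction(s), diopters,
#'   recycled over eyes; injected as the matching defocus coefficient on top
#'   of the random defocus term.
#' @param seed Seed; `NULL` uses the current RNG state.
#' @return An object of class `eye_population_spec`.
#' @export
eye_population_spec <- function(n_eyes = 65L,
                                pupil_range_mm = c(2.45, 6.27),
                                coeff_scales_um = c(`2` = 0.12, `3` = 0.07,
                                                    `4` = 0.035, `5` = 0.015,
                                                    `6` = 0.008),
                                sa_mean_um = 0.05, equiv_sphere_D = NULL,
                                seed = NULL) {
  if (n_eyes < 1L) fail_validation("n_eyes must be >= 1")
  if (length(pupil_range_mm) != 2L || any(pupil_range_mm <= 1) ||
      any(pupil_range_mm >= 9) || pupil_range_mm[1] > pupil_range_mm[2])
    fail_validation("pupil_range_mm must be an increasing pair inside (1, 9) mm")
  if (!all(as.character(2:6) %in% names(coeff_scales_um)))
    fail_validation("coeff_scales_um must name orders '2' through '6'")
  structure(list(n_eyes = as.integer(n_eyes), pupil_range_mm = pupil_range_mm,
                 coeff_scales_um = coeff_scales_um, sa_mean_um = sa_mean_um,
                 equiv_sphere_D = equiv_sphere_D, seed = seed),
            class = "eye_population_spec")
}

#' Generate a synthetic eye population
#'
#' Deterministic given the spec's seed.
#'
#' @param spec An [eye_population_spec()].
#' @return A list of [eye_record()] objects.
#' @export
generate_eye_population <- function(spec = eye_population_spec()) {
  stopifnot(inherits(spec, "eye_population_spec"))
  modes <- list()
  for (n in 2:5) for (m in seq(-n, n, by = 2))
    modes[[length(modes) + 1L]] <- c(n, m)
  modes[[length(modes) + 1L]] <- c(6, 0)
  es <- if (is.null(spec$equiv_sphere_D)) rep(0, spec$n_eyes)
        else rep_len(spec$equiv_sphere_D, spec$n_eyes)
  with_seed(spec$seed, {
    pupils <- runif(spec$n_eyes, spec$pupil_range_mm[1], spec$pupil_range_mm[2])
    lapply(seq_len(spec$n_eyes), function(i) {
      cf <- rep(0, 28L)
      names(cf) <- as.character(0:27)
      for (nm in modes) {
        sc <- spec$coeff_scales_um[[as.character(nm[1])]]
        mu <- if (nm[1] == 4 && nm[2] == 0) spec$sa_mean_um else 0
        cf[[as.character(osa_index(nm[1], nm[2]))]] <- rnorm(1, mu, sc)
      }
      if (es[i] != 0) {
        j4 <- as.character(osa_index(2, 0))
        cf[[j4]] <- cf[[j4]] + defocus_coeff_from_diopters(es[i], pupils[i] / 2)
      }
      eye_record(zernike_coefficients(cf, pupils[i] / 2), pupils[i],
                 sprintf("eye%03d", i))
    })
  })
}

#' Generate a study-scale synthetic batch
#'
#' Mirrors the scale of a full lens-comparison study: 12 multifocal designs
#' spanning centre-near, centre-distance, aspheric and concentric-bifocal
#' families with low, medium and high additions, each measured at three
#' distance prescriptions (-6.00, -3.00 and +1.00 D), plus one monofocal
#' control and a 65-eye population.
#'
#' @param seed Master seed; per-profile seeds are derived from it.
#' @param n_eyes Number of eyes. Default 65.
#' @param noise_sd_D Measurement noise on each profile, D. Default 0.05.
#' @return A list with `designs` (12 design templates), `profiles` (36
#'   multifocal [sagittal_profile()]s plus the monofocal control, base
#'   corrections not yet removed), `monofocal` (the control profile), and
#'   `eyes`.
#' @export
generate_study_batch <- function(seed = 1L, n_eyes = 65L, noise_sd_D = 0.05) {
  seed <- as.integer(seed)
  fam <- list(
    cn_low   = list(design = "center_near", add = 0.75, tw = 0.50),
    cn_mid   = list(design = "center_near", add = 1.50, tw = 0.50),
    cn_high  = list(design = "center_near", add = 2.50, tw = 0.50),
    cd_low   = list(design = "center_distance", add = 0.75, tw = 0.50),
    cd_mid   = list(design = "center_distance", add = 1.50, tw = 0.50),
    cd_high  = list(design = "center_distance", add = 2.50, tw = 0.50),
    asp_low  = list(design = "aspheric", add = 0.75, tw = 0.25),
    asp_mid  = list(design = "aspheric", add = 1.50, tw = 0.25),
    asp_high = list(design = "aspheric", add = 3.00, tw = 0.25),
    bif_low  = list(design = "concentric_bifocal", add = 1.00, tw = 0.25),
    bif_mid  = list(design = "concentric_bifocal", add = 2.00, tw = 0.25),
    bif_high = list(design = "concentric_bifocal", add = 3.00, tw = 0.25))
  bases <- c(-6, -3, 1)
  designs <- lapply(names(fam), function(nm) {
    f <- fam[[nm]]
    lens_design_spec(f$design, base_power_D = 0, addition_D = f$add,
                     transition_width_mm = f$tw, noise_sd_D = noise_sd_D,
                     label = nm)
  })
  names(designs) <- names(fam)
  profiles <- list()
  k <- 0L
  for (nm in names(fam)) {
    for (b in bases) {
      k <- k + 1L
      sp <- designs[[nm]]
      sp$base_power_D <- b
      sp$label <- sprintf("%s_base%+.2f", nm, b)
      sp$seed <- (seed * 1009L + k * 31L) %% 2147483647L
      profiles[[sp$label]] <- generate_lens_profile(sp)
    }
  }
  mono_spec <- lens_design_spec("monofocal", base_power_D = -3,
                                noise_sd_D = noise_sd_D, label = "monofocal",
                                seed = (seed * 1009L + 999L) %% 2147483647L)
  mono <- generate_lens_profile(mono_spec)
  eyes <- generate_eye_population(eye_population_spec(
    n_eyes = n_eyes, seed = (seed * 2003L + 7L) %% 2147483647L))
  list(designs = designs, profiles = profiles, monofocal = mono, eyes = eyes,
       seed = seed)
}
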