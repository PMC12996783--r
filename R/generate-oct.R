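#' Generate a synthetic longitudinal OCT boundary series
#'
#' Builds one boundary volume per eye and visit. The Choroid/BrM boundary
#' is a smooth undulating surface plus axial noise; the RPE/POS boundary
#' is the BrM boundary minus the nominal layer thickness, minus the sum of
#' the active druse bumps (each an anisotropic Gaussian, see
#' [druse_seed()]), plus independent axial noise. The undulation is shared
#' by both boundaries so the drusen-free thickness stays at
#' `nominal_thickness_um` in expectation.
#'
#' @param spec An [oct_study_spec()].
#' @param seeds List of [druse_seed()] objects (may be empty).
#' @return A list of class `oct_series` with elements
#'   * `volumes`: flat list of `boundary_volume` objects (one per
#'     eye x visit), each with matrices `rpe_pos_depth_um` and
#'     `brm_depth_um` indexed `[bscan, ascan]`;
#'   * `truth`: tibble with one row per druse per visit recording the
#'     analytic peak amplitude and geometry (`druse_id, eye_id, arm,
#'     timepoint_months, center_bscan, center_ascan, sigma_bscan_um,
#'     sigma_ascan_um, amplitude_um`);
#'   * `spec`: the input spec.
#' @export
generate_oct_series <- function(spec, seeds = list()) {
  stopifnot(inherits(spec, "oct_study_spec"))
  if (inherits(seeds, "druse_seed")) seeds <- list(seeds)
  ids <- eye_ids(spec)
  arms <- eye_arms(spec)
  for (s in seeds) {
    if (!s$eye_id %in% ids) {
      abort(sprintf("druse seed '%s': unknown eye_id '%s'.", s$druse_id, s$eye_id))
    }
    if (s$center_bscan < 1 || s$center_bscan > spec$n_bscans ||
        s$center_ascan < 1 || s$center_ascan > spec$n_ascans) {
      abort(sprintf("druse seed '%s' lies outside the volume grid.", s$druse_id))
    }
    extra <- setdiff(names(s$amplitude_by_timepoint),
                     as.character(spec$timepoints_months))
    if (length(extra)) {
      abort(sprintf("druse seed '%s' has amplitudes at unknown timepoints: %s.",
                    s$druse_id, paste(extra, collapse = ", ")))
    }
  }

  nb <- spec$n_bscans; na <- spec$n_ascans
  x_um <- (seq_len(na) - 1) * spec$ascan_spacing_um   # lateral position
  y_um <- (seq_len(nb) - 1) * spec$bscan_spacing_um
  und <- spec$undulation_amplitude_um *
    (outer(rep(1, nb), sin(2 * pi * x_um / spec$undulation_wavelength_um)) +
       0.5 * outer(sin(2 * pi * y_um / (1.7 * spec$undulation_wavelength_um)),
                   rep(1, na)))
  base_depth <- 300  # arbitrary posterior reference depth, um

  withr::with_seed(spec$rng_seed, {
    volumes <- list()
    truth <- list()
    for (eye in ids) {
      eye_seeds <- Filter(function(s) s$eye_id == eye, seeds)
      for (tp in spec$timepoints_months) {
        bump <- matrix(0, nb, na)
        for (s in eye_seeds) {
          amp <- s$amplitude_by_timepoint[as.character(tp)]
          amp <- if (is.na(amp)) 0 else unname(amp)
          truth[[length(truth) + 1L]] <- tibble(
            druse_id = s$druse_id, eye_id = eye, arm = unname(arms[eye]),
            timepoint_months = tp,
            center_bscan = s$center_bscan, center_ascan = s$center_ascan,
            sigma_bscan_um = s$sigma_bscan_um, sigma_ascan_um = s$sigma_ascan_um,
            amplitude_um = amp)
          if (amp > 0) {
            bump <- bump + amp * outer(
              exp(-0.5 * ((y_um - (s$center_bscan - 1) * spec$bscan_spacing_um) /
                            s$sigma_bscan_um)^2),
              exp(-0.5 * ((x_um - (s$center_ascan - 1) * spec$ascan_spacing_um) /
                            s$sigma_ascan_um)^2))
          }
        }
        brm <- base_depth + und +
          matrix(rnorm(nb * na, 0, spec$axial_noise_sd_um), nb, na)
        rpe <- base_depth + und - spec$nominal_thickness_um - bump +
          matrix(rnorm(nb * na, 0, spec$axial_noise_sd_um), nb, na)
        volumes[[length(volumes) + 1L]] <- structure(
          list(eye_id = eye, arm = unname(arms[eye]), timepoint_months = tp,
               rpe_pos_depth_um = rpe, brm_depth_um = brm,
               bscan_spacing_um = spec$bscan_spacing_um,
               ascan_spacing_um = spec$ascan_spacing_um,
               axial_noise_sd_um = spec$axial_noise_sd_um),
          class = "boundary_volume")
      }
    }
    truth <- if (length(truth)) bind_rows(truth) else
      tibble(druse_id = character(), eye_id = character(), arm = character(),
             timepoint_months = numeric(), center_bscan = integer(),
             center_ascan = integer(), sigma_bscan_um = numeric(),
             sigma_ascan_um = numeric(), amplitude_um = numeric())
    structure(list(volumes = volumes, truth = truth, spec = spec),
              class = "oct_series")
  })
}

#' @export
print.boundary_volume <- function(x, ...) {
  cat(sprintf("<boundary_volume> eye %s (%s), month %s: %d B-scans x %d A-scans\n",
              x$eye_id, x$arm, format(x$timepoint_months),
              nrow(x$brm_depth_um), ncol(x$brm_depth_um)))
  invisible(x)
}

#' Draw random druse seeds for a two-arm growth study
#'
#' Places `n_per_eye` drusen per eye at random grid locations (kept away
#' from volume edges and at least `min_separation_um` apart), draws
#' baseline peak amplitudes uniformly from `amplitude_range_um`, and lets
#' each druse grow or shrink geometrically: the amplitude at month t is
#' `A0 * g^(t/3)` where `g` is the arm's per-3-month growth multiplier.
#' Optionally a fraction of drusen appear only after baseline (amplitude 0
#' at baseline) or disappear mid-study, emulating the small drusen that
#' come and go between visits.
#'
#' @param spec An [oct_study_spec()].
#' @param n_per_eye Drusen per eye.
#' @param amplitude_range_um Range of baseline peak amplitudes, um.
#' @param growth_by_arm Named vector, arm -> per-3-month multiplier.
#' @param appear_fraction,disappear_fraction Fractions of drusen that are
#'   absent at baseline (appear at the second visit) or vanish from the
#'   third visit onward.
#' @param min_separation_um Minimum pairwise physical distance between
#'   druse centers within an eye.
#' @param seed Integer seed for this draw.
#' @return List of [druse_seed()] objects.
#' @export
random_druse_seeds <- function(spec, n_per_eye = 10,
                               amplitude_range_um = c(15, 60),
                               growth_by_arm = NULL,
                               appear_fraction = 0,
                               disappear_fraction = 0,
                               min_separation_um = 500,
                               seed = 1L) {
  stopifnot(inherits(spec, "oct_study_spec"))
  if (is.null(growth_by_arm)) {
    growth_by_arm <- stats::setNames(rep(1, length(spec$arms)), spec$arms)
  }
  if (!all(spec$arms %in% names(growth_by_arm))) {
    abort("`growth_by_arm` must name every arm.")
  }
  tps <- spec$timepoints_months
  arms <- eye_arms(spec)
  b_margin <- 4L; a_margin <- 40L
  withr::with_seed(seed, {
    seeds <- list()
    for (eye in eye_ids(spec)) {
      g <- growth_by_arm[[arms[eye]]]
      centers <- matrix(numeric(0), 0, 2)
      k <- 0L; tries <- 0L
      while (k < n_per_eye && tries < 10000L) {
        tries <- tries + 1L
        cb <- sample(seq(b_margin + 1L, spec$n_bscans - b_margin), 1)
        ca <- sample(seq(a_margin + 1L, spec$n_ascans - a_margin), 1)
        pos <- c(cb * spec$bscan_spacing_um, ca * spec$ascan_spacing_um)
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums(sweep(centers, 2, pos)^2))) >= min_separation_um) {
          centers <- rbind(centers, pos)
          k <- k + 1L
          a0 <- runif(1, amplitude_range_um[1], amplitude_range_um[2])
          amp <- a0 * g^(tps / 3)
          if (runif(1) < appear_fraction) amp[1] <- 0
          if (runif(1) < disappear_fraction && length(tps) > 2) {
            amp[seq(3, length(tps))] <- 0
          }
          names(amp) <- as.character(tps)
          seeds[[length(seeds) + 1L]] <- druse_seed(
            druse_id = sprintf("%s_d%02d", eye, k), eye_id = eye,
            center_bscan = cb, center_ascan = ca,
            amplitude_by_timepoint = amp)
        }
      }
      if (k < n_per_eye) {
        abort("could not place drusen with the requested separation; reduce `n_per_eye`.")
      }
    }
    seeds
  })
}
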