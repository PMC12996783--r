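#' Study specification for a synthetic OCT boundary series
#'
#' Describes the scan geometry and noise model used by
#' [generate_oct_series()]. Defaults reproduce the macaque imaging protocol
#' this package targets: volumes of 61 B-scans spaced 109 um apart, five
#' visits (baseline and 3, 6, 9, 12 months), and an injected and an
#' uninjected arm with two eyes each.
#'
#' The two boundary surfaces are the Choroid/Bruch's-membrane (BrM) boundary
#' and the RPE/photoreceptor-outer-segment (RPE/POS) boundary. Depths
#' increase posteriorly, so in healthy geometry the BrM depth is the larger
#' of the two and the layer thickness is `brm_depth - rpe_pos_depth`.
#' Drusen elevate the RPE/POS boundary toward the vitreous (smaller depth),
#' increasing the thickness locally.
#'
#' @param n_bscans Number of B-scans (sections) per volume.
#' @param bscan_spacing_um Distance between adjacent B-scans, um.
#' @param n_ascans Number of A-scans per B-scan.
#' @param ascan_spacing_um Lateral distance between adjacent A-scans, um.
#' @param nominal_thickness_um Drusen-free BrM-to-RPE/POS distance, um.
#' @param axial_noise_sd_um Standard deviation of i.i.d. Gaussian axial
#'   noise added independently to each boundary sample, um.
#' @param undulation_amplitude_um Amplitude of the smooth undulation shared
#'   by both boundaries (does not change thickness), um.
#' @param undulation_wavelength_um Wavelength of the undulation, um.
#' @param timepoints_months Strictly increasing visit labels in months.
#' @param arms Character vector of arm labels.
#' @param eyes_per_arm Eyes simulated per arm (counts are pooled per arm).
#' @param rng_seed Integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return An object of class `oct_study_spec`.
#' @seealso [generate_oct_series()], [random_druse_seeds()]
#' @export
oct_study_spec <- function(n_bscans = 61,
                           bscan_spacing_um = 109,
                           n_ascans = 512,
                           ascan_spacing_um = 17,
                           nominal_thickness_um = 35,
                           axial_noise_sd_um = 2,
                           undulation_amplitude_um = 5,
                           undulation_wavelength_um = 2000,
                           timepoints_months = c(0, 3, 6, 9, 12),
                           arms = c("injected", "uninjected"),
                           eyes_per_arm = 2,
                           rng_seed = 1L) {
  if (n_bscans < 3) abort("`n_bscans` must be >= 3.")
  lens <- c(bscan_spacing_um, ascan_spacing_um, nominal_thickness_um,
            undulation_wavelength_um)
  if (any(lens <= 0)) abort("spacings, nominal thickness and wavelength must be > 0.")
  if (axial_noise_sd_um < 0 || undulation_amplitude_um < 0) {
    abort("noise sd and undulation amplitude must be >= 0.")
  }
  if (is.unsorted(timepoints_months, strictly = TRUE)) {
    abort("`timepoints_months` must be strictly increasing.")
  }
  if (length(arms) < 1 || anyDuplicated(arms)) abort("`arms` must be distinct labels.")
  structure(
    list(n_bscans = as.integer(n_bscans),
         bscan_spacing_um = bscan_spacing_um,
         n_ascans = as.integer(n_ascans),
         ascan_spacing_um = ascan_spacing_um,
         nominal_thickness_um = nominal_thickness_um,
         axial_noise_sd_um = axial_noise_sd_um,
         undulation_amplitude_um = undulation_amplitude_um,
         undulation_wavelength_um = undulation_wavelength_um,
         timepoints_months = timepoints_months,
         arms = arms,
         eyes_per_arm = as.integer(eyes_per_arm),
         rng_seed = as.integer(rng_seed)),
    class = "oct_study_spec")
}

#' Eye identifiers implied by a study spec
#'
#' @param spec An [oct_study_spec()].
#' @return Character vector, `"<arm>_e<i>"` for each eye, and a matching
#'   `arm` attribute-free lookup via [eye_arms()].
#' @export
eye_ids <- function(spec) {
  unlist(lapply(spec$arms, function(a) paste0(a, "_e", seq_len(spec$eyes_per_arm))))
}

#' @rdname eye_ids
#' @return For `eye_arms()`, a named character vector mapping eye id to arm.
#' @export
eye_arms <- function(spec) {
  ids <- eye_ids(spec)
  stats::setNames(rep(spec$arms, each = spec$eyes_per_arm), ids)
}

#' Ground-truth seed for one synthetic druse
#'
#' A druse is modelled as an anisotropic Gaussian elevation of the RPE/POS
#' boundary: at grid offset (db, da) from the center (in B-scan/A-scan
#' index units) the added thickness is
#' `A(t) * exp(-((db*bspacing)^2/sigma_b^2 + (da*aspacing)^2/sigma_a^2)/2)`,
#' where `A(t)` is the per-visit peak amplitude. An amplitude of 0 means
#' the druse is absent at that visit, which is how appearance and
#' disappearance during the study are encoded.
#'
#' @param druse_id Identifier string.
#' @param eye_id Eye the druse belongs to (see [eye_ids()]).
#' @param center_bscan,center_ascan 1-based grid indices of the peak.
#' @param sigma_bscan_um,sigma_ascan_um Gaussian scales, um. Defaults (80 and
#'   60 um) give drusen that span 2-3 B-scans at 109-um spacing while
#'   leaving under 1 um of residual elevation in the first B-scan beyond
#'   the detected footprint.
#' @param amplitude_by_timepoint Named numeric vector, months -> peak um.
#' @return An object of class `druse_seed`.
#' @export
druse_seed <- function(druse_id, eye_id, center_bscan, center_ascan,
                       sigma_bscan_um = 80, sigma_ascan_um = 60,
                       amplitude_by_timepoint) {
  if (sigma_bscan_um <= 0 || sigma_ascan_um <= 0) abort("sigmas must be > 0.")
  amp <- amplitude_by_timepoint
  if (is.null(names(amp)) || any(amp < 0) || !any(amp > 0)) {
    abort("`amplitude_by_timepoint` must be named (months), >= 0, with at least one > 0.")
  }
  structure(
    list(druse_id = as.character(druse_id), eye_id = as.character(eye_id),
         center_bscan = as.integer(center_bscan),
         center_ascan = as.integer(center_ascan),
         sigma_bscan_um = sigma_bscan_um, sigma_ascan_um = sigma_ascan_um,
         amplitude_by_timepoint = amp),
    class = "druse_seed")
}

#' Specification for a synthetic RPE flat mount
#'
#' Emulates the flat-mount records consumed by the clearance pipeline: RPE
#' cells tessellating a disk, with rhodopsin-positive dots (phagocytosed
#' photoreceptor outer segments) recorded per cell at the 8 am shedding
#' peak and again at 11 am. `clearance_fraction_11am` is the expected
#' fraction of 8 am dots still present at 11 am, i.e. the ground-truth
#' "percent of POS remaining" divided by 100.
#'
#' @param mount_radius_um Mount radius, um; must contain the 1.5 mm
#'   sampling radius plus a field half-diagonal (>= 1642 um with default
#'   fields), so the default is 1700 um.
#' @param mean_cell_area_um2 Mean RPE cell area, um^2.
#' @param dots_per_cell_8am Expected dots per cell at 8 am.
#' @param clearance_fraction_11am Fraction in [0, 1].
#' @param dot_diameter_mean_um,dot_diameter_sd_um Normal dot-diameter
#'   distribution, um (truncated just above zero).
#' @param rng_seed Integer seed.
#' @return An object of class `flatmount_spec`.
#' @export
flatmount_spec <- function(mount_radius_um = 1700,
                           mean_cell_area_um2 = 400,
                           dots_per_cell_8am = 10,
                           clearance_fraction_11am = 0.8,
                           dot_diameter_mean_um = 3,
                           dot_diameter_sd_um = 0.6,
                           rng_seed = 1L) {
  if (mount_radius_um < 1500) abort("`mount_radius_um` must be >= 1500 um.")
  if (mean_cell_area_um2 <= 0) abort("`mean_cell_area_um2` must be > 0.")
  if (dots_per_cell_8am < 0) abort("`dots_per_cell_8am` must be >= 0.")
  if (clearance_fraction_11am < 0 || clearance_fraction_11am > 1) {
    abort("`clearance_fraction_11am` must lie in [0, 1].")
  }
  structure(
    list(mount_radius_um = mount_radius_um,
         mean_cell_area_um2 = mean_cell_area_um2,
         dots_per_cell_8am = dots_per_cell_8am,
         clearance_fraction_11am = clearance_fraction_11am,
         dot_diameter_mean_um = dot_diameter_mean_um,
         dot_diameter_sd_um = dot_diameter_sd_um,
         rng_seed = as.integer(rng_seed)),
    class = "flatmount_spec")
}

#' Specification for a synthetic phospholipid panel
#'
#' @param classes Phospholipid class labels.
#' @param species_per_class Species simulated per class.
#' @param baseline_class_fractions Named fractions summing to 1: expected
#'   share of total response per class in the reference group.
#' @param group_effects Data frame with columns `group`, `class`, `effect`
#'   (multiplicative shift on that class's response in that group), or
#'   `NULL` for two groups ("control", "treated") with no effect.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   noise on each species response.
#' @param n_samples_per_group Samples (retinas) per group; default 6,
#'   one retina per animal.
#' @param rng_seed Integer seed.
#' @return An object of class `lipid_panel_spec`.
#' @export
lipid_panel_spec <- function(classes = c("PE", "PC", "PS", "PI", "PG", "BMP"),
                             species_per_class = 5,
                             baseline_class_fractions = c(
                               PE = 0.30, PC = 0.40, PS = 0.12,
                               PI = 0.08, PG = 0.05, BMP = 0.05),
                             group_effects = NULL,
                             noise_cv = 0.15,
                             n_samples_per_group = 6,
                             rng_seed = 1L) {
  if (!setequal(names(baseline_class_fractions), classes)) {
    abort("`baseline_class_fractions` must be named by `classes`.")
  }
  fr <- baseline_class_fractions[classes]
  if (abs(sum(fr) - 1) > 1e-8) abort("baseline class fractions must sum to 1.")
  if (is.null(group_effects)) {
    group_effects <- tibble(group = rep(c("control", "treated"), each = length(classes)),
                            class = rep(classes, 2), effect = 1)
  }
  group_effects <- as_tibble(group_effects)
  if (!all(c("group", "class", "effect") %in% names(group_effects))) {
    abort("`group_effects` needs columns group, class, effect.")
  }
  if (any(group_effects$effect <= 0)) abort("group effects must be > 0.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  structure(
    list(classes = classes,
         species_per_class = as.integer(species_per_class),
         baseline_class_fractions = fr,
         group_effects = group_effects,
         noise_cv = noise_cv,
         n_samples_per_group = as.integer(n_samples_per_group),
         rng_seed = as.integer(rng_seed)),
    class = "lipid_panel_spec")
}
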