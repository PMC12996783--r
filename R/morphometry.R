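#' Layer thickness between the Choroid/BrM and RPE/POS boundaries
#'
#' Thickness is the pointwise distance `brm_depth - rpe_pos_depth` in um,
#' computed on the full (B-scan x A-scan) grid. The grid must be complete:
#' a missing (NA) boundary sample is an error, not something to impute.
#' Points more negative than `-3 * axial_noise_sd_um` (which noise alone
#' should essentially never produce) are counted in the
#' `n_flagged_negative` attribute.
#'
#' @param volume A `boundary_volume` (see [generate_oct_series()] or
#'   [read_boundaries()]).
#' @return A `thickness_map`: numeric matrix `[bscan, ascan]` of um with
#'   attributes `bscan_spacing_um`, `ascan_spacing_um`, `eye_id`, `arm`,
#'   `timepoint_months`, `n_flagged_negative`.
#' @export
compute_thickness <- function(volume) {
  stopifnot(inherits(volume, "boundary_volume"))
  rpe <- volume$rpe_pos_depth_um
  brm <- volume$brm_depth_um
  if (!identical(dim(rpe), dim(brm))) abort("boundary grids differ in shape.")
  bad <- which(is.na(rpe) | is.na(brm), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("missing boundary sample at (bscan %d, ascan %d).",
                  bad[1, 1], bad[1, 2]))
  }
  tmap <- brm - rpe
  noise_sd <- volume$axial_noise_sd_um %||% 0
  structure(tmap,
            class = c("thickness_map", "matrix", "array"),
            bscan_spacing_um = volume$bscan_spacing_um,
            ascan_spacing_um = volume$ascan_spacing_um,
            eye_id = volume$eye_id, arm = volume$arm,
            timepoint_months = volume$timepoint_months,
            n_flagged_negative = sum(tmap < -3 * noise_sd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detection parameters for drusen footprints
#'
#' Operationalizes the study's visual criterion ("a clear visible druse
#' with a distortion of the RPE/POS boundary") as numeric thresholds. A
#' footprint is retained if its peak excess over the per-B-scan reference
#' reaches `min_peak_height_um`; it is flagged `visible` only if it also
#' spans at least `min_sections` B-scans and at least
#' `min_footprint_ascans` A-scans in its widest section.
#'
#' @param min_peak_height_um Peak excess threshold, um.
#' @param min_sections Minimum B-scan span for visibility.
#' @param min_footprint_ascans Minimum A-scan width (widest section).
#' @param baseline_smoothing_window Odd running-median window, in A-scans,
#'   for the per-B-scan drusen-free reference profile.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_peak_height_um = 10,
                             min_sections = 2,
                             min_footprint_ascans = 3,
                             baseline_smoothing_window = 31) {
  if (min_peak_height_um <= 0 || min_sections <= 0 || min_footprint_ascans <= 0 ||
      baseline_smoothing_window <= 0) {
    abort("all detection parameters must be positive.")
  }
  if (baseline_smoothing_window %% 2 == 0) {
    abort("`baseline_smoothing_window` must be odd.")
  }
  structure(list(min_peak_height_um = min_peak_height_um,
                 min_sections = as.integer(min_sections),
                 min_footprint_ascans = as.integer(min_footprint_ascans),
                 baseline_smoothing_window = as.integer(baseline_smoothing_window)),
            class = "detection_params")
}

# excess of thickness over a per-B-scan running-median reference
excess_map <- function(tmap, params) {
  if (params$baseline_smoothing_window > ncol(tmap)) {
    abort("`baseline_smoothing_window` exceeds the A-scan count.")
  }
  ref <- t(apply(tmap, 1, stats::runmed,
                 k = params$baseline_smoothing_window, endrule = "median"))
  unclass(tmap) - ref
}

#' Detect drusen footprints on a thickness map
#'
#' Estimates a drusen-free reference per B-scan by running-median
#' smoothing, thresholds the excess map at half the peak threshold, labels
#' 4-connected components, and keeps the components whose peak excess
#' reaches `min_peak_height_um`. Heights are not measured here; see
#' [flanking_baseline()] and [measure_druse()].
#'
#' @param tmap A `thickness_map` from [compute_thickness()].
#' @param params A [detection_params()].
#' @return Tibble ordered by (centroid B-scan, centroid A-scan), one row
#'   per footprint: `druse_id` (within-map ordinal), `footprint`
#'   (list-column of 2-column integer matrices `bscan, ascan`), `sections`
#'   (list-column), `n_sections`, `widest_section_ascans`,
#'   `centroid_bscan`, `centroid_ascan`, `peak_excess_um`, `visible`.
#' @export
detect_drusen <- function(tmap, params = detection_params()) {
  stopifnot(inherits(tmap, "thickness_map"), inherits(params, "detection_params"))
  ex <- excess_map(tmap, params)
  mask <- ex >= params$min_peak_height_um / 2
  lab <- EBImage::bwlabel(mask * 1)  # 4-connected components
  nlab <- max(lab)
  rows <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    peak <- max(ex[lab == l])
    if (peak < params$min_peak_height_um) next
    colnames(idx) <- c("bscan", "ascan")
    sections <- sort(unique(idx[, "bscan"]))
    widest <- max(table(idx[, "bscan"]))
    n_sec <- length(sections)
    rows[[length(rows) + 1L]] <- tibble(
      footprint = list(idx[order(idx[, "bscan"], idx[, "ascan"]), , drop = FALSE]),
      sections = list(as.integer(sections)),
      n_sections = n_sec,
      widest_section_ascans = as.integer(widest),
      centroid_bscan = mean(idx[, "bscan"]),
      centroid_ascan = mean(idx[, "ascan"]),
      peak_excess_um = peak,
      visible = n_sec >= params$min_sections &&
        widest >= params$min_footprint_ascans)
  }
  if (!length(rows)) {
    return(tibble(druse_id = integer(), footprint = list(), sections = list(),
                  n_sections = integer(), widest_section_ascans = integer(),
                  centroid_bscan = numeric(), centroid_ascan = numeric(),
                  peak_excess_um = numeric(), visible = logical()))
  }
  out <- bind_rows(rows)
  out <- out[order(out$centroid_bscan, out$centroid_ascan), ]
  out$druse_id <- seq_len(nrow(out))
  out[, c("druse_id", setdiff(names(out), "druse_id"))]
}

#' Flanking-section baseline for one druse
#'
#' The drusen-free baseline thickness for a druse is the average thickness
#' of the two adjacent sections — the first B-scan before the footprint
#' and the first after it — taken over the druse's A-scan span. The same
#' two flanking sections serve every section of that druse. If the
#' footprint touches the first or last B-scan, the available side alone is
#' used and the result is flagged `edge`.
#'
#' @param tmap A `thickness_map`.
#' @param footprint Integer matrix with columns `bscan`, `ascan`.
#' @return List with `baseline_um` and `edge` (logical).
#' @export
flanking_baseline <- function(tmap, footprint) {
  stopifnot(is.matrix(footprint), nrow(footprint) > 0)
  sections <- range(footprint[, "bscan"])
  span <- seq(min(footprint[, "ascan"]), max(footprint[, "ascan"]))
  before <- sections[1] - 1L
  after <- sections[2] + 1L
  vals <- c(if (before >= 1) mean(tmap[before, span]),
            if (after <= nrow(tmap)) mean(tmap[after, span]))
  if (!length(vals)) abort("footprint spans every B-scan; no flanking section exists.")
  list(baseline_um = mean(vals), edge = length(vals) < 2)
}

#' Measure one druse's per-section and average height
#'
#' The height in each section is the mean thickness over the footprint's
#' A-scans in that section minus the flanking baseline, clipped below at
#' zero; the druse's average height is the arithmetic mean of the
#' per-section heights over every section in which the druse appears.
#'
#' @param tmap A `thickness_map`.
#' @param footprint Integer matrix with columns `bscan`, `ascan`.
#' @param baseline Result of [flanking_baseline()], or a number (um).
#' @return List: `per_section_height_um` (named by B-scan index),
#'   `avg_height_um`, `peak_height_um`, `sections`, `edge`.
#' @export
measure_druse <- function(tmap, footprint, baseline) {
  stopifnot(is.matrix(footprint), nrow(footprint) > 0)
  if (is.list(baseline)) {
    edge <- isTRUE(baseline$edge)
    baseline <- baseline$baseline_um
  } else edge <- FALSE
  sections <- sort(unique(footprint[, "bscan"]))
  per <- vapply(sections, function(b) {
    a <- footprint[footprint[, "bscan"] == b, "ascan"]
    max(0, mean(tmap[b, a]) - baseline)
  }, numeric(1))
  names(per) <- sections
  peak <- max(vapply(sections, function(b) {
    a <- footprint[footprint[, "bscan"] == b, "ascan"]
    max(0, max(tmap[b, a]) - baseline)
  }, numeric(1)))
  list(per_section_height_um = per, avg_height_um = mean(per),
       peak_height_um = peak, sections = as.integer(sections), edge = edge)
}

#' Detect and measure every druse in one volume
#'
#' Convenience wrapper: thickness, detection, flanking baseline and
#' height measurement for one eye at one visit.
#'
#' @param volume A `boundary_volume`.
#' @param params A [detection_params()].
#' @return Tibble with one row per detected druse: identification columns
#'   (`eye_id`, `arm`, `timepoint_months`, `druse_id`), geometry
#'   (`centroid_bscan`, `centroid_ascan`, `n_sections`, `footprint`
#'   list-column), and measurements (`avg_height_um`, `peak_height_um`,
#'   `baseline_um`, `visible`, `edge`).
#' @export
measure_volume <- function(volume, params = detection_params()) {
  tmap <- compute_thickness(volume)
  det <- detect_drusen(tmap, params)
  if (nrow(det) == 0) {
    return(tibble(eye_id = character(), arm = character(),
                  timepoint_months = numeric(), druse_id = integer(),
                  centroid_bscan = numeric(), centroid_ascan = numeric(),
                  n_sections = integer(), footprint = list(),
                  avg_height_um = numeric(), peak_height_um = numeric(),
                  baseline_um = numeric(), visible = logical(), edge = logical()))
  }
  meas <- purrr::map(det$footprint, function(fp) {
    bl <- flanking_baseline(tmap, fp)
    c(measure_druse(tmap, fp, bl), baseline_um = bl$baseline_um)
  })
  tibble(eye_id = volume$eye_id, arm = volume$arm,
         timepoint_months = volume$timepoint_months,
         druse_id = det$druse_id,
         centroid_bscan = det$centroid_bscan,
         centroid_ascan = det$centroid_ascan,
         n_sections = det$n_sections,
         footprint = det$footprint,
         avg_height_um = purrr::map_dbl(meas, "avg_height_um"),
         peak_height_um = purrr::map_dbl(meas, "peak_height_um"),
         baseline_um = purrr::map_dbl(meas, "baseline_um"),
         visible = det$visible,
         edge = purrr::map_lgl(meas, "edge"))
}
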