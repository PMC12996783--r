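#' Link drusen across visits into tracks
#'
#' Every location that carries a druse at any visit is measured at every
#' visit, even when no druse is present there. Detections at consecutive
#' visits are linked by greedy nearest-centroid matching within
#' `match_radius_um` (physical distance, using the B-scan and A-scan
#' spacings); an unmatched detection starts a new track. Each track keeps
#' a fixed anchor — the footprint and centroid of its first detection —
#' and at visits where the track has no detection its height is
#' re-measured at the anchor footprint on that visit's thickness map
#' (flanking baseline, clipped at zero) with `detected = FALSE`.
#'
#' Ties (two detections equidistant from a track) are broken in favour of
#' the lower detection id and reported with a warning.
#'
#' @param volumes List of `boundary_volume` objects covering one or more
#'   eyes, each eye observed at the same set of visits (e.g. the
#'   `volumes` element of [generate_oct_series()]).
#' @param params A [detection_params()].
#' @param match_radius_um Match radius, um (default 200, about two B-scan
#'   spacings).
#' @param visible_only Link only detections passing the visibility
#'   criterion (default TRUE, matching how drusen are counted).
#' @return Tibble with one row per track per visit: `track_id`, `eye_id`,
#'   `arm`, `anchor_bscan`, `anchor_ascan`, `timepoint_months`,
#'   `height_um`, `visible`, `detected`, `edge`.
#' @export
build_tracks <- function(volumes, params = detection_params(),
                         match_radius_um = 200, visible_only = TRUE) {
  stopifnot(length(volumes) > 0)
  eyes <- unique(vapply(volumes, `[[`, "", "eye_id"))
  out <- list()
  for (eye in eyes) {
    vols <- Filter(function(v) v$eye_id == eye, volumes)
    tps <- vapply(vols, `[[`, 0, "timepoint_months")
    if (anyDuplicated(tps)) abort(sprintf("eye %s has duplicate timepoints.", eye))
    vols <- vols[order(tps)]
    tps <- sort(tps)
    bsp <- vols[[1]]$bscan_spacing_um
    asp <- vols[[1]]$ascan_spacing_um
    tmaps <- lapply(vols, compute_thickness)
    dets <- lapply(vols, measure_volume, params = params)
    if (visible_only) dets <- lapply(dets, function(d) d[d$visible, , drop = FALSE])

    # tracks: list of (anchor_bscan, anchor_ascan, footprint, match index per tp)
    tracks <- list()
    for (ti in seq_along(tps)) {
      d <- dets[[ti]]
      free <- rep(TRUE, length(tracks))
      if (nrow(d) > 0) {
        for (di in seq_len(nrow(d))) {
          if (length(tracks)) {
            dist <- vapply(seq_along(tracks), function(k) {
              if (!free[k]) return(Inf)
              tr <- tracks[[k]]
              sqrt(((tr$anchor_bscan - d$centroid_bscan[di]) * bsp)^2 +
                     ((tr$anchor_ascan - d$centroid_ascan[di]) * asp)^2)
            }, numeric(1))
            if (any(is.finite(dist)) && min(dist) <= match_radius_um) {
              k <- which(dist == min(dist))
              if (length(k) > 1) {
                warn(sprintf("tie while matching detection %d at month %s (eye %s); lower id wins.",
                             di, format(tps[ti]), eye))
                k <- k[1]
              }
              tracks[[k]]$match[[ti]] <- di
              free[k] <- FALSE
              next
            }
          }
          tracks[[length(tracks) + 1L]] <- list(
            anchor_bscan = d$centroid_bscan[di],
            anchor_ascan = d$centroid_ascan[di],
            footprint = d$footprint[[di]],
            match = stats::setNames(as.list(rep(NA_integer_, length(tps))),
                                    as.character(tps)))
          tracks[[length(tracks)]]$match[[ti]] <- di
          free <- c(free, FALSE)
        }
      }
    }

    arm <- vols[[1]]$arm
    for (k in seq_along(tracks)) {
      tr <- tracks[[k]]
      for (ti in seq_along(tps)) {
        di <- tr$match[[ti]]
        if (!is.na(di)) {
          d <- dets[[ti]]
          rec <- tibble(height_um = d$avg_height_um[di], visible = d$visible[di],
                        detected = TRUE, edge = d$edge[di])
        } else {
          bl <- flanking_baseline(tmaps[[ti]], tr$footprint)
          m <- measure_druse(tmaps[[ti]], tr$footprint, bl)
          rec <- tibble(height_um = m$avg_height_um, visible = FALSE,
                        detected = FALSE, edge = m$edge)
        }
        out[[length(out) + 1L]] <- tibble(
          track_id = sprintf("%s_t%03d", eye, k), eye_id = eye, arm = arm,
          anchor_bscan = tr$anchor_bscan, anchor_ascan = tr$anchor_ascan,
          timepoint_months = tps[ti]) |> dplyr::bind_cols(rec)
      }
    }
  }
  if (!length(out)) {
    return(tibble(track_id = character(), eye_id = character(), arm = character(),
                  anchor_bscan = numeric(), anchor_ascan = numeric(),
                  timepoint_months = numeric(), height_um = numeric(),
                  visible = logical(), detected = logical(), edge = logical()))
  }
  bind_rows(out)
}

#' Druse height change ratio
#'
#' The change ratio is the druse's height at the analysis visit divided by
#' its height at baseline, with two degenerate-case rules: if the baseline
#' height is 0 (the druse appeared during the study) the denominator is
#' set to 1 to avoid division by zero, so the ratio numerically equals the
#' later height in um; if the later height is 0 (the druse disappeared, or
#' had not yet appeared) the ratio is 0. A ratio of 1 means no change,
#' above 1 growth, below 1 shrinkage.
#'
#' @param height_um Height(s) at the analysis visit, um (vectorised).
#' @param baseline_height_um Baseline height(s), um.
#' @return Numeric ratio(s), always >= 0.
#' @export
change_ratio <- function(height_um, baseline_height_um) {
  if (any(height_um < 0) || any(baseline_height_um < 0)) {
    abort("heights must be >= 0.")
  }
  denom <- ifelse(baseline_height_um == 0, 1, baseline_height_um)
  height_um / denom
}

#' Per-track change ratios at every visit
#'
#' @param tracks Tibble from [build_tracks()].
#' @return Tibble `track_id, eye_id, arm, timepoint_months, ratio`, where
#'   the baseline is each track's height at the earliest visit.
#' @export
change_ratios <- function(tracks) {
  base_tp <- min(tracks$timepoint_months)
  base <- tracks[tracks$timepoint_months == base_tp,
                 c("track_id", "height_um")]
  names(base)[2] <- "baseline_height_um"
  x <- dplyr::left_join(tracks, base, by = "track_id")
  tibble(track_id = x$track_id, eye_id = x$eye_id, arm = x$arm,
         timepoint_months = x$timepoint_months,
         ratio = change_ratio(x$height_um, x$baseline_height_um))
}

#' Count visible drusen in an arm at a visit
#'
#' Only tracks that pass the visibility criterion at the visit are
#' counted; counts are pooled across the arm's eyes.
#'
#' @param tracks Tibble from [build_tracks()].
#' @param timepoint_months Visit.
#' @param arm Arm label.
#' @return Integer count.
#' @export
count_visible <- function(tracks, timepoint_months, arm) {
  if (!arm %in% tracks$arm) abort(sprintf("unknown arm '%s'.", arm))
  sum(tracks$arm == arm & tracks$timepoint_months == timepoint_months &
        tracks$visible)
}

#' Average druse height change from baseline
#'
#' Mean height over all tracked locations in the arm at the visit, minus
#' the same mean at baseline. All tracked locations enter the means,
#' including heights of 0 where a druse is absent. Positive values mean
#' the average druse height increased.
#'
#' @inheritParams count_visible
#' @return Signed change in um.
#' @export
average_height_change <- function(tracks, timepoint_months, arm) {
  x <- tracks[tracks$arm == arm, ]
  if (nrow(x) == 0) abort(sprintf("no tracks in arm '%s'.", arm))
  base_tp <- min(x$timepoint_months)
  mean(x$height_um[x$timepoint_months == timepoint_months]) -
    mean(x$height_um[x$timepoint_months == base_tp])
}

#' Per-arm, per-visit longitudinal summary
#'
#' For each arm and visit: the visible-druse count, the average height
#' change from baseline, and the change ratios summarised as mean, SEM
#' and a classification into grew (ratio > 1), unchanged (|ratio - 1| <=
#' `ratio_tolerance`), shrank (0 < ratio < 1) and disappeared (ratio = 0).
#'
#' @param tracks Tibble from [build_tracks()].
#' @param ratio_tolerance Half-width of the "unchanged" band around 1.
#' @return Tibble: `arm, timepoint_months, n_drusen,
#'   mean_height_change_um, mean_ratio, sem_ratio, n_ratio_gt1,
#'   n_ratio_eq1, n_ratio_lt1, n_ratio_eq0`.
#' @export
summarize_study <- function(tracks, ratio_tolerance = 0.05) {
  ratios <- change_ratios(tracks)
  grid <- unique(tracks[, c("arm", "timepoint_months")])
  grid <- grid[order(grid$arm, grid$timepoint_months), ]
  purrr::pmap_dfr(grid, function(arm, timepoint_months) {
    r <- ratios$ratio[ratios$arm == arm &
                        ratios$timepoint_months == timepoint_months]
    tibble(arm = arm, timepoint_months = timepoint_months,
           n_drusen = count_visible(tracks, timepoint_months, arm),
           mean_height_change_um =
             average_height_change(tracks, timepoint_months, arm),
           mean_ratio = mean(r),
           sem_ratio = stats::sd(r) / sqrt(length(r)),
           n_ratio_gt1 = sum(r > 1 + ratio_tolerance),
           n_ratio_eq1 = sum(abs(r - 1) <= ratio_tolerance),
           n_ratio_lt1 = sum(r > 0 & r < 1 - ratio_tolerance),
           n_ratio_eq0 = sum(r == 0))
  })
}
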