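#' Write boundary volumes to a CSV table
#'
#' Long format, one row per grid point:
#' `eye_id, arm, timepoint_months, bscan_index, ascan_index,
#' rpe_pos_depth_um, brm_depth_um` with 0-based indices, plus the two
#' spacings repeated per row so the file is self-describing.
#'
#' @param volumes List of `boundary_volume` objects (or an `oct_series`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(volumes, path) {
  if (inherits(volumes, "oct_series")) volumes <- volumes$volumes
  rows <- purrr::map_dfr(volumes, function(v) {
    nb <- nrow(v$brm_depth_um); na <- ncol(v$brm_depth_um)
    tibble(eye_id = v$eye_id, arm = v$arm,
           timepoint_months = v$timepoint_months,
           bscan_index = rep(seq_len(nb) - 1L, times = na),
           ascan_index = rep(seq_len(na) - 1L, each = nb),
           rpe_pos_depth_um = as.vector(v$rpe_pos_depth_um),
           brm_depth_um = as.vector(v$brm_depth_um),
           bscan_spacing_um = v$bscan_spacing_um,
           ascan_spacing_um = v$ascan_spacing_um)
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' Read boundary volumes from a CSV table
#'
#' Inverse of [write_boundaries()]. The grid must be rectangular and
#' complete for every (eye, visit): a missing row is an error naming the
#' first missing (B-scan, A-scan) index, never imputed.
#'
#' @param path CSV path with the [write_boundaries()] schema.
#' @return List of `boundary_volume` objects.
#' @export
read_boundaries <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("eye_id", "arm", "timepoint_months", "bscan_index", "ascan_index",
           "rpe_pos_depth_um", "brm_depth_um")
  if (!all(req %in% names(x))) {
    abort(sprintf("boundaries file needs columns: %s.", paste(req, collapse = ", ")))
  }
  keys <- unique(x[, c("eye_id", "timepoint_months")])
  purrr::pmap(keys, function(eye_id, timepoint_months) {
    v <- x[x$eye_id == eye_id & x$timepoint_months == timepoint_months, ]
    nb <- max(v$bscan_index) + 1L
    na <- max(v$ascan_index) + 1L
    got <- paste(v$bscan_index, v$ascan_index)
    want <- paste(rep(0:(nb - 1), times = na), rep(0:(na - 1), each = nb))
    miss <- setdiff(want, got)
    if (length(miss)) {
      ij <- strsplit(miss[1], " ")[[1]]
      abort(sprintf("missing boundary sample for eye %s month %s at (bscan %s, ascan %s).",
                    eye_id, format(timepoint_months), ij[1], ij[2]))
    }
    o <- order(v$ascan_index, v$bscan_index)
    structure(
      list(eye_id = eye_id, arm = v$arm[1], timepoint_months = timepoint_months,
           rpe_pos_depth_um = matrix(v$rpe_pos_depth_um[o], nb, na),
           brm_depth_um = matrix(v$brm_depth_um[o], nb, na),
           bscan_spacing_um = if ("bscan_spacing_um" %in% names(v))
             v$bscan_spacing_um[1] else 109,
           ascan_spacing_um = if ("ascan_spacing_um" %in% names(v))
             v$ascan_spacing_um[1] else 17,
           axial_noise_sd_um = 0),
      class = "boundary_volume")
  })
}

#' Published macaque drusen count series
#'
#' Total visible drusen per arm (pooled over the arm's two eyes) at each
#' visit of the intravitreal-injection study, as reported: the injected
#' (OS) eyes went 25, 21, 23, 25, 32 from baseline to 12 months; the
#' uninjected (OD) eyes rose continuously from 27 at baseline to 48 at 12
#' months. The uninjected 9-month value (41) follows from the reported
#' equal 7-drusen increment between 9 and 12 months in both arms; the
#' unreported uninjected 3- and 6-month counts are NA.
#'
#' @return Tibble `arm, timepoint_months, n_drusen`.
#' @export
nhp_drusen_counts <- function() {
  path <- system.file("extdata", "nhp_drusen_counts.csv", package = "retquant",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    arm = readr::col_character(),
                    timepoint_months = readr::col_double(),
                    n_drusen = readr::col_integer()))
}
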