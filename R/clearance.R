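#' Filter dot records by diameter
#'
#' Keeps exactly the dots with diameter strictly greater than
#' `min_diameter_um` (default 2 um, the counting threshold for
#' rhodopsin-positive dots); a dot of exactly 2 um is excluded.
#'
#' @param dots Tibble with at least a `diameter_um` column.
#' @param min_diameter_um Strict lower bound, um.
#' @return The retained rows.
#' @export
filter_dots <- function(dots, min_diameter_um = 2) {
  dots[dots$diameter_um > min_diameter_um, , drop = FALSE]
}

#' Randomly sample counting fields on a flat mount
#'
#' Draws `n_fields` axis-aligned square fields of area `field_area_um2`
#' (default 40,000 um^2, side 200 um) with centers uniform in the disk of
#' radius `sampling_radius_um` (default 1.5 mm) around the mount center.
#' Fields are non-overlapping, enforced by rejection sampling with an
#' attempt budget. Deterministic for a fixed seed.
#'
#' @param mount A `flatmount` (or any list with `mount_radius_um`).
#' @param n_fields Number of fields.
#' @param seed Integer seed.
#' @param field_area_um2 Field area, um^2.
#' @param sampling_radius_um Radius of the sampling disk, um.
#' @param max_attempts Rejection-sampling budget.
#' @return Tibble `field_id, center_x_um, center_y_um, side_um`.
#' @export
sample_fields <- function(mount, n_fields = 10, seed = 1L,
                          field_area_um2 = 40000, sampling_radius_um = 1500,
                          max_attempts = 10000) {
  side <- sqrt(field_area_um2)
  if (mount$mount_radius_um < sampling_radius_um + side * sqrt(2) / 2) {
    abort(sprintf(
      "mount radius %.0f um cannot contain %.0f-um sampling radius plus a field half-diagonal (%.0f um needed).",
      mount$mount_radius_um, sampling_radius_um,
      sampling_radius_um + side * sqrt(2) / 2))
  }
  withr::with_seed(seed, {
    cx <- numeric(0); cy <- numeric(0)
    attempts <- 0L
    while (length(cx) < n_fields && attempts < max_attempts) {
      attempts <- attempts + 1L
      r <- sampling_radius_um * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      x <- r * cos(th); y <- r * sin(th)
      if (length(cx) == 0 || all(abs(cx - x) >= side | abs(cy - y) >= side)) {
        cx <- c(cx, x); cy <- c(cy, y)
      }
    }
    if (length(cx) < n_fields) {
      abort("could not place non-overlapping fields within the attempt budget.")
    }
    tibble(field_id = seq_len(n_fields), center_x_um = cx, center_y_um = cy,
           side_um = side)
  })
}

#' Dots per RPE cell in each sampled field
#'
#' Counts, per field, the diameter-filtered dots whose centers fall in
#' the field square and the cells whose centroids fall in it, and forms
#' their ratio.
#'
#' @param mount A `flatmount`.
#' @param fields Tibble from [sample_fields()].
#' @param time_label `"8am"` or `"11am"`.
#' @param min_diameter_um Strict dot-diameter threshold, um.
#' @return Tibble `field_id, dot_count, cell_count, dots_per_cell`.
#' @export
dots_per_cell <- function(mount, fields, time_label, min_diameter_um = 2) {
  dots <- filter_dots(mount$dots[mount$dots$time_label == time_label, ],
                      min_diameter_um)
  purrr::pmap_dfr(fields, function(field_id, center_x_um, center_y_um, side_um) {
    h <- side_um / 2
    in_field <- function(x, y) {
      x >= center_x_um - h & x < center_x_um + h &
        y >= center_y_um - h & y < center_y_um + h
    }
    nd <- sum(in_field(dots$x_um, dots$y_um))
    nc <- sum(in_field(mount$cells$x_um, mount$cells$y_um))
    if (nc == 0) abort(sprintf("field %d contains no cell centroid.", field_id))
    tibble(field_id = field_id, dot_count = nd, cell_count = nc,
           dots_per_cell = nd / nc)
  })
}

#' Photoreceptor outer-segment clearance percentage
#'
#' The clearance statistic: per mount, dots-per-cell is computed in each
#' of `n_fields` randomly sampled fields and averaged; the result is
#' `100 * mean_11am / mean_8am`, the percentage of outer segments (dots)
#' remaining at 11 am relative to the 8 am shedding peak. With a single
#' mount carrying both clock times (the synthetic generator's layout) the
#' same fields are used at both times; with a separate 11 am mount,
#' fields are drawn independently on it (seed + 1).
#'
#' @param mount_8am A `flatmount` carrying 8 am dots (and 11 am dots, if
#'   `mount_11am` is NULL).
#' @param mount_11am Optional second `flatmount` carrying the 11 am dots.
#' @param n_fields Fields per mount (default 10).
#' @param seed Integer seed for field sampling.
#' @param min_diameter_um Strict dot-diameter threshold, um.
#' @return One-row tibble: `mean_dpc_8am, mean_dpc_11am,
#'   percent_remaining`.
#' @export
clearance_percent <- function(mount_8am, mount_11am = NULL, n_fields = 10,
                              seed = 1L, min_diameter_um = 2) {
  f8 <- sample_fields(mount_8am, n_fields, seed)
  d8 <- dots_per_cell(mount_8am, f8, "8am", min_diameter_um)
  if (is.null(mount_11am)) {
    d11 <- dots_per_cell(mount_8am, f8, "11am", min_diameter_um)
  } else {
    f11 <- sample_fields(mount_11am, n_fields, seed + 1L)
    d11 <- dots_per_cell(mount_11am, f11, "11am", min_diameter_um)
  }
  m8 <- mean(d8$dots_per_cell)
  m11 <- mean(d11$dots_per_cell)
  if (m8 == 0) abort("mean dots per cell at 8 am is zero; clearance ratio undefined.")
  tibble(mean_dpc_8am = m8, mean_dpc_11am = m11,
         percent_remaining = 100 * m11 / m8)
}
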