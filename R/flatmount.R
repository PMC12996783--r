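#' Generate a synthetic RPE flat mount with rhodopsin-positive dots
#'
#' RPE cell centroids are laid on a jittered hexagonal lattice whose
#' density matches `mean_cell_area_um2`, so the implied (Voronoi) cell
#' regions tile the mount disk. Dot counts per cell are Poisson with rate
#' `dots_per_cell_8am` at 8 am and an independent redraw with rate
#' `dots_per_cell_8am * clearance_fraction_11am` at 11 am; each dot is
#' placed inside its parent cell's disk, so every dot belongs to exactly
#' one cell by construction. Dot diameters are normal, truncated just
#' above zero.
#'
#' @param spec A [flatmount_spec()].
#' @return A list of class `flatmount`: `cells` (tibble `cell_id, x_um,
#'   y_um, area_um2`), `dots` (tibble `dot_id, time_label, x_um, y_um,
#'   diameter_um, cell_id` with `time_label` in `{"8am", "11am"}`),
#'   `mount_radius_um`, `spec`, and `truth` (the ground-truth clearance
#'   fraction).
#' @export
generate_flatmount <- function(spec) {
  stopifnot(inherits(spec, "flatmount_spec"))
  withr::with_seed(spec$rng_seed, {
    A <- spec$mean_cell_area_um2
    s <- sqrt(2 * A / sqrt(3))          # hex lattice pitch for area A
    dy <- s * sqrt(3) / 2
    R <- spec$mount_radius_um
    ys <- seq(-R, R, by = dy)
    centers <- purrr::map_dfr(seq_along(ys), function(i) {
      xo <- if (i %% 2 == 0) s / 2 else 0
      xs <- seq(-R - s, R + s, by = s) + xo
      tibble(x = xs, y = ys[i])
    })
    jit <- 0.2 * s
    centers$x <- centers$x + runif(nrow(centers), -jit, jit)
    centers$y <- centers$y + runif(nrow(centers), -jit, jit)
    keep <- centers$x^2 + centers$y^2 <= R^2
    centers <- centers[keep, ]
    n_cells <- nrow(centers)
    cells <- tibble(cell_id = seq_len(n_cells),
                    x_um = centers$x, y_um = centers$y, area_um2 = A)

    r_cell <- sqrt(A / pi)
    place_dots <- function(rate, label, id_offset) {
      n_per <- rpois(n_cells, rate)
      total <- sum(n_per)
      if (total == 0) {
        return(tibble(dot_id = integer(), time_label = character(),
                      x_um = numeric(), y_um = numeric(),
                      diameter_um = numeric(), cell_id = integer()))
      }
      cid <- rep.int(cells$cell_id, n_per)
      rr <- r_cell * sqrt(runif(total))
      th <- runif(total, 0, 2 * pi)
      tibble(dot_id = id_offset + seq_len(total), time_label = label,
             x_um = cells$x_um[cid] + rr * cos(th),
             y_um = cells$y_um[cid] + rr * sin(th),
             diameter_um = pmax(0.2, rnorm(total, spec$dot_diameter_mean_um,
                                           spec$dot_diameter_sd_um)),
             cell_id = cid)
    }
    d8 <- place_dots(spec$dots_per_cell_8am, "8am", 0L)
    d11 <- place_dots(spec$dots_per_cell_8am * spec$clearance_fraction_11am,
                      "11am", nrow(d8))
    structure(list(cells = cells, dots = bind_rows(d8, d11),
                   mount_radius_um = R, spec = spec,
                   truth = list(clearance_fraction = spec$clearance_fraction_11am)),
              class = "flatmount")
  })
}

#' @export
print.flatmount <- function(x, ...) {
  cat(sprintf("<flatmount> radius %.0f um, %d cells, %d dots (8am: %d, 11am: %d)\n",
              x$mount_radius_um, nrow(x$cells), nrow(x$dots),
              sum(x$dots$time_label == "8am"), sum(x$dots$time_label == "11am")))
  invisible(x)
}

#' Catalog of packaged flat-mount fixtures
#'
#' Two seeded fixture configurations whose ground-truth clearance matches
#' the two genotype outcomes the clearance statistic distinguishes: a
#' "rescued" mount pair with normal clearance (40% of outer segments
#' remaining at 11 am) and a "diseased" pair with delayed clearance (80%
#' remaining).
#'
#' @return Tibble: `fixture, clearance_fraction_11am, dots_per_cell_8am,
#'   description`.
#' @seealso [generate_fixture_mount()]
#' @export
flatmount_fixture_catalog <- function() {
  tibble(fixture = c("rescued", "diseased"),
         clearance_fraction_11am = c(0.40, 0.80),
         dots_per_cell_8am = c(10, 10),
         description = c("normal POS clearance: 40% of dots remaining at 11 am",
                         "delayed POS clearance: 80% of dots remaining at 11 am"))
}

#' Generate a catalog fixture mount
#'
#' @param fixture `"rescued"` or `"diseased"` (see
#'   [flatmount_fixture_catalog()]).
#' @param seed Integer seed.
#' @return A `flatmount` carrying both 8 am and 11 am dot records.
#' @export
generate_fixture_mount <- function(fixture, seed = 1L) {
  cat <- flatmount_fixture_catalog()
  row <- cat[cat$fixture == fixture, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown fixture '%s'; see flatmount_fixture_catalog().", fixture))
  }
  generate_flatmount(flatmount_spec(
    dots_per_cell_8am = row$dots_per_cell_8am,
    clearance_fraction_11am = row$clearance_fraction_11am,
    rng_seed = seed))
}
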