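#' Generate a synthetic phospholipid panel
#'
#' Species responses are drawn so that, in expectation, each class's
#' share of a sample's total response equals the baseline class fraction
#' times the group's multiplicative effect (before renormalisation).
#' Within a class the total is split across species by fixed weights
#' drawn once per panel, and every response carries multiplicative
#' log-normal noise with the requested coefficient of variation.
#'
#' @param spec A [lipid_panel_spec()].
#' @return Tibble `sample_id, group, class, species, response`
#'   (class `lipid_table`).
#' @export
generate_lipid_panel <- function(spec) {
  stopifnot(inherits(spec, "lipid_panel_spec"))
  withr::with_seed(spec$rng_seed, {
    groups <- unique(spec$group_effects$group)
    cv <- spec$noise_cv
    sdlog <- sqrt(log(1 + cv^2))
    # fixed uneven species weights per class, mean-one noise
    weights <- lapply(spec$classes, function(cl) {
      w <- rexp(spec$species_per_class) + 0.2
      w / sum(w)
    })
    names(weights) <- spec$classes
    total_scale <- 1e6
    rows <- list()
    for (g in groups) {
      eff <- spec$group_effects[spec$group_effects$group == g, ]
      eff_by_class <- stats::setNames(rep(1, length(spec$classes)), spec$classes)
      eff_by_class[eff$class] <- eff$effect
      for (i in seq_len(spec$n_samples_per_group)) {
        sid <- sprintf("%s_s%02d", g, i)
        for (cl in spec$classes) {
          mu <- total_scale * spec$baseline_class_fractions[[cl]] *
            eff_by_class[[cl]] * weights[[cl]]
          noise <- if (cv > 0) {
            exp(rnorm(spec$species_per_class, -sdlog^2 / 2, sdlog))
          } else rep(1, spec$species_per_class)
          rows[[length(rows) + 1L]] <- tibble(
            sample_id = sid, group = g, class = cl,
            species = sprintf("%s(%d)", cl, seq_len(spec$species_per_class)),
            response = mu * noise)
        }
      }
    }
    out <- bind_rows(rows)
    class(out) <- c("lipid_table", class(out))
    out
  })
}

#' Phospholipid class and species composition percentages
#'
#' Every species response is expressed as a relative percentage of a sum:
#' class percentages are 100 x (sum of the class's responses) / (sum of
#' all responses) per sample, and species-within-class percentages are
#' 100 x (species response) / (class sum) per sample. Group-level means
#' with SEM are reported per class.
#'
#' @param table Tibble with columns `sample_id, group, class, species,
#'   response` (responses >= 0).
#' @return List of tibbles:
#'   * `class_percent`: `sample_id, group, class, percent`;
#'   * `species_percent`: `sample_id, group, class, species,
#'     percent_of_class`;
#'   * `class_summary`: `group, class, n, mean_percent, sem_percent`.
#' @export
lipid_percentages <- function(table) {
  req <- c("sample_id", "group", "class", "species", "response")
  if (!all(req %in% names(table))) {
    abort(sprintf("lipid table needs columns: %s.", paste(req, collapse = ", ")))
  }
  if (any(table$response < 0)) abort("responses must be >= 0.")
  sp_cl <- unique(table[, c("species", "class")])
  if (anyDuplicated(sp_cl$species)) {
    abort("a species maps to more than one class.")
  }
  totals <- dplyr::summarise(dplyr::group_by(table, .data$sample_id),
                             total = sum(.data$response), .groups = "drop")
  zero <- totals$sample_id[totals$total <= 0]
  if (length(zero)) {
    abort(sprintf("sample '%s' has no positive response.", zero[1]))
  }
  x <- dplyr::left_join(table, totals, by = "sample_id")
  class_sums <- dplyr::summarise(
    dplyr::group_by(x, .data$sample_id, .data$group, .data$class),
    class_sum = sum(.data$response), total = .data$total[1], .groups = "drop")
  class_percent <- tibble(sample_id = class_sums$sample_id,
                          group = class_sums$group, class = class_sums$class,
                          percent = 100 * class_sums$class_sum / class_sums$total)
  y <- dplyr::left_join(x, class_sums[, c("sample_id", "class", "class_sum")],
                        by = c("sample_id", "class"))
  species_percent <- tibble(
    sample_id = y$sample_id, group = y$group, class = y$class,
    species = y$species,
    percent_of_class = ifelse(y$class_sum > 0,
                              100 * y$response / y$class_sum, NA_real_))
  class_summary <- dplyr::summarise(
    dplyr::group_by(class_percent, .data$group, .data$class),
    n = dplyr::n(), mean_percent = mean(.data$percent),
    sem_percent = stats::sd(.data$percent) / sqrt(dplyr::n()),
    .groups = "drop")
  list(class_percent = class_percent, species_percent = species_percent,
       class_summary = class_summary)
}
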