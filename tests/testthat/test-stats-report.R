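test_that("class percentages are per-sample shares of the total response", {
  one <- tibble::tibble(sample_id = "s1", group = "g", class = "PC",
                        species = paste0("PC", 1:3), response = c(1, 2, 3))
  expect_equal(lipid_percentages(one)$class_percent$percent, 100)

  mixed <- tibble::tibble(sample_id = "s1", group = "g",
                          class = c("PC", "PG", "PE"),
                          species = c("PC1", "PG1", "PE1"),
                          response = c(30, 10, 60))
  cp <- lipid_percentages(mixed)$class_percent
  expect_equal(setNames(cp$percent, cp$class)[c("PC", "PG", "PE")],
               c(PC = 30, PG = 10, PE = 60), ignore_attr = TRUE)
})

test_that("random panels match brute-force sums and normalise to 100 per sample", {
  pan <- generate_lipid_panel(lipid_panel_spec(rng_seed = 19))
  res <- lipid_percentages(pan)
  for (sid in unique(pan$sample_id)[1:4]) {
    rows <- pan[pan$sample_id == sid, ]
    for (cl in unique(rows$class)) {
      brute <- 100 * sum(rows$response[rows$class == cl]) / sum(rows$response)
      got <- res$class_percent$percent[res$class_percent$sample_id == sid &
                                         res$class_percent$class == cl]
      expect_equal(got, brute, tolerance = 1e-12)
    }
  }
  sums <- tapply(res$class_percent$percent, res$class_percent$sample_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # species shares also sum to 100 within each (sample, class)
  sp <- res$species_percent
  by_sc <- tapply(sp$percent_of_class, paste(sp$sample_id, sp$class), sum)
  expect_true(all(abs(by_sc - 100) < 1e-9))
})

test_that("degenerate lipid tables are rejected with the offending sample named", {
  bad <- tibble::tibble(sample_id = c("ok", "allzero"), group = "g",
                        class = "PC", species = c("PC1", "PC1"),
                        response = c(5, 0))
  expect_error(lipid_percentages(bad), "allzero")
  dup <- tibble::tibble(sample_id = "s", group = "g",
                        class = c("PC", "PE"), species = c("X", "X"),
                        response = c(1, 1))
  expect_error(lipid_percentages(dup), "more than one class")
})

test_that("generator group effects propagate as the analytic renormalised fractions", {
  fr <- c(PE = 0.3, PC = 0.4, PS = 0.3)
  eff <- tibble::tibble(group = rep(c("ctl", "trt"), each = 3),
                        class = rep(names(fr), 2),
                        effect = c(1, 1, 1, 1, 1.2, 1))
  sp <- lipid_panel_spec(classes = names(fr), species_per_class = 4,
                         baseline_class_fractions = fr, group_effects = eff,
                         noise_cv = 0, n_samples_per_group = 2, rng_seed = 1)
  res <- lipid_percentages(generate_lipid_panel(sp))
  sm <- res$class_summary
  shifted <- fr * c(1, 1.2, 1)
  expected <- 100 * shifted / sum(shifted)   # closed-form renormalisation
  for (cl in names(fr)) {
    expect_equal(sm$mean_percent[sm$group == "trt" & sm$class == cl],
                 unname(expected[cl]), tolerance = 1e-9)
    expect_equal(sm$mean_percent[sm$group == "ctl" & sm$class == cl],
                 unname(100 * fr[cl]), tolerance = 1e-9)
  }
  # symmetry: equal expected responses over six classes -> 100/6 each
  sp6 <- lipid_panel_spec(noise_cv = 0,
                          baseline_class_fractions = setNames(
                            rep(1 / 6, 6), c("PE", "PC", "PS", "PI", "PG", "BMP")))
  res6 <- lipid_percentages(generate_lipid_panel(sp6))
  expect_true(all(abs(res6$class_percent$percent - 100 / 6) < 1e-9))
})

test_that("the Wald margin of error follows its closed form and bounds", {
  expect_equal(binomial_moe(0, 10)$moe, 0)
  expect_equal(binomial_moe(10, 10)$moe, 0)
  m <- binomial_moe(12, 25)
  expect_equal(m$moe, qnorm(0.975) * sqrt(0.48 * 0.52 / 25), tolerance = 1e-12)
  # moe maximal at p_hat = 0.5 and bounded by z * 0.5 / sqrt(n)
  n <- 40
  moes <- binomial_moe(0:n, n)$moe
  expect_equal(which.max(moes), n / 2 + 1)
  expect_true(all(moes <= qnorm(0.975) * 0.5 / sqrt(n) + 1e-12))
  # Wilson does not degenerate at the extremes
  expect_gt(binomial_moe(0, 10, method = "wilson")$moe, 0)
  expect_error(binomial_moe(5, 0), "n")
})

test_that("group tests dispatch Welch t for two groups and ANOVA beyond", {
  two_same <- data.frame(group = rep(c("a", "b"), each = 3),
                         value = rep(c(1, 2, 3), 2))
  gt <- group_tests(two_same)
  expect_equal(gt$test$statistic, 0)
  expect_equal(gt$test$p_value, 1)
  expect_equal(gt$test$stars, "n.s.")

  three_same <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                           value = rep(c(1, 2, 3), 3))
  gt3 <- group_tests(three_same)
  expect_equal(gt3$test$method, "one-way ANOVA")
  expect_equal(gt3$test$statistic, 0)

  set.seed(8)
  x <- rnorm(12); y <- rnorm(10, 0.8)
  d <- data.frame(group = rep(c("x", "y"), c(12, 10)), value = c(x, y))
  gt2 <- group_tests(d)
  oracle <- oracle_welch(x, y)
  expect_equal(gt2$test$statistic, oracle$t, tolerance = 1e-10)
  expect_equal(gt2$test$df, oracle$df, tolerance = 1e-10)
  expect_equal(gt2$test$p_value, oracle$p, tolerance = 1e-10)
  # per-group SEM = sd/sqrt(n)
  expect_equal(gt2$groups$sem[gt2$groups$group == "x"], sd(x) / sqrt(12))

  expect_error(group_tests(data.frame(group = c("a", "a", "b"), value = 1:3)),
               "fewer than 2")
  expect_error(group_tests(data.frame(group = "a", value = 1)), "two groups")
})

test_that("boundary tables round-trip through CSV and reject incomplete grids", {
  sp <- oct_study_spec(n_bscans = 5, n_ascans = 8, arms = "a", eyes_per_arm = 1,
                       timepoints_months = c(0, 3), rng_seed = 3)
  ser <- generate_oct_series(sp, list(
    druse_seed("d", "a_e1", 3, 4, amplitude_by_timepoint = c("0" = 15, "3" = 20))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_boundaries(ser, path)
  back <- read_boundaries(path)
  expect_length(back, 2)
  i0 <- which(vapply(back, `[[`, 0, "timepoint_months") == 0)
  expect_equal(back[[i0]]$brm_depth_um, ser$volumes[[1]]$brm_depth_um,
               tolerance = 1e-9)
  expect_equal(back[[i0]]$rpe_pos_depth_um, ser$volumes[[1]]$rpe_pos_depth_um,
               tolerance = 1e-9)
  # drop one grid row -> error naming the hole
  x <- readr::read_csv(path, show_col_types = FALSE)
  x <- x[!(x$bscan_index == 2 & x$ascan_index == 3 & x$timepoint_months == 0), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(x, path2)
  expect_error(read_boundaries(path2), "bscan 2, ascan 3")
})
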