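# small fast study geometry used throughout this file
small_spec <- function(timepoints_months = c(0, 3, 6), ...) {
  oct_study_spec(n_bscans = 21, n_ascans = 128, axial_noise_sd_um = 0,
                 undulation_amplitude_um = 0, arms = "a", eyes_per_arm = 1,
                 timepoints_months = timepoints_months, ...)
}

test_that("identical detections at every visit give 1:1 tracks with no births", {
  sp <- small_spec()
  s1 <- druse_seed("d1", "a_e1", 6, 30,
                   amplitude_by_timepoint = c("0" = 30, "3" = 30, "6" = 30))
  s2 <- druse_seed("d2", "a_e1", 15, 90,
                   amplitude_by_timepoint = c("0" = 25, "3" = 25, "6" = 25))
  tr <- build_tracks(generate_oct_series(sp, list(s1, s2))$volumes)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(nrow(tr), 2 * 3)  # one record per track per visit
  expect_true(all(tr$detected))
  expect_true(all(tr$visible))
})

test_that("a druse present only mid-study is re-measured (near zero) at other visits", {
  sp <- small_spec()
  s <- druse_seed("d", "a_e1", 10, 60,
                  amplitude_by_timepoint = c("0" = 0, "3" = 30, "6" = 0))
  tr <- build_tracks(generate_oct_series(sp, list(s))$volumes)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(sort(tr$timepoint_months), c(0, 3, 6))
  expect_equal(tr$detected, c(FALSE, TRUE, FALSE)[order(c(0, 3, 6))])
  expect_equal(tr$height_um[tr$timepoint_months == 0], 0, tolerance = 1e-9)
  expect_equal(tr$height_um[tr$timepoint_months == 6], 0, tolerance = 1e-9)
  expect_gt(tr$height_um[tr$timepoint_months == 3], 10)
})

test_that("greedy linkage matches exhaustive minimum-distance assignment on a small instance", {
  # three drusen whose inter-visit distances straddle the match radius
  sp <- small_spec(timepoints_months = c(0, 3))
  seeds <- list(
    druse_seed("a", "a_e1", 5, 25, amplitude_by_timepoint = c("0" = 30, "3" = 30)),
    druse_seed("b", "a_e1", 5, 70, amplitude_by_timepoint = c("0" = 30, "3" = 30)),
    druse_seed("c", "a_e1", 15, 100, amplitude_by_timepoint = c("0" = 0, "3" = 30)))
  tr <- build_tracks(generate_oct_series(sp, seeds)$volumes, match_radius_um = 200)
  # the optimal assignment here is a<->a, b<->b, c unmatched (a birth):
  # a and b sit on top of their month-0 selves, c is >1 mm from either
  expect_equal(length(unique(tr$track_id)), 3)
  expect_true(all(table(tr$track_id) == 2))
  born <- tr[tr$detected == FALSE, ]
  expect_equal(nrow(born), 1)
  expect_equal(born$timepoint_months, 0)
})

test_that("change ratios follow the degenerate-case rules exactly", {
  expect_equal(change_ratio(25, 25), 1)       # unchanged
  expect_equal(change_ratio(12, 0), 12)       # appeared: denominator set to 1
  expect_equal(change_ratio(0, 20), 0)        # disappeared
  expect_equal(change_ratio(0, 0), 0)         # never present
  expect_error(change_ratio(-1, 5), ">= 0")
  # vectorised and always non-negative
  h <- c(0, 5, 10, 40); b <- c(0, 0, 20, 20)
  expect_equal(change_ratio(h, b), c(0, 5, 0.5, 2))
  expect_true(all(change_ratio(h, b) >= 0))
})

test_that("ratio at baseline is 1 whenever baseline height is positive", {
  sp <- small_spec()
  seeds <- list(
    druse_seed("d1", "a_e1", 6, 30,
               amplitude_by_timepoint = c("0" = 20, "3" = 28, "6" = 35)),
    druse_seed("d2", "a_e1", 15, 90,
               amplitude_by_timepoint = c("0" = 40, "3" = 30, "6" = 0)))
  tr <- build_tracks(generate_oct_series(sp, seeds)$volumes)
  r <- change_ratios(tr)
  expect_equal(r$ratio[r$timepoint_months == 0], c(1, 1))
  expect_true(all(r$ratio >= 0))
})

test_that("visible counts pool an arm's eyes and reject unknown arms", {
  sp <- oct_study_spec(n_bscans = 21, n_ascans = 128, axial_noise_sd_um = 0,
                       undulation_amplitude_um = 0, arms = "a", eyes_per_arm = 2,
                       timepoints_months = c(0, 3))
  seeds <- list(
    druse_seed("d1", "a_e1", 6, 30, amplitude_by_timepoint = c("0" = 30, "3" = 30)),
    druse_seed("d2", "a_e2", 15, 90, amplitude_by_timepoint = c("0" = 25, "3" = 25)))
  tr <- build_tracks(generate_oct_series(sp, seeds)$volumes)
  expect_equal(count_visible(tr, 0, "a"), 2)  # pooled across the two eyes
  expect_error(count_visible(tr, 0, "z"), "unknown arm")
  empty <- tr[0, ]
  expect_error(count_visible(empty, 0, "a"), "unknown arm")
})

test_that("the published injected-eye count series rises by seven drusen from 9 to 12 months", {
  counts <- nhp_drusen_counts()
  inj <- counts[counts$arm == "injected", ]
  expect_equal(inj$n_drusen[inj$timepoint_months == 12] -
                 inj$n_drusen[inj$timepoint_months == 9], 7L)
  # and both arms share that increment
  un <- counts[counts$arm == "uninjected", ]
  expect_equal(un$n_drusen[un$timepoint_months == 12] -
                 un$n_drusen[un$timepoint_months == 9], 7L)
})

test_that("average height change is signed mean-minus-baseline-mean over all locations", {
  tracks <- tibble::tibble(
    track_id = rep(c("t1", "t2"), each = 2), eye_id = "e", arm = "a",
    anchor_bscan = 1, anchor_ascan = 1,
    timepoint_months = rep(c(0, 3), 2),
    height_um = c(20, 25, 20, 25), visible = TRUE, detected = TRUE, edge = FALSE)
  expect_equal(average_height_change(tracks, 3, "a"), 5)
  expect_equal(average_height_change(tracks, 0, "a"), 0)
  expect_error(average_height_change(tracks, 3, "z"), "no tracks")
})

test_that("summaries classify ratios into grew/unchanged/shrank/disappeared", {
  mk_tracks <- function(h0, h3) tibble::tibble(
    track_id = paste0("t", seq_along(h0)) |> rep(each = 2),
    eye_id = "e", arm = "a", anchor_bscan = 1, anchor_ascan = 1,
    timepoint_months = rep(c(0, 3), length(h0)),
    height_um = as.vector(rbind(h0, h3)),
    visible = TRUE, detected = TRUE, edge = FALSE)
  s <- summarize_study(mk_tracks(20, 20))
  m3 <- s[s$timepoint_months == 3, ]
  expect_equal(m3$mean_ratio, 1)
  expect_equal(m3$n_ratio_eq1, 1L)

  s2 <- summarize_study(mk_tracks(c(20, 20), c(0, 40)))
  m3 <- s2[s2$timepoint_months == 3, ]
  expect_equal(m3$mean_ratio, 1)  # ratios {0, 2}
  expect_equal(c(m3$n_ratio_eq0, m3$n_ratio_gt1, m3$n_ratio_eq1, m3$n_ratio_lt1),
               c(1L, 1L, 0L, 0L))
})

test_that("arm-specific growth is recovered and destroyed by label shuffling", {
  # two-arm studies on a reduced grid: treated shrinks, untreated grows
  diffs <- c(); perm_diffs <- c()
  for (study_seed in 1:5) {
    sp <- oct_study_spec(n_bscans = 21, n_ascans = 128, axial_noise_sd_um = 2,
                         timepoints_months = c(0, 3, 6), rng_seed = study_seed)
    seeds <- random_druse_seeds(sp, n_per_eye = 3,
                                growth_by_arm = c(injected = 0.8, uninjected = 1.2),
                                min_separation_um = 400, seed = study_seed + 100)
    tr <- build_tracks(generate_oct_series(sp, seeds)$volumes)
    diffs <- c(diffs, average_height_change(tr, 6, "injected") -
                 average_height_change(tr, 6, "uninjected"))
    # permute arm labels at the track level
    ids <- unique(tr$track_id)
    set.seed(study_seed)
    relab <- setNames(sample(rep(c("injected", "uninjected"),
                                 length.out = length(ids))), ids)
    trp <- tr
    trp$arm <- unname(relab[trp$track_id])
    perm_diffs <- c(perm_diffs, average_height_change(trp, 6, "injected") -
                      average_height_change(trp, 6, "uninjected"))
  }
  expect_true(all(diffs < 0))             # consistent ordering with true labels
  expect_true(any(perm_diffs > 0) || mean(abs(perm_diffs)) < mean(abs(diffs)))
})
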