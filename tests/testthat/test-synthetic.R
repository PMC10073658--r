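test_that("noise-free bout-free video is perfectly static", {
  sc <- video_scenario(n_frames = 20, frame_width = 40, frame_height = 30,
                       region = roi(0, 0, 40, 24), noise_sd = 0,
                       off_mean_s = 1e6, distractor = FALSE, seed = 3)
  gv <- generate_video(sc)
  expect_equal(sum(gv$labels), 0)
  expect_equal(nrow(gv$bouts), 0)
  for (t in 2:20)
    expect_identical(gv$stack$frames[, , t], gv$stack$frames[, , 1])
})

test_that("video generation is deterministic given the seed", {
  sc <- video_scenario(n_frames = 50, frame_width = 60, frame_height = 45,
                       region = roi(0, 0, 60, 36), seed = 11)
  a <- generate_video(sc)
  b <- generate_video(sc)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$bouts, b$bouts)
  sc2 <- video_scenario(n_frames = 50, frame_width = 60, frame_height = 45,
                        region = roi(0, 0, 60, 36), seed = 12)
  expect_false(identical(generate_video(sc2)$stack$frames, a$stack$frames))
})

test_that("gold bouts coincide with frames where the climb texture acts", {
  sc <- video_scenario(n_frames = 400, frame_width = 60, frame_height = 45,
                       region = roi(0, 0, 60, 36), off_mean_s = 4,
                       on_mean_s = 2, noise_sd = 0, distractor = FALSE,
                       seed = 21)
  gv <- generate_video(sc)
  expect_gt(sum(gv$labels), 0)
  # frames differing from the background are exactly the labelled ones
  bgframe <- gv$stack$frames[, , which(gv$labels == 0)[1]]
  differs <- vapply(seq_len(400), function(t)
    !identical(gv$stack$frames[, , t], bgframe), TRUE)
  expect_equal(as.integer(differs), gv$labels)
  expect_equal(bouts_to_labels(gv$bouts, "gold",
                               gv$bouts$segment_id[1], 400), gv$labels)
})

test_that("the climbing fraction approaches the renewal expectation", {
  withr::with_seed(31, {
    n <- 500000  # 5.5 h at 25 fps
    lab <- simulate_bout_labels(n, 25, off_mean_s = 60, on_mean_s = 8)
    want <- 8 / 68
    # 3 SE of the renewal-process estimate (cycles ~ n / (25 * 68))
    cycles <- n / (25 * 68)
    se <- want * sqrt(2 / cycles)
    expect_lt(abs(mean(lab) - want), 3 * se)
  })
})

test_that("roi outside the frame is rejected", {
  sc <- video_scenario(frame_width = 50, frame_height = 40,
                       region = roi(0, 0, 60, 36))
  expect_error(generate_video(sc), "bounds")
})

test_that("zero-noise annotators reproduce the gold standard", {
  gold <- bout_table(data.frame(segment_id = "s", annotator_id = "gold",
                                start_frame = c(100, 900, 2000),
                                end_frame = c(300, 1200, 2600),
                                label = "climbing"))
  ann <- simulate_annotators(gold, 3000, jitter_sd = 0, miss_prob = 0,
                             false_rate_per_h = 0, seed = 5)
  for (a in c("A1", "A2", "A3"))
    expect_equal(bouts_to_labels(ann, a, "s", 3000),
                 bouts_to_labels(gold, "gold", "s", 3000))
})

test_that("certain misses leave only false bouts", {
  gold <- bout_table(data.frame(segment_id = "s", annotator_id = "gold",
                                start_frame = 100, end_frame = 50000,
                                label = "climbing"))
  ann <- simulate_annotators(gold, 90000, miss_prob = 1,
                             false_rate_per_h = 30, seed = 7)
  lab_gold <- bouts_to_labels(gold, "gold", "s", 90000)
  for (a in unique(ann$annotator_id)) {
    lab <- bouts_to_labels(ann, a, "s", 90000)
    # false bouts are short (mean 2 s); overlap with the long gold bout is
    # incidental, total marked time stays far below the gold bout
    expect_lt(sum(lab), 0.2 * sum(lab_gold))
  }
})

test_that("majority consensus beats the average single annotator", {
  withr::with_seed(41, {
    wins <- 0
    for (rep in 1:50) {
      n <- 30000
      lab <- simulate_bout_labels(n, 25, off_mean_s = 40, on_mean_s = 8)
      gold <- labels_to_bouts(lab, "s", "gold")
      ann <- simulate_annotators(gold, n, jitter_sd = 20, miss_prob = 0.15,
                                 false_rate_per_h = 6,
                                 seed = sample.int(1e6, 1))
      series <- lapply(c("A1", "A2", "A3"), function(a)
        bouts_to_labels(ann, a, "s", n))
      maj <- consensus(series, "majority")
      acc_maj <- mean(maj == lab)
      acc_single <- mean(vapply(series, function(s) mean(s == lab), 0))
      if (acc_maj > acc_single) wins <- wins + 1
    }
    expect_gte(wins / 50, 0.9)
  })
})

test_that("noise-free activity equals its deterministic bin means", {
  sc <- activity_scenario(sex_mult = c(F = 1, M = 1),
                          age_mult = c(young = 1, old = 1),
                          genotype_deficit = 1, cage_sd_frac = 0,
                          day_slope_sd_frac = 0, noise_sd_frac = 0, seed = 9)
  act <- generate_activity(sc)
  mu <- climbr:::activity_mu(sc, act$bin_start_zt, "young", "F", "WT",
                             "distance")
  expect_equal(act$distance_mm, unname(mu))
  # light bins sit at the light baseline exactly
  expect_equal(unique(act$distance_mm[act$phase == "light"]), 2500)
  expect_equal(nrow(act), 24 * 3 * 240)
})

test_that("the genotype deficit shifts the end-of-dark window by the stated factor", {
  sc <- activity_scenario(genotype_deficit = 0.5, cage_sd_frac = 0,
                          day_slope_sd_frac = 0, noise_sd_frac = 0, seed = 13)
  wt <- expected_window_mean(sc, "end_of_dark", "young", "F", "WT")
  hemi <- expected_window_mean(sc, "end_of_dark", "young", "F", "Hemi")
  expect_equal(hemi, 0.5 * wt)
  # closed-form check against the generated table
  act <- generate_activity(sc)
  wm <- window_means(act, "distance_mm", "end_of_dark")
  info <- unique(act[c("cage_id", "Age", "Genotype", "Sex")])
  wm <- merge(wm, info)
  got <- wm$mean_activity[wm$cage_id == "cage01"][1]
  cell <- info[info$cage_id == "cage01", ]
  expect_equal(got, expected_window_mean(sc, "end_of_dark",
                                         as.character(cell$Age),
                                         as.character(cell$Sex),
                                         as.character(cell$Genotype)))
  # no deficit outside the window
  expect_equal(expected_window_mean(sc, "end_of_light", "young", "F", "Hemi"),
               expected_window_mean(sc, "end_of_light", "young", "F", "WT"))
})

test_that("activity generation is deterministic given the seed", {
  sc <- activity_scenario(seed = 17)
  expect_identical(generate_activity(sc), generate_activity(sc))
})
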