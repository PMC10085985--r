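test_that("blink schedule is evenly spaced, deterministic, and rejects infeasible configs", {
  cfg <- sim_config(duration_s = 20, n_blinks = 3, blink_jitter_frac = 0,
                    breakup_times_s = 1, seed = 1)
  sched <- schedule_blinks(cfg)
  expect_equal(sched$close_s, c(5, 10, 15))
  expect_equal(nrow(sched), 3)

  cfg_j <- sim_config(duration_s = 20, n_blinks = 3, blink_jitter_frac = 0.1,
                      breakup_times_s = 1, seed = 7)
  expect_identical(schedule_blinks(cfg_j), schedule_blinks(cfg_j))
  cfg_j2 <- sim_config(duration_s = 20, n_blinks = 3, blink_jitter_frac = 0.1,
                       breakup_times_s = 1, seed = 8)
  expect_false(identical(schedule_blinks(cfg_j), schedule_blinks(cfg_j2)))

  expect_error(schedule_blinks(sim_config(duration_s = 1, n_blinks = 3,
                                          blink_duration_s = 0.5, seed = 1)),
               "cannot fit")
})

test_that("configuration validation enforces the device and protocol ranges", {
  expect_error(sim_config(fps = 24), "fps")
  expect_error(sim_config(resolution = c(480, 640)), "resolution")
  expect_error(sim_config(n_blinks = 2), "three blinks")
  expect_error(sim_config(breakup_times_s = c(1, 2)), "length")
  expect_error(sim_config(spot_depth = 1.5), "spot_depth")
  # breakup beyond its segment is rejected at scene construction
  expect_error(sim_scene(sim_config(duration_s = 12, breakup_times_s = 10,
                                    blink_jitter_frac = 0, seed = 1)),
               "segment length")
})

test_that("frame grid covers duration at fps and true TFBUT averages the segments", {
  truth <- simulate_truth(sim_config(duration_s = 10, breakup_times_s = 1,
                                     blink_jitter_frac = 0, seed = 1))
  expect_equal(nrow(truth$per_frame), 300) # 10 s at 30 fps

  t2 <- simulate_truth(sim_config(duration_s = 20, blink_jitter_frac = 0,
                                  breakup_times_s = c(3, 3, 3), seed = 1))
  expect_equal(t2$true_tfbut_s, 3)
  t3 <- simulate_truth(sim_config(duration_s = 30, blink_jitter_frac = 0,
                                  breakup_times_s = c(2, 4, 6), seed = 1))
  expect_equal(t3$true_tfbut_s, 4)
  # censored segments yield no three-measurement mean
  t4 <- simulate_truth(sim_config(duration_s = 30, blink_jitter_frac = 0,
                                  breakup_times_s = c(2, NA, 6), seed = 1))
  expect_true(is.na(t4$true_tfbut_s))
  expect_equal(t4$segments$censored, c(FALSE, TRUE, FALSE))
})

test_that("identical config and seed give bit-identical frames and ground truth", {
  cfg <- std_config(seed = 13, artifact_rate = 0.3)
  v1 <- simulate_video(cfg, interval_s = 0.4)
  v2 <- simulate_video(cfg, interval_s = 0.4)
  expect_identical(v1$frames$image, v2$frames$image)
  expect_identical(v1$truth, v2$truth)
  # a frame rendered alone matches the same frame inside the video
  sc <- sim_scene(cfg)
  k <- 7
  expect_identical(render_frame(sc, v1$frames$frame[k]), v1$frames$image[[k]])
})

test_that("renderer matches ground-truth labels: spots visible iff labeled positive", {
  cfg <- std_config(seed = 21, noise_sd = 0)
  vid <- simulate_video(cfg, interval_s = 0.2, noiseless = TRUE)
  pf <- vid$truth$per_frame
  # brute-force check on every 4th frame: threshold + flood fill on the
  # standardized noiseless render
  idx <- seq(1, nrow(pf), by = 4)
  for (i in idx) {
    img <- vid$frames$image[[i]]
    if (pf$label[i] == "blink") {
      expect_lt(mean(img > 0.3), 0.005)
      next
    }
    roi <- detect_cornea(img)
    spots <- bf_spots(standardize_frame(img, roi))
    expect_identical(length(spots) >= 1, pf$label[i] == "positive")
  }
  # monotone onset: once positive within a segment, positive until its end
  seg <- vid$truth$segments
  for (s in seq_len(nrow(seg))) {
    lab <- pf$label[pf$timestamp_s >= seg$opening_s[s] &
                      pf$timestamp_s < seg$end_s[s]]
    pos <- which(lab == "positive")
    if (length(pos) > 0) {
      expect_equal(pos, seq(min(pos), length(lab)))
    }
  }
})

test_that("rendered spot radius follows the growth law", {
  cfg <- std_config(seed = 11, noise_sd = 0)
  sc <- sim_scene(cfg)
  seg <- sc$segments
  # 1 s after breakup: radius = spot_min_radius + growth * 1 = 12 px
  fr <- round((seg$opening_s[1] + seg$breakup_s[1] + 1) * cfg$fps)
  img <- render_frame(sc, fr, noiseless = TRUE)
  dark <- img < 0.5 * median(img[img > 0.3])
  # confine to the disc to ignore the dark background
  roi <- detect_cornea(img)
  d <- sqrt(outer((seq_len(nrow(img)) - roi$y)^2,
                  (seq_len(ncol(img)) - roi$x)^2, `+`))
  area <- sum(dark & d < 0.9 * roi$r)
  r_measured <- sqrt(area / pi)
  expect_lt(abs(r_measured - 12), 2)
})

test_that("frame export and import round-trip with a truth sidecar", {
  dir <- withr::local_tempdir()
  cfg <- std_config(seed = 3)
  vid <- simulate_video(cfg, interval_s = 2)
  write_video_frames(vid, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_frame_dir(dir)
  expect_equal(nrow(back), nrow(vid$frames))
  expect_equal(back$timestamp_s, vid$frames$timestamp_s)
  # green channel round-trips through 8-bit PNG
  expect_lt(max(abs(back$image[[3]] - vid$frames$image[[3]])), 1 / 254)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_tfbut_s, vid$truth$true_tfbut_s)
})
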