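test_that("spot detector finds nothing on a clean disc and sizes real spots", {
  cl <- classified_video()
  pp <- cl$frames
  neg_i <- which(cl$frames$truth == "negative" & pp$quality == "pass")[5]
  expect_equal(nrow(detect_spots(pp$image_std[[neg_i]])), 0)

  # one rendered spot of known radius: area within 20%
  cfg <- std_config(seed = 11, noise_sd = 0)
  sc <- sim_scene(cfg)
  seg <- sc$segments
  fr <- round((seg$opening_s[1] + seg$breakup_s[1] + 2.6) * cfg$fps) # r = 20
  img <- render_frame(sc, fr, noiseless = TRUE)
  roi <- detect_cornea(img)
  sp <- detect_spots(standardize_frame(img, roi))
  expect_equal(nrow(sp), 1)
  scale <- 384 / (2 * 1.1 * roi$r)
  expect_lt(abs(sp$area_px - pi * (20 * scale)^2) / (pi * (20 * scale)^2), 0.2)

  # two well-separated spots give two components
  cfg2 <- sim_config(duration_s = 16, breakup_times_s = 2, blink_jitter_frac = 0,
                     artifact_rate = 0, noise_sd = 0, spots_per_segment = 2,
                     seed = 8)
  sc2 <- sim_scene(cfg2)
  fr2 <- round((sc2$segments$opening_s[1] + 3) * 30)
  img2 <- render_frame(sc2, fr2, noiseless = TRUE)
  sp2 <- detect_spots(standardize_frame(img2, detect_cornea(img2)))
  expect_equal(nrow(sp2), 2)
})

test_that("spot detector agrees exactly with a flood-fill oracle on noiseless frames", {
  nl <- noiseless_video()
  pass_i <- which(nl$frames$quality == "pass")
  for (i in pass_i[seq(1, length(pass_i), by = 7)]) {
    img <- nl$frames$image_std[[i]]
    expect_identical(pkg_spot_pixels(img), bf_spots(img))
  }
})

test_that("rule-based confidence is zero without evidence and saturates with it", {
  cl <- classified_video()
  pp <- cl$frames
  neg <- pp$image_std[[which(cl$frames$truth == "negative" & pp$quality == "pass")[3]]]
  out <- classify_frame(neg)
  expect_equal(out$confidence, 0)
  expect_equal(out$label, "negative")

  # a large deep spot saturates toward 1
  cfg <- std_config(seed = 11)
  sc <- sim_scene(cfg)
  seg <- sc$segments
  fr <- round((seg$opening_s[1] + seg$breakup_s[1] + 2.5) * cfg$fps)
  img <- render_frame(sc, fr)
  std <- standardize_frame(img, detect_cornea(img))
  out2 <- classify_frame(std)
  expect_gt(out2$confidence, 0.95)
  expect_equal(out2$label, "positive")

  # the calibration anchor: one min-area spot at full depth scores ~0.7
  expect_equal(1 - exp(-rule_classifier()$k * 20), 0.7, tolerance = 0.02)
})

test_that("confidence is monotone in spot evidence and label flips at the threshold", {
  cfg <- std_config(seed = 11, noise_sd = 0)
  sc <- sim_scene(cfg)
  seg <- sc$segments
  t0 <- seg$opening_s[1] + seg$breakup_s[1]
  confs <- sapply(c(0.1, 0.5, 1.0, 2.0), function(dt) {
    img <- render_frame(sc, round((t0 + dt) * cfg$fps), noiseless = TRUE)
    predict(rule_classifier(), standardize_frame(img, detect_cornea(img)))
  })
  expect_true(all(diff(confs) > 0)) # growing spot never lowers confidence

  img <- render_frame(sc, round((t0 + 1) * cfg$fps), noiseless = TRUE)
  std <- standardize_frame(img, detect_cornea(img))
  conf <- predict(rule_classifier(), std)
  below <- rule_classifier(spot_params(decision_threshold = conf - 1e-6))
  above <- rule_classifier(spot_params(decision_threshold = conf + 1e-6))
  expect_equal(classify_frame(std, below)$label, "positive")
  expect_equal(classify_frame(std, above)$label, "negative")
})

test_that("frame labels on a noiseless video reproduce ground truth exactly", {
  nl <- noiseless_video()
  open_eye <- nl$frames$truth %in% c("positive", "negative")
  expect_true(all(nl$frames$quality[open_eye] == "pass"))
  expect_identical(nl$frames$label[open_eye], nl$frames$truth[open_eye])
})

test_that("the trained surrogate fits the synthetic set and collapses under permutation", {
  m <- surrogate_model()
  expect_gte(m$metadata$valid_accuracy, 0.95)
  expect_equal(m$metadata$split_fractions, c(train = 0.8, valid = 0.2))
  # determinism: same data and seed, identical parameters
  m2 <- train_classifier(training_frames(), seed = 7)
  expect_identical(m$beta, m2$beta)
  expect_identical(m$lambda, m2$lambda)
  # group split: enough frames on both sides
  expect_gt(m$metadata$n_valid, 0.1 * (m$metadata$n_train + m$metadata$n_valid))

  # permuted labels: validation accuracy ~ class prior
  fr <- training_frames()
  fr$label <- withr::with_seed(3, sample(fr$label))
  mp <- train_classifier(fr, seed = 7)
  prior <- max(table(fr$label)) / nrow(fr)
  expect_lt(abs(mp$metadata$valid_accuracy - prior), 0.15)

  expect_error(train_classifier(fr[fr$label == "negative", ], seed = 1),
               "both classes")
  expect_error(train_classifier(fr[0, ], seed = 1), "no usable frames")
})

test_that("classifier serialization round-trips both kinds", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- surrogate_model()
  write_classifier(m, path)
  m2 <- read_classifier(path)
  img <- training_frames()$image_std[[4]]
  expect_equal(predict(m2, img), predict(m, img), tolerance = 1e-12)

  rc <- rule_classifier(spot_params(min_area = 33), k = 0.1)
  write_classifier(rc, path)
  rc2 <- read_classifier(path)
  expect_equal(rc2$k, 0.1)
  expect_equal(rc2$params$min_area, 33)
  expect_equal(predict(rc2, img), predict(rc, img), tolerance = 1e-12)
})

test_that("attribution maps highlight spots on positives and stay cold on negatives", {
  fr <- training_frames()
  m <- surrogate_model()
  pos_idx <- which(fr$label == "positive")[c(5, 25, 45)]
  for (i in pos_idx) {
    img <- fr$image_std[[i]]
    sp <- detect_spots(img)
    for (model in list(m, rule_classifier())) {
      hm <- attribution_map(img, model)
      am <- which(hm == max(hm), arr.ind = TRUE)[1, ]
      d <- min(sqrt((am[2] - sp$x)^2 + (am[1] - sp$y)^2))
      expect_lt(d, sqrt(max(sp$area_px) / pi) + 2)
    }
  }
  neg <- fr$image_std[[which(fr$label == "negative")[7]]]
  expect_lt(max(attribution_map(neg, m)), 0.2)
  expect_lt(max(attribution_map(neg, rule_classifier())), 0.2)
  # a uniform frame yields a flat map
  u <- matrix(0.5, 384, 384)
  expect_equal(diff(range(attribution_map(u, m))), 0)
  expect_equal(diff(range(attribution_map(u, rule_classifier()))), 0)
})
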