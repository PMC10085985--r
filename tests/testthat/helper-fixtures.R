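# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A short clean video (no artifacts, default noise) used across tests.
std_config <- function(seed = 42, artifact_rate = 0, ...) {
  sim_config(duration_s = 16, breakup_times_s = c(1.0, 1.4, 1.8),
             blink_jitter_frac = 0, artifact_rate = artifact_rate,
             seed = seed, ...)
}

classified_video <- function() {
  fixture("classified_video", function() {
    vid <- simulate_video(std_config(), interval_s = 0.2)
    cl <- classify_frames(preprocess_frames(vid$frames))
    cl$truth <- vid$truth$per_frame$label
    list(video = vid, frames = cl)
  })
}

noiseless_video <- function() {
  fixture("noiseless_video", function() {
    cfg <- std_config(seed = 5, noise_sd = 0)
    vid <- simulate_video(cfg, interval_s = 0.2)
    cl <- classify_frames(preprocess_frames(vid$frames))
    cl$truth <- vid$truth$per_frame$label
    list(video = vid, frames = cl)
  })
}

# Standardized training frames from several short clean videos, with
# ground-truth labels and a source-video id.
training_frames <- function() {
  fixture("training_frames", function() {
    purrr::map_dfr(1:10, function(i) {
      b <- 0.4 + 0.25 * i
      cfg <- sim_config(n_blinks = 3, breakup_times_s = b,
                        segment_lengths_s = c(1.2, rep(b + 1.2, 3)),
                        artifact_rate = 0, seed = 100 + i)
      vid <- simulate_video(cfg, interval_s = 0.2)
      pp <- preprocess_frames(vid$frames)
      pp$truth <- vid$truth$per_frame$label
      keep <- pp$quality == "pass"
      tibble::tibble(video = paste0("v", i),
                     image_std = pp$image_std[keep],
                     label = pp$truth[keep])
    })
  })
}

surrogate_model <- function() {
  fixture("surrogate_model", function() training_frames() |>
            train_classifier(seed = 7))
}

# ---- independent oracles -------------------------------------------------

# Brute-force spot finder: threshold below depth_frac * median background
# inside the eroded disc, then 4-neighbor flood fill. Independent of
# detect_spots (no EBImage).
bf_spots <- function(img, depth_frac = 0.55, min_area = 20, erosion = 8,
                     margin = 0.1) {
  n <- nrow(img)
  c0 <- (n + 1) / 2
  r <- n / (2 * (1 + margin)) - erosion
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`))
  mask <- d <= r
  bg <- median(img[mask])
  dark <- mask & (img < depth_frac * bg)
  lab <- matrix(0L, n, n)
  comp <- 0L
  out <- list()
  for (start in which(dark & lab == 0L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    px <- integer()
    lab[start] <- comp
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      px <- c(px, cur)
      i <- (cur - 1) %% n + 1
      j <- (cur - 1) %/% n + 1
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (nb[1] < 1 || nb[1] > n || nb[2] < 1 || nb[2] > n) next
        idx <- (nb[2] - 1) * n + nb[1]
        if (dark[idx] && lab[idx] == 0L) {
          lab[idx] <- comp
          queue <- c(queue, idx)
        }
      }
    }
    out[[comp]] <- as.integer(sort(px))
  }
  out[vapply(out, length, integer(1)) >= min_area]
}

# Pixel sets of detect_spots() output, for exact comparison with bf_spots.
pkg_spot_pixels <- function(img, params = spot_params()) {
  geo <- tearfilm:::corneal_mask(params$size, params$margin,
                                 params$mask_erosion)
  bg <- median(img[geo$mask])
  dark <- geo$mask & (img < params$depth_frac * bg)
  lab <- EBImage::bwlabel(dark)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_area)
  lapply(keep, function(k) sort(which(lab == k)))
}

# Formula oracles for 2x2-table metrics.
bf_metrics <- function(tp, fp, fn, tn) {
  list(accuracy = (tp + tn) / (tp + fp + fn + tn),
       f1 = 2 * tp / (2 * tp + fp + fn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = tp / (tp + fp),
       npv = tn / (tn + fn))
}

# AUC by exhaustive pair counting (ties get half credit).
bf_auc_pairs <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Trapezoid area under a (fpr, tpr) curve sorted by increasing fpr.
trapezoid_auc <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  fpr <- curve$fpr[o]
  tpr <- curve$tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Spearman by hand: rank with midranks, then the Pearson formula.
bf_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
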