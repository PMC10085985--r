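#' Configure a synthetic fluorescein video
#'
#' Builds the parameter set for the synthetic blue-light fluorescein video
#' simulator. The simulated scene is a bright green corneal disc on a dark
#' background; after each eye opening, dark breakup spots appear at the
#' configured per-segment breakup times and grow linearly, blinks fully
#' occlude the disc, and a configurable fraction of frames carries an
#' acquisition artifact (defocus or an eyelash occluder).
#'
#' Segment conventions: a video has `n_blinks` blink closures and therefore
#' `n_blinks` measurement segments, each starting at an eye opening. The
#' interval before the first blink is rendered (eye open, no breakup) but is
#' not a measurement segment, matching the clinical protocol in which
#' breakup is timed from a blink opening.
#'
#' @param duration_s Video length in seconds. Default 56.1 s, the mean
#'   clinical video length the pipeline was designed around. Recomputed from
#'   `segment_lengths_s` when those are given.
#' @param fps Frame rate; 30 or 60 frames/s.
#' @param resolution `c(height, width)` in pixels, within the supported
#'   device range 720x1280 to 1080x1920.
#' @param n_blinks Number of blink closures; at least 3 (a valid measurement
#'   video must contain at least three blinks).
#' @param blink_duration_s Duration of each full eyelid closure, seconds.
#' @param breakup_times_s Per-segment breakup times in seconds after eye
#'   opening (length `n_blinks`, recycled from length 1). `NA` means the
#'   tear film never ruptures in that segment (censored).
#' @param segment_lengths_s Optional explicit lengths of the pre-blink
#'   prefix plus the `n_blinks` measurement segments (length `n_blinks + 1`).
#'   When given, blinks are scheduled exactly and `duration_s` is derived.
#' @param blink_jitter_frac Relative jitter on the evenly spaced blink
#'   closures (ignored when `segment_lengths_s` is given).
#' @param corneal_radius_frac Corneal disc radius as a fraction of the
#'   smaller image dimension.
#' @param spot_growth_rate Breakup spot radial growth, pixels/second.
#' @param spot_min_radius Spot radius at onset, pixels. A rupture appears as
#'   a finite dark region the instant it forms, so a frame at the breakup
#'   time is already positive.
#' @param spot_depth Fractional intensity loss inside a spot, in `(0, 1]`.
#' @param spots_per_segment Number of simultaneous spots per rupture.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param artifact_rate Per-frame probability of an acquisition artifact on
#'   open-eye frames.
#' @param artifact_blur_factor Down/up-sampling factor used to emulate a
#'   defocused frame.
#' @param seed Integer seed; the video and its ground truth are fully
#'   reproducible from it.
#' @return A `tf_sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(duration_s = 20, breakup_times_s = c(3, 4, 5), seed = 1)
#' schedule_blinks(cfg)
#' @export
sim_config <- function(duration_s = 56.1,
                       fps = 30,
                       resolution = c(720, 1280),
                       n_blinks = 3,
                       blink_duration_s = 0.3,
                       breakup_times_s = 4,
                       segment_lengths_s = NULL,
                       blink_jitter_frac = 0.1,
                       corneal_radius_frac = 0.35,
                       spot_growth_rate = 5,
                       spot_min_radius = 7,
                       spot_depth = 0.6,
                       spots_per_segment = 1,
                       noise_sd = 0.05,
                       artifact_rate = 0.03,
                       artifact_blur_factor = 12,
                       seed = 1) {
  if (!fps %in% c(30, 60)) abort("`fps` must be 30 or 60.")
  if (length(resolution) != 2L ||
      resolution[1] < 720 || resolution[1] > 1080 ||
      resolution[2] < 1280 || resolution[2] > 1920) {
    abort("`resolution` must be c(height, width) within 720x1280 to 1080x1920.")
  }
  if (n_blinks < 3) abort("`n_blinks` must be at least 3 (a valid video contains at least three blinks).")
  if (spot_depth <= 0 || spot_depth > 1) abort("`spot_depth` must be in (0, 1].")
  if (blink_duration_s <= 0) abort("`blink_duration_s` must be positive.")
  if (length(breakup_times_s) == 1L) breakup_times_s <- rep(breakup_times_s, n_blinks)
  if (length(breakup_times_s) != n_blinks) {
    abort("`breakup_times_s` must have length 1 or `n_blinks` (NA = no breakup).")
  }
  if (any(!is.na(breakup_times_s) & breakup_times_s <= 0)) {
    abort("breakup times must be positive (seconds after eye opening).")
  }
  if (!is.null(segment_lengths_s)) {
    if (length(segment_lengths_s) != n_blinks + 1L || any(segment_lengths_s <= 0)) {
      abort("`segment_lengths_s` must be `n_blinks + 1` positive lengths (prefix + segments).")
    }
    duration_s <- sum(segment_lengths_s) + n_blinks * blink_duration_s
  }
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  structure(
    list(duration_s = duration_s, fps = fps, resolution = as.integer(resolution),
         n_blinks = as.integer(n_blinks), blink_duration_s = blink_duration_s,
         breakup_times_s = breakup_times_s, segment_lengths_s = segment_lengths_s,
         blink_jitter_frac = blink_jitter_frac,
         corneal_radius_frac = corneal_radius_frac,
         spot_growth_rate = spot_growth_rate, spot_min_radius = spot_min_radius,
         spot_depth = spot_depth, spots_per_segment = as.integer(spots_per_segment),
         noise_sd = noise_sd, artifact_rate = artifact_rate,
         artifact_blur_factor = artifact_blur_factor, seed = as.integer(seed)),
    class = "tf_sim_config")
}

#' @exportS3Method base::print
print.tf_sim_config <- function(x, ...) {
  cat(sprintf("<tf_sim_config> %.1f s @ %d fps, %dx%d, %d blinks, seed %d\n",
              x$duration_s, x$fps, x$resolution[1], x$resolution[2],
              x$n_blinks, x$seed))
  cat("  breakup times (s after opening):",
      paste(ifelse(is.na(x$breakup_times_s), "none", x$breakup_times_s),
            collapse = ", "), "\n")
  invisible(x)
}

#' Schedule blink closures
#'
#' Places `n_blinks` full eyelid closures in the video: evenly spaced with
#' seeded jitter by default, or exactly at the boundaries implied by
#' `segment_lengths_s` when the configuration fixes those. Deterministic for
#' a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per blink: `blink`, `close_s`, `open_s`.
#' @export
schedule_blinks <- function(config) {
  stopifnot(inherits(config, "tf_sim_config"))
  n <- config$n_blinks
  bd <- config$blink_duration_s
  min_seg <- 0.5
  if (!is.null(config$segment_lengths_s)) {
    segs <- config$segment_lengths_s
    close_s <- cumsum(segs[-length(segs)]) + (seq_len(n) - 1) * bd
  } else {
    if (config$duration_s < (n + 1) * min_seg + n * bd) {
      abort(sprintf(paste0(
        "duration %.2f s cannot fit %d blinks of %.2f s plus %d open segments ",
        "of at least %.2f s each"),
        config$duration_s, n, bd, n + 1, min_seg))
    }
    spacing <- config$duration_s / (n + 1)
    close_s <- spacing * seq_len(n)
    if (config$blink_jitter_frac > 0) {
      jit <- withr::with_seed(frame_seed(config$seed, 0), {
        runif(n, -1, 1) * config$blink_jitter_frac * spacing
      })
      close_s <- close_s + jit
    }
  }
  open_s <- close_s + bd
  seg_len <- diff(c(0, close_s)) - c(0, rep(bd, n - 1))
  if (any(seg_len < min_seg) || open_s[n] >= config$duration_s - 0.2) {
    abort("blink schedule infeasible: open segments shorter than 0.5 s; reduce n_blinks or jitter, or lengthen the video")
  }
  tibble(blink = seq_len(n), close_s = close_s, open_s = open_s)
}

# Measurement segments: one per blink, from its eye opening to the next
# closure (or the end of the video), with the configured breakup time.
sim_segments <- function(config, schedule) {
  n <- config$n_blinks
  open_s <- schedule$open_s
  end_s <- c(schedule$close_s[-1], config$duration_s)
  b <- config$breakup_times_s
  len <- end_s - open_s
  bad <- !is.na(b) & b >= len
  if (any(bad)) {
    abort(sprintf(
      "breakup time(s) %s not strictly less than their segment length(s) %s",
      paste(b[bad], collapse = ", "),
      paste(round(len[bad], 2), collapse = ", ")))
  }
  tibble(segment = seq_len(n), opening_s = open_s, end_s = end_s,
         breakup_s = b, censored = is.na(b))
}

#' Build the renderable scene for a configuration
#'
#' Precomputes everything deterministic about a simulated video: the blink
#' schedule, measurement segments, corneal disc geometry, spot placements,
#' and the noiseless base frame. [render_frame()] then renders any frame
#' index from it.
#'
#' @param config A [sim_config()].
#' @return A `tf_scene` object.
#' @export
sim_scene <- function(config) {
  stopifnot(inherits(config, "tf_sim_config"))
  schedule <- schedule_blinks(config)
  segments <- sim_segments(config, schedule)
  h <- config$resolution[1]; w <- config$resolution[2]
  r <- config$corneal_radius_frac * min(h, w)
  geom <- withr::with_seed(frame_seed(config$seed, 1), {
    list(cy = h / 2 + runif(1, -0.04, 0.04) * h,
         cx = w / 2 + runif(1, -0.04, 0.04) * w)
  })
  # Spot centers stay within 0.55 r of the disc center so grown spots never
  # reach the limbus ring used by the occluder score.
  spots <- purrr::map_dfr(seq_len(config$n_blinks), function(i) {
    if (segments$censored[i]) return(tibble())
    withr::with_seed(frame_seed(config$seed, 1000 + i), {
      k <- config$spots_per_segment
      rho <- sqrt(runif(k)) * 0.55 * r
      th <- runif(k, 0, 2 * pi)
      tibble(segment = i,
             onset_s = segments$opening_s[i] + segments$breakup_s[i],
             y = geom$cy + rho * sin(th), x = geom$cx + rho * cos(th))
    })
  })
  if (nrow(spots) == 0) {
    spots <- tibble(segment = integer(), onset_s = numeric(),
                    y = numeric(), x = numeric())
  }
  # Noiseless base frame: dark background, bright disc with a mild radial
  # vignette and a ~2.5 px smooth rim.
  bg <- 0.06; disc <- 0.78
  base <- matrix(bg, h, w)
  yy <- (seq_len(h) - geom$cy); xx <- (seq_len(w) - geom$cx)
  d <- sqrt(outer(yy^2, xx^2, `+`))
  rim <- pmin(pmax((r - d) / 2.5, 0), 1)
  vign <- 1 - 0.12 * pmin(d / r, 1)^2
  base <- bg + (disc * vign - bg) * rim
  structure(
    list(config = config, schedule = schedule, segments = segments,
         disc = list(cy = geom$cy, cx = geom$cx, r = r),
         spots = spots, base = base, blank = matrix(bg, h, w),
         background = bg),
    class = "tf_scene")
}

#' @exportS3Method base::print
print.tf_scene <- function(x, ...) {
  cat(sprintf("<tf_scene> disc r=%.0f px at (%.0f, %.0f); %d segment(s), %d spot(s)\n",
              x$disc$r, x$disc$cx, x$disc$cy, nrow(x$segments), nrow(x$spots)))
  invisible(x)
}

# Is the eye closed at time t?
is_blink_time <- function(scene, t) {
  any(t >= scene$schedule$close_s & t < scene$schedule$open_s)
}

# Artifact decision for an open-eye frame. Drawn from the head of the
# frame's RNG substream; render_frame() consumes the same draws before
# generating noise, so truth and render always agree.
frame_artifact <- function(scene, frame) {
  cfg <- scene$config
  if (cfg$artifact_rate <= 0) return("none")
  withr::with_seed(frame_seed(cfg$seed, 2 * frame + 3), {
    if (runif(1) >= cfg$artifact_rate) "none"
    else if (runif(1) < 0.5) "blur" else "lash"
  })
}

# Spots visible at time t: onset reached and segment's eye still open.
active_spots <- function(scene, t) {
  sp <- scene$spots
  if (nrow(sp) == 0) return(sp[0, ])
  seg <- scene$segments
  keep <- !logical(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    s <- sp$segment[i]
    keep[i] <- t >= sp$onset_s[i] && t < seg$end_s[s]
  }
  sp[keep, , drop = FALSE]
}

#' Render one simulated frame
#'
#' Total function over valid frame indices: renders the corneal disc with
#' any active breakup spots (radius `spot_min_radius + spot_growth_rate *
#' (t - breakup onset)`), a plain dark frame during blinks, and applies the
#' frame's artifact (defocus or eyelash stroke) and seeded Gaussian noise.
#' Frame `i` is at `t = i / fps`; frame indices are 0-based so that the
#' first frame sits at t = 0.
#'
#' @param scene A [sim_scene()].
#' @param frame 0-based frame index.
#' @param channels `"fluor"` for the fluorescein-channel matrix (the
#'   representation the analysis pipeline consumes) or `"rgb"` for the full
#'   color array.
#' @param noiseless Render without noise or artifacts (used by the
#'   label/render consistency checks).
#' @return A matrix (`"fluor"`) or H x W x 3 array (`"rgb"`) in `[0, 1]`.
#' @export
render_frame <- function(scene, frame, channels = c("fluor", "rgb"),
                         noiseless = FALSE) {
  stopifnot(inherits(scene, "tf_scene"))
  channels <- match.arg(channels)
  cfg <- scene$config
  t <- frame / cfg$fps
  blink <- is_blink_time(scene, t)
  sp <- if (blink) scene$spots[0, ] else active_spots(scene, t)
  rad <- if (nrow(sp) > 0) {
    cfg$spot_min_radius + cfg$spot_growth_rate * (t - sp$onset_s)
  } else numeric()
  base <- if (blink) scene$blank else scene$base
  if (noiseless) {
    img <- cpp_render(base, sp$y, sp$x, rad, cfg$spot_depth, 0)
  } else {
    art <- if (blink) "none" else frame_artifact(scene, frame)
    img <- withr::with_seed(frame_seed(cfg$seed, 2 * frame + 3), {
      if (cfg$artifact_rate > 0 && !blink) {
        runif(2)  # consume the artifact-decision draws
      }
      if (art == "lash") {
        base <- base + 0  # copy before painting the occluder
        lash <- lash_curve(scene)
        cpp_draw_stroke(base, lash$y, lash$x, halfwidth = 14, value = 0.03)
      }
      out <- cpp_render(base, sp$y, sp$x, rad, cfg$spot_depth, cfg$noise_sd)
      if (art == "blur") out <- defocus(out, cfg$artifact_blur_factor)
      out
    })
  }
  if (channels == "rgb") fluor_to_rgb(img) else img
}

# Eyelash occluder: a quadratic curve from the top edge across the disc,
# sampled every ~2 px. Geometry is a deterministic function of the scene.
lash_curve <- function(scene) {
  d <- scene$disc
  p0 <- c(y = 1, x = d$cx - 0.9 * d$r)
  p1 <- c(y = d$cy, x = d$cx + 0.4 * d$r)        # control point
  p2 <- c(y = d$cy + 1.1 * d$r, x = d$cx - 0.2 * d$r)
  s <- seq(0, 1, length.out = 400)
  y <- (1 - s)^2 * p0["y"] + 2 * s * (1 - s) * p1["y"] + s^2 * p2["y"]
  x <- (1 - s)^2 * p0["x"] + 2 * s * (1 - s) * p1["x"] + s^2 * p2["x"]
  list(y = y, x = x)
}

# Defocused capture: strong low-pass via down/up-sampling. Applied to the
# recorded (noisy) frame, emulating the smoothed look of a defocused,
# compressed video frame.
defocus <- function(img, factor) {
  h <- nrow(img); w <- ncol(img)
  small <- EBImage::resize(img, round(h / factor), round(w / factor))
  EBImage::resize(small, h, w)
}

# Ground-truth label of a frame: blink > artifact > positive/negative.
# A frame is positive iff at least one spot is visible at its timestamp.
frame_label <- function(scene, frame) {
  t <- frame / scene$config$fps
  if (is_blink_time(scene, t)) return("blink")
  if (frame_artifact(scene, frame) != "none") return("artifact")
  if (nrow(active_spots(scene, t)) > 0) "positive" else "negative"
}

# Frame indices rendered for a config: all frames, or the nearest frame to
# each tick of an `interval_s` grid (tick 0 included). Because frames sit at
# i / fps, tick times map to indices round(t * fps); at 30 fps and 0.2 s
# this is every 6th frame, exactly the slicing convention of
# `slice_frames()`.
sim_frame_index <- function(config, interval_s = NULL) {
  n <- round(config$duration_s * config$fps)
  if (is.null(interval_s)) {
    idx <- 0:(n - 1)
    tibble(frame = idx, timestamp_s = idx / config$fps)
  } else {
    ticks <- seq(0, config$duration_s, by = interval_s)
    idx <- pmin(round(ticks * config$fps), n - 1)
    keep <- !duplicated(idx)
    tibble(frame = idx[keep], timestamp_s = ticks[keep])
  }
}

#' Simulate a fluorescein video with ground truth
#'
#' Renders a full synthetic video (or only the frames on a slicing grid,
#' which is exactly equivalent to rendering everything and then calling
#' [slice_frames()]) together with per-frame ground-truth labels, the blink
#' schedule, per-segment breakup times, and the true TFBUT (the mean of the
#' first three uncensored segment breakup times).
#'
#' @param config A [sim_config()].
#' @param interval_s Optional slicing interval in seconds; `NULL` renders
#'   every frame at `fps`.
#' @param noiseless Disable noise and artifacts.
#' @return A `tf_video` object: list with `frames` (tibble `frame`,
#'   `timestamp_s`, `image` list-column of fluorescein-channel matrices),
#'   `truth` (see [simulate_truth()]), `scene`, and `config`.
#' @examples
#' cfg <- sim_config(duration_s = 12, n_blinks = 3, breakup_times_s = 1,
#'                   blink_jitter_frac = 0, artifact_rate = 0, seed = 7)
#' vid <- simulate_video(cfg, interval_s = 0.4)
#' vid$truth$true_tfbut_s
#' @export
simulate_video <- function(config, interval_s = NULL, noiseless = FALSE) {
  scene <- sim_scene(config)
  grid <- sim_frame_index(config, interval_s)
  frames <- grid
  frames$image <- purrr::map(grid$frame, function(i) {
    render_frame(scene, i, channels = "fluor", noiseless = noiseless)
  })
  truth <- truth_from_scene(scene, grid)
  structure(list(frames = frames, truth = truth, scene = scene,
                 config = config),
            class = "tf_video")
}

#' @exportS3Method base::print
print.tf_video <- function(x, ...) {
  cat(sprintf("<tf_video> %d frame(s), %.1f s @ %d fps; true TFBUT %s s\n",
              nrow(x$frames), x$config$duration_s, x$config$fps,
              ifelse(is.na(x$truth$true_tfbut_s), "censored",
                     format(x$truth$true_tfbut_s))))
  invisible(x)
}

#' Ground truth of a simulated video without rendering
#'
#' Computes the per-frame labels, blink schedule, per-segment breakup times
#' and true TFBUT for a configuration, without touching pixels. Useful for
#' oracle-label experiments at scale.
#'
#' @param config A [sim_config()].
#' @param interval_s Optional slicing interval (as in [simulate_video()]).
#' @return A list with `per_frame` (tibble `frame`, `timestamp_s`, `label`),
#'   `segments`, `blink_schedule`, and `true_tfbut_s` (`NA` when fewer than
#'   three segments are uncensored).
#' @export
simulate_truth <- function(config, interval_s = NULL) {
  scene <- sim_scene(config)
  truth_from_scene(scene, sim_frame_index(config, interval_s))
}

truth_from_scene <- function(scene, grid) {
  labels <- vapply(grid$frame, function(i) frame_label(scene, i), character(1))
  seg <- scene$segments
  unc <- seg$breakup_s[!seg$censored]
  true_tfbut <- if (length(unc) >= 3) mean(unc[1:3]) else NA_real_
  list(per_frame = tibble(frame = grid$frame, timestamp_s = grid$timestamp_s,
                          label = labels),
       segments = seg,
       blink_schedule = scene$schedule,
       true_tfbut_s = true_tfbut)
}

#' Oracle frame table from ground truth
#'
#' Converts simulator ground truth into the frame-table shape produced by
#' [preprocess_frames()] + [classify_frames()], with perfect quality calls
#' and labels. This is the "oracle labels" pathway for isolating the timing
#' logic from the classifier.
#'
#' @param truth The result of [simulate_truth()] (or a `tf_video$truth`).
#' @return A tibble with `frame`, `timestamp_s`, `quality`, `reason`,
#'   `label`, `confidence`.
#' @export
oracle_frames <- function(truth) {
  pf <- truth$per_frame
  tibble(
    frame = pf$frame, timestamp_s = pf$timestamp_s,
    quality = ifelse(pf$label %in% c("blink", "artifact"), "fail", "pass"),
    reason = dplyr::case_when(pf$label == "blink" ~ "no_cornea",
                              pf$label == "artifact" ~ "noise",
                              TRUE ~ NA_character_),
    label = ifelse(pf$label %in% c("positive", "negative"), pf$label,
                   "unknown"),
    confidence = dplyr::case_when(pf$label == "positive" ~ 1,
                                  pf$label == "negative" ~ 0,
                                  TRUE ~ NA_real_))
}

#' Write a simulated video as PNG frames with a ground-truth sidecar
#'
#' Writes `frame_000000.png` files (RGB), a `manifest.csv` (filename,
#' frame, timestamp_s) and a `truth.json` sidecar with the blink schedule,
#' per-frame labels, per-segment breakup times and true TFBUT.
#'
#' @param video A `tf_video`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_video_frames <- function(video, dir) {
  stopifnot(inherits(video, "tf_video"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("frame_%06d.png", video$frames$frame)
  purrr::walk2(video$frames$image, files, function(img, f) {
    png::writePNG(fluor_to_rgb(img), file.path(dir, f))
  })
  utils::write.csv(
    data.frame(filename = files, frame = video$frames$frame,
               timestamp_s = video$frames$timestamp_s),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- video$truth
  jsonlite::write_json(
    list(blink_schedule = truth$blink_schedule,
         per_frame_labels = truth$per_frame,
         segment_breakup_times_s = truth$segments,
         true_tfbut_s = truth$true_tfbut_s),
    file.path(dir, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a directory of frames with a manifest
#'
#' Reads ordered PNG frames plus `manifest.csv` (columns `filename`,
#' `timestamp_s`, optionally `frame`) into a frame tibble ready for
#' [preprocess_frames()].
#'
#' @param dir Directory written by [write_video_frames()] or produced by an
#'   external frame extractor.
#' @return A tibble `frame`, `timestamp_s`, `image`.
#' @export
read_frame_dir <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"))
  if (is.null(mf$frame)) mf$frame <- seq_len(nrow(mf)) - 1L
  imgs <- purrr::map(mf$filename, function(f) {
    x <- png::readPNG(file.path(dir, f))
    as_fluor(x)
  })
  tibble(frame = mf$frame, timestamp_s = mf$timestamp_s, image = imgs)
}
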