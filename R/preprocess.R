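#' Quality-screening parameters
#'
#' Thresholds for the frame exclusion rules: defocused frames
#' (`fail(no_focus)`), frames without a visible corneal disc, including
#' blinks (`fail(no_cornea)`), and frames with an occluder such as an
#' eyelash crossing the cornea (`fail(noise)`).
#'
#' @param tau_focus Minimum variance of the Laplacian response (computed on
#'   a 4x-downsampled fluorescein channel). Calibrated so that clean
#'   renders, noisy or noiseless, pass while defocused frames fail.
#' @param tau_area Minimum fraction of pixels above `bright_thr`; the open
#'   corneal disc covers roughly 20% of the frame at default geometry.
#' @param tau_occ Maximum tolerated dark fraction in the limbal ring
#'   (`ring` x disc radius): an eyelash stroke crossing the corneal rim
#'   darkens this ring, while breakup spots, confined well inside the disc,
#'   do not reach it.
#' @param bright_thr Intensity threshold separating the fluorescein disc
#'   from the dark background.
#' @param dark_thr Intensity below which a ring pixel counts as occluded.
#' @param ring Inner/outer limbal ring radii as fractions of the disc
#'   radius.
#' @return A `tf_quality_params` list.
#' @export
quality_params <- function(tau_focus = 2e-3, tau_area = 0.04, tau_occ = 0.02,
                           bright_thr = 0.3, dark_thr = 0.3,
                           ring = c(0.80, 0.93)) {
  structure(list(tau_focus = tau_focus, tau_area = tau_area,
                 tau_occ = tau_occ, bright_thr = bright_thr,
                 dark_thr = dark_thr, ring = ring),
            class = "tf_quality_params")
}

#' Slice a frame sequence onto a regular time grid
#'
#' Selects the frame nearest each tick `t = 0, interval_s, 2 interval_s, ...`
#' up to the end of the video (tick 0 included). Output timestamps are the
#' tick times. With `interval_s = 1/fps` this is the identity.
#'
#' @param frames A tibble with `timestamp_s` (strictly increasing) and any
#'   other per-frame columns.
#' @param interval_s Grid spacing in seconds, default 0.2 (the 200-ms
#'   clinical slicing convention); must be at least the source frame
#'   spacing.
#' @return The selected rows with `timestamp_s` replaced by the tick times
#'   (the source timestamp is kept as `source_timestamp_s`).
#' @export
slice_frames <- function(frames, interval_s = 0.2) {
  if (nrow(frames) == 0) abort("empty frame sequence")
  ts <- frames$timestamp_s
  if (is.unsorted(ts, strictly = TRUE)) abort("timestamps must be strictly increasing")
  dt <- if (nrow(frames) > 1) median(diff(ts)) else interval_s
  if (interval_s < dt - 1e-9) {
    abort(sprintf("interval_s (%.4f) must be at least the frame spacing (%.4f)",
                  interval_s, dt))
  }
  duration <- ts[length(ts)] + dt
  ticks <- interval_s * (0:floor(duration / interval_s + 1e-9))
  mid <- if (length(ts) > 1) (ts[-1] + ts[-length(ts)]) / 2 else numeric()
  idx <- findInterval(ticks, mid) + 1L
  keep <- !duplicated(idx)
  out <- frames[idx[keep], , drop = FALSE]
  out$source_timestamp_s <- out$timestamp_s
  out$timestamp_s <- ticks[keep]
  out
}

# Laplacian-response variance on a 4x-downsampled fluorescein channel:
# the focus score. Sharp frames keep high-frequency content (disc rim and
# sensor noise); defocused frames lose both.
focus_score <- function(img) focus_score_ds(cpp_downsample(img, 4L))

focus_score_ds <- function(d) {
  nr <- nrow(d); nc <- ncol(d)
  lap <- 4 * d[2:(nr - 1), 2:(nc - 1)] -
    d[1:(nr - 2), 2:(nc - 1)] - d[3:nr, 2:(nc - 1)] -
    d[2:(nr - 1), 1:(nc - 2)] - d[2:(nr - 1), 3:nc]
  var(as.vector(lap))
}

# Full quality workup of one frame; returns the ROI when one was found so
# callers do not detect it twice. Rule order: a frame without a visible
# corneal disc (blink) is no_cornea regardless of sharpness; then focus;
# then the occluder score on the detected disc.
frame_quality <- function(image, params = quality_params()) {
  img <- as_fluor(image)
  ds <- cpp_downsample(img, 4L)
  bc <- cpp_bright_counts(ds, params$bright_thr)
  focus <- focus_score_ds(ds)
  if (bc$frac < params$tau_area) {
    return(list(status = "fail", reason = "no_cornea", roi = NULL,
                focus = focus, bright_frac = bc$frac, occ_frac = NA_real_))
  }
  if (focus < params$tau_focus) {
    return(list(status = "fail", reason = "no_focus", roi = NULL,
                focus = focus, bright_frac = bc$frac, occ_frac = NA_real_))
  }
  roi <- tryCatch(detect_cornea(img, bright_thr = params$bright_thr, ds = ds),
                  error = function(e) NULL)
  if (is.null(roi)) {
    return(list(status = "fail", reason = "no_cornea", roi = NULL,
                focus = focus, bright_frac = bc$frac, occ_frac = NA_real_))
  }
  occ <- cpp_dark_ring_frac(img, roi$y, roi$x, params$ring[1] * roi$r,
                            params$ring[2] * roi$r, params$dark_thr)
  if (occ > params$tau_occ) {
    return(list(status = "fail", reason = "noise", roi = roi,
                focus = focus, bright_frac = bc$frac, occ_frac = occ))
  }
  list(status = "pass", reason = NA_character_, roi = roi,
       focus = focus, bright_frac = bc$frac, occ_frac = occ)
}

#' Screen a frame for usability
#'
#' Applies the exclusion rules in order: defocus, missing corneal disc
#' (covers blink frames), occluding noise such as eyelashes.
#'
#' @param image A frame (matrix or RGB array) in `[0, 1]`.
#' @param params A [quality_params()].
#' @return A list with `status` (`"pass"`/`"fail"`) and `reason`
#'   (`NA`, `"no_focus"`, `"no_cornea"`, or `"noise"`).
#' @export
assess_quality <- function(image, params = quality_params()) {
  q <- frame_quality(image, params)
  list(status = q$status, reason = q$reason)
}

#' Detect the corneal region of interest
#'
#' Finds the enclosing circle of the largest bright connected component of
#' the fluorescein channel: components are labeled on a 4x-downsampled
#' threshold mask, the largest is selected, and its extent is refined at
#' full resolution from bright-run row/column projections (isolated
#' supra-threshold noise pixels are ignored). Deterministic.
#'
#' @param image A frame in `[0, 1]`.
#' @param bright_thr Disc/background intensity threshold.
#' @param min_frac Minimum component size as a fraction of the frame; below
#'   this the frame has no usable cornea and an error is raised (the
#'   quality filter should have excluded it).
#' @param ds Optional precomputed 4x-downsample of the fluorescein channel.
#' @return A list `x`, `y` (1-based center column/row) and `r` (radius,
#'   pixels) in source coordinates.
#' @export
detect_cornea <- function(image, bright_thr = 0.3, min_frac = 0.01,
                          ds = NULL) {
  img <- as_fluor(image)
  if (is.null(ds)) ds <- cpp_downsample(img, 4L)
  lab <- EBImage::bwlabel(ds > bright_thr)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0 || max(sizes) < min_frac * length(ds)) {
    abort("no bright corneal component found")
  }
  k <- which.max(sizes)
  px <- which(lab == k, arr.ind = TRUE)
  # full-resolution window around the component, with a small guard band
  r0 <- max(1L, (min(px[, 1]) - 2L) * 4L - 4L)
  r1 <- min(nrow(img), max(px[, 1]) * 4L + 4L)
  c0 <- max(1L, (min(px[, 2]) - 2L) * 4L - 4L)
  c1 <- min(ncol(img), max(px[, 2]) * 4L + 4L)
  sub <- img[r0:r1, c0:c1]
  bc <- cpp_bright_counts(sub, bright_thr)
  rows <- which(bc$rows >= 3L)
  cols <- which(bc$cols >= 3L)
  if (length(rows) == 0 || length(cols) == 0) abort("no bright corneal component found")
  cy <- (min(rows) + max(rows)) / 2 + r0 - 1
  cx <- (min(cols) + max(cols)) / 2 + c0 - 1
  r <- ((max(rows) - min(rows)) + (max(cols) - min(cols))) / 4 + 0.5
  list(x = cx, y = cy, r = r)
}

#' Standardize a frame to 384 x 384 corneal coordinates
#'
#' Crops the square bounding box of the ROI circle plus a relative margin
#' (clipped to the image bounds), resizes with bilinear interpolation and
#' clamps intensities to `[0, 1]`. In standardized coordinates the corneal
#' disc is centered with radius `size / (2 (1 + margin))`.
#'
#' @param image A frame in `[0, 1]` (matrix or RGB array; channels are
#'   resized independently).
#' @param roi A list `x`, `y`, `r` from [detect_cornea()].
#' @param size Output side length in pixels.
#' @param margin Extra crop margin as a fraction of the ROI radius.
#' @return A `size` x `size` matrix (or array).
#' @export
standardize_frame <- function(image, roi, size = 384L, margin = 0.1) {
  if (is.null(roi$r) || roi$r <= 0) abort("degenerate ROI: radius must be positive")
  half <- roi$r * (1 + margin)
  crop1 <- function(m) {
    r0 <- max(1L, as.integer(floor(roi$y - half + 0.5)))
    r1 <- min(nrow(m), as.integer(floor(roi$y + half - 0.5)))
    c0 <- max(1L, as.integer(floor(roi$x - half + 0.5)))
    c1 <- min(ncol(m), as.integer(floor(roi$x + half - 0.5)))
    cpp_crop_resize(m, r0, r1, c0, c1, size, size)
  }
  if (is.matrix(image)) return(crop1(image))
  out <- array(0, dim = c(size, size, dim(image)[3]))
  for (k in seq_len(dim(image)[3])) out[, , k] <- crop1(image[, , k])
  out
}

# ImageNet channel normalization constants (RGB order).
IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Augment a standardized frame
#'
#' The training-time augmentation recipe: horizontal flip with probability
#' `p_flip`, transpose with probability `p_transpose`, then always
#' channel-wise normalization with the fixed ImageNet mean/sd constants
#' (the green-channel constants for single-channel frames). Seeded and
#' reproducible.
#'
#' @param image A standardized frame.
#' @param seed Integer seed for the flip/transpose draws.
#' @param p_flip,p_transpose Application probabilities.
#' @param normalize Apply the normalization step (always on during
#'   training; disable to inspect the geometric part alone).
#' @return The augmented frame; normalized output is no longer confined to
#'   `[0, 1]`.
#' @export
augment_frame <- function(image, seed, p_flip = 0.5, p_transpose = 0.5,
                          normalize = TRUE) {
  geom <- withr::with_seed(seed, list(flip = runif(1) < p_flip,
                                      transpose = runif(1) < p_transpose))
  flip1 <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  app <- function(m, mean, sd) {
    if (geom$flip) m <- flip1(m)
    if (geom$transpose) m <- t(m)
    if (normalize) m <- (m - mean) / sd
    m
  }
  if (is.matrix(image)) {
    return(app(image, IMAGENET_MEAN[2], IMAGENET_SD[2]))
  }
  out <- array(0, dim = dim(image))
  for (k in seq_len(dim(image)[3])) {
    out[, , k] <- app(image[, , k], IMAGENET_MEAN[k], IMAGENET_SD[k])
  }
  out
}

#' Preprocess a frame table
#'
#' Runs the standardization pipeline over a frame tibble: optional slicing
#' onto the 0.2-s grid, quality screening, corneal ROI detection, and
#' 384 x 384 standardization of passing frames. Quality-failed frames keep
#' their row (and timestamp) so that segment timing sees a gap, not a time
#' shift.
#'
#' @param frames A tibble with `frame`, `timestamp_s` and an `image`
#'   list-column (as from [simulate_video()]`$frames` or
#'   [read_frame_dir()]).
#' @param interval_s Optional slicing interval; `NULL` keeps all frames.
#' @param params [quality_params()].
#' @param size,margin Standardization geometry (see [standardize_frame()]).
#' @param keep_source Keep the source `image` column (off by default: the
#'   standardized crop is what downstream steps consume).
#' @return A tibble `frame`, `timestamp_s`, `quality`, `reason`, `roi_x`,
#'   `roi_y`, `roi_r`, `focus`, `image_std` (list-column, `NULL` where
#'   quality failed).
#' @export
preprocess_frames <- function(frames, interval_s = NULL,
                              params = quality_params(),
                              size = 384L, margin = 0.1,
                              keep_source = FALSE) {
  if (!is.null(interval_s)) frames <- slice_frames(frames, interval_s)
  res <- purrr::map(frames$image, function(img) {
    q <- frame_quality(img, params)
    std <- if (q$status == "pass") {
      standardize_frame(img, q$roi, size = size, margin = margin)
    } else NULL
    list(q = q, std = std)
  })
  out <- tibble(
    frame = frames$frame,
    timestamp_s = frames$timestamp_s,
    quality = purrr::map_chr(res, ~ .x$q$status),
    reason = purrr::map_chr(res, ~ .x$q$reason %||% NA_character_),
    roi_x = purrr::map_dbl(res, ~ .x$q$roi$x %||% NA_real_),
    roi_y = purrr::map_dbl(res, ~ .x$q$roi$y %||% NA_real_),
    roi_r = purrr::map_dbl(res, ~ .x$q$roi$r %||% NA_real_),
    focus = purrr::map_dbl(res, ~ .x$q$focus),
    image_std = purrr::map(res, "std"))
  if (keep_source) out$image <- frames$image
  out
}
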