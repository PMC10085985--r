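#' Dark-spot detector parameters
#'
#' Parameters of the interpretable breakup detector, which implements the
#' clinical annotation criterion directly: a frame is breakup-positive when
#' it contains at least one black (fluorescein-dark) spot on the cornea.
#'
#' @param depth_frac A pixel is "dark" when below `depth_frac` times the
#'   local fluorescein background.
#' @param min_area Minimum connected dark area, in pixels, to count as a
#'   spot.
#' @param mask_erosion Pixels shaved off the corneal mask radius to avoid
#'   limbus edge effects.
#' @param decision_threshold Confidence cutoff for the positive label.
#' @param size,margin Standardized-frame geometry; the corneal disc in
#'   standardized coordinates is centered with radius
#'   `size / (2 (1 + margin))`.
#' @return A `tf_spot_params` list.
#' @export
spot_params <- function(depth_frac = 0.55, min_area = 20, mask_erosion = 8,
                        decision_threshold = 0.5, size = 384L, margin = 0.1) {
  stopifnot(depth_frac > 0, depth_frac < 1, min_area >= 1,
            decision_threshold >= 0, decision_threshold <= 1)
  structure(list(depth_frac = depth_frac, min_area = min_area,
                 mask_erosion = mask_erosion,
                 decision_threshold = decision_threshold,
                 size = as.integer(size), margin = margin),
            class = "tf_spot_params")
}

# Cache of corneal-mask geometry per (size, margin, erosion).
.mask_cache <- new.env(parent = emptyenv())

corneal_mask <- function(size, margin, erosion) {
  key <- paste(size, margin, erosion, sep = "_")
  m <- .mask_cache[[key]]
  if (!is.null(m)) return(m)
  c0 <- (size + 1) / 2
  r <- size / (2 * (1 + margin)) - erosion
  d <- sqrt(outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, `+`))
  m <- list(mask = d <= r, r = r, c0 = c0)
  .mask_cache[[key]] <- m
  m
}

#' Detect dark breakup spots in a standardized frame
#'
#' Estimates the fluorescein background as the median intensity inside the
#' eroded corneal mask, thresholds pixels below `depth_frac` times that
#' background, and returns connected components of at least `min_area`
#' pixels. Deterministic; an empty tibble means no spots.
#'
#' @param image A standardized `size` x `size` frame.
#' @param params [spot_params()].
#' @return A tibble with one row per spot: `spot`, `x`, `y` (centroid),
#'   `area_px`, `mean_depth` (mean fractional intensity loss relative to
#'   background).
#' @export
detect_spots <- function(image, params = spot_params()) {
  img <- check_standardized(image, params$size)
  geo <- corneal_mask(params$size, params$margin, params$mask_erosion)
  bg <- median(img[geo$mask])
  dark <- geo$mask & (img < params$depth_frac * bg)
  empty <- tibble(spot = integer(), x = numeric(), y = numeric(),
                  area_px = integer(), mean_depth = numeric())
  if (!any(dark)) return(empty)
  lab <- EBImage::bwlabel(dark)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_area)
  if (length(keep) == 0) return(empty)
  purrr::map_dfr(seq_along(keep), function(i) {
    px <- which(lab == keep[i], arr.ind = TRUE)
    vals <- img[px]
    tibble(spot = i, x = mean(px[, 2]), y = mean(px[, 1]),
           area_px = nrow(px), mean_depth = mean(1 - vals / bg))
  })
}

#' Rule-based breakup classifier
#'
#' The default frame classifier: confidence is a monotone saturating
#' function of the total spot evidence,
#' `1 - exp(-k * sum(area * mean_depth))`, so zero evidence gives
#' confidence 0 and adding or deepening spots never lowers it. The default
#' `k` makes a single minimum-area spot at full depth score about 0.7.
#'
#' @param params [spot_params()].
#' @param k Evidence-to-confidence rate.
#' @return A `tf_classifier` of kind `"rule_based"`.
#' @export
rule_classifier <- function(params = spot_params(), k = 0.06) {
  structure(list(kind = "rule_based", params = params, k = k),
            class = "tf_classifier")
}

#' @exportS3Method base::print
print.tf_classifier <- function(x, ...) {
  if (x$kind == "rule_based") {
    cat(sprintf("<tf_classifier> rule_based (k = %g, min_area = %g, depth_frac = %g)\n",
                x$k, x$params$min_area, x$params$depth_frac))
  } else {
    md <- x$metadata
    cat(sprintf("<tf_classifier> trained (n_train = %d, n_valid = %d, valid accuracy = %.3f)\n",
                md$n_train, md$n_valid, md$valid_accuracy))
  }
  invisible(x)
}

#' Classify one standardized frame
#'
#' @param image A standardized frame.
#' @param model A `tf_classifier` ([rule_classifier()] or
#'   [train_classifier()]).
#' @return A list with `label` (`"positive"`/`"negative"`) and `confidence`
#'   in `[0, 1]`; the label is positive iff confidence is at least the
#'   model's decision threshold.
#' @export
classify_frame <- function(image, model = rule_classifier()) {
  stopifnot(inherits(model, "tf_classifier"))
  conf <- predict(model, image)
  thr <- decision_threshold(model)
  list(label = if (conf >= thr) "positive" else "negative", confidence = conf)
}

decision_threshold <- function(model) {
  if (model$kind == "rule_based") model$params$decision_threshold
  else model$decision_threshold
}

#' Predict breakup confidence for a frame
#'
#' @param object A `tf_classifier`.
#' @param image A standardized frame.
#' @param ... Unused.
#' @return Confidence in `[0, 1]`.
#' @export
predict.tf_classifier <- function(object, image, ...) {
  if (object$kind == "rule_based") {
    spots <- detect_spots(image, object$params)
    evidence <- sum(spots$area_px * spots$mean_depth)
    1 - exp(-object$k * evidence)
  } else {
    img <- check_standardized(image, object$size)
    img <- (img - IMAGENET_MEAN[2]) / IMAGENET_SD[2]
    f <- frame_features(img)
    unname(plogis(object$a0 + sum(f * object$beta)))
  }
}

#' Classify all passing frames of a frame table
#'
#' Adds `label` and `confidence` columns: quality-passing frames are
#' classified; failed frames get label `"unknown"` and `NA` confidence (they
#' are excluded from timing but keep their place in the segment timeline).
#'
#' @param frames A preprocessed frame tibble (see [preprocess_frames()]).
#' @param model A `tf_classifier`.
#' @return The tibble with `label` and `confidence` columns.
#' @export
classify_frames <- function(frames, model = rule_classifier()) {
  res <- purrr::map2(frames$image_std, frames$quality, function(img, q) {
    if (!identical(q, "pass") || is.null(img)) {
      list(label = "unknown", confidence = NA_real_)
    } else {
      classify_frame(img, model)
    }
  })
  frames$label <- purrr::map_chr(res, "label")
  frames$confidence <- purrr::map_dbl(res, "confidence")
  frames
}

# Feature map of the trainable surrogate: intensity quantiles of the
# eroded corneal interior. The low quantiles collapse as soon as any dark
# region exists on the cornea -- the defining property of a breakup frame
# -- and the descriptor is invariant to the flip/transpose augmentation
# and to where on the cornea the spot sits, so the model generalizes
# across videos instead of memorizing per-video spot positions.
FEATURE_PROBS <- c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9)

frame_features <- function(img) {
  geo <- corneal_mask(nrow(img), 0.1, 8)
  quantile(img[geo$mask], FEATURE_PROBS, names = FALSE)
}

#' Train the small surrogate classifier
#'
#' A ridge-regularized logistic regression on corneal-interior intensity
#' quantile features of
#' normalized standardized frames. The development set is split 8:2 into
#' train and validation, grouped by source video (no video straddles the
#' split) and seeded; augmentation ([augment_frame()]) is applied to
#' training frames only; the regularization strength is chosen by
#' validation deviance. The same data and seed always give identical
#' parameters. Features are intensity quantiles of the corneal interior
#' of the normalized frame (see the package vignette for why pooled-pixel
#' grids were rejected: they memorize per-video spot positions).
#'
#' @param frames A tibble with `image_std` (standardized frames), `label`
#'   (`"positive"`/`"negative"`), and optionally `video` (source-video id
#'   used for group-aware splitting; without it every frame is its own
#'   group).
#' @param seed Integer seed for the split and augmentation.
#' @param valid_frac Validation fraction of the development set.
#' @param decision_threshold Confidence cutoff for the positive label.
#' @return A `tf_classifier` of kind `"trained"` with training metadata.
#' @export
train_classifier <- function(frames, seed = 1,
                             valid_frac = 0.2, decision_threshold = 0.5) {
  qual <- if ("quality" %in% names(frames)) frames$quality else "pass"
  frames <- frames[qual == "pass" &
                     !purrr::map_lgl(frames$image_std, is.null), ]
  if (nrow(frames) == 0) abort("no usable frames to train on")
  y <- frames$label
  if (length(unique(y)) < 2) abort("training data must contain both classes")
  group <- if (!is.null(frames$video)) as.character(frames$video)
           else as.character(seq_len(nrow(frames)))
  vids <- unique(group)
  valid_groups <- withr::with_seed(seed, {
    if (length(vids) < 2) {
      character()
    } else {
      vs <- sample(vids)
      sizes <- vapply(vs, function(v) sum(group == v), integer(1))
      k <- which(cumsum(sizes) >= valid_frac * nrow(frames))[1]
      if (is.na(k)) k <- 1L
      vs[seq_len(min(k, length(vs) - 1L))]
    }
  })
  in_valid <- group %in% valid_groups
  if (!any(in_valid) || all(in_valid)) {
    # fall back to a stratified frame-level split
    in_valid <- withr::with_seed(seed, {
      iv <- logical(nrow(frames))
      for (cl in unique(y)) {
        idx <- which(y == cl)
        iv[sample(idx, max(1, round(valid_frac * length(idx))))] <- TRUE
      }
      iv
    })
  }
  size <- nrow(frames$image_std[[1]])
  feats <- purrr::imap(frames$image_std, function(img, i) {
    img <- if (in_valid[i]) {
      augment_frame(img, seed = 0, p_flip = 0, p_transpose = 0)
    } else {
      augment_frame(img, seed = frame_seed(seed, i))
    }
    frame_features(img)
  })
  x <- do.call(rbind, feats)
  yy <- as.integer(y == "positive")
  # ridge paths start very high in glmnet; extend the path far enough down
  # that the validation-selected model can actually fit the signal
  fit <- glmnet::glmnet(x[!in_valid, , drop = FALSE], yy[!in_valid],
                        family = "binomial", alpha = 0, nlambda = 50,
                        lambda.min.ratio = 1e-7)
  pv <- predict(fit, x[in_valid, , drop = FALSE], type = "response")
  dev <- apply(pv, 2, function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -2 * sum(yy[in_valid] * log(p) + (1 - yy[in_valid]) * log(1 - p))
  })
  j <- which.min(dev)
  beta <- as.numeric(fit$beta[, j])
  a0 <- fit$a0[[j]]
  acc <- mean((pv[, j] >= decision_threshold) == (yy[in_valid] == 1))
  structure(
    list(kind = "trained", a0 = a0, beta = beta, lambda = fit$lambda[[j]],
         size = as.integer(size), feature_probs = FEATURE_PROBS,
         decision_threshold = decision_threshold,
         metadata = list(split_fractions = c(train = 1 - valid_frac,
                                             valid = valid_frac),
                         seed = seed, n_train = sum(!in_valid),
                         n_valid = sum(in_valid), valid_accuracy = acc)),
    class = "tf_classifier")
}

#' Serialize a classifier to a self-describing JSON file
#'
#' @param model A `tf_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "tf_classifier"))
  obj <- unclass(model)
  if (obj$kind == "rule_based") obj$params <- unclass(obj$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "rule_based") {
    return(rule_classifier(params = do.call(spot_params, as.list(obj$params)),
                           k = obj$k))
  }
  obj$metadata <- as.list(obj$metadata)
  structure(obj, class = "tf_classifier")
}

#' Attribution heatmap for a classified frame
#'
#' Highlights the image evidence behind a classification, mirroring
#' class-activation visualization: on a breakup-positive frame the hottest
#' region lies inside a spot; on a negative frame the map stays near zero.
#' For the rule-based classifier the map is the analytic per-pixel spot
#' contribution (fractional intensity loss inside detected spots); for
#' trained models it is model-agnostic occlusion attribution (confidence
#' drop when a patch is replaced by the background median), so values are
#' in confidence units in `[0, 1]` and are deliberately not re-normalized
#' to full scale.
#'
#' @param image A standardized frame.
#' @param model A `tf_classifier`.
#' @param patch,stride Occlusion patch size and stride, pixels.
#' @return A matrix of the same size as the frame with values in `[0, 1]`.
#' @export
attribution_map <- function(image, model = rule_classifier(),
                            patch = 48L, stride = 24L) {
  img <- check_standardized(image,
                            if (model$kind == "rule_based") model$params$size
                            else model$size)
  hm <- matrix(0, nrow(img), ncol(img))
  if (model$kind == "rule_based") {
    params <- model$params
    geo <- corneal_mask(params$size, params$margin, params$mask_erosion)
    bg <- median(img[geo$mask])
    dark <- geo$mask & (img < params$depth_frac * bg)
    if (any(dark)) {
      lab <- EBImage::bwlabel(dark)
      sizes <- tabulate(lab[lab > 0])
      for (k in which(sizes >= params$min_area)) {
        px <- which(lab == k)
        hm[px] <- pmin(pmax(1 - img[px] / bg, 0), 1)
      }
    }
    return(hm)
  }
  base <- predict(model, img)
  starts <- seq(1, nrow(img) - patch + 1, by = stride)
  for (i in starts) {
    for (j in starts) {
      ri <- i:(i + patch - 1); cj <- j:(j + patch - 1)
      med <- median(img[ri, cj])
      occ <- img
      # flatten the patch to its own median: removes local structure
      # without pushing the frame outside the training distribution
      occ[ri, cj] <- med
      drop <- max(0, base - predict(model, occ))
      if (drop > 0) {
        # credit the pixels the occlusion actually erased (darker than
        # the patch median), so the peak lands inside the dark evidence
        w <- pmax(med - img[ri, cj], 0)
        if (max(w) > 0) w <- w / max(w)
        hm[ri, cj] <- pmax(hm[ri, cj], drop * w)
      }
    }
  }
  pmin(pmax(hm, 0), 1)
}
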