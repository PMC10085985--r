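#' Build a 2 x 2 confusion table
#'
#' @param pred,truth Equal-length label vectors.
#' @param positive The positive-class label (breakup-positive at frame
#'   level, DED at case level).
#' @return A `tf_confusion` with counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_table <- function(pred, truth, positive = "positive") {
  if (length(pred) != length(truth)) abort("pred and truth must have equal length")
  p <- pred == positive
  t <- truth == positive
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t),
                 positive = positive),
            class = "tf_confusion")
}

#' @exportS3Method base::print
print.tf_confusion <- function(x, ...) {
  cat(sprintf("<tf_confusion> tp=%d fp=%d fn=%d tn=%d (positive = %s)\n",
              x$tp, x$fp, x$fn, x$tn, x$positive))
  invisible(x)
}

#' @export
tidy.tf_confusion <- function(x, ...) {
  tibble(cell = c("tp", "fp", "fn", "tn"),
         count = c(x$tp, x$fp, x$fn, x$tn))
}

ct_total <- function(ct) ct$tp + ct$fp + ct$fn + ct$tn

# Exact (Clopper-Pearson) binomial interval for k successes of n.
exact_ci <- function(k, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(binom.test(k, n, conf.level = conf_level)$conf.int)
}

#' Accuracy and F1 with confidence intervals
#'
#' Accuracy gets an exact binomial interval; F1 (harmonic mean of precision
#' and recall) a seeded multinomial bootstrap over the table cells
#' (equivalent to resampling items). When no positives are predicted or
#' present, F1 is flagged undefined (`NA`) rather than silently zero.
#'
#' @param ct A [confusion_table()].
#' @param conf_level Confidence level.
#' @param n_boot Bootstrap replicates for the F1 interval.
#' @param seed Bootstrap seed.
#' @return A tibble `metric`, `estimate`, `conf_low`, `conf_high`, `method`.
#' @export
accuracy_f1 <- function(ct, conf_level = 0.95, n_boot = 2000, seed = 1) {
  stopifnot(inherits(ct, "tf_confusion"))
  n <- ct_total(ct)
  if (n == 0) abort("empty confusion table")
  acc <- (ct$tp + ct$tn) / n
  acc_ci <- exact_ci(ct$tp + ct$tn, n, conf_level)
  f1_of <- function(tp, fp, fn) {
    if (tp + fp == 0 || tp + fn == 0) return(NA_real_)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    if (prec + rec == 0) return(NA_real_)
    2 * prec * rec / (prec + rec)
  }
  f1 <- f1_of(ct$tp, ct$fp, ct$fn)
  f1_ci <- c(NA_real_, NA_real_)
  if (!is.na(f1)) {
    probs <- c(ct$tp, ct$fp, ct$fn, ct$tn) / n
    f1s <- withr::with_seed(seed, {
      draws <- stats::rmultinom(n_boot, n, probs)
      vapply(seq_len(n_boot), function(i) {
        f1_of(draws[1, i], draws[2, i], draws[3, i])
      }, numeric(1))
    })
    a <- (1 - conf_level) / 2
    f1_ci <- unname(quantile(f1s, c(a, 1 - a), na.rm = TRUE))
  }
  tibble(metric = c("accuracy", "f1"),
         estimate = c(acc, f1),
         conf_low = c(acc_ci[1], f1_ci[1]),
         conf_high = c(acc_ci[2], f1_ci[2]),
         method = c("exact binomial", sprintf("bootstrap (%d, seed %d)", n_boot, seed)))
}

#' Sensitivity, specificity, PPV and NPV with exact intervals
#'
#' Each proportion gets an exact binomial (Clopper-Pearson) interval on its
#' own margin. A zero denominator leaves the metric `NA` (undefined,
#' flagged by the `n` column).
#'
#' @param ct A [confusion_table()].
#' @param conf_level Confidence level.
#' @return A tibble `metric`, `estimate`, `conf_low`, `conf_high`, `n`.
#' @export
diagnostic_metrics <- function(ct, conf_level = 0.95) {
  stopifnot(inherits(ct, "tf_confusion"))
  rows <- list(
    sensitivity = c(ct$tp, ct$tp + ct$fn),
    specificity = c(ct$tn, ct$tn + ct$fp),
    ppv = c(ct$tp, ct$tp + ct$fp),
    npv = c(ct$tn, ct$tn + ct$fn))
  purrr::imap_dfr(rows, function(kn, metric) {
    k <- kn[1]; n <- kn[2]
    est <- if (n > 0) k / n else NA_real_
    ci <- exact_ci(k, n, conf_level)
    tibble(metric = metric, estimate = est,
           conf_low = ci[1], conf_high = ci[2], n = n)
  })
}

# Rank-statistic AUC: probability a random positive outranks a random
# negative, midrank ties counted half.
auc_rank <- function(scores, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  r <- rank(scores)  # midranks
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve and AUC with a bootstrap interval
#'
#' AUC by the rank statistic (midrank ties get half credit); the curve from
#' a full sweep over the observed score thresholds (prediction positive iff
#' score >= threshold); the interval from a seeded stratified bootstrap
#' with percentile limits. The trapezoid area under the returned curve
#' equals the rank-statistic AUC.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth Label vector.
#' @param positive Positive-class label.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level.
#' @return A `tf_roc`: `auc`, `conf_low`, `conf_high`, `curve` (tibble
#'   `threshold`, `tpr`, `fpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, truth, positive = "positive", n_boot = 2000,
                    seed = 1, conf_level = 0.95) {
  is_pos <- truth == positive
  if (!any(is_pos) || all(is_pos)) abort("both classes must be present for a ROC curve")
  if (any(is.na(scores))) abort("scores must be finite (NA found)")
  auc <- auc_rank(scores, is_pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[is_pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!is_pos] >= t), numeric(1))
  pos_scores <- scores[is_pos]; neg_scores <- scores[!is_pos]
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      p <- sample(pos_scores, replace = TRUE)
      n <- sample(neg_scores, replace = TRUE)
      auc_rank(c(p, n), c(rep(TRUE, length(p)), rep(FALSE, length(n))))
    }, numeric(1))
  })
  a <- (1 - conf_level) / 2
  ci <- unname(quantile(aucs, c(a, 1 - a)))
  structure(list(auc = auc, conf_low = ci[1], conf_high = ci[2],
                 curve = tibble(threshold = thr, tpr = tpr, fpr = fpr),
                 n_pos = sum(is_pos), n_neg = sum(!is_pos),
                 n_boot = n_boot, seed = seed),
            class = "tf_roc")
}

#' @exportS3Method base::print
print.tf_roc <- function(x, ...) {
  cat(sprintf("<tf_roc> AUC = %.3f (95%% CI %.3f-%.3f), %d positive / %d negative\n",
              x$auc, x$conf_low, x$conf_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.tf_roc <- function(x, ...) x$curve

#' @export
glance.tf_roc <- function(x, ...) {
  tibble(auc = x$auc, conf_low = x$conf_low, conf_high = x$conf_high,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Spearman correlation with a Fisher-z interval
#'
#' Spearman's r as the Pearson correlation of midranks, with the interval
#' from the Fisher z transform and standard error `1/sqrt(n - 3)` (a
#' documented large-sample approximation).
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @param conf_level Confidence level.
#' @return A tibble `estimate`, `conf_low`, `conf_high`, `n`.
#' @export
spearman_ci <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant input: Spearman correlation undefined")
    return(tibble(estimate = NA_real_, conf_low = NA_real_,
                  conf_high = NA_real_, n = n))
  }
  r <- cor(x, y, method = "spearman")
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble(estimate = r, conf_low = tanh(z - q * se),
         conf_high = tanh(z + q * se), n = n)
}

#' Frame-level evaluation report
#'
#' The frame-classification statistics: confusion table, accuracy, F1 and
#' ROC/AUC of the confidence scores, each with a 95% interval.
#'
#' @param frames A classified frame tibble with a ground-truth column.
#' @param truth_col Name of the truth column (labels
#'   `"positive"`/`"negative"`).
#' @param n_boot,seed Bootstrap settings for the F1 and AUC intervals.
#' @return A `tf_eval`: `metrics` tibble, `confusion`, `roc`.
#' @export
evaluate_frames <- function(frames, truth_col = "truth", n_boot = 2000,
                            seed = 1) {
  keep <- frames$label %in% c("positive", "negative") &
    frames[[truth_col]] %in% c("positive", "negative")
  fr <- frames[keep, ]
  ct <- confusion_table(fr$label, fr[[truth_col]])
  af <- accuracy_f1(ct, n_boot = n_boot, seed = seed)
  roc <- roc_auc(fr$confidence, fr[[truth_col]], n_boot = n_boot, seed = seed)
  metrics <- dplyr::bind_rows(
    af[, c("metric", "estimate", "conf_low", "conf_high")],
    tibble(metric = "auc", estimate = roc$auc,
           conf_low = roc$conf_low, conf_high = roc$conf_high))
  structure(list(metrics = metrics, confusion = ct, roc = roc,
                 level = "frame", n = nrow(fr)),
            class = "tf_eval")
}

#' Case-level evaluation report
#'
#' Diagnostic performance of the predicted dry-eye labels against the
#' reference: sensitivity, specificity, PPV, NPV (exact intervals) and a
#' ROC over the estimated TFBUT as continuous score (symptom criterion
#' held fixed: eyes with OSDI of 13 or less can never score as DED, so
#' their score is `-Inf`; otherwise the score is `-tfbut_s`, shorter
#' breakup scoring higher).
#'
#' @param cases A diagnosed case tibble with `predicted_dx`,
#'   `reference_dx`, `tfbut_s`, `osdi_score`.
#' @param n_boot,seed Bootstrap settings for the AUC interval.
#' @return A `tf_eval`: `metrics`, `confusion`, `roc`.
#' @export
evaluate_cases <- function(cases, n_boot = 2000, seed = 1) {
  keep <- cases$reference_dx %in% c("DED", "non-DED")
  cs <- cases[keep, ]
  ct <- confusion_table(cs$predicted_dx, cs$reference_dx, positive = "DED")
  dm <- diagnostic_metrics(ct)
  score <- ifelse(cs$osdi_score > 13, -cs$tfbut_s, -Inf)
  roc <- roc_auc(score, cs$reference_dx, positive = "DED",
                 n_boot = n_boot, seed = seed)
  metrics <- dplyr::bind_rows(
    dm[, c("metric", "estimate", "conf_low", "conf_high")],
    tibble(metric = "auc", estimate = roc$auc,
           conf_low = roc$conf_low, conf_high = roc$conf_high))
  structure(list(metrics = metrics, confusion = ct, roc = roc,
                 level = "case", n = nrow(cs)),
            class = "tf_eval")
}

#' @exportS3Method base::print
print.tf_eval <- function(x, ...) {
  cat(sprintf("<tf_eval> %s-level report over %d unit(s)\n", x$level, x$n))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.tf_eval <- function(x, ...) x$metrics

#' @export
glance.tf_eval <- function(x, ...) {
  est <- setNames(as.list(x$metrics$estimate), x$metrics$metric)
  dplyr::bind_cols(tibble(level = x$level, n = x$n), as_tibble(est))
}
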