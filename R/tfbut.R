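#' Segment a frame table into inter-blink intervals
#'
#' A blink is a maximal run of `fail(no_cornea)` frames; each measurement
#' segment starts at the timestamp of the first passing frame after a blink
#' (eye opening, the t = 0 reference of that segment) and ends at the next
#' blink onset or the end of the video. The interval before the first blink
#' is discarded: clinically, breakup is timed from a blink opening.
#'
#' @param frames A frame tibble with `timestamp_s`, `quality`, `reason`.
#' @return A tibble `segment`, `opening_s`, `end_s`, `n_frames` (passing
#'   frames in the segment). If fewer than three segments are found (the
#'   protocol requires three measurements), the result carries a
#'   `"warning"` attribute and a warning is raised.
#' @export
blink_segments <- function(frames) {
  stopifnot(all(c("timestamp_s", "quality", "reason") %in% names(frames)))
  frames <- frames[order(frames$timestamp_s), ]
  ts <- frames$timestamp_s
  is_blink <- frames$quality == "fail" & !is.na(frames$reason) &
    frames$reason == "no_cornea"
  r <- rle(is_blink)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blink_runs <- which(r$values)
  dt <- if (length(ts) > 1) median(diff(ts)) else 0
  video_end <- ts[length(ts)] + dt
  segs <- purrr::map_dfr(seq_along(blink_runs), function(k) {
    run_end <- ends[blink_runs[k]]
    after <- which(frames$quality == "pass" & seq_along(ts) > run_end)
    # segment ends at the next blink onset
    nxt <- if (k < length(blink_runs)) ts[starts[blink_runs[k + 1]]] else video_end
    after <- after[ts[after] < nxt]
    if (length(after) == 0) return(tibble())
    tibble(opening_s = ts[after[1]], end_s = nxt, n_frames = length(after))
  })
  if (nrow(segs) > 0) segs <- tibble(segment = seq_len(nrow(segs)), segs)
  else segs <- tibble(segment = integer(), opening_s = numeric(),
                      end_s = numeric(), n_frames = integer())
  if (nrow(segs) < 3) {
    warn(sprintf("only %d complete blink segment(s) found; the measurement protocol requires three",
                 nrow(segs)))
    attr(segs, "warning") <- "fewer_than_three_segments"
  }
  segs
}

#' Per-segment breakup times
#'
#' Within each segment, the breakup time is the timestamp of the first
#' quality-passing frame labeled positive -- with positivity required to
#' persist for `k_persist` consecutive passing frames -- minus the opening
#' time. If no such frame exists before the segment ends, the segment is
#' censored at its length (the breakup time is only known to exceed it).
#' Quality-failed frames leave gaps in the timeline; onset is never
#' interpolated across them.
#'
#' @param frames A classified frame tibble (`timestamp_s`, `quality`,
#'   `label`).
#' @param segments A [blink_segments()] tibble (computed from `frames` when
#'   omitted).
#' @param k_persist Consecutive positive passing frames required to accept
#'   an onset; the default 1 takes the first dry spot literally.
#' @return `segments` with `breakup_s` and `censored` columns.
#' @export
segment_breakup_times <- function(frames, segments = NULL, k_persist = 1L) {
  if (is.null(segments)) segments <- suppressWarnings(blink_segments(frames))
  stopifnot(k_persist >= 1)
  frames <- frames[order(frames$timestamp_s), ]
  res <- purrr::pmap_dfr(segments, function(segment, opening_s, end_s, ...) {
    sel <- frames$quality == "pass" & frames$timestamp_s >= opening_s &
      frames$timestamp_s < end_s
    if (!any(sel)) abort(sprintf("segment %d has no quality-passing frame", segment))
    lab <- frames$label[sel]
    ts <- frames$timestamp_s[sel]
    pos <- lab == "positive"
    onset <- NA_real_
    if (any(pos)) {
      r <- rle(pos)
      hit <- which(r$values & r$lengths >= k_persist)[1]
      if (!is.na(hit)) {
        first <- cumsum(r$lengths)[hit] - r$lengths[hit] + 1L
        onset <- ts[first]
      }
    }
    if (is.na(onset)) {
      tibble(breakup_s = end_s - opening_s, censored = TRUE)
    } else {
      tibble(breakup_s = onset - opening_s, censored = FALSE)
    }
  })
  dplyr::bind_cols(segments, res)
}

#' Estimate TFBUT from segment breakup times
#'
#' The tear-film breakup time of an eye is the mean of the first three
#' uncensored segment breakup times (measured thrice and averaged). With
#' fewer than three uncensored segments, the available uncensored values
#' are averaged and censored segments contribute only as lower bounds to
#' the short/not-short decision: a censoring bound of at least 5 s counts
#' as evidence against a short TFBUT, never for it.
#'
#' @param segments A tibble with `breakup_s` and `censored` (from
#'   [segment_breakup_times()], or simulator ground-truth segments).
#' @return A `tf_tfbut` object: `segments`, `tfbut_s` (mean of up to the
#'   first three uncensored values; `NA` if none), `lower_bound_s` (largest
#'   censoring bound when no uncensored value exists), `n_segments_used`,
#'   `censored_flag` (any of the first three segments censored), and
#'   `short` (`TRUE` when the estimate supports TFBUT <= 5 s).
#' @export
estimate_tfbut <- function(segments) {
  if (nrow(segments) == 0) abort("no blink segments: cannot estimate TFBUT")
  stopifnot(all(c("breakup_s", "censored") %in% names(segments)))
  unc <- which(!segments$censored)
  used <- unc[seq_len(min(3L, length(unc)))]
  first3 <- seq_len(min(3L, nrow(segments)))
  tfbut <- if (length(used) > 0) mean(segments$breakup_s[used]) else NA_real_
  lower <- if (length(used) == 0) max(segments$breakup_s) else NA_real_
  structure(
    list(segments = segments,
         tfbut_s = tfbut,
         lower_bound_s = lower,
         n_segments_used = length(used),
         censored_flag = any(segments$censored[first3]),
         short = isTRUE(!is.na(tfbut) && tfbut <= 5)),
    class = "tf_tfbut")
}

#' @exportS3Method base::print
print.tf_tfbut <- function(x, ...) {
  if (!is.na(x$tfbut_s)) {
    cat(sprintf("<tf_tfbut> TFBUT = %.3f s (mean of %d segment(s)%s)\n",
                x$tfbut_s, x$n_segments_used,
                if (x$censored_flag) ", censoring present" else ""))
  } else {
    cat(sprintf("<tf_tfbut> TFBUT > %.1f s (all %d segment(s) censored)\n",
                x$lower_bound_s, nrow(x$segments)))
  }
  invisible(x)
}

#' @export
tidy.tf_tfbut <- function(x, ...) as_tibble(x$segments)

#' @export
glance.tf_tfbut <- function(x, ...) {
  tibble(tfbut_s = x$tfbut_s, lower_bound_s = x$lower_bound_s,
         n_segments_used = x$n_segments_used,
         n_segments = nrow(x$segments),
         censored_flag = x$censored_flag, short = x$short)
}

#' Full TFBUT computation from a classified frame table
#'
#' Convenience wrapper: [blink_segments()], [segment_breakup_times()],
#' [estimate_tfbut()].
#'
#' @param frames A classified frame tibble.
#' @param k_persist See [segment_breakup_times()].
#' @return A `tf_tfbut`.
#' @export
compute_tfbut <- function(frames, k_persist = 1L) {
  segs <- suppressWarnings(blink_segments(frames))
  if (nrow(segs) == 0) abort("no blink segments: cannot estimate TFBUT")
  estimate_tfbut(segment_breakup_times(frames, segs, k_persist = k_persist))
}
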