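#' Published clinical dataset counts
#'
#' The frame bookkeeping of the 79-video clinical cohort the pipeline was
#' designed around, as printed in its report: total seconds of video,
#' frames sliced at 200 ms, frames excluded by the quality rules,
#' breakup-negative frames among those retained, and the
#' training/validation/test split sizes. These serve as inputs to
#' [dataset_composition()], which derives the remaining quantities.
#'
#' @return A named list of counts.
#' @export
reference_dataset_counts <- function() {
  list(videos = 79L,
       eyes = 158L,
       total_seconds = 4434,
       frames_total = 22172L,
       frames_excluded = 5732L,
       frames_negative = 10504L,
       split = c(train = 12011L, valid = 2830L, test = 1599L))
}

#' Dataset composition arithmetic
#'
#' Derives the composition of an annotated frame dataset from its raw
#' counts: retained frames (total minus excluded), breakup-positive frames
#' (retained minus negative), the split total, and the mean video duration.
#'
#' @param counts A list as returned by [reference_dataset_counts()].
#' @return A one-row tibble with `videos`, `mean_duration_s`,
#'   `frames_total`, `frames_excluded`, `frames_retained`,
#'   `frames_positive`, `frames_negative`, `split_total`,
#'   `split_consistent`.
#' @examples
#' dataset_composition(reference_dataset_counts())
#' @export
dataset_composition <- function(counts = reference_dataset_counts()) {
  retained <- counts$frames_total - counts$frames_excluded
  positive <- retained - counts$frames_negative
  split_total <- sum(counts$split)
  tibble(videos = counts$videos,
         mean_duration_s = counts$total_seconds / counts$videos,
         frames_total = counts$frames_total,
         frames_excluded = counts$frames_excluded,
         frames_retained = retained,
         frames_positive = positive,
         frames_negative = counts$frames_negative,
         split_total = split_total,
         split_consistent = split_total == retained)
}

#' Summarize a processed frame table
#'
#' The same bookkeeping for a frame table produced by this pipeline:
#' total/excluded/retained frame counts, exclusion reasons, and label
#' counts among retained frames.
#'
#' @param frames A classified frame tibble.
#' @return A one-row tibble.
#' @export
frame_table_summary <- function(frames) {
  retained <- frames$quality == "pass"
  tibble(frames_total = nrow(frames),
         frames_excluded = sum(!retained),
         frames_retained = sum(retained),
         fail_no_focus = sum(frames$reason %in% "no_focus"),
         fail_no_cornea = sum(frames$reason %in% "no_cornea"),
         fail_noise = sum(frames$reason %in% "noise"),
         frames_positive = if (!is.null(frames$label)) sum(frames$label %in% "positive") else NA_integer_,
         frames_negative = if (!is.null(frames$label)) sum(frames$label %in% "negative") else NA_integer_)
}
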