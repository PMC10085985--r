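#' Simulation configuration targeting a given TFBUT
#'
#' Builds a [sim_config()] whose three measurement segments break up at the
#' target time (with optional per-segment jitter), each segment extending
#' `segment_margin_s` past its breakup so the rupture is observable, after
#' a `prefix_s` pre-measurement interval. `NA` targets give a fully
#' censored video with `censored_length_s` segments.
#'
#' @param tfbut_s Target TFBUT in seconds, or `NA` for no breakup.
#' @param seed Simulation seed.
#' @param jitter_s Half-width of the uniform per-segment jitter around the
#'   target.
#' @param segment_margin_s Observation time after breakup within each
#'   segment.
#' @param prefix_s Length of the pre-first-blink interval.
#' @param censored_length_s Segment length of censored videos.
#' @param ... Passed on to [sim_config()] (noise, artifacts, geometry).
#' @return A `tf_sim_config`.
#' @export
config_for_tfbut <- function(tfbut_s, seed = 1, jitter_s = 0.15,
                             segment_margin_s = 1.0, prefix_s = 1.2,
                             censored_length_s = 6.5, ...) {
  if (is.na(tfbut_s)) {
    return(sim_config(n_blinks = 3, breakup_times_s = NA,
                      segment_lengths_s = c(prefix_s, rep(censored_length_s, 3)),
                      seed = seed, ...))
  }
  b <- withr::with_seed(frame_seed(seed, 5), {
    pmax(tfbut_s + runif(3, -jitter_s, jitter_s), 0.4)
  })
  sim_config(n_blinks = 3, breakup_times_s = b,
             segment_lengths_s = c(prefix_s, b + segment_margin_s),
             seed = seed, ...)
}

#' TFBUT parameter-recovery suite
#'
#' Simulates seeded videos with true TFBUT drawn uniformly and estimates
#' each one end to end, either from oracle ground-truth labels (isolating
#' the blink segmentation and timing logic: the only error left is the
#' 0.2-s grid quantization) or through the rendered pipeline
#' (preprocessing, quality screening, dark-spot classification). Oracle
#' runs disable artifacts so that timing is compared on an uninterrupted
#' grid; detector runs keep the simulator's default noise and artifact
#' rate.
#'
#' @param n_videos Number of videos.
#' @param seed Suite seed.
#' @param method `"oracle"` or `"detector"`.
#' @param tfbut_range Range of the uniform true-TFBUT draw, seconds.
#' @param interval_s Frame grid spacing.
#' @param model Classifier for the detector pathway.
#' @return A tibble `video`, `true_tfbut_s`, `estimated_tfbut_s`,
#'   `abs_error_s`.
#' @export
tfbut_recovery <- function(n_videos = 50, seed = 1,
                           method = c("oracle", "detector"),
                           tfbut_range = c(1, 10), interval_s = 0.2,
                           model = rule_classifier()) {
  method <- match.arg(method)
  targets <- withr::with_seed(seed, {
    runif(n_videos, tfbut_range[1], tfbut_range[2])
  })
  purrr::map_dfr(seq_len(n_videos), function(i) {
    cfg <- config_for_tfbut(
      targets[i], seed = frame_seed(seed, 37 + i),
      artifact_rate = if (method == "oracle") 0 else 0.03)
    if (method == "oracle") {
      truth <- simulate_truth(cfg, interval_s = interval_s)
      ft <- oracle_frames(truth)
      true_tfbut <- truth$true_tfbut_s
    } else {
      vid <- simulate_video(cfg, interval_s = interval_s)
      ft <- classify_frames(preprocess_frames(vid$frames), model)
      true_tfbut <- vid$truth$true_tfbut_s
    }
    est <- compute_tfbut(ft)
    tibble(video = i, true_tfbut_s = true_tfbut,
           estimated_tfbut_s = est$tfbut_s,
           abs_error_s = abs(est$tfbut_s - true_tfbut))
  })
}

#' Simulate a diagnostic cohort
#'
#' Builds a synthetic per-eye cohort with known TFBUT and OSDI ground
#' truth: half the cases are dry eye (short TFBUT, symptomatic OSDI), the
#' rest split between symptomatic eyes with stable tear film (including
#' fully censored, no-breakup videos) and asymptomatic eyes with short or
#' long TFBUT. True TFBUT values keep a margin of at least 0.5 s from the
#' 5-s diagnostic boundary so that the 0.2-s measurement grid cannot flip
#' a diagnosis. The reference diagnosis applies the diagnostic rule to the
#' true values.
#'
#' @param n_cases Number of eyes (default 40).
#' @param seed Cohort seed.
#' @param prop_ded Fraction of dry-eye cases.
#' @return A tibble `case_id`, `group`, `true_tfbut_s` (`NA` when
#'   censored), `osdi` (list of 12 responses), `osdi_score`,
#'   `reference_dx`, `config` (list of `tf_sim_config`).
#' @export
simulate_cohort <- function(n_cases = 40, seed = 1, prop_ded = 0.5) {
  n_ded <- round(n_cases * prop_ded)
  n_non <- n_cases - n_ded
  # non-DED mix: symptomatic/long, symptomatic/censored, asymptomatic
  n_sym_long <- round(0.35 * n_non)
  n_sym_cens <- round(0.15 * n_non)
  n_asym <- n_non - n_sym_long - n_sym_cens
  groups <- c(rep("ded", n_ded), rep("sym_long", n_sym_long),
              rep("sym_cens", n_sym_cens),
              rep(c("asym_short", "asym_long"), length.out = n_asym))
  draw_osdi <- function(symptomatic, seed) {
    withr::with_seed(seed, {
      repeat {
        p <- if (symptomatic) c(0.10, 0.20, 0.30, 0.25, 0.15)
             else c(0.65, 0.25, 0.10, 0, 0)
        r <- sample(0:4, 12, replace = TRUE, prob = p)
        s <- compute_osdi(r)
        if ((symptomatic && s > 13) || (!symptomatic && s <= 13)) break
      }
      list(responses = r, score = s)
    })
  }
  purrr::map_dfr(seq_along(groups), function(i) {
    g <- groups[i]
    cseed <- frame_seed(seed, 101 + 13 * i)
    tf <- withr::with_seed(cseed, switch(
      g,
      ded = runif(1, 2.0, 4.4),
      sym_long = runif(1, 5.7, 9.0),
      sym_cens = NA_real_,
      asym_short = runif(1, 2.0, 4.4),
      asym_long = runif(1, 5.7, 9.0)))
    responses <- draw_osdi(g %in% c("ded", "sym_long", "sym_cens"),
                           frame_seed(seed, 499 + 13 * i))
    ref <- diagnose_dry_eye(ifelse(is.na(tf), Inf, tf), responses$score,
                            censored = is.na(tf))
    tibble(case_id = sprintf("case_%03d", i), group = g,
           true_tfbut_s = tf,
           osdi = list(responses$responses), osdi_score = responses$score,
           reference_dx = ref,
           config = list(config_for_tfbut(tf, seed = cseed)))
  })
}

#' Run a cohort through the pipeline
#'
#' Estimates each case's TFBUT (oracle labels or the rendered pipeline, as
#' in [tfbut_recovery()]) and applies the diagnostic rule.
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param method `"oracle"` or `"detector"`.
#' @param model Classifier for the detector pathway.
#' @param interval_s Frame grid spacing.
#' @return `cohort` plus `tfbut_s`, `censored`, `predicted_dx`.
#' @export
run_cohort <- function(cohort, method = c("oracle", "detector"),
                       model = rule_classifier(), interval_s = 0.2) {
  method <- match.arg(method)
  est <- purrr::map_dfr(cohort$config, function(cfg) {
    if (method == "oracle") {
      cfg$artifact_rate <- 0
      ft <- oracle_frames(simulate_truth(cfg, interval_s = interval_s))
    } else {
      vid <- simulate_video(cfg, interval_s = interval_s)
      ft <- classify_frames(preprocess_frames(vid$frames), model)
    }
    res <- compute_tfbut(ft)
    censored <- res$n_segments_used == 0
    tibble(tfbut_s = if (censored) res$lower_bound_s else res$tfbut_s,
           censored = censored)
  })
  out <- dplyr::bind_cols(cohort, est)
  diagnose_cases(out)
}
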