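#' Build a pseudorandom color-word Stroop task schedule
#'
#' 18 blocks of 5 consecutive trials. Each block opens with a 2 s
#' emotional priming picture (valences balanced: 9 positive, 9 negative
#' blocks in shuffled order) followed by a 1 s blank; each trial shows a
#' 0.5 s fixation and a 1.1 s color word; blocks end with a rest drawn
#' uniformly from 17-21 s. Trial conditions (congruent, incongruent,
#' neutral) are balanced across the 90 trials and shuffled.
#'
#' @param seed optional integer seed.
#' @param fixation_per_trial if `FALSE`, one fixation per block instead of
#'   one before every trial.
#' @return object of class `task_schedule`: list with `trials`
#'   (data.frame `block`, `trial`, `condition`, `valence`), `rests`
#'   (per-block rest seconds) and `timings`.
#' @export
build_schedule <- function(seed = NULL, fixation_per_trial = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- 18L; trials_per_block <- 5L
  n_trials <- n_blocks * trials_per_block
  conditions <- sample(rep(c("congruent", "incongruent", "neutral"),
                           length.out = n_trials))
  valence <- sample(rep(c("positive", "negative"), each = n_blocks / 2L))
  trials <- data.frame(block = rep(seq_len(n_blocks), each = trials_per_block),
                       trial = rep(seq_len(trials_per_block), n_blocks),
                       condition = conditions,
                       valence = valence[rep(seq_len(n_blocks), each = trials_per_block)])
  structure(list(trials = trials,
                 rests = runif(n_blocks, 17, 21),
                 timings = list(prime_s = 2, blank_s = 1, fixation_s = 0.5,
                                word_s = 1.1,
                                fixation_per_trial = fixation_per_trial)),
            class = "task_schedule")
}

#' Total schedule duration in minutes
#'
#' Sums prime, blank, per-trial fixation + word, and rest over the 18
#' blocks using a nominal mean rest (default 19 s, the midpoint of the
#' 17-21 s range), which gives exactly 9 minutes for the default timings:
#' each block is 2 + 1 + 5 x (0.5 + 1.1) + 19 = 30 s.
#'
#' @param schedule a [build_schedule()] object.
#' @param mean_rest nominal per-block rest in seconds (default 19).
#' @return duration in minutes.
#' @export
schedule_duration <- function(schedule, mean_rest = 19) {
  tm <- schedule$timings
  n_blocks <- length(schedule$rests)
  trials_per_block <- nrow(schedule$trials) / n_blocks
  trial_time <- if (tm$fixation_per_trial) {
    trials_per_block * (tm$fixation_s + tm$word_s)
  } else {
    tm$fixation_s + trials_per_block * tm$word_s
  }
  block_s <- tm$prime_s + tm$blank_s + trial_time + mean_rest
  n_blocks * block_s / 60
}

#' Score a Stroop test from trial records
#'
#' Summarizes trial tables into per-subject-day accuracy, per-condition
#' mean reaction times (error trials excluded, no outlier trimming) and
#' the Stroop effect (mean incongruent RT minus mean congruent RT). A
#' condition with zero correct trials for some subject-day is an error.
#'
#' @param trials data.frame with columns `subject`, `day`, `condition`,
#'   `rt_ms`, `correct` (and optionally `group`).
#' @return data.frame of class `stroop_summary` with one row per
#'   subject-day: `accuracy` (%), `rt_congruent`, `rt_incongruent`,
#'   `rt_neutral` (ms), `stroop_effect` (ms).
#' @export
score_test <- function(trials) {
  need <- c("subject", "day", "condition", "rt_ms", "correct")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns ", paste(need, collapse = ", "))
  }
  dt <- data.table::as.data.table(trials)
  keys <- intersect(c("subject", "group", "day"), names(dt))
  acc <- dt[, list(accuracy = 100 * mean(correct)), by = keys]
  ok <- dt[dt$correct == 1, ]
  rt <- data.table::dcast(
    ok[, list(rt = mean(rt_ms)), by = c(keys, "condition")],
    formula = stats::as.formula(paste(paste(keys, collapse = " + "), "~ condition")),
    value.var = "rt")
  miss <- setdiff(c("congruent", "incongruent", "neutral"), names(rt))
  out <- merge(acc, rt, by = keys)
  if (length(miss) > 0 || anyNA(out)) {
    stop("some subject-day has no correct trials in at least one condition")
  }
  data.table::setnames(out, c("congruent", "incongruent", "neutral"),
                       c("rt_congruent", "rt_incongruent", "rt_neutral"))
  out <- as.data.frame(out)
  out$stroop_effect <- out$rt_incongruent - out$rt_congruent
  class(out) <- c("stroop_summary", class(out))
  out
}

#' Change scores between two test days
#'
#' Post-minus-pre differences per subject: `d_accuracy` (percentage
#' points), `d_rt_neutral` (ms, the practice-effect carrier) and
#' `d_stroop` (ms, negative values mean improved inhibitory control).
#'
#' @param pre,post `stroop_summary` rows for the same subjects on two
#'   test days.
#' @return data.frame with one row per subject: `subject`, `d_accuracy`,
#'   `d_rt_neutral`, `d_stroop`.
#' @export
delta_metrics <- function(pre, post) {
  pre <- as.data.frame(pre); post <- as.data.frame(post)
  pre <- pre[order(pre$subject), ]; post <- post[order(post$subject), ]
  if (nrow(pre) != nrow(post) || any(pre$subject != post$subject)) {
    stop("pre and post summaries must cover the same subjects")
  }
  data.frame(subject = pre$subject,
             d_accuracy = post$accuracy - pre$accuracy,
             d_rt_neutral = post$rt_neutral - pre$rt_neutral,
             d_stroop = post$stroop_effect - pre$stroop_effect)
}
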