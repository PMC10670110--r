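#' Baseline statistics of a small-worldness sequence
#'
#' Arithmetic mean and sample standard deviation of the sigma values
#' computed during the continuous-subtraction baseline span of a block.
#' A degenerate baseline (fewer than two values, or zero spread) is an
#' error: the feedback score divides by the baseline SD.
#'
#' @param sigma_sequence numeric vector of baseline sigma values.
#' @return object of class `baseline_stats`: list with `sigma_base`, `sd`
#'   and `n`.
#' @export
baseline_stats <- function(sigma_sequence) {
  if (length(sigma_sequence) < 2) stop("baseline needs at least 2 sigma values")
  s <- stats::sd(sigma_sequence)
  if (s == 0) stop("degenerate baseline: zero standard deviation")
  structure(list(sigma_base = mean(sigma_sequence), sd = s,
                 n = length(sigma_sequence)),
            class = "baseline_stats")
}

#' Real-time feedback score
#'
#' The baseline-normalized score shown to the participant:
#' `score = 50 * (sigma + 3 * SD - sigma_base) / (3 * SD)`, clamped to
#' `[0, 100]`. Small-worldness equal to the baseline mean maps to 50;
#' baseline +/- 3 SD map to 100 and 0.
#'
#' @param sigma_i instantaneous small-worldness value(s).
#' @param baseline a [baseline_stats()] object (or list with `sigma_base`
#'   and `sd`).
#' @return score(s) in `[0, 100]`, same length as `sigma_i`.
#' @export
feedback_score <- function(sigma_i, baseline) {
  raw <- 50 * (sigma_i + 3 * baseline$sd - baseline$sigma_base) / (3 * baseline$sd)
  pmin(100, pmax(0, raw))
}

#' Run the online engine over one training block
#'
#' Computes sigma over trailing 5 s (128-sample) windows at the nominal
#' 3 Hz refresh (8-sample step, optionally strided) separately within the
#' 15 s baseline span and the 25 s regulation span (the 2 s stimulus gap
#' is excluded from both), derives the block's own baseline statistics,
#' scores every regulation update, and tracks the thermometer (running
#' mean of the regulation scores). At the full refresh this yields 33
#' baseline and 65 regulation updates per block.
#'
#' @param segment time x channel matrix holding one block
#'   (baseline + gap + regulation at `sampling_rate`).
#' @param sampling_rate sampling frequency in Hz (default 25.6).
#' @param sparsity retained connection fraction (default 0.3).
#' @param null_count random networks per sigma evaluation (default 30).
#' @param window_len,step online window length and step in samples.
#' @param stride evaluate every `stride`-th update (default 1; larger
#'   values thin the refresh for scaled-down simulations).
#' @param baseline_s,gap_s,regulation_s span durations in seconds.
#' @param baseline override: a precomputed [baseline_stats()] (e.g. a
#'   session-level baseline) instead of the block's own.
#' @return list of class `feedback_block`: `baseline_sigma`,
#'   `regulation_sigma`, `scores`, `thermometer` (running mean),
#'   `baseline` stats used.
#' @export
run_block <- function(segment, sampling_rate = 25.6, sparsity = 0.3,
                      null_count = 30, window_len = 128, step = 8, stride = 1,
                      baseline_s = 15, gap_s = 2, regulation_s = 25,
                      baseline = NULL) {
  segment <- as.matrix(segment)
  base_n <- round(baseline_s * sampling_rate)
  gap_n <- floor(gap_s * sampling_rate)
  reg_n <- round(regulation_s * sampling_rate)
  if (nrow(segment) < base_n + gap_n + reg_n) stop("segment shorter than one block")
  if (base_n < window_len || reg_n < window_len) stop("spans shorter than one window")
  eff_step <- step * stride

  span_sigmas <- function(offset, span_n) {
    starts <- seq.int(offset + 1L, offset + span_n - window_len + 1L, by = eff_step)
    vapply(starts, function(s) {
      network_sigma(segment[s:(s + window_len - 1L), , drop = FALSE],
                    sparsity = sparsity, null_count = null_count)
    }, numeric(1))
  }

  base_sigma <- span_sigmas(0L, base_n)
  reg_sigma <- span_sigmas(base_n + gap_n, reg_n)
  bs <- baseline %||% baseline_stats(base_sigma)
  scores <- feedback_score(reg_sigma, bs)
  structure(list(baseline_sigma = base_sigma, regulation_sigma = reg_sigma,
                 scores = scores, thermometer = cumsum(scores) / seq_along(scores),
                 baseline = bs),
            class = "feedback_block")
}

#' Session-level feedback summary
#'
#' The per-session statistic is the mean regulation score across the
#' day's blocks minus 50, i.e. the baseline-relative score in feedback
#' points: 0 means performance at baseline, positive values mean the
#' small-worldness was held above its baseline on average.
#'
#' @param blocks list of [run_block()] results (>= 1).
#' @return list of class `session_summary`: `session_score` (mean score
#'   minus 50), `block_means`.
#' @export
session_summary <- function(blocks) {
  if (inherits(blocks, "feedback_block")) blocks <- list(blocks)
  if (length(blocks) < 1) stop("at least one block is required")
  bm <- vapply(blocks, function(b) mean(b$scores), numeric(1))
  structure(list(session_score = mean(bm) - 50, block_means = bm),
            class = "session_summary")
}

#' Run the online engine over a full session recording
#'
#' Splits a [gen_session()] recording into its 18 blocks using the
#' attached layout and applies [run_block()] to each.
#'
#' @param recording a session [hemo_recording()] with a `"layout"`
#'   attribute (or supply `layout`).
#' @param layout a [session_layout()] data.frame.
#' @param session_baseline use one session-level baseline (pooled over
#'   all block baselines) instead of per-block baselines (default FALSE).
#' @param ... passed to [run_block()].
#' @return list with `blocks` (list of `feedback_block`) and `summary`
#'   (a [session_summary()]).
#' @export
simulate_session <- function(recording, layout = attr(recording, "layout"),
                             session_baseline = FALSE, ...) {
  if (is.null(layout)) stop("no session layout available")
  data <- recording$data
  segs <- lapply(seq_len(nrow(layout)), function(b) {
    data[layout$baseline_start[b]:layout$reg_end[b], , drop = FALSE]
  })
  blocks <- lapply(segs, run_block, sampling_rate = recording$sampling_rate, ...)
  if (session_baseline) {
    bs <- baseline_stats(unlist(lapply(blocks, `[[`, "baseline_sigma")))
    blocks <- lapply(blocks, function(b) {
      b$scores <- feedback_score(b$regulation_sigma, bs)
      b$thermometer <- cumsum(b$scores) / seq_along(b$scores)
      b$baseline <- bs
      b
    })
  }
  list(blocks = blocks, summary = session_summary(blocks))
}

#' Simulate one training day of a cohort through the online pipeline
#'
#' Generates every subject's session for the given day and runs the full
#' online chain (windowed connectivity, thresholding, null-normalized
#' small-worldness, baseline-anchored scoring) on it.
#'
#' @param cohort a [cohort_config()].
#' @param signal a [signal_gen_config()].
#' @param day training day (1..5).
#' @param blend_mult calibration multiplier on the regulation blend
#'   weight (see [gen_session()]).
#' @param stride,null_count,sparsity online-engine settings (see
#'   [run_block()]).
#' @param seed seed for the null-network randomization streams.
#' @return list with `scores` (per-subject session statistics) and
#'   `mean` (group mean).
#' @export
simulate_cohort_day <- function(cohort, signal = signal_gen_config(), day,
                                blend_mult = 1, stride = 1, null_count = 30,
                                sparsity = 0.3, seed = 1L) {
  scores <- vapply(seq_len(cohort$n_subjects), function(s) {
    rec <- gen_session(cohort, signal, s, day, blend_mult)
    set.seed(derive_seed(seed, s, day))
    sim <- simulate_session(rec, stride = stride, null_count = null_count,
                            sparsity = sparsity)
    sim$summary$session_score
  }, numeric(1))
  list(scores = scores, mean = mean(scores))
}

#' Calibrate the regulation drift to a session-score target
#'
#' The calibration hook of the generator: finds the regulation blend
#' multiplier at which the cohort's group-mean session score (mean
#' feedback score minus 50) matches a target, by secant iteration on the
#' full online pipeline under common random numbers (every evaluation
#' reuses the same derived seeds, so the measured mean is a smooth,
#' near-linear function of the multiplier and converges in a few
#' iterations). The returned value is the pipeline's measured mean at the
#' final multiplier.
#'
#' @param target desired group-mean session score (baseline-relative
#'   feedback points).
#' @param cohort,signal,day,stride,null_count,seed as in
#'   [simulate_cohort_day()].
#' @param w_init two starting multipliers for the secant iteration.
#' @param tol stop when the measured mean is within `tol` of the target.
#' @param max_iter maximum number of pipeline evaluations.
#' @return list with `blend_mult`, `value` (measured group mean),
#'   `scores` (per-subject statistics at the final multiplier) and
#'   `history` (data.frame of iterations).
#' @export
calibrate_session_drift <- function(target, cohort, signal = signal_gen_config(),
                                    day = 5, stride = 4, null_count = 10,
                                    seed = 1L, w_init = c(0.01, 0.05),
                                    tol = 0.05, max_iter = 8) {
  evals <- list()
  f <- function(w) {
    r <- simulate_cohort_day(cohort, signal, day, blend_mult = w,
                             stride = stride, null_count = null_count, seed = seed)
    evals[[length(evals) + 1L]] <<- c(w = w, value = r$mean)
    r
  }
  w0 <- w_init[1]; w1 <- w_init[2]
  r0 <- f(w0); r1 <- f(w1)
  it <- 2L
  while (abs(r1$mean - target) > tol && it < max_iter) {
    if (r1$mean == r0$mean) break
    w2 <- w1 + (target - r1$mean) * (w1 - w0) / (r1$mean - r0$mean)
    w2 <- min(max(w2, 0), 4)
    w0 <- w1; r0 <- r1
    w1 <- w2; r1 <- f(w2)
    it <- it + 1L
  }
  list(blend_mult = w1, value = r1$mean, scores = r1$scores,
       history = as.data.frame(do.call(rbind, evals)))
}
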