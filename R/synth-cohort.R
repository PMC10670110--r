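#' Configuration of a simulated training cohort
#'
#' Describes one training group: its regulation direction, size, the
#' latent Watts-Strogatz rewiring-probability schedule across the five
#' training days, and the behavioral effect parameters per test day. The
#' defaults encode the emulated experiment's conditions: 17 subjects per
#' group; the UP
#' group's latent regulation graph becomes progressively more lattice-like
#' (rewiring probability decreasing across days) while the DOWN group's
#' becomes weakly more random; the behavioral posttest/follow-up effects
#' are the target group means/SDs for the color-word Stroop task.
#'
#' @param group `"UP"` or `"DOWN"`.
#' @param n_subjects subjects per group (default 17).
#' @param p_baseline latent rewiring probability of the baseline
#'   (continuous-subtraction) cognitive state, default 0.4.
#' @param p_schedule per-training-day latent rewiring probability during
#'   regulation (5 entries; defaults depend on `group`).
#' @param subject_sd between-subject SD of the regulation-strength
#'   multiplier (multipliers are drawn from `N(1, subject_sd)` and
#'   centered to mean 1 within the cohort).
#' @param behavior behavioral generator parameters; see
#'   [default_behavior_config()].
#' @param seed master seed; all per-subject and per-day streams are
#'   derived from it by fixed offsets.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(group = c("UP", "DOWN"),
                          n_subjects = 17,
                          p_baseline = 0.4,
                          p_schedule = NULL,
                          subject_sd = 0.15,
                          behavior = NULL,
                          seed = 1L) {
  group <- match.arg(group)
  p_schedule <- p_schedule %||% if (group == "UP") {
    c(0.40, 0.34, 0.28, 0.21, 0.15)
  } else {
    c(0.40, 0.43, 0.46, 0.48, 0.50)
  }
  if (length(p_schedule) != 5) stop("p_schedule needs one entry per training day (5)")
  if (any(p_schedule < 0 | p_schedule > 1)) stop("p_schedule entries must lie in [0, 1]")
  behavior <- behavior %||% default_behavior_config(group)
  sds <- c(behavior$pretest$between_sd, behavior$pretest$stroop_sd,
           behavior$pretest$accuracy_sd, behavior$effects$dstroop_sd,
           behavior$effects$dacc_sd, behavior$effects$drt_neutral_sd)
  if (any(sds <= 0)) stop("behavioral SDs must be > 0")
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 p_baseline = p_baseline, p_schedule = p_schedule,
                 subject_sd = subject_sd, behavior = behavior, seed = seed),
            class = "cohort_config")
}

#' Default behavioral effect parameters per group
#'
#' Pretest condition means are typical for a speeded color-word Stroop
#' task with emotional priming (congruent 620 ms, incongruent 700 ms,
#' neutral 600 ms; accuracy 85%, kept away from the 100% ceiling so that
#' truncation does not bias change scores). Posttest and follow-up changes
#' encode the group-level effects: the UP group's Stroop effect shrinks by
#' 60 +/- 45 ms at posttest and its follow-up accuracy rises by
#' 2.48 +/- 4.69 percentage points; the DOWN group's Stroop change is
#' 9 +/- 77 ms; both groups share a practice-driven decrease in neutral
#' reaction time across repeated tests.
#'
#' @param group `"UP"` or `"DOWN"`.
#' @return list with elements `pretest`, `effects` (data.frame with one
#'   row per post-pretest day) and `trial_rt_sd`.
#' @export
default_behavior_config <- function(group = c("UP", "DOWN")) {
  group <- match.arg(group)
  effects <- if (group == "UP") {
    data.frame(day = c("posttest", "followup"),
               dstroop_mean = c(-60, -30), dstroop_sd = c(45, 60),
               dacc_mean = c(0.5, 2.48), dacc_sd = c(4.7, 4.69),
               drt_neutral_mean = c(-25, -35), drt_neutral_sd = c(40, 40))
  } else {
    data.frame(day = c("posttest", "followup"),
               dstroop_mean = c(9, 0), dstroop_sd = c(77, 70),
               dacc_mean = c(0, 0.5), dacc_sd = c(4.7, 4.7),
               drt_neutral_mean = c(-25, -35), drt_neutral_sd = c(40, 40))
  }
  list(pretest = list(rt_congruent = 620, rt_incongruent = 700, rt_neutral = 600,
                      between_sd = 60, stroop_sd = 30,
                      accuracy = 85, accuracy_sd = 4),
       effects = effects,
       trial_rt_sd = 80)
}

#' Sample layout of one training session
#'
#' 120 s of rest followed by 18 blocks of 15 s baseline (continuous
#' subtraction), a 2 s stimulus gap, and 25 s of neurofeedback regulation,
#' all at the 25.6 Hz sampling rate: 3072 rest samples and blocks of
#' 384 + 51 + 640 samples (the 51.2-sample stimulus gap is floored to 51;
#' it is excluded from every statistic).
#'
#' @param n_blocks number of blocks (default 18).
#' @param sampling_rate sampling frequency in Hz (default 25.6).
#' @return data.frame with one row per block: sample indices
#'   `baseline_start`, `baseline_end`, `reg_start`, `reg_end`, plus
#'   attributes `rest_samples` and `block_samples`.
#' @export
session_layout <- function(n_blocks = 18, sampling_rate = 25.6) {
  rest_n <- round(120 * sampling_rate)   # 3072
  base_n <- round(15 * sampling_rate)    # 384
  gap_n <- floor(2 * sampling_rate)      # 51
  reg_n <- round(25 * sampling_rate)     # 640
  block_n <- base_n + gap_n + reg_n
  starts <- rest_n + (seq_len(n_blocks) - 1L) * block_n + 1L
  out <- data.frame(block = seq_len(n_blocks),
                    baseline_start = starts,
                    baseline_end = starts + base_n - 1L,
                    reg_start = starts + base_n + gap_n,
                    reg_end = starts + block_n - 1L)
  attr(out, "rest_samples") <- rest_n
  attr(out, "block_samples") <- block_n
  attr(out, "sampling_rate") <- sampling_rate
  out
}

# per-subject regulation-strength multipliers, deterministic in the cohort
# seed and centered to mean 1 so cohort-level calibration targets transfer
subject_multipliers <- function(cohort) {
  set.seed(derive_seed(cohort$seed, 7L))
  m <- rnorm(cohort$n_subjects, 1, cohort$subject_sd)
  m / mean(m)
}

#' Generate one subject-day training session recording
#'
#' Lays out 120 s rest plus 18 blocks (15 s baseline, 2 s stimulus gap,
#' 25 s regulation) at 25.6 Hz. Rest, baseline and gap samples are drawn
#' from the subject's baseline latent graph; regulation samples are drawn
#' from a covariance blend
#' `Sigma_base + v * (Sigma_day - Sigma_base)` where `Sigma_day` comes
#' from the group's day-specific rewiring probability and
#' `v = blend_mult * subject multiplier` (projected back to positive
#' definite when extrapolating `v > 1`). `blend_mult` is the calibration
#' hook by which score-domain session means are targeted; the default 1
#' uses the schedule as-is.
#'
#' @param cohort a [cohort_config()].
#' @param signal a [signal_gen_config()].
#' @param subject subject index in `1:n_subjects`.
#' @param day training day in 1..5.
#' @param blend_mult global multiplier on the regulation blend weight.
#' @return a [hemo_recording()] with the block layout as attribute
#'   `"layout"` and the latent parameters as attribute `"ground_truth"`.
#' @export
gen_session <- function(cohort, signal = signal_gen_config(), subject, day,
                        blend_mult = 1) {
  if (day < 1 || day > length(cohort$p_schedule)) stop("day outside the training schedule")
  if (subject < 1 || subject > cohort$n_subjects) stop("unknown subject index")
  n_ch <- 35L
  layout <- session_layout(sampling_rate = signal$sampling_rate)
  n_t <- attr(layout, "rest_samples") + 18L * attr(layout, "block_samples")

  g_base <- make_ws_graph(n_ch, 10, cohort$p_baseline,
                          seed = derive_seed(cohort$seed, subject, 1L))
  g_day <- make_ws_graph(n_ch, 10, cohort$p_schedule[day],
                         seed = derive_seed(cohort$seed, subject, 10L + day))
  sig_base <- latent_covariance(g_base$adjacency, signal$coupling_strength)
  sig_day <- latent_covariance(g_day$adjacency, signal$coupling_strength)
  v <- blend_mult * subject_multipliers(cohort)[subject]
  sig_reg <- project_pd(sig_base + v * (sig_day - sig_base))

  set.seed(derive_seed(cohort$seed, subject, 100L * day))
  z <- matrix(rnorm(n_t * n_ch), n_t, n_ch)
  data <- z %*% chol(sig_base)
  reg_rows <- unlist(lapply(seq_len(nrow(layout)), function(b) {
    layout$reg_start[b]:layout$reg_end[b]
  }))
  data[reg_rows, ] <- z[reg_rows, ] %*% chol(sig_reg)
  data <- data + nuisance_components(n_t, n_ch, signal)

  rec <- hemo_recording(data, signal$sampling_rate)
  attr(rec, "layout") <- layout
  attr(rec, "ground_truth") <- list(group = cohort$group, subject = subject,
                                    day = day, p_baseline = cohort$p_baseline,
                                    p_day = cohort$p_schedule[day], blend = v)
  rec
}

#' Describe a full training cohort without materializing the recordings
#'
#' Returns the cohort's ground-truth record (latent rewiring probability
#' and blend weight per subject and day) together with a generator
#' function producing any single session on demand; a five-day cohort of
#' 35-channel sessions is far too large to hold in memory at once.
#'
#' @param cohort a [cohort_config()].
#' @param signal a [signal_gen_config()].
#' @param days training days to include (default 1:5).
#' @return object of class `training_cohort`: list with `ground_truth`
#'   data.frame, `layout`, and `generate(subject, day, blend_mult = 1)`.
#' @export
gen_training_cohort <- function(cohort, signal = signal_gen_config(), days = 1:5) {
  if (any(days < 1 | days > length(cohort$p_schedule))) stop("days outside the schedule")
  mult <- subject_multipliers(cohort)
  gt <- expand.grid(subject = seq_len(cohort$n_subjects), day = days)
  gt$group <- cohort$group
  gt$p_baseline <- cohort$p_baseline
  gt$p_day <- cohort$p_schedule[gt$day]
  gt$blend <- mult[gt$subject]
  structure(list(ground_truth = gt,
                 layout = session_layout(sampling_rate = signal$sampling_rate),
                 cohort = cohort, signal = signal,
                 generate = function(subject, day, blend_mult = 1) {
                   gen_session(cohort, signal, subject, day, blend_mult)
                 }),
            class = "training_cohort")
}

#' Generate Stroop behavioral data for a cohort
#'
#' Draws per-subject condition-mean reaction times so that the
#' posttest-minus-pretest (and follow-up-minus-pretest) Stroop-effect
#' differences are normal with the configured group mean and SD, applies
#' the shared practice-effect decrease to the neutral (and congruent)
#' conditions, and draws accuracies from the configured change
#' distributions truncated to `[0, 100]`. With `trial_level = TRUE` the
#' condition means are expanded into a full pseudorandom trial table
#' (18 blocks x 5 trials per day) with per-trial RT noise and Bernoulli
#' correctness, suitable for the scoring pipeline.
#'
#' @param cohort a [cohort_config()].
#' @param days test days to generate, a subset of
#'   `c("pretest", "posttest", "followup")`.
#' @param trial_level expand to single trials (default FALSE: per-subject
#'   condition summaries).
#' @param seed optional seed (defaults to a stream derived from the cohort
#'   seed).
#' @return data.frame: either per-subject-day summaries (columns
#'   `subject`, `group`, `day`, `accuracy`, `rt_congruent`,
#'   `rt_incongruent`, `rt_neutral`, `stroop_effect`) or a trial table
#'   (columns `subject`, `group`, `day`, `block`, `trial`, `condition`,
#'   `valence`, `rt_ms`, `correct`).
#' @export
gen_behavior <- function(cohort, days = c("pretest", "posttest", "followup"),
                         trial_level = FALSE, seed = NULL) {
  days <- match.arg(days, several.ok = TRUE)
  set.seed(seed %||% derive_seed(cohort$seed, 3L))
  beh <- cohort$behavior
  n <- cohort$n_subjects
  pre <- beh$pretest

  subj <- data.frame(
    subject = seq_len(n),
    rt_congruent = rnorm(n, pre$rt_congruent, pre$between_sd),
    stroop = rnorm(n, pre$rt_incongruent - pre$rt_congruent, pre$stroop_sd),
    rt_neutral_off = rnorm(n, pre$rt_neutral - pre$rt_congruent, 20),
    accuracy = pmin(100, pmax(0, rnorm(n, pre$accuracy, pre$accuracy_sd)))
  )

  rows <- list()
  for (d in days) {
    if (d == "pretest") {
      rows[[d]] <- data.frame(
        subject = subj$subject, group = cohort$group, day = d,
        accuracy = subj$accuracy,
        rt_congruent = subj$rt_congruent,
        rt_incongruent = subj$rt_congruent + subj$stroop,
        rt_neutral = subj$rt_congruent + subj$rt_neutral_off)
    } else {
      eff <- beh$effects[beh$effects$day == d, ]
      if (nrow(eff) != 1) stop(sprintf("no effect parameters for day '%s'", d))
      practice <- rnorm(n, eff$drt_neutral_mean, eff$drt_neutral_sd)
      dstroop <- rnorm(n, eff$dstroop_mean, eff$dstroop_sd)
      dacc <- rnorm(n, eff$dacc_mean, eff$dacc_sd)
      cong <- subj$rt_congruent + practice + rnorm(n, 0, 15)
      rows[[d]] <- data.frame(
        subject = subj$subject, group = cohort$group, day = d,
        accuracy = pmin(100, pmax(0, subj$accuracy + dacc)),
        rt_congruent = cong,
        rt_incongruent = cong + subj$stroop + dstroop,
        rt_neutral = subj$rt_congruent + subj$rt_neutral_off + practice)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$stroop_effect <- out$rt_incongruent - out$rt_congruent
  if (!trial_level) return(out)
  expand_trials(out, beh$trial_rt_sd)
}

# condition-mean summaries -> pseudorandom trial table
expand_trials <- function(summaries, trial_rt_sd) {
  rows <- vector("list", nrow(summaries))
  for (r in seq_len(nrow(summaries))) {
    s <- summaries[r, ]
    sched <- build_schedule()
    tr <- sched$trials
    mu <- c(congruent = s$rt_congruent, incongruent = s$rt_incongruent,
            neutral = s$rt_neutral)[tr$condition]
    rows[[r]] <- data.frame(
      subject = s$subject, group = s$group, day = s$day,
      block = tr$block, trial = tr$trial, condition = tr$condition,
      valence = tr$valence,
      rt_ms = pmax(150, mu + rnorm(nrow(tr), 0, trial_rt_sd)),
      correct = rbinom(nrow(tr), 1, s$accuracy / 100))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
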