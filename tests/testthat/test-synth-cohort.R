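test_that("the session layout matches the training protocol at 25.6 Hz", {
  lay <- session_layout()
  expect_equal(attr(lay, "rest_samples"), 3072)            # 120 s
  expect_equal(nrow(lay), 18)
  expect_true(all(lay$reg_end - lay$reg_start + 1 == 640)) # 25 s regulation
  expect_true(all(lay$baseline_end - lay$baseline_start + 1 == 384)) # 15 s
  expect_equal(lay$baseline_start[1], 3073)
})

test_that("the UP schedule moves every subject toward the lattice regime", {
  co <- cohort_config("UP", seed = 1)
  tc <- gen_training_cohort(co)
  gt <- tc$ground_truth
  for (s in unique(gt$subject)) {
    expect_lt(gt$p_day[gt$subject == s & gt$day == 5],
              gt$p_day[gt$subject == s & gt$day == 1])
  }
  down <- gen_training_cohort(cohort_config("DOWN", seed = 1))$ground_truth
  expect_true(all(down$p_day[down$day == 5] >= down$p_day[down$day == 1]))
})

test_that("session generation is deterministic and honors the blend hook", {
  co <- cohort_config("UP", n_subjects = 3, seed = 2)
  r1 <- gen_session(co, signal_gen_config(), 2, 4)
  r2 <- gen_session(co, signal_gen_config(), 2, 4)
  expect_identical(r1$data, r2$data)
  expect_equal(nrow(r1$data), 3072 + 18 * 1075)
  expect_equal(ncol(r1$data), 35)
  # blend 0 collapses regulation onto the baseline covariance
  r0 <- gen_session(co, signal_gen_config(), 2, 4, blend_mult = 0)
  lay <- attr(r0, "layout")
  base_span <- r0$data[lay$baseline_start[1]:lay$baseline_end[1], ]
  expect_false(identical(r1$data, r0$data))
  expect_error(gen_session(co, signal_gen_config(), 2, 9), "schedule")
})

test_that("behavioral generation recovers configured group effects", {
  set.seed(5)
  seeds <- sample.int(1e6, 120)
  up_means <- vapply(seeds, function(s) {
    co <- cohort_config("UP", seed = s)
    b <- gen_behavior(co, days = c("pretest", "posttest"))
    mean(delta_metrics(b[b$day == "pretest", ], b[b$day == "posttest", ])$d_stroop)
  }, numeric(1))
  expect_lt(abs(mean(up_means) - (-60)), 4)

  # a zero-effect configuration is centered on zero
  beh0 <- default_behavior_config("UP")
  beh0$effects$dstroop_mean <- 0
  zero_means <- vapply(seeds[1:100], function(s) {
    co <- cohort_config("UP", behavior = beh0, seed = s)
    b <- gen_behavior(co, days = c("pretest", "posttest"))
    mean(delta_metrics(b[b$day == "pretest", ], b[b$day == "posttest", ])$d_stroop)
  }, numeric(1))
  expect_lt(abs(mean(zero_means)), 4)
})

test_that("trial tables are reproducible and well-formed", {
  co <- cohort_config("DOWN", n_subjects = 4, seed = 6)
  t1 <- gen_behavior(co, days = c("pretest", "posttest"), trial_level = TRUE,
                     seed = 9)
  t2 <- gen_behavior(co, days = c("pretest", "posttest"), trial_level = TRUE,
                     seed = 9)
  expect_identical(t1, t2)
  expect_setequal(names(t1), c("subject", "group", "day", "block", "trial",
                               "condition", "valence", "rt_ms", "correct"))
  expect_equal(nrow(t1), 4 * 2 * 90)
  expect_true(all(t1$rt_ms >= 150))
  expect_true(all(t1$correct %in% c(0, 1)))
  # accuracies stay inside [0, 100] after truncation
  b <- gen_behavior(co, days = c("pretest", "posttest", "followup"))
  expect_true(all(b$accuracy >= 0 & b$accuracy <= 100))
})

test_that("recordings survive a text round trip", {
  g <- make_ws_graph(35, 10, 0.2, seed = 7)
  rec <- gen_oxyhb(g, signal_gen_config(seed = 8), 6)
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$sampling_rate, 25.6)
  expect_equal(back$data, rec$data, tolerance = 1e-10, ignore_attr = TRUE)
  unlink(path)

  co <- cohort_config("UP", n_subjects = 2, seed = 9)
  tr <- gen_behavior(co, days = "pretest", trial_level = TRUE)
  tpath <- tempfile(fileext = ".tsv")
  write_trials(tr, tpath)
  tr2 <- read_trials(tpath)
  expect_equal(tr2$rt_ms, tr$rt_ms, tolerance = 1e-10)
  unlink(tpath)
})
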