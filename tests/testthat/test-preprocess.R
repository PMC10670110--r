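fs <- 25.6

test_that("optical density conversion matches its closed form", {
  # constant intensity -> OD identically zero
  const <- matrix(2, 100, 3)
  expect_equal(max(abs(intensity_to_od(const)$values)), 0)

  # halving the intensity at one sample gives OD = ln 2 there
  x <- matrix(1, 200, 1)
  x[50, 1] <- 0.5
  od <- intensity_to_od(x, reference = 1)$values[, 1, 1]
  expect_equal(od[50], log(2), tolerance = 1e-12)
  expect_equal(od[49], 0)

  expect_error(intensity_to_od(matrix(c(1, -1, 1, 1), 2, 2)),
               "non-positive intensity")
})

test_that("motion detection flags injected steps but not clean oscillations", {
  cfg <- preprocess_config()
  t <- seq(0, 60, by = 1 / fs)
  clean <- matrix(0.1 * sin(2 * pi * 0.1 * t), ncol = 1)
  mask <- detect_motion(clean, cfg, sampling_rate = fs)
  expect_equal(nrow(mask$intervals[[1]]), 0)

  set.seed(2)
  noisy <- clean + rnorm(length(t), 0, 0.01)
  stepped <- noisy
  stepped[700:nrow(stepped), 1] <- stepped[700:nrow(stepped), 1] + 1.0
  mask <- detect_motion(stepped, cfg, sampling_rate = fs)
  iv <- mask$intervals[[1]]
  expect_gt(nrow(iv), 0)
  expect_true(any(iv[, "start"] <= 700 & iv[, "end"] >= 700))
})

test_that("nearby flags merge into a single padded interval", {
  m <- swnf:::merge_intervals(cbind(start = c(10, 40, 200), end = c(45, 90, 240)))
  expect_equal(nrow(m), 2)
  expect_equal(m[1, ], c(start = 10, end = 90))
})

test_that("spline correction removes step discontinuities and preserves length", {
  cfg <- preprocess_config()
  set.seed(3)
  n <- round(60 * fs)
  x <- matrix(0.05 * sin(2 * pi * 0.08 * seq_len(n) / fs) + rnorm(n, 0, 0.01),
              ncol = 1)
  step_at <- 800
  step_size <- 1.0
  x[step_at:n, 1] <- x[step_at:n, 1] + step_size
  mask <- detect_motion(x, cfg, sampling_rate = fs)
  expect_gt(nrow(mask$intervals[[1]]), 0)
  fixed <- spline_correct(x, mask)
  expect_equal(dim(fixed), dim(x))
  # residual jumps at the interval edges are small relative to the step
  iv <- mask$intervals[[1]]
  for (r in seq_len(nrow(iv))) {
    s <- iv[r, 1]; e <- iv[r, 2]
    if (s > 1) expect_lt(abs(fixed[s] - fixed[s - 1]), 0.1 * step_size)
    if (e < n) expect_lt(abs(fixed[e + 1] - fixed[e]), 0.1 * step_size)
  }
  # an empty mask leaves the signal untouched
  clean <- matrix(rnorm(2000, 0, 0.001), ncol = 1)
  empty <- detect_motion(clean, cfg, sampling_rate = fs)
  expect_equal(spline_correct(clean, empty), clean)
})

test_that("band-pass magnitude response passes 0.05 Hz and rejects 1.2 Hz", {
  cfg <- preprocess_config()
  t <- seq(0, 400, by = 1 / fs)
  rms <- function(v) sqrt(mean(v^2))
  cardiac <- sin(2 * pi * 1.2 * t)
  slow <- sin(2 * pi * 0.05 * t)
  expect_lt(rms(bandpass(cardiac, cfg, sampling_rate = fs)) / rms(cardiac), 0.05)
  expect_gt(rms(bandpass(slow, cfg, sampling_rate = fs)) / rms(slow), 0.80)
  expect_equal(bandpass(rep(0, 1000), cfg, sampling_rate = fs), rep(0, 1000))
})

test_that("causal and zero-phase filtering agree in passband magnitude", {
  t <- seq(0, 600, by = 1 / fs)
  x <- sin(2 * pi * 0.05 * t)
  off <- bandpass(x, preprocess_config(mode = "offline"), sampling_rate = fs)
  on <- bandpass(x, preprocess_config(mode = "online"), sampling_rate = fs)
  expect_equal(length(on), length(x))
  rms <- function(v) sqrt(mean(v^2))
  skip_transient <- seq(round(length(x) / 3), length(x))
  expect_equal(rms(on[skip_transient]), rms(off[skip_transient]), tolerance = 0.1)
})

test_that("every preprocessing stage preserves sample count", {
  set.seed(4)
  t <- seq_len(1280) / fs
  hbo <- outer(sin(2 * pi * 0.05 * t), c(0.3, 0.2, 0.25, 0.15)) / 100 +
    matrix(rnorm(1280 * 4, 0, 1e-4), 1280, 4)
  hbr <- -0.3 * hbo + matrix(rnorm(1280 * 4, 0, 1e-4), 1280, 4)
  ri <- gen_raw_intensity(hbo, hbr)
  conc <- preprocess_intensity(ri, preprocess_config())
  expect_equal(nrow(conc$hbo$data), 1280)
  expect_equal(nrow(conc$hbr$data), 1280)
})

test_that("Beer-Lambert inversion is linear and exact at zero", {
  zero <- array(0, c(50, 2, 3))
  od <- structure(list(values = zero, sampling_rate = fs), class = "od_series")
  conc <- od_to_conc(od)
  expect_equal(max(abs(conc$hbo$data)), 0)

  set.seed(5)
  vals <- array(rnorm(50 * 2 * 3, 0, 0.1), c(50, 2, 3))
  od1 <- structure(list(values = vals, sampling_rate = fs), class = "od_series")
  od2 <- structure(list(values = 2 * vals, sampling_rate = fs), class = "od_series")
  c1 <- od_to_conc(od1); c2 <- od_to_conc(od2)
  expect_equal(c2$hbo$data, 2 * c1$hbo$data, tolerance = 1e-12)
  expect_equal(c2$hbr$data, 2 * c1$hbr$data, tolerance = 1e-12)
})
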