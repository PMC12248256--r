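# Preprocessing chain: 1 Hz resampling, half-open segmentation, 3-per-minute
# length normalization, and the no-overshoot / integral-conservation
# properties of the interpolation steps.

test_that("1 Hz resampling linearly interpolates between 24-s records", {
  stream <- data.frame(timestamp = c(0, 24), v = c(0, 24))
  s <- resample_to_1hz(stream, "v")
  expect_equal(s$values[s$times == 12], 12)
  expect_equal(s$times, 0:24)
  expect_equal(s$values, 0:24)  # a linear signal is reproduced exactly

  const <- data.frame(timestamp = seq(0, 240, 24), v = 7.5)
  expect_true(all(resample_to_1hz(const, "v")$values == 7.5))
})

test_that("resampling matches an independent piecewise-linear oracle", {
  set.seed(42)
  t <- seq(0, 480, by = 24)
  v <- stats::runif(length(t), 5, 50)
  s <- resample_to_1hz(data.frame(timestamp = t, v = v), "v")
  expect_equal(s$values, plin_eval(t, v, s$times), tolerance = 1e-12)
})

test_that("resampling an already-1 Hz series is the identity", {
  t <- 0:99
  v <- stats::rnorm(100)
  s <- resample_to_1hz(data.frame(timestamp = t, v = v), "v")
  expect_equal(s$times, t)
  expect_equal(s$values, v, tolerance = 1e-12)
})

test_that("degenerate streams are rejected", {
  expect_error(resample_to_1hz(data.frame(timestamp = 1, v = 1), "v"),
               class = "pape_preprocess_error")
  expect_error(resample_to_1hz(data.frame(timestamp = c(0, 10, 5), v = 1:3), "v"),
               class = "pape_preprocess_error")
  expect_error(resample_to_1hz(data.frame(timestamp = 0:5, v = 0:5), "nope"),
               class = "pape_io_error")
})

test_that("segmentation is half-open and counts 300 samples per 5-min dwell", {
  t <- 0:2000
  series <- pape::resample_to_1hz(data.frame(timestamp = t, v = t), "v")
  plan <- data.frame(label = c("A", "B"), arrive_ts = c(100, 400),
                     leave_ts = c(400, 700))
  segs <- segment_series(series, plan)
  expect_length(segs$static$A, 300)
  expect_length(segs$static$B, 300)
  # adjacent half-open intervals share no sample
  expect_equal(max(segs$static$A), 399)
  expect_equal(min(segs$static$B), 400)
  expect_length(intersect(segs$static$A, segs$static$B), 0)
  # the trailing dynamic segment runs from leave(B) to the series end
  expect_equal(segs$dynamic$`B>end`[1], 700)
})

test_that("segmenting is invariant to input ordering upstream", {
  set.seed(7)
  t <- 0:600
  v <- stats::rnorm(601)
  perm <- sample(601)
  sorted <- resample_to_1hz(data.frame(timestamp = t, v = v), "v")
  unsorted <- data.frame(timestamp = t[perm], v = v[perm])
  unsorted <- unsorted[order(unsorted$timestamp), ]
  resorted <- resample_to_1hz(unsorted, "v")
  plan <- data.frame(label = "A", arrive_ts = 60, leave_ts = 360)
  expect_equal(segment_series(sorted, plan)$static$A,
               segment_series(resorted, plan)$static$A)
})

test_that("segments outside the series span raise an error naming the segment", {
  series <- resample_to_1hz(data.frame(timestamp = 0:100, v = 0:100), "v")
  plan <- data.frame(label = "Z", arrive_ts = 50, leave_ts = 500)
  expect_error(segment_series(series, plan), "Z",
               class = "pape_preprocess_error")
})

test_that("length normalization hits 3 nodes per minute with preserved endpoints", {
  out <- normalize_length(0:299, samples_per_minute = 3)
  expect_length(out, 15)
  expect_equal(out[1], 0)
  expect_equal(out[15], 299)
  expect_equal(diff(out), rep(diff(out)[1], 14))  # even spacing of a ramp
  expect_equal(normalize_length(rep(4.2, 300)), rep(4.2, 15))
  expect_error(normalize_length(1), class = "pape_preprocess_error")
})

test_that("normalization agrees with an independent interpolation oracle", {
  set.seed(11)
  v <- cumsum(stats::rnorm(300))
  out <- normalize_length(v, 3)
  nodes <- seq(0, 299, length.out = 15)
  expect_equal(out, plin_eval(0:299, v, nodes), tolerance = 1e-12)
})

test_that("interpolated values never overshoot their bracketing inputs", {
  set.seed(13)
  for (k in 1:10) {
    v <- stats::runif(120, 0, 100)
    out <- normalize_length(v, 3)
    expect_true(all(out >= min(v) - 1e-12 & out <= max(v) + 1e-12))
    t <- seq(0, by = 24, length.out = 30)
    s <- resample_to_1hz(data.frame(timestamp = t, v = v[1:30]), "v")
    expect_true(all(s$values >= min(v[1:30]) - 1e-12 &
                      s$values <= max(v[1:30]) + 1e-12))
  }
})

test_that("normalization conserves the trapezoidal integral of smooth signals", {
  t <- 0:299
  v <- 20 + 10 * sin(2 * pi * t / 150) + 0.02 * t
  out <- normalize_length(v, 3)
  trapz <- function(x, y) sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))
  before <- trapz(t / 60, v)
  after <- trapz(seq(0, 299, length.out = 15) / 60, out)
  expect_lt(abs(after - before) / before, 0.02)
})

test_that("physiological channels block-average to 1 Hz before segmentation", {
  t <- seq(0, 10, by = 0.1)
  stream <- data.frame(timestamp = t, pr = 60 + t)  # linear in time
  s <- block_average_1hz(stream, "pr")
  expect_equal(s$rate_hz, 1)
  # mean of 60 + t over t in [k, k+1) at 0.1 steps is 60 + k + 0.45
  expect_equal(s$values[1:10], 60 + 0:9 + 0.45, tolerance = 1e-9)
})

test_that("preprocess_session yields aligned 15-node static arrays per channel", {
  p <- fixture_profile()
  s <- generate_session(p, scenario_config(), seed = 21)
  segs <- preprocess_session(s)
  for (ch in names(segs)) {
    expect_named(segs[[ch]]$static, c("A", "B", "C", "D", "E", "F", "G"))
    expect_true(all(lengths(segs[[ch]]$static) == 15L))
    expect_length(segs[[ch]]$dynamic, 7L)
  }
  df <- segments_to_df(segs, "TP01")
  expect_true(all(c("participant", "channel", "segment", "segment_type",
                    "node_index", "value") %in% names(df)))
  expect_equal(sum(df$segment_type == "static"),
               length(segs) * 7L * 15L)
})
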