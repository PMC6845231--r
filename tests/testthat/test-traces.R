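test_that("extract_traces subtracts the background region mean", {
  # cell pixels = 10, background = 2 -> trace = 8
  mask <- matrix(0L, 10, 10); mask[4:6, 4:6] <- 1L
  frames <- array(2, dim = c(10, 10, 5))
  for (k in 1:5) frames[4:6, 4:6, k] <- 10
  m <- ca_movie(frames, (0:4) / 10)
  tr <- extract_traces(m, roi_set(mask))
  expect_equal(unname(tr$traces[, 1]), rep(8, 5))

  # uniform movie: cancellation to zero
  mu <- ca_movie(array(3, dim = c(10, 10, 4)), (0:3) / 10)
  tr0 <- extract_traces(mu, roi_set(mask))
  expect_equal(unname(tr0$traces[, 1]), rep(0, 4))

  expect_error(roi_set(mask, roi_ids = c(1, 2)), "absent")
  # empty background: warn, no subtraction
  full <- matrix(1L, 4, 4)
  expect_warning(
    tr2 <- extract_traces(ca_movie(array(5, dim = c(4, 4, 2)), c(0, 0.1)),
                          roi_set(full)),
    "background")
  expect_equal(unname(tr2$traces[, 1]), c(5, 5))
})

test_that("resampling is exact for constants and affine ramps", {
  p <- build_flash_protocol(1, 2)
  # native 15 Hz constant trace
  t15 <- seq(0, 4 - 1e-9, by = 1 / 15)
  ts <- trace_set(t15, matrix(3.5, length(t15)), "1", protocol = p)
  seg <- resample_and_segment(ts, p, rate_hz = 10, pre_s = 0)
  expect_true(all(vapply(seg$segments,
                         function(s) all(s$values == 3.5), logical(1))))

  # ramp F(t) = t at 12 Hz: linear interpolation is exact on affine signals
  t12 <- seq(0, 4 - 1e-9, by = 1 / 12)
  tsr <- trace_set(t12, matrix(t12, length(t12)), "1", protocol = p)
  segr <- resample_and_segment(tsr, p, rate_hz = 10, pre_s = 0)
  s1 <- segr$segments[[1]]
  expect_equal(unname(s1$values[, 1]), s1$t_rel, tolerance = 1e-12)

  # native rate exactly 10 Hz and aligned grid: identity
  t10 <- seq(0, 4 - 1e-9, by = 0.1)
  v <- stats::rnorm(length(t10))
  ts10 <- trace_set(t10, matrix(v, length(t10)), "1", protocol = p)
  seg10 <- resample_and_segment(ts10, p, rate_hz = 10, pre_s = 0)
  expect_equal(unname(seg10$segments[[1]]$values[, 1]), v[1:20],
               tolerance = 1e-12)
})

test_that("epochs outside the recording are dropped with a warning", {
  p <- build_flash_protocol(2, 5)
  tshort <- seq(0, 12, by = 0.1)   # second trial pair incomplete
  ts <- trace_set(tshort, matrix(1, length(tshort)), "1", protocol = p)
  w <- capture_warnings(seg <- resample_and_segment(ts, p))
  expect_true(length(w) >= 1 && all(grepl("dropped", w)))
  expect_lt(length(seg$segments), 4)
})

test_that("trial averaging conserves identical trials and cancels symmetric ones", {
  p <- build_flash_protocol(2, 2)
  t10 <- seq(0, 8 - 1e-9, by = 0.1)
  v <- sin(t10)
  ts <- trace_set(t10, matrix(v, length(t10)), "1", protocol = p)
  seg <- resample_and_segment(ts, p, pre_s = 0)
  avg <- trial_average(seg)
  # period of sin != epoch length, so trials differ; check mean by hand
  on1 <- seg$segments[[1]]$values[, 1]; on2 <- seg$segments[[3]]$values[, 1]
  expect_equal(unname(avg$groups[["flash_on"]]$values[, 1]),
               unname((on1 + on2) / 2))
  expect_equal(avg$groups[["flash_on"]]$n_trials, 2)

  # v and -v average to zero
  ts2 <- trace_set(t10, cbind(v, -v), c("a", "b"), protocol = p)
  avg2 <- trial_average(resample_and_segment(ts2, p, pre_s = 0))
  summed <- avg2$groups[["flash_on"]]$values[, "a"] +
    avg2$groups[["flash_on"]]$values[, "b"]
  expect_equal(unname(summed), rep(0, 20))
})

test_that("averaging noisy trials converges to the ideal trace (CLT bound)", {
  p <- build_flash_protocol(7, 5, pre_gray_s = 2)
  cl <- fast_on_cell()
  noise_sd <- 0.1
  ts <- simulate_traces(list(cl), p, frame_rate_hz = 10,
                        noise_sd = noise_sd, seed = 31)
  ideal <- simulate_traces(list(cl), p, frame_rate_hz = 10, noise_sd = 0)
  avg <- trial_average(resample_and_segment(ts, p))
  avg_ideal <- trial_average(resample_and_segment(ideal, p))
  err <- abs(avg$groups[["flash_on"]]$values[, 1] -
             avg_ideal$groups[["flash_on"]]$values[, 1])
  # per-sample noise sd of the 7-trial mean, in fluorescence units
  expect_true(all(err < 4 * noise_sd * cl$f_baseline / sqrt(7)))
})

test_that("dF/F arithmetic matches hand-worked examples", {
  # F = [1,1,3,3], whole-trace mean F0 = 2 -> [-0.5,-0.5,0.5,0.5]
  p <- build_flash_protocol(1, 0.2)
  tt <- c(0, 0.1, 0.2, 0.3)
  ts <- trace_set(tt, matrix(c(1, 1, 3, 3), 4), "1", protocol = p)
  dff <- compute_dff(ts, f0_mode = "whole_trace_mean")
  native <- (c(1, 1, 3, 3) - 2) / 2
  s <- dff$segments$segments[[1]]
  expect_equal(unname(s$values[s$t_rel >= 0, 1]), native[1:2])
  expect_equal(unname(dff$f0), 2, ignore_attr = TRUE)

  # constant trace -> dF/F = 0 under either mode
  p2 <- build_flash_protocol(1, 1, pre_gray_s = 2)
  t2 <- seq(0, 4 - 1e-9, by = 0.1)
  ts2 <- trace_set(t2, matrix(4, length(t2)), "1", protocol = p2)
  for (mode in c("whole_trace_mean", "gray_last_second")) {
    d <- compute_dff(ts2, f0_mode = mode)
    expect_true(all(vapply(d$segments$segments,
                           function(s) all(s$values == 0), logical(1))))
  }

  # gray-referenced: gray-end mean 2, F = 3 during stimulus -> 0.5
  p3 <- build_flash_protocol(1, 1, pre_gray_s = 2)
  f3 <- ifelse(t2 < 2, 2, 3)
  ts3 <- trace_set(t2, matrix(f3, length(t2)), "1", protocol = p3)
  d3 <- compute_dff(ts3, f0_mode = "gray_last_second")
  s3 <- d3$segments$segments[[1]]
  expect_equal(unname(s3$values[s3$t_rel >= 0, 1]), rep(0.5, 10))
})

test_that("whole-trace-mean dF/F has zero mean and is gain invariant", {
  p <- build_flash_protocol(3, 5)
  ts <- simulate_traces(list(fast_on_cell()), p, frame_rate_hz = 12,
                        noise_sd = 0.05, seed = 17)
  dff1 <- compute_dff(ts, f0_mode = "whole_trace_mean")
  # mean over the whole native trace is zero by construction
  f0 <- mean(ts$traces[, 1])
  expect_equal(mean((ts$traces[, 1] - f0) / f0), 0, tolerance = 1e-12)
  # multiplying the recording by a positive constant leaves dF/F unchanged
  ts_scaled <- ts; ts_scaled$traces <- ts$traces * 3.7
  dff2 <- compute_dff(ts_scaled, f0_mode = "whole_trace_mean")
  expect_equal(dff1$avg$groups[["flash_on"]]$values,
               dff2$avg$groups[["flash_on"]]$values, tolerance = 1e-10)
})

test_that("nonpositive F0 excludes the ROI with a warning", {
  p <- build_flash_protocol(1, 0.2)
  tt <- c(0, 0.1, 0.2, 0.3)
  ts <- trace_set(tt, cbind(a = c(1, 1, 3, 3), b = c(-1, -1, -1, -1)),
                  c("a", "b"), protocol = p)
  expect_warning(d <- compute_dff(ts, f0_mode = "whole_trace_mean"),
                 "nonpositive F0")
  expect_equal(d$roi_ids, "a")
  expect_equal(d$excluded_rois, "b")
})
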