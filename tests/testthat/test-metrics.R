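grid_trace <- function(pre, epoch) {
  list(values = c(pre, epoch),
       t_rel = c(seq(-0.1 * length(pre), -0.1, by = 0.1),
                 seq(0, by = 0.1, length.out = length(epoch))))
}

test_that("step, plateau and integral match hand-worked examples", {
  # pre mean 0.1, epoch peak 1.3 -> step 1.2
  tr <- grid_trace(rep(0.1, 5), c(seq(0.1, 1.3, length.out = 25),
                                  seq(1.3, 0.5, length.out = 25)))
  expect_equal(step_response(tr$values, tr$t_rel), 1.2)

  # flat trace: all metrics zero except integral = value * 50
  fl <- grid_trace(rep(0.2, 5), rep(0.2, 50))
  expect_equal(step_response(fl$values, fl$t_rel), 0)
  expect_equal(plateau_response(fl$values, fl$t_rel), 0)
  expect_equal(integrated_response(fl$values, fl$t_rel), 10.0)

  # sustained offset 0.4 above a zero baseline
  su <- grid_trace(rep(0, 5), rep(0.4, 50))
  expect_equal(plateau_response(su$values, su$t_rel), 0.4)

  # monotonically decreasing trace: negative step (suppression)
  de <- grid_trace(rep(0.5, 5), seq(0.45, -0.5, length.out = 50))
  expect_lt(step_response(de$values, de$t_rel), 0)

  # transient returning to the pre level by epoch end: plateau ~ 0
  tv <- grid_trace(rep(0, 5), c(exp(-seq(0, 4.9, 0.1) / 0.5)))
  expect_lt(abs(plateau_response(tv$values, tv$t_rel)), 1e-3)

  # sign-symmetric trace integrates to zero
  ss <- grid_trace(rep(0, 5), rep(c(1, -1), 25))
  expect_equal(integrated_response(ss$values, ss$t_rel), 0)

  # zero trace
  expect_equal(integrated_response(grid_trace(rep(0, 5), rep(0, 50))$values,
                                   grid_trace(rep(0, 5), rep(0, 50))$t_rel), 0)
})

test_that("metrics demand their context windows", {
  short <- list(values = rep(1, 52), t_rel = seq(-0.2, 4.9, by = 0.1))
  expect_error(step_response(short$values, short$t_rel), "pre-onset")
  shorter <- grid_trace(rep(0, 5), rep(1, 30))
  expect_error(integrated_response(shorter$values, shorter$t_rel), "shorter")
})

test_that("edge amplitude equals step on gray-referenced segments", {
  tr <- grid_trace(rep(0, 5), c(seq(0, 0.8, length.out = 10),
                                seq(0.8, 0, length.out = 20)))
  expect_equal(edge_amplitude(tr$values, tr$t_rel), 0.8)
  fl <- grid_trace(rep(0, 5), rep(0, 30))
  expect_equal(edge_amplitude(fl$values, fl$t_rel), 0)
})

test_that("peak alignment recovers a common pulse from shifted copies", {
  pulse <- exp(-(seq(0, 29) - 10)^2 / 8)
  shifted <- cbind(pulse, c(pulse[-(1:5)], pulse[1:5]),
                   c(pulse[26:30], pulse[1:25]))
  out <- align_and_average(shifted)
  # aligned mean is the pulse itself, up to the common circular position
  expect_equal(max(out), max(pulse), tolerance = 1e-12)
  expect_equal(sort(out), sort(pulse), tolerance = 1e-12)
  # identical traces and single traces pass through
  expect_equal(align_and_average(cbind(pulse, pulse)), pulse)
  expect_equal(align_and_average(pulse), pulse)
})

test_that("direction tuning implements (PD - ND)/PD with smallest-angle ties", {
  r <- c(2, 1, 1, 1, 1, 1, 1, 1)   # PD at 0 deg, ND = 1
  dt <- direction_tuning(r)
  expect_equal(dt$pd_deg, 0)
  expect_equal(dt$dsi, 0.5)
  # all equal: DSI 0, tie broken to smallest angle
  dt0 <- direction_tuning(rep(3, 8))
  expect_equal(dt0$dsi, 0)
  expect_equal(dt0$pd_deg, 0)
  # ND = 0 bound
  expect_equal(direction_tuning(c(0, 0, 2, 0, 0, 0, 0, 0))$dsi, 1)
  # scale invariance
  resp <- c(0.2, 0.9, 1.8, 0.9, 0.2, 0.05, 0.02, 0.05)
  expect_equal(direction_tuning(resp * 7.3)$dsi, direction_tuning(resp)$dsi)
  # nonpositive PD flagged
  flagged <- direction_tuning(rep(-1, 8))
  expect_true(is.na(flagged$dsi) && !flagged$dsi_defined)
  expect_error(direction_tuning(1:7), "8 directions")
})

test_that("fly summary averages ROIs within fly before SEM across flies", {
  tab <- data.frame(fly = c("f1", "f1", "f2"), step = c(0.5, 1.5, 3.0))
  fs <- fly_summary(tab, "step")
  expect_equal(fs$per_fly$mean, c(1.0, 3.0))
  expect_equal(fs$mean, 2.0)
  expect_equal(fs$sem, 1.0)          # sd([1,3])/sqrt(2) = sqrt(2)/sqrt(2)
  expect_equal(fs$n_flies, 2)

  # equal-fly weighting: duplicating one fly's ROIs changes nothing
  tab2 <- rbind(tab, data.frame(fly = "f1", step = c(0.5, 1.5)))
  fs2 <- fly_summary(tab2, "step")
  expect_equal(fs2$mean, fs$mean)
  expect_equal(fs2$sem, fs$sem)

  # identical ROIs -> SEM 0; single fly -> SEM undefined
  expect_equal(fly_summary(data.frame(fly = c("a", "b"), m = c(2, 2)),
                           "m")$sem, 0)
  expect_true(is.na(fly_summary(data.frame(fly = "a", m = 1:3), "m")$sem))
  expect_error(fly_summary(data.frame(fly = character(), m = numeric()), "m"),
               "empty")
})

test_that("condition normalization divides by the pre-drug group mean", {
  expect_equal(normalize_to_condition(c(1.2, 1.2), c(1.2, 1.2)), c(1, 1))
  expect_equal(normalize_to_condition(0, c(1, 2)), 0)
  expect_equal(normalize_to_condition(0.6, c(1.0, 1.4)), 0.5)
  expect_error(normalize_to_condition(1, c(-1, 1)), "positive")
})

test_that("oocyte peak current is normalized to the wash-out mean", {
  tm <- seq(0, 100, by = 0.1)
  cur <- numeric(length(tm))
  cur[tm >= 10 & tm <= 12] <- -30    # glutamate + antagonist
  cur[tm >= 50 & tm <= 52] <- -110   # wash-out application 1
  cur[tm >= 80 & tm <= 82] <- -130   # wash-out application 2
  rec <- list(time = tm, current = cur,
              epochs = data.frame(label = c("antagonist", "washout",
                                            "washout"),
                                  start_s = c(5, 45, 75),
                                  end_s = c(20, 60, 90)))
  expect_equal(normalized_peak_current(rec), 30 / 120)
  # equal peaks -> 1; fully blocked -> 0
  rec2 <- rec; rec2$current[tm >= 10 & tm <= 12] <- -120
  expect_equal(normalized_peak_current(rec2), 1)
  rec3 <- rec; rec3$current[tm >= 10 & tm <= 12] <- 0
  expect_equal(normalized_peak_current(rec3), 0)
  rec4 <- rec; rec4$epochs <- rec4$epochs[1, , drop = FALSE]
  expect_error(normalized_peak_current(rec4), "wash-out")
})

test_that("noiseless tuned cells give exact PD and unit DSI through the pipeline", {
  p <- build_edge_protocol(20, reps = 1, gray_s = 2, seed = 2)
  prefs <- c(0, 90, 225)
  cells <- lapply(seq_along(prefs), function(i) {
    fast_on_cell(i, tuning = list(kind = "cosine_rectified",
                                  pref_dir_deg = prefs[i]))
  })
  ts <- simulate_traces(cells, p, frame_rate_hz = 12)
  dff <- compute_dff(ts, f0_mode = "gray_last_second")
  et <- edge_response_table(dff)
  on <- et[et$contrast > 0, ]
  for (i in seq_along(prefs)) {
    ri <- on[on$roi == as.character(i), ]
    dt <- direction_tuning(setNames(ri$amplitude, ri$direction_deg))
    expect_equal(dt$pd_deg, prefs[i])
    # ND is zero up to the residual indicator tail of earlier epochs
    expect_lt(abs(dt$nd_response), 0.01)
    expect_equal(dt$dsi, 1, tolerance = 0.01)
  }
})
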