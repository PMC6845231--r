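test_that("ideal response is rectified by polarity", {
  p <- build_flash_protocol(2, 5)
  times <- seq(0, 19.9, by = 0.1)
  on_cell <- fast_on_cell()
  tr <- ideal_response(on_cell, p, times = times)
  ep <- protocol_epoch_times(p)
  off_idx <- times >= ep$onset_s[2] & times < ep$offset_s[2]
  expect_true(all(tr[off_idx] == 0))
  expect_gt(max(tr[!off_idx]), 0.9)
  # OFF cell: mirror image
  off_cell <- fast_on_cell(polarity = -1)
  tr2 <- ideal_response(off_cell, p, times = times)
  expect_true(all(tr2[times < ep$onset_s[2]] == 0))
  expect_gt(max(tr2[off_idx]), 0.9)
})

test_that("two-receptor gain formula matches hand calculations", {
  cl <- fast_on_cell(receptor_weights = c(1, 0))
  full_block <- drug_condition("b", block_glu = 1)
  expect_equal(unname(drug_gains(cl, full_block)), c(0, 0))
  p <- build_flash_protocol(1, 5)
  expect_true(all(ideal_response(cl, p, full_block,
                                 times = seq(0, 9.9, 0.1)) == 0))

  cl2 <- fast_on_cell(receptor_weights = c(0.6, 0.4))
  resc <- drug_condition("r", block_glu = 1, block_gaba = 1,
                         insensitive_glu = TRUE)
  g <- drug_gains(cl2, resc)
  expect_equal(unname(g[1]), 0.6)   # w_glu * 1 + w_gaba * 0
  tr <- ideal_response(cl2, p, resc, times = seq(0, 4.99, 0.01))
  # tau_rise -> small limit: peak = 0.6 * amp_transient
  expect_within(max(tr), 0.6 * cl2$amp_transient, 0.01)
})

test_that("insensitive alleles restore gain 1 for any block level", {
  cl <- fast_on_cell()
  for (bg in c(0.3, 0.7, 1)) {
    for (bb in c(0.2, 1)) {
      d <- drug_condition("x", block_glu = bg, block_gaba = bb,
                          insensitive_glu = TRUE, insensitive_gaba = TRUE)
      expect_equal(unname(drug_gains(cl, d)), c(1, 1))
      expect_equal(unname(drug_gains(cl, d, per_component = TRUE)), c(1, 1))
    }
  }
})

test_that("per-component block dissociates step and plateau", {
  p <- build_flash_protocol(1, 5)
  cl <- fast_on_cell()
  times <- seq(0, 9.99, by = 0.01)
  ctrl <- ideal_response(cl, p, drug_condition(), times, per_component = TRUE)
  glu_only <- ideal_response(cl, p,
    drug_condition("g", 1, 1, insensitive_glu = TRUE), times,
    per_component = TRUE)
  gaba_only <- ideal_response(cl, p,
    drug_condition("r", 1, 1, insensitive_gaba = TRUE), times,
    per_component = TRUE)
  # GluCl-insensitive keeps the full transient peak, loses the plateau
  expect_within(max(glu_only), max(ctrl), 0.01)
  expect_lt(glu_only[times > 4.5 & times < 5][1], 0.05)
  # Rdl-insensitive keeps the plateau, loses the transient overshoot
  late <- times > 4.5 & times < 5
  expect_within(mean(gaba_only[late]), mean(ctrl[late]), 0.02)
  expect_lt(max(gaba_only), 0.45)
})

test_that("noiseless rendering reproduces the ideal response in pixel space", {
  sim <- noiseless_flash_sim()
  cl <- sim$truth$cells[[1]]
  px <- sim$movie$frames[cl$center_px[1], cl$center_px[2], ]
  expected <- 5 + cl$f_baseline * (1 + sim$truth$ideal_dff[1, ])
  expect_equal(px, expected, tolerance = 1e-12)
})

test_that("rendering is deterministic for identical config and seed", {
  p <- build_flash_protocol(1, 2)
  cfg <- movie_config(32, 32, frame_rate_hz = 10, photon_gain = 50,
                      read_noise_sd = 1, motion_walk_sd = 1, seed = 9)
  a <- render_movie(list(fast_on_cell(center = c(16, 16))), p, config = cfg)
  b <- render_movie(list(fast_on_cell(center = c(16, 16))), p, config = cfg)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$shifts, b$truth$shifts)
  cfg2 <- cfg; cfg2$seed <- 10L
  c <- render_movie(list(fast_on_cell(center = c(16, 16))), p, config = cfg2)
  expect_false(identical(a$movie$frames, c$movie$frames))
})

test_that("motion ground truth is a bounded integer walk starting at rest", {
  p <- build_flash_protocol(2, 5)
  cfg <- movie_config(40, 40, frame_rate_hz = 12, motion_walk_sd = 1,
                      max_shift_px = 6, seed = 4)
  sim <- render_movie(list(fast_on_cell(center = c(20, 20))), p, config = cfg)
  s <- sim$truth$shifts
  expect_equal(unname(s[1, ]), c(0, 0))
  expect_true(all(s == round(s)))
  expect_true(all(abs(s) <= 6))
  expect_gt(max(abs(s)), 0)
})

test_that("cells outside the frame error; overlaps warn and sum", {
  p <- build_flash_protocol(1, 1)
  cfg <- movie_config(32, 32, frame_rate_hz = 10)
  expect_error(render_movie(list(fast_on_cell(center = c(2, 2))), p,
                            config = cfg), "outside")
  expect_warning(
    render_movie(list(fast_on_cell(1, center = c(16, 16)),
                      fast_on_cell(2, center = c(17, 17))), p, config = cfg),
    "overlap")
})

test_that("simulate_traces matches the rendered-movie trace path", {
  # noiseless: background-subtracted ROI mean equals f_baseline * (1 + dff)
  sim <- noiseless_flash_sim()
  tr_movie <- extract_traces(sim$movie, sim$rois, protocol = sim$protocol)
  tr_direct <- simulate_traces(sim$truth$cells, sim$protocol,
                               frame_rate_hz = 12, noise_sd = 0)
  expect_equal(unname(tr_movie$traces[, 1]), unname(tr_direct$traces[, 1]),
               tolerance = 1e-10)
})
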