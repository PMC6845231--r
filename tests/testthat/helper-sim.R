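# shared fixture builders: tiny simulations used across test files

# single fast-rising ON cell with the canonical transient/plateau shape
fast_on_cell <- function(id = 1, center = c(20, 20), ...) {
  args <- list(id, center_px = center, radius_px = 4, f_baseline = 30,
               amp_transient = 1.0, amp_plateau = 0.4, tau_rise_s = 0.05)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cell_spec, args)
}

# noiseless rendered flash movie with a leading gray baseline
noiseless_flash_sim <- function(n_trials = 3, pre_gray_s = 5,
                                frame_rate_hz = 12, cells = NULL) {
  p <- build_flash_protocol(n_trials, 5, pre_gray_s = pre_gray_s)
  if (is.null(cells)) cells <- list(fast_on_cell())
  cfg <- movie_config(height_px = 48, width_px = 48,
                      frame_rate_hz = frame_rate_hz, seed = 11)
  sim <- render_movie(cells, p, config = cfg)
  sim$protocol <- p
  sim
}

# trace-level flash population: n_resp responsive ON cells, n_flat flat,
# n_anti OFF (anti-correlated) cells; returns a dff_trace_set
flash_population_dff <- function(n_resp = 20, n_flat = 20, n_anti = 10,
                                 noise_sd = 0, seed = 42,
                                 f0_mode = "whole_trace_mean") {
  p <- build_flash_protocol(7, 5, pre_gray_s = 5)
  mk <- function(i, pol, a_tr, a_pl) {
    cell_spec(i, polarity = pol, amp_transient = a_tr, amp_plateau = a_pl,
              tau_rise_s = 0.05)
  }
  cells <- c(
    lapply(seq_len(n_resp), function(i) mk(i, 1, 1.0, 0.4)),
    lapply(seq_len(n_flat), function(i) mk(n_resp + i, 1, 0, 0)),
    lapply(seq_len(n_anti), function(i) mk(n_resp + n_flat + i, -1, 1.0, 0.4))
  )
  ts <- simulate_traces(cells, p, frame_rate_hz = 12, noise_sd = noise_sd,
                        seed = seed)
  compute_dff(ts, f0_mode = f0_mode)
}

expect_within <- function(object, expected, rel) {
  expect_lt(abs(object - expected), abs(expected) * rel)
}
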