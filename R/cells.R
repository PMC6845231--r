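#' Specify a simulated cell
#'
#' Describes one fluorescent cell body for the synthetic-movie generator: its
#' position and size in the frame, response polarity (ON cells respond to
#' luminance increments, OFF cells to decrements), calcium-response
#' amplitudes and kinetics, direction tuning, and the split of its visual
#' drive between a glutamate-gated (GluClalpha) and a GABA-gated (Rdl)
#' chloride-channel pathway.
#'
#' The response to a sustained contrast step is a fast rise (`tau_rise_s`) to
#' a transient peak of `amp_transient` dF/F which, after a short hold
#' (`hold_s`), decays with `tau_transient_s` to a sustained plateau of
#' `amp_plateau` dF/F — the canonical ON-cell shape in which the transient
#' has settled onto the plateau within ~2 s.
#'
#' @param id integer or character cell id.
#' @param center_px numeric length-2, (row, col) center in pixels.
#' @param radius_px disc radius in pixels (>= 1).
#' @param polarity +1 for ON, -1 for OFF.
#' @param f_baseline baseline fluorescence, arbitrary units (> 0).
#' @param amp_transient peak dF/F of the transient (>= amp_plateau).
#' @param amp_plateau sustained dF/F (>= 0).
#' @param tau_rise_s rise time constant, s.
#' @param tau_transient_s transient decay time constant, s.
#' @param hold_s time the transient holds at peak before decaying, s.
#' @param tuning list: `kind` one of `"untuned"` / `"cosine_rectified"`, and
#'   `pref_dir_deg` for tuned cells.
#' @param receptor_weights numeric length-2 `(w_glu, w_gaba)`, nonnegative,
#'   summing to 1: split of the response between the glutamatergic and
#'   GABAergic input pathway.
#' @param rf_center_deg optional (azimuth, elevation) of the receptive-field
#'   center in degrees relative to the display center; used to delay
#'   moving-edge responses. Default c(0, 0) (display center).
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(id, center_px = c(16, 16), radius_px = 3, polarity = 1,
                      f_baseline = 30, amp_transient = 1.0, amp_plateau = 0.4,
                      tau_rise_s = 0.1, tau_transient_s = 0.8, hold_s = 0.5,
                      tuning = list(kind = "untuned", pref_dir_deg = NA_real_),
                      receptor_weights = c(0.6, 0.4),
                      rf_center_deg = c(0, 0)) {
  if (radius_px < 1) stop("radius_px must be >= 1", call. = FALSE)
  if (f_baseline <= 0) stop("f_baseline must be > 0", call. = FALSE)
  if (!(polarity %in% c(-1, 1))) stop("polarity must be +1 or -1", call. = FALSE)
  if (amp_plateau < 0 || amp_transient < amp_plateau) {
    stop("need amp_transient >= amp_plateau >= 0", call. = FALSE)
  }
  if (length(receptor_weights) != 2 || any(receptor_weights < 0) ||
      abs(sum(receptor_weights) - 1) > 1e-8) {
    stop("receptor_weights must be two nonnegative values summing to 1",
         call. = FALSE)
  }
  if (!tuning$kind %in% c("untuned", "cosine_rectified")) {
    stop("unknown tuning kind: ", tuning$kind, call. = FALSE)
  }
  if (tuning$kind == "cosine_rectified" && !is.finite(tuning$pref_dir_deg)) {
    stop("tuned cells need pref_dir_deg", call. = FALSE)
  }
  structure(
    list(id = id, center_px = center_px, radius_px = radius_px,
         polarity = polarity, f_baseline = f_baseline,
         amp_transient = amp_transient, amp_plateau = amp_plateau,
         tau_rise_s = tau_rise_s, tau_transient_s = tau_transient_s,
         hold_s = hold_s, tuning = tuning,
         receptor_weights = receptor_weights, rf_center_deg = rf_center_deg),
    class = "cell_spec"
  )
}

#' Specify a pharmacological / pharmacogenetic condition
#'
#' Models bath-applied channel block (e.g. picrotoxin) acting on the
#' glutamate-gated and GABA-gated chloride conductances, and block-insensitive
#' point-mutant alleles (GluClalpha S278T, Rdl MDRR) that force the effective
#' block of the corresponding channel to zero.
#'
#' @param name condition label.
#' @param block_glu,block_gaba fraction of the respective conductance blocked,
#'   in \[0, 1\].
#' @param insensitive_glu,insensitive_gaba logical; a block-insensitive allele
#'   of the respective channel (effective block forced to 0).
#' @return An object of class `drug_condition`.
#' @examples
#' ctrl <- drug_condition("control")
#' ptx  <- drug_condition("ptx", block_glu = 1, block_gaba = 1)
#' resc <- drug_condition("ptx_glu_insens", block_glu = 1, block_gaba = 1,
#'                        insensitive_glu = TRUE)
#' @export
drug_condition <- function(name = "control", block_glu = 0, block_gaba = 0,
                           insensitive_glu = FALSE, insensitive_gaba = FALSE) {
  if (block_glu < 0 || block_glu > 1 || block_gaba < 0 || block_gaba > 1) {
    stop("blocks must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, block_glu = block_glu, block_gaba = block_gaba,
         insensitive_glu = isTRUE(insensitive_glu),
         insensitive_gaba = isTRUE(insensitive_gaba)),
    class = "drug_condition"
  )
}

#' Effective per-channel block of a condition
#'
#' An insensitive allele forces the corresponding effective block to zero.
#'
#' @param drug a `drug_condition`.
#' @return numeric length-2 `(b_glu, b_gaba)`.
#' @export
effective_block <- function(drug) {
  stopifnot(inherits(drug, "drug_condition"))
  c(glu  = if (drug$insensitive_glu)  0 else drug$block_glu,
    gaba = if (drug$insensitive_gaba) 0 else drug$block_gaba)
}

#' Movie generator configuration
#'
#' @param height_px,width_px frame size in pixels.
#' @param frame_rate_hz acquisition rate, Hz (typical in vivo range 10-15).
#' @param photon_gain expected photon counts per unit fluorescence; 0 disables
#'   shot noise (deterministic pixel = expected fluorescence).
#' @param read_noise_sd additive Gaussian read noise, counts (>= 0).
#' @param motion_walk_sd per-frame step s.d. of the integer random-walk
#'   motion, pixels; 0 disables motion.
#' @param max_shift_px bound at which the motion walk reflects (brain motion
#'   oscillates about a rest position rather than diffusing freely); keep
#'   <= the registration search radius.
#' @param background_level uniform background fluorescence added everywhere.
#' @param seed RNG seed: identical seed + config give a bit-identical movie.
#' @return An object of class `movie_config`.
#' @export
movie_config <- function(height_px = 64, width_px = 64, frame_rate_hz = 12,
                         photon_gain = 0, read_noise_sd = 0,
                         motion_walk_sd = 0, max_shift_px = 8,
                         background_level = 5, seed = 1L) {
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0", call. = FALSE)
  if (photon_gain < 0 || read_noise_sd < 0 || motion_walk_sd < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  structure(
    list(height_px = height_px, width_px = width_px,
         frame_rate_hz = frame_rate_hz, photon_gain = photon_gain,
         read_noise_sd = read_noise_sd, motion_walk_sd = motion_walk_sd,
         max_shift_px = max_shift_px, background_level = background_level,
         seed = as.integer(seed)),
    class = "movie_config"
  )
}
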