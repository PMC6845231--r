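#' Calcium-response kernel
#'
#' Shared response shape: a rise with time constant `tau_rise_s` to a
#' transient peak, a short hold at the peak, then exponential relaxation with
#' `tau_transient_s` onto the plateau. The kernel is the sum of a transient
#' component `amp_transient * D(t)` and a plateau component
#' `amp_plateau * (1 - D(t))`, where `D(t)` is the post-hold decay factor;
#' the two components are scaled independently by the glutamatergic and
#' GABAergic pathway gains, so the kernel doubles as the two-receptor block
#' model (equal gains collapse to a plain scalar gain).
#'
#' @param t time since drive onset, seconds (values < 0 give 0).
#' @param amp_transient,amp_plateau peak and sustained dF/F.
#' @param tau_rise_s,tau_transient_s,hold_s kinetics, seconds.
#' @param g_glu,g_gaba pathway gains in \[0, 1\] applied to the transient and
#'   plateau component respectively.
#' @param sustained logical; TRUE for a maintained contrast step (flash),
#'   FALSE for a passing event (moving edge), in which case the plateau
#'   component is absent and the transient decays back to zero.
#' @return numeric vector of dF/F values, same length as `t`.
#' @export
response_kernel <- function(t, amp_transient, amp_plateau = 0,
                            tau_rise_s = 0.1, tau_transient_s = 0.8,
                            hold_s = 0.5, g_glu = 1, g_gaba = 1,
                            sustained = TRUE) {
  out <- numeric(length(t))
  pos <- which(t >= 0)
  if (!length(pos)) return(out)
  tp <- t[pos]
  rise <- if (tau_rise_s > 0) 1 - exp(-tp / tau_rise_s) else rep(1, length(tp))
  decay <- exp(-pmax(0, tp - hold_s) / tau_transient_s)
  env <- if (sustained) {
    g_glu * amp_transient * decay + g_gaba * amp_plateau * (1 - decay)
  } else {
    g_glu * amp_transient * decay
  }
  out[pos] <- rise * env
  out
}

#' Direction-tuning factor of a cell
#'
#' Rectified-cosine tuning: `max(0, cos(direction - preferred))`; untuned
#' cells return 1 for every direction.
#'
#' @param cell a `cell_spec`.
#' @param direction_deg motion direction in degrees.
#' @return scalar in \[0, 1\].
#' @export
tuning_factor <- function(cell, direction_deg) {
  if (cell$tuning$kind == "untuned") return(1)
  max(0, cos((direction_deg - cell$tuning$pref_dir_deg) * pi / 180))
}

#' Pathway gains of a cell under a drug condition
#'
#' Scalar mode: a single gain
#' `g = w_glu * (1 - b_glu) + w_gaba * (1 - b_gaba)` (effective blocks, i.e.
#' zero for insensitive alleles) applied to the whole response. Component
#' mode: the glutamatergic gain `(1 - b_glu)` scales the transient component
#' and the GABAergic gain `(1 - b_gaba)` the plateau component, which is the
#' minimal model in which a block-insensitive GluClalpha allele restores the
#' full step response and an insensitive Rdl allele the full plateau.
#'
#' @param cell a `cell_spec`.
#' @param drug a `drug_condition`.
#' @param per_component logical, see above.
#' @return numeric length-2 `(g_glu, g_gaba)`; in scalar mode both entries
#'   equal the scalar gain.
#' @export
drug_gains <- function(cell, drug, per_component = FALSE) {
  b <- effective_block(drug)
  if (per_component) {
    c(g_glu = unname(1 - b["glu"]), g_gaba = unname(1 - b["gaba"]))
  } else {
    w <- cell$receptor_weights
    g <- w[1] * (1 - b[["glu"]]) + w[2] * (1 - b[["gaba"]])
    c(g_glu = g, g_gaba = g)
  }
}

#' Ideal (noiseless) dF/F response of a cell to a protocol
#'
#' Evaluates the cell's deterministic calcium response at the given sample
#' times. Flash epochs whose contrast sign matches the cell's polarity drive
#' a sustained kernel that is cut off when the epoch ends (full-field
#' contrast reversal); non-matching epochs leave the trace at zero. A moving
#' edge of matching sign triggers a transient event when the edge crosses the
#' cell's receptive-field center — i.e. delayed within the epoch by
#' `(projection onto the motion axis + span/2) / speed` — scaled by the
#' cell's direction tuning; the event transient relaxes freely into the
#' following gray epoch.
#'
#' @param cell a `cell_spec`.
#' @param protocol a `stimulus_protocol`.
#' @param drug a `drug_condition` (default: no block).
#' @param times sample times in seconds (e.g. frame times).
#' @param per_component logical; use the per-component receptor model (see
#'   [drug_gains()]).
#' @return numeric dF/F trace, `length(times)`.
#' @export
ideal_response <- function(cell, protocol, drug = drug_condition(),
                           times, per_component = FALSE) {
  stopifnot(inherits(cell, "cell_spec"), inherits(protocol, "stimulus_protocol"))
  g <- drug_gains(cell, drug, per_component = per_component)
  ep <- protocol_epoch_times(protocol)
  trace <- numeric(length(times))
  for (i in seq_len(nrow(ep))) {
    kind <- ep$kind[i]
    if (kind == "gray") next
    matches <- sign(ep$contrast[i]) == cell$polarity
    if (!matches) next
    if (kind %in% c("flash_on", "flash_off")) {
      idx <- which(times >= ep$onset_s[i] & times < ep$offset_s[i])
      if (length(idx)) {
        trace[idx] <- trace[idx] + response_kernel(
          times[idx] - ep$onset_s[i],
          cell$amp_transient, cell$amp_plateau,
          cell$tau_rise_s, cell$tau_transient_s, cell$hold_s,
          g_glu = g[["g_glu"]], g_gaba = g[["g_gaba"]], sustained = TRUE)
      }
    } else if (kind == "edge") {
      speed <- protocol$edge_speed_dps
      span <- protocol$field_span_deg
      u <- c(cos(ep$direction_deg[i] * pi / 180),
             sin(ep$direction_deg[i] * pi / 180))
      proj <- sum(cell$rf_center_deg * u)
      delay <- (proj + span / 2) / speed
      t0 <- ep$onset_s[i] + delay
      amp <- cell$amp_transient * tuning_factor(cell, ep$direction_deg[i])
      if (amp > 0) {
        idx <- which(times >= t0)
        if (length(idx)) {
          trace[idx] <- trace[idx] + response_kernel(
            times[idx] - t0, amp, 0,
            cell$tau_rise_s, cell$tau_transient_s, cell$hold_s,
            g_glu = g[["g_glu"]], g_gaba = g[["g_gaba"]], sustained = FALSE)
        }
      }
    }
  }
  trace
}
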