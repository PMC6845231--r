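#' Flash and edge response metrics
#'
#' All metrics operate on a single trial-averaged dF/F segment sampled on
#' the stimulus-locked 10 Hz grid: `values` indexed by `t_rel`, with t = 0 at
#' epoch onset, negative times the pre-onset context and the epoch samples
#' spanning the stimulus duration.
#'
#' * `step_response`: peak dF/F during the epoch minus the mean of the
#'   500 ms (5 samples) before onset. Negative values are allowed and signal
#'   suppression.
#' * `plateau_response`: mean of the last 500 ms (5 samples) of the epoch
#'   minus the same pre-onset mean.
#' * `integrated_response`: plain sum of the epoch samples (50 for a 5 s
#'   epoch at 10 Hz); no baseline subtraction.
#' * `edge_amplitude`: as `step_response`, on gray-referenced edge segments.
#'
#' @param values numeric dF/F samples.
#' @param t_rel sample times relative to epoch onset, seconds.
#' @param rate_hz grid rate (default 10).
#' @param epoch_s nominal epoch duration for `integrated_response`
#'   (default 5 s; shorter epochs are an error).
#' @return scalar dF/F (dF/F-samples for the integral).
#' @name response_metrics
NULL

.pre_mean <- function(values, t_rel, rate_hz) {
  pre_idx <- which(t_rel < 0 & t_rel >= -0.5 - 1e-9)
  if (length(pre_idx) < round(0.5 * rate_hz)) {
    stop("500 ms pre-onset context (", round(0.5 * rate_hz),
         " samples) required", call. = FALSE)
  }
  mean(values[pre_idx])
}

#' @rdname response_metrics
#' @export
step_response <- function(values, t_rel, rate_hz = 10) {
  stopifnot(length(values) == length(t_rel))
  max(values[t_rel >= 0]) - .pre_mean(values, t_rel, rate_hz)
}

#' @rdname response_metrics
#' @export
plateau_response <- function(values, t_rel, rate_hz = 10) {
  stopifnot(length(values) == length(t_rel))
  ep <- which(t_rel >= 0)
  n_last <- round(0.5 * rate_hz)
  last_idx <- ep[(length(ep) - n_last + 1):length(ep)]
  mean(values[last_idx]) - .pre_mean(values, t_rel, rate_hz)
}

#' @rdname response_metrics
#' @export
integrated_response <- function(values, t_rel, rate_hz = 10, epoch_s = 5) {
  stopifnot(length(values) == length(t_rel))
  ep <- which(t_rel >= 0)
  if (length(ep) < round(epoch_s * rate_hz)) {
    stop("epoch shorter than the nominal ", epoch_s, " s", call. = FALSE)
  }
  sum(values[ep[seq_len(round(epoch_s * rate_hz))]])
}

#' @rdname response_metrics
#' @export
edge_amplitude <- function(values, t_rel, rate_hz = 10) {
  step_response(values, t_rel, rate_hz)
}

#' Peak-aligned population mean trace
#'
#' Each trace is circularly shifted so its maximum lands at the median peak
#' index across traces, then the traces are averaged pointwise — the
#' population mean used for displaying edge responses, which would otherwise
#' be smeared by receptive-field position.
#'
#' @param traces numeric matrix, time x ROIs (or a single vector).
#' @return numeric vector: the aligned mean trace.
#' @export
align_and_average <- function(traces) {
  traces <- as.matrix(traces)
  if (!ncol(traces)) stop("no traces to align", call. = FALSE)
  peaks <- apply(traces, 2, which.max)
  target <- round(stats::median(peaks))
  n <- nrow(traces)
  aligned <- vapply(seq_len(ncol(traces)), function(j) {
    shift <- target - peaks[j]
    idx <- ((seq_len(n) - 1 - shift) %% n) + 1
    traces[idx, j]
  }, numeric(n))
  rowMeans(aligned)
}

#' Direction tuning from eight direction-indexed amplitudes
#'
#' PD is the direction of maximal response (ties broken toward the smallest
#' angle), ND the response 180 degrees away, and the direction selectivity
#' index DSI = (PD - ND) / PD.
#'
#' @param responses numeric length-8, amplitudes for directions 0, 45, ...,
#'   315 degrees (in that order, or named with the directions).
#' @return list of class `direction_tuning`: `responses`, `pd_deg`,
#'   `pd_response`, `nd_response`, `dsi` (NA with a flag when the PD
#'   response is not positive).
#' @export
direction_tuning <- function(responses) {
  if (length(responses) != 8) {
    stop("exactly 8 directions at 45 degree spacing required", call. = FALSE)
  }
  dirs <- seq(0, 315, by = 45)
  if (!is.null(names(responses))) {
    responses <- responses[as.character(dirs)]
  }
  responses <- as.numeric(responses)
  pd_idx <- which.max(responses)            # which.max takes the first max
  nd_idx <- ((pd_idx - 1 + 4) %% 8) + 1
  pd <- responses[pd_idx]; nd <- responses[nd_idx]
  dsi <- if (pd > 0) (pd - nd) / pd else NA_real_
  structure(list(responses = stats::setNames(responses, dirs),
                 pd_deg = dirs[pd_idx], pd_response = pd, nd_response = nd,
                 dsi = dsi, dsi_defined = pd > 0),
            class = "direction_tuning")
}

#' Flash response table for a dF/F set
#'
#' Step, plateau and integrated responses of every ROI for each flash epoch
#' kind of the trial-averaged traces.
#'
#' @param dff a `dff_trace_set` from a flash protocol.
#' @param epoch_s nominal epoch duration for the integral, seconds.
#' @return data.frame: roi, fly, condition, kind, step, plateau, integral.
#' @export
flash_response_table <- function(dff, epoch_s = 5) {
  stopifnot(inherits(dff, "dff_trace_set"))
  g <- dff$avg$groups
  kinds <- intersect(c("flash_on", "flash_off"), names(g))
  rows <- lapply(kinds, function(k) {
    s <- g[[k]]
    do.call(rbind, lapply(dff$roi_ids, function(id) {
      v <- s$values[, id]
      data.frame(roi = id, fly = dff$fly, condition = dff$condition,
                 kind = k,
                 step = step_response(v, s$t_rel, dff$rate_hz),
                 plateau = plateau_response(v, s$t_rel, dff$rate_hz),
                 integral = integrated_response(v, s$t_rel, dff$rate_hz,
                                                epoch_s),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Edge response table for a dF/F set
#'
#' Edge amplitude of every ROI for each direction x contrast of the
#' trial-averaged traces, computed per ROI before any peak alignment.
#'
#' @param dff a `dff_trace_set` from an edge protocol (gray-referenced F0).
#' @return data.frame: roi, fly, condition, contrast, direction_deg,
#'   amplitude.
#' @export
edge_response_table <- function(dff) {
  stopifnot(inherits(dff, "dff_trace_set"))
  g <- dff$avg$groups
  edge_keys <- names(g)[vapply(g, function(x) x$kind == "edge", logical(1))]
  rows <- lapply(edge_keys, function(k) {
    s <- g[[k]]
    do.call(rbind, lapply(dff$roi_ids, function(id) {
      v <- s$values[, id]
      data.frame(roi = id, fly = dff$fly, condition = dff$condition,
                 contrast = s$contrast, direction_deg = s$direction_deg,
                 amplitude = edge_amplitude(v, s$t_rel, dff$rate_hz),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fly-level summary of a metric
#'
#' Group statistics computed across flies after averaging over the ROIs of
#' each fly, so every fly contributes equally regardless of ROI count:
#' per-fly means, the grand mean, and SEM = sd(per-fly means) / sqrt(n
#' flies). With a single fly the SEM is undefined (NA).
#'
#' @param table data.frame with at least a `fly` column and the metric.
#' @param metric column name to summarize.
#' @return list of class `fly_summary`: `per_fly` (data.frame fly, mean,
#'   n_cells), `mean`, `sem`, `n_flies`, `n_cells`.
#' @export
fly_summary <- function(table, metric) {
  if (!nrow(table)) stop("empty table", call. = FALSE)
  if (!metric %in% names(table)) stop("no column '", metric, "'", call. = FALSE)
  per_fly <- aggregate(table[[metric]], by = list(fly = table$fly), FUN = mean)
  names(per_fly)[2] <- "mean"
  per_fly$n_cells <- as.vector(table(table$fly)[per_fly$fly])
  n_flies <- nrow(per_fly)
  structure(list(per_fly = per_fly,
                 mean = mean(per_fly$mean),
                 sem = if (n_flies > 1)
                   stats::sd(per_fly$mean) / sqrt(n_flies) else NA_real_,
                 n_flies = n_flies, n_cells = sum(per_fly$n_cells)),
            class = "fly_summary")
}

#' @export
print.fly_summary <- function(x, ...) {
  cat(sprintf("mean %.4g +/- %.4g SEM, n = %d (%d)\n",
              x$mean, x$sem, x$n_flies, x$n_cells))
  invisible(x)
}

#' Normalize post-drug metrics to the pre-drug group mean
#'
#' Each post-condition value (typically a per-fly mean) is divided by the
#' mean of the pre-condition values of the same genotype.
#'
#' @param post_values numeric post-drug values.
#' @param pre_values numeric pre-drug values of the matching group.
#' @return numeric, `post_values / mean(pre_values)`.
#' @export
normalize_to_condition <- function(post_values, pre_values) {
  m <- mean(pre_values)
  if (!is.finite(m) || m <= 0) {
    stop("pre-condition mean must be positive", call. = FALSE)
  }
  post_values / m
}

#' Normalized peak current of an oocyte recording
#'
#' Two-electrode voltage-clamp summary: the absolute peak current evoked by
#' agonist application in the presence of the antagonist, divided by the
#' mean absolute peak evoked by agonist after antagonist wash-out.
#'
#' @param rec list with `time` (s), `current` (nA) and `epochs`, a
#'   data.frame with `label` (`"antagonist"` / `"washout"`), `start_s`,
#'   `end_s`; each labelled window must contain an agonist application.
#' @return fraction of the wash-out peak (scalar).
#' @export
normalized_peak_current <- function(rec) {
  stopifnot(all(c("time", "current", "epochs") %in% names(rec)))
  ep <- rec$epochs
  wash <- ep[ep$label == "washout", , drop = FALSE]
  anta <- ep[ep$label == "antagonist", , drop = FALSE]
  if (!nrow(wash)) stop("wash-out epoch required for normalization",
                        call. = FALSE)
  if (!nrow(anta)) stop("antagonist epoch missing", call. = FALSE)
  peak_in <- function(w) {
    idx <- rec$time >= w["start_s"] & rec$time <= w["end_s"]
    max(abs(rec$current[idx]))
  }
  anta_peak <- max(apply(anta[c("start_s", "end_s")], 1, peak_in))
  wash_peaks <- apply(wash[c("start_s", "end_s")], 1, peak_in)
  anta_peak / mean(wash_peaks)
}
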