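#' ROI set: integer label mask plus metadata
#'
#' @param mask integer matrix; pixels of ROI `i` carry label `i`, 0 elsewhere.
#'   All unlabeled pixels form the background region unless a dedicated
#'   `background_mask` is given.
#' @param roi_ids ROI labels to use (default: all labels present).
#' @param background_mask optional logical matrix marking the background
#'   region (must be disjoint from ROIs).
#' @param fly,condition metadata labels.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(mask, roi_ids = NULL, background_mask = NULL,
                    fly = "fly1", condition = "control") {
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  present <- sort(unique(mask[mask > 0]))
  if (is.null(roi_ids)) roi_ids <- present
  if (!length(roi_ids)) stop("mask contains no ROI labels", call. = FALSE)
  missing <- setdiff(roi_ids, present)
  if (length(missing)) {
    stop("ROI id(s) absent from mask: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(background_mask)) {
    background_mask <- mask == 0L
  } else if (any(background_mask & mask > 0)) {
    stop("background region overlaps ROIs", call. = FALSE)
  }
  structure(list(mask = mask, roi_ids = roi_ids,
                 background_mask = background_mask,
                 fly = fly, condition = condition),
            class = "roi_set")
}

#' Raw ROI trace container
#'
#' Background-subtracted mean fluorescence per ROI at native frame times.
#'
#' @param times frame timestamps, seconds.
#' @param traces numeric matrix, frames x ROIs.
#' @param roi_ids column labels.
#' @param background background-region trace (already subtracted from
#'   `traces`; kept for reference).
#' @param fly,condition metadata.
#' @param protocol the `stimulus_protocol` the recording was synchronized to.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(times, traces, roi_ids, background = NULL,
                      fly = "fly1", condition = "control", protocol = NULL) {
  traces <- as.matrix(traces)
  stopifnot(nrow(traces) == length(times))
  colnames(traces) <- as.character(roi_ids)
  structure(list(times = times, traces = traces,
                 roi_ids = as.character(roi_ids),
                 background = background, fly = fly, condition = condition,
                 protocol = protocol),
            class = "trace_set")
}

#' Extract background-subtracted ROI traces from a movie
#'
#' Per frame, each ROI's value is the mean intensity over its pixels minus
#' the mean over the background region.
#'
#' @param movie a `ca_movie`.
#' @param rois a [roi_set()] whose mask matches the frame size.
#' @param protocol optional `stimulus_protocol` to attach.
#' @return a [trace_set()].
#' @export
extract_traces <- function(movie, rois, protocol = NULL) {
  stopifnot(inherits(movie, "ca_movie"), inherits(rois, "roi_set"))
  d <- dim(movie$frames)
  if (!all(dim(rois$mask) == d[1:2])) {
    stop("mask shape does not match movie frames", call. = FALSE)
  }
  flat <- matrix(movie$frames, d[1] * d[2], d[3])
  bg_idx <- which(rois$background_mask)
  if (!length(bg_idx)) {
    warning("empty background region: no background subtraction",
            call. = FALSE)
    bg <- rep(0, d[3])
  } else {
    bg <- colMeans(flat[bg_idx, , drop = FALSE])
  }
  tr <- vapply(rois$roi_ids, function(id) {
    idx <- which(rois$mask == id)
    colMeans(flat[idx, , drop = FALSE]) - bg
  }, numeric(d[3]))
  trace_set(movie$times, tr, rois$roi_ids, background = bg,
            fly = rois$fly, condition = rois$condition, protocol = protocol)
}

#' Resample traces onto a stimulus-locked grid and cut into epoch segments
#'
#' Each trace is linearly interpolated onto a grid with spacing
#' `1 / rate_hz` whose phase is locked to each epoch onset (t = 0 at onset),
#' one segment per epoch instance, with up to `pre_s` seconds of pre-onset
#' context when the recording covers it. Epoch samples run from 0 to
#' `duration - 1/rate_hz` (50 samples for a 5 s epoch at 10 Hz).
#'
#' @param traces a [trace_set()].
#' @param protocol a `stimulus_protocol` (defaults to the one attached to
#'   `traces`).
#' @param rate_hz resampling rate, Hz (default 10).
#' @param pre_s pre-onset context window, seconds (default 2).
#' @param include_gray keep gray epochs as segments (default FALSE).
#' @return list of segments (class `epoch_segments`); each segment holds
#'   `t_rel`, a `values` matrix (grid x ROIs), the epoch descriptors and the
#'   onset time. Epochs extending past the recording are dropped with a
#'   warning.
#' @export
resample_and_segment <- function(traces, protocol = NULL, rate_hz = 10,
                                 pre_s = 2, include_gray = FALSE) {
  stopifnot(inherits(traces, "trace_set"))
  if (is.null(protocol)) protocol <- traces$protocol
  stopifnot(inherits(protocol, "stimulus_protocol"))
  ep <- protocol_epoch_times(protocol)
  if (!include_gray) ep <- ep[ep$kind != "gray", , drop = FALSE]
  dt <- 1 / rate_hz
  t0 <- min(traces$times); t1 <- max(traces$times)
  segs <- list()
  for (i in seq_len(nrow(ep))) {
    n_ep <- round(ep$duration_s[i] * rate_hz)
    pre_grid <- if (pre_s >= dt) seq(-round(pre_s * rate_hz) * dt, -dt,
                                     by = dt) else numeric(0)
    t_rel <- c(pre_grid, seq(0, by = dt, length.out = n_ep))
    t_abs <- ep$onset_s[i] + t_rel
    keep_pre <- t_rel < 0 & t_abs >= t0
    keep_ep <- t_rel >= 0
    if (any(t_abs[keep_ep] > t1 + 1e-9)) {
      warning("epoch ", ep$epoch_index[i],
              " extends past the recording: segment dropped", call. = FALSE)
      next
    }
    t_rel <- t_rel[keep_pre | keep_ep]
    t_abs <- ep$onset_s[i] + t_rel
    vals <- apply(traces$traces, 2, function(f) {
      stats::approx(traces$times, f, xout = t_abs, rule = 2)$y
    })
    vals <- matrix(vals, nrow = length(t_abs),
                   dimnames = list(NULL, traces$roi_ids))
    segs[[length(segs) + 1]] <- list(
      t_rel = t_rel, values = vals, kind = ep$kind[i],
      contrast = ep$contrast[i], direction_deg = ep$direction_deg[i],
      epoch_index = ep$epoch_index[i], onset_s = ep$onset_s[i])
  }
  structure(list(segments = segs, rate_hz = rate_hz, pre_s = pre_s,
                 roi_ids = traces$roi_ids, fly = traces$fly,
                 condition = traces$condition, protocol = protocol),
            class = "epoch_segments")
}

.segment_group_key <- function(seg) {
  if (seg$kind == "edge") {
    sprintf("edge|%g|%g", seg$direction_deg, seg$contrast)
  } else {
    seg$kind
  }
}

#' Trial-average epoch segments
#'
#' Pointwise mean over trials of the same epoch kind (flashes) or the same
#' direction x contrast (edges). Segments are aligned on their relative time
#' grid; only time points present in every trial of a group are kept (the
#' first trial may lack part of the pre-onset context).
#'
#' @param segments an `epoch_segments` object (raw F or dF/F values).
#' @return list of class `avg_traces`: one element per group with `t_rel`,
#'   `values` (grid x ROIs), epoch descriptors and `n_trials`.
#' @export
trial_average <- function(segments) {
  stopifnot(inherits(segments, "epoch_segments"))
  if (!length(segments$segments)) stop("no segments to average", call. = FALSE)
  keys <- vapply(segments$segments, .segment_group_key, character(1))
  groups <- split(segments$segments, keys)
  out <- lapply(groups, function(gr) {
    t_common <- Reduce(intersect, lapply(gr, function(s) round(s$t_rel * 1e6)))
    t_common <- sort(t_common)
    mats <- lapply(gr, function(s) {
      s$values[match(t_common, round(s$t_rel * 1e6)), , drop = FALSE]
    })
    list(t_rel = t_common / 1e6,
         values = Reduce(`+`, mats) / length(mats),
         kind = gr[[1]]$kind, contrast = gr[[1]]$contrast,
         direction_deg = gr[[1]]$direction_deg, n_trials = length(gr))
  })
  structure(list(groups = out, rate_hz = segments$rate_hz,
                 roi_ids = segments$roi_ids, fly = segments$fly,
                 condition = segments$condition,
                 protocol = segments$protocol),
            class = "avg_traces")
}

#' Compute dF/F0 traces
#'
#' Converts background-subtracted fluorescence into relative changes
#' `(F - F0) / F0` under one of the two baseline conventions used for this
#' kind of data:
#' \describe{
#'   \item{`whole_trace_mean`}{F0 is the mean of the whole native trace,
#'     computed before segmentation (the flash convention). The resulting
#'     dF/F has zero mean over the recording by construction.}
#'   \item{`gray_last_second`}{F0 is the mean of the native samples in the
#'     last second of the gray epoch preceding each stimulus epoch (the
#'     moving-edge convention); requires interleaved gray epochs.}
#' }
#' ROIs whose F0 is not positive are excluded with a warning (their dF/F
#' would be unbounded or sign-flipped).
#'
#' @param traces a [trace_set()] of background-subtracted fluorescence.
#' @param protocol a `stimulus_protocol` (defaults to the attached one).
#' @param f0_mode `"whole_trace_mean"` or `"gray_last_second"`.
#' @param rate_hz stimulus-locked grid rate, Hz.
#' @param pre_s pre-onset context, seconds.
#' @return An object of class `dff_trace_set`: per-epoch-instance dF/F
#'   segments (`segments`), trial-averaged traces (`avg`), the F0 values,
#'   the mode, surviving `roi_ids` and any `excluded_rois`.
#' @export
compute_dff <- function(traces, protocol = NULL,
                        f0_mode = c("whole_trace_mean", "gray_last_second"),
                        rate_hz = 10, pre_s = 2) {
  stopifnot(inherits(traces, "trace_set"))
  f0_mode <- match.arg(f0_mode)
  if (is.null(protocol)) protocol <- traces$protocol
  stopifnot(inherits(protocol, "stimulus_protocol"))

  if (f0_mode == "whole_trace_mean") {
    f0 <- colMeans(traces$traces)
    bad <- which(!is.finite(f0) | f0 <= 0)
    if (length(bad)) {
      warning("excluding ROI(s) with nonpositive F0: ",
              paste(traces$roi_ids[bad], collapse = ", "), call. = FALSE)
    }
    keep <- setdiff(seq_along(f0), bad)
    if (!length(keep)) stop("no ROI with positive F0", call. = FALSE)
    dffm <- sweep(sweep(traces$traces[, keep, drop = FALSE], 2, f0[keep]),
                  2, f0[keep], "/")
    dff_native <- trace_set(traces$times, dffm, traces$roi_ids[keep],
                            fly = traces$fly, condition = traces$condition,
                            protocol = protocol)
    segs <- resample_and_segment(dff_native, protocol, rate_hz, pre_s)
    avg <- trial_average(segs)
    f0_out <- f0[keep]
    excluded <- traces$roi_ids[bad]
  } else {
    ep <- protocol_epoch_times(protocol)
    if (!any(ep$kind == "gray")) {
      stop("gray_last_second mode needs gray epochs in the protocol",
           call. = FALSE)
    }
    segs_raw <- resample_and_segment(traces, protocol, rate_hz, pre_s)
    # per stimulus epoch, F0 = mean native F over the last 1 s of the
    # preceding gray epoch
    f0_mat <- matrix(NA_real_, length(segs_raw$segments),
                     length(traces$roi_ids))
    for (i in seq_along(segs_raw$segments)) {
      s <- segs_raw$segments[[i]]
      gray_before <- ep[ep$kind == "gray" & ep$offset_s <= s$onset_s + 1e-9, ,
                        drop = FALSE]
      if (!nrow(gray_before)) {
        stop("no gray epoch precedes epoch ", s$epoch_index, call. = FALSE)
      }
      g_end <- max(gray_before$offset_s)
      idx <- traces$times >= g_end - 1 & traces$times < g_end
      f0_mat[i, ] <- colMeans(traces$traces[idx, , drop = FALSE])
    }
    bad <- which(apply(f0_mat, 2, function(v) any(!is.finite(v) | v <= 0)))
    if (length(bad)) {
      warning("excluding ROI(s) with nonpositive F0: ",
              paste(traces$roi_ids[bad], collapse = ", "), call. = FALSE)
    }
    keep <- setdiff(seq_along(traces$roi_ids), bad)
    if (!length(keep)) stop("no ROI with positive F0", call. = FALSE)
    for (i in seq_along(segs_raw$segments)) {
      s <- segs_raw$segments[[i]]
      v <- s$values[, keep, drop = FALSE]
      v <- sweep(sweep(v, 2, f0_mat[i, keep]), 2, f0_mat[i, keep], "/")
      segs_raw$segments[[i]]$values <- v
    }
    segs_raw$roi_ids <- traces$roi_ids[keep]
    segs <- segs_raw
    avg <- trial_average(segs)
    f0_out <- f0_mat[, keep, drop = FALSE]
    excluded <- traces$roi_ids[bad]
  }

  structure(list(segments = segs, avg = avg, f0 = f0_out, f0_mode = f0_mode,
                 rate_hz = rate_hz, roi_ids = segs$roi_ids,
                 excluded_rois = excluded, fly = traces$fly,
                 condition = traces$condition, protocol = protocol),
            class = "dff_trace_set")
}

#' Tidy export of trial-averaged dF/F traces
#'
#' @param dff a `dff_trace_set`.
#' @return data.frame with columns roi, fly, condition, epoch, t, value.
#' @export
dff_as_data_frame <- function(dff) {
  stopifnot(inherits(dff, "dff_trace_set"))
  rows <- lapply(names(dff$avg$groups), function(key) {
    g <- dff$avg$groups[[key]]
    do.call(rbind, lapply(dff$roi_ids, function(id) {
      data.frame(roi = id, fly = dff$fly, condition = dff$condition,
                 epoch = key, t = g$t_rel, value = g$values[, id],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
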