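#' Stimulus protocols
#'
#' A `stimulus_protocol` is an ordered table of stimulus epochs together with
#' the trial structure and display geometry. Epoch kinds are `"flash_on"`,
#' `"flash_off"`, `"gray"` and `"edge"`; contrasts are Weber fractions in
#' \[-1, 1\]; edge epochs carry a motion direction in degrees.
#'
#' @param epochs data.frame with columns `kind`, `contrast`, `direction_deg`
#'   (NA for non-edge epochs) and `duration_s`.
#' @param n_trials number of trials (repetitions of the basic epoch cycle).
#' @param display_rate_hz refresh rate of the display, Hz.
#' @param field_span_deg visual angle spanned by the display, degrees
#'   (azimuth = elevation).
#' @param edge_speed_dps edge speed in deg/s, `NA` for flash protocols.
#' @return An object of class `stimulus_protocol`.
#' @export
new_stimulus_protocol <- function(epochs, n_trials, display_rate_hz = 100,
                                  field_span_deg = 60, edge_speed_dps = NA_real_) {
  stopifnot(is.data.frame(epochs),
            all(c("kind", "contrast", "direction_deg", "duration_s") %in% names(epochs)))
  if (any(epochs$duration_s <= 0)) {
    stop("all epoch durations must be > 0", call. = FALSE)
  }
  if (any(epochs$kind == "edge" & is.na(epochs$direction_deg))) {
    stop("every edge epoch needs a direction", call. = FALSE)
  }
  structure(
    list(epochs = epochs, n_trials = n_trials,
         display_rate_hz = display_rate_hz, field_span_deg = field_span_deg,
         edge_speed_dps = edge_speed_dps),
    class = "stimulus_protocol"
  )
}

#' Build an alternating full-field flash protocol
#'
#' Alternating full-contrast ON and OFF full-field flashes of equal duration,
#' the stimulus used to probe ON/OFF polarity of medulla interneurons. An
#' optional leading gray epoch provides a pre-stimulus baseline window.
#'
#' @param n_trials number of ON/OFF trial pairs (>= 1); ~7 in typical
#'   recordings.
#' @param epoch_s duration of each flash epoch in seconds (default 5).
#' @param pre_gray_s duration of a leading gray epoch in seconds (0 = none).
#'   A baseline of at least 2 s is needed by the pre-stimulus noise filter.
#' @param field_span_deg display span in degrees.
#' @return A `stimulus_protocol` with `2 * n_trials` flash epochs (plus the
#'   optional gray epoch), total stimulus duration `2 * n_trials * epoch_s`.
#' @examples
#' p <- build_flash_protocol(7, 5)
#' nrow(p$epochs)          # 14
#' sum(p$epochs$duration_s) # 70
#' @export
build_flash_protocol <- function(n_trials, epoch_s = 5, pre_gray_s = 0,
                                 field_span_deg = 60) {
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 1 ||
      n_trials != round(n_trials)) {
    stop("n_trials must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(epoch_s) || length(epoch_s) != 1 || epoch_s <= 0) {
    stop("epoch_s must be > 0", call. = FALSE)
  }
  if (pre_gray_s < 0) stop("pre_gray_s must be >= 0", call. = FALSE)
  kinds <- rep(c("flash_on", "flash_off"), n_trials)
  epochs <- data.frame(
    kind = kinds,
    contrast = ifelse(kinds == "flash_on", 1, -1),
    direction_deg = NA_real_,
    duration_s = epoch_s,
    stringsAsFactors = FALSE
  )
  if (pre_gray_s > 0) {
    epochs <- rbind(
      data.frame(kind = "gray", contrast = 0, direction_deg = NA_real_,
                 duration_s = pre_gray_s, stringsAsFactors = FALSE),
      epochs
    )
  }
  new_stimulus_protocol(epochs, n_trials = n_trials,
                        field_span_deg = field_span_deg)
}

#' Build a moving-edge protocol
#'
#' Full-contrast bright and dark edges moving at a fixed speed in the eight
#' cardinal/oblique directions (0, 45, ..., 315 degrees), each combination
#' repeated `reps` times in seeded random order, with gray epochs interleaved
#' so a baseline precedes every edge. Each edge epoch lasts exactly
#' `field_span_deg / speed_dps` seconds (the time the edge needs to cross the
#' display).
#'
#' @param speed_dps edge speed, deg/s (> 0); 20 deg/s in typical recordings.
#' @param reps repetitions per direction x contrast (>= 1; at least 3 in
#'   typical recordings).
#' @param gray_s duration of each interleaved gray epoch, seconds (>= 1 so a
#'   "last second of gray" baseline exists).
#' @param field_span_deg display span in degrees.
#' @param seed integer seed for the epoch-order randomization; stored in the
#'   protocol so the analysis can re-synchronize.
#' @return A `stimulus_protocol` with `2 * 8 * reps` edge epochs, each
#'   preceded by a gray epoch.
#' @examples
#' p <- build_edge_protocol(20, reps = 3, gray_s = 2)
#' sum(p$epochs$kind == "edge")                    # 48
#' unique(p$epochs$duration_s[p$epochs$kind == "edge"])  # 3
#' @export
build_edge_protocol <- function(speed_dps = 20, reps = 3, gray_s = 2,
                                field_span_deg = 60, seed = 1L) {
  if (!is.numeric(speed_dps) || speed_dps <= 0) {
    stop("speed_dps must be > 0", call. = FALSE)
  }
  if (!is.numeric(reps) || length(reps) != 1 || reps < 1 || reps != round(reps)) {
    stop("reps must be a positive integer", call. = FALSE)
  }
  if (gray_s < 1) stop("gray_s must be >= 1 s (baseline window)", call. = FALSE)
  edge_s <- field_span_deg / speed_dps
  design <- expand.grid(direction_deg = seq(0, 315, by = 45),
                        contrast = c(1, -1), rep = seq_len(reps))
  # seeded randomization without touching the caller's RNG stream
  old <- .Random.seed_exists()
  set.seed(seed)
  perm <- sample.int(nrow(design))
  .restore_seed(old)
  design <- design[perm, , drop = FALSE]

  gray <- data.frame(kind = "gray", contrast = 0, direction_deg = NA_real_,
                     duration_s = gray_s, stringsAsFactors = FALSE)
  blocks <- lapply(seq_len(nrow(design)), function(i) {
    rbind(gray,
          data.frame(kind = "edge", contrast = design$contrast[i],
                     direction_deg = design$direction_deg[i],
                     duration_s = edge_s, stringsAsFactors = FALSE))
  })
  epochs <- do.call(rbind, blocks)
  rownames(epochs) <- NULL
  p <- new_stimulus_protocol(epochs, n_trials = reps,
                             field_span_deg = field_span_deg,
                             edge_speed_dps = speed_dps)
  p$seed <- seed
  p
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Epoch onset/offset times of a protocol
#'
#' @param protocol a `stimulus_protocol`.
#' @return data.frame with one row per epoch: `kind`, `contrast`,
#'   `direction_deg`, `duration_s`, `onset_s`, `offset_s`, `epoch_index`.
#' @export
protocol_epoch_times <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  ep <- protocol$epochs
  off <- cumsum(ep$duration_s)
  ep$onset_s <- off - ep$duration_s
  ep$offset_s <- off
  ep$epoch_index <- seq_len(nrow(ep))
  ep
}

#' Total duration of a protocol in seconds
#' @param protocol a `stimulus_protocol`.
#' @export
protocol_duration <- function(protocol) {
  sum(protocol$epochs$duration_s)
}

#' Write / read a stimulus protocol as JSON
#'
#' @param protocol a `stimulus_protocol`.
#' @param path file path.
#' @return `read_protocol_json` returns a `stimulus_protocol`.
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$epochs$direction_deg <- as.numeric(x$epochs$direction_deg)
  p <- new_stimulus_protocol(x$epochs, n_trials = x$n_trials,
                             display_rate_hz = x$display_rate_hz,
                             field_span_deg = x$field_span_deg,
                             edge_speed_dps = if (is.null(x$edge_speed_dps))
                               NA_real_ else as.numeric(x$edge_speed_dps))
  if (!is.null(x$seed)) p$seed <- x$seed
  p
}
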