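#' Construct a calcium movie object
#'
#' @param frames numeric array, height x width x frames, fluorescence units.
#' @param times numeric frame timestamps in seconds (length = n frames).
#' @return An object of class `ca_movie`.
#' @export
ca_movie <- function(frames, times) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == length(times))
  structure(list(frames = frames, times = times), class = "ca_movie")
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ca_movie> %d x %d px, %d frames, %.2f-%.2f s\n",
              d[1], d[2], d[3], min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a `ca_movie`.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

.disc_pixels <- function(center, radius, h, w, clip = TRUE) {
  r0 <- round(center[1]); c0 <- round(center[2])
  rr <- seq(floor(r0 - radius), ceiling(r0 + radius))
  cc <- seq(floor(c0 - radius), ceiling(c0 + radius))
  g <- expand.grid(row = rr, col = cc)
  g <- g[(g$row - r0)^2 + (g$col - c0)^2 <= radius^2, , drop = FALSE]
  if (clip) g <- g[g$row >= 1 & g$row <= h & g$col >= 1 & g$col <= w, , drop = FALSE]
  g
}

.reflect_walk <- function(steps, bound) {
  # integer random walk reflected at +/- bound
  s <- numeric(length(steps) + 1)
  for (i in seq_along(steps)) {
    x <- s[i] + steps[i]
    if (abs(x) > bound) x <- sign(x) * (2 * bound - abs(x))
    s[i + 1] <- x
  }
  s[-1]
}

#' Render a synthetic two-photon movie with ground truth
#'
#' Rasterizes each cell as a disc of intensity
#' `f_baseline * (1 + dF/F(t))` on a uniform background, applies an
#' integer-pixel random-walk translation per frame (reflected at
#' `max_shift_px`, modelling bounded brain motion), Poisson photon noise at
#' `photon_gain` expected counts per fluorescence unit, and additive Gaussian
#' read noise. Identical `config` (including its seed) gives a bit-identical
#' movie.
#'
#' @param cells list of [cell_spec()] objects; discs must lie inside the
#'   frame at their rest position (overlaps are summed with a warning).
#' @param protocol a `stimulus_protocol`.
#' @param drug a `drug_condition`.
#' @param config a [movie_config()].
#' @param per_component logical, per-component receptor model (see
#'   [drug_gains()]).
#' @return list with elements `movie` (a `ca_movie`), `rois` (a [roi_set()]
#'   label mask at rest positions, background = all unlabeled pixels) and
#'   `truth` (per-frame true shifts, per-cell ideal dF/F at frame times, and
#'   the cell specs).
#' @export
render_movie <- function(cells, protocol, drug = drug_condition(),
                         config = movie_config(), per_component = FALSE) {
  stopifnot(inherits(config, "movie_config"))
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  h <- config$height_px; w <- config$width_px
  nt <- floor(protocol_duration(protocol) * config$frame_rate_hz)
  times <- (seq_len(nt) - 1) / config$frame_rate_hz

  # rest-position discs; reject cells leaving the frame, warn on overlap
  discs <- lapply(cells, function(cl) {
    d <- .disc_pixels(cl$center_px, cl$radius_px, h, w, clip = FALSE)
    if (any(d$row < 1 | d$row > h | d$col < 1 | d$col > w)) {
      stop("cell ", cl$id, " extends outside the frame", call. = FALSE)
    }
    d
  })
  lin <- unlist(lapply(discs, function(d) (d$col - 1) * h + d$row))
  if (anyDuplicated(lin)) {
    warning("overlapping cells: intensities are summed", call. = FALSE)
  }

  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.restore_seed(old), add = TRUE)

  if (config$motion_walk_sd > 0) {
    dy <- .reflect_walk(round(stats::rnorm(nt, 0, config$motion_walk_sd)),
                        config$max_shift_px)
    dx <- .reflect_walk(round(stats::rnorm(nt, 0, config$motion_walk_sd)),
                        config$max_shift_px)
    dy[1] <- 0; dx[1] <- 0
  } else {
    dy <- dx <- rep(0, nt)
  }

  ideal <- t(vapply(cells, function(cl) {
    ideal_response(cl, protocol, drug, times, per_component = per_component)
  }, numeric(nt)))

  frames <- array(config$background_level, dim = c(h, w, nt))
  for (k in seq_len(nt)) {
    fr <- frames[, , k]
    for (j in seq_along(cells)) {
      d <- discs[[j]]
      rows <- d$row + dy[k]; cols <- d$col + dx[k]
      keep <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
      if (!any(keep)) next
      idx <- cbind(rows[keep], cols[keep])
      fr[idx] <- fr[idx] + cells[[j]]$f_baseline * (1 + ideal[j, k])
    }
    if (config$photon_gain > 0) {
      fr <- stats::rpois(length(fr), config$photon_gain * pmax(fr, 0)) /
        config$photon_gain
      dim(fr) <- c(h, w)
      if (config$read_noise_sd > 0) {
        fr <- fr + stats::rnorm(length(fr), 0, config$read_noise_sd) /
          config$photon_gain
      }
    } else if (config$read_noise_sd > 0) {
      fr <- fr + stats::rnorm(length(fr), 0, config$read_noise_sd)
    }
    frames[, , k] <- fr
  }

  mask <- matrix(0L, h, w)
  for (j in seq_along(cells)) {
    mask[cbind(discs[[j]]$row, discs[[j]]$col)] <- j
  }
  rois <- roi_set(mask, roi_ids = seq_along(cells),
                  fly = "sim", condition = drug$name)

  list(
    movie = ca_movie(frames, times),
    rois = rois,
    truth = list(shifts = cbind(dy = dy, dx = dx), ideal_dff = ideal,
                 times = times, cells = cells, drug = drug,
                 per_component = per_component)
  )
}

#' Simulate background-subtracted ROI traces directly
#'
#' Lightweight alternative to full movie rendering for population-scale
#' simulations: evaluates each cell's ideal response at native frame times,
#' scales by its baseline fluorescence and adds white Gaussian noise, giving
#' the background-subtracted [trace_set()] that [extract_traces()] would
#' produce from a rendered movie of the same cells.
#'
#' @param cells list of [cell_spec()].
#' @param protocol a `stimulus_protocol`.
#' @param drug a `drug_condition`.
#' @param frame_rate_hz native acquisition rate, Hz.
#' @param noise_sd Gaussian noise s.d. in dF/F units (scaled by each cell's
#'   baseline), per native sample.
#' @param fly,condition metadata labels.
#' @param seed RNG seed.
#' @param per_component logical, per-component receptor model.
#' @return a [trace_set()] plus attribute `ideal_dff` (cells x time matrix).
#' @export
simulate_traces <- function(cells, protocol, drug = drug_condition(),
                            frame_rate_hz = 12, noise_sd = 0,
                            fly = "fly1", condition = drug$name,
                            seed = 1L, per_component = FALSE) {
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  nt <- floor(protocol_duration(protocol) * frame_rate_hz)
  times <- (seq_len(nt) - 1) / frame_rate_hz
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  ideal <- t(vapply(cells, function(cl) {
    ideal_response(cl, protocol, drug, times, per_component = per_component)
  }, numeric(nt)))
  traces <- vapply(seq_along(cells), function(j) {
    f <- cells[[j]]$f_baseline
    f * (1 + ideal[j, ]) +
      if (noise_sd > 0) stats::rnorm(nt, 0, noise_sd * f) else 0
  }, numeric(nt))
  ts <- trace_set(times = times, traces = traces,
                  roi_ids = vapply(cells, function(cl) as.character(cl$id),
                                   character(1)),
                  background = rep(0, nt), fly = fly, condition = condition,
                  protocol = protocol)
  attr(ts, "ideal_dff") <- ideal
  ts
}
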