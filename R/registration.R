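#' Build a registration reference image
#'
#' Pixel-wise maximum-intensity projection of the first `n_frames` frames.
#'
#' @param movie a `ca_movie`.
#' @param n_frames number of leading frames to project (default 30). If the
#'   movie is shorter, all frames are used with a warning.
#' @return numeric matrix (height x width).
#' @export
make_reference <- function(movie, n_frames = 30) {
  stopifnot(inherits(movie, "ca_movie"))
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  nt <- n_frames(movie)
  if (nt < n_frames) {
    warning("movie has only ", nt, " frames; using all of them",
            call. = FALSE)
    n_frames <- nt
  }
  apply(movie$frames[, , seq_len(n_frames), drop = FALSE], c(1, 2), max)
}

.shift_image <- function(img, dy, dx, fill) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

# integral image with a leading zero row/col so rectangle sums are O(1)
.integral <- function(m) {
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed double cumsum
  ii <- t(ii)
  rbind(0, cbind(0, ii))
}

.rect_sum <- function(ii, r1, r2, c1, c2) {
  ii[r2 + 1, c2 + 1] - ii[r1, c2 + 1] - ii[r2 + 1, c1] + ii[r1, c1]
}

# reference NCC search by direct correlation of the overlap; used as the
# oracle for the FFT implementation in tests
.estimate_shift_naive <- function(frame, reference, r) {
  h <- nrow(frame); w <- ncol(frame)
  best <- c(0L, 0L); best_cc <- -Inf; best_norm <- Inf
  for (dy in -r:r) {
    fr_r <- max(1, 1 + dy):min(h, h + dy)
    rf_r <- fr_r - dy
    for (dx in -r:r) {
      fr_c <- max(1, 1 + dx):min(w, w + dx)
      rf_c <- fr_c - dx
      a <- frame[fr_r, fr_c]; b <- reference[rf_r, rf_c]
      cc <- if (stats::sd(a) == 0 || stats::sd(b) == 0) -Inf
            else stats::cor(c(a), c(b))
      nrm <- dy * dy + dx * dx
      if (cc > best_cc + 1e-9 ||
          (cc > best_cc - 1e-9 && nrm < best_norm)) {
        best <- c(dy, dx); best_cc <- cc; best_norm <- nrm
      }
    }
  }
  c(dy = as.integer(best[1]), dx = as.integer(best[2]))
}

#' Estimate the rigid integer translation of a frame
#'
#' Exhaustive search over integer shifts within `search_radius_px`,
#' maximizing the normalized cross-correlation (Pearson correlation of the
#' overlapping regions; cross-terms via FFT, means and variances via
#' integral images, so the search is exact but fast). Ties are broken toward
#' the smallest Euclidean shift norm, then row-major order.
#'
#' @param frame,reference numeric matrices of identical shape.
#' @param search_radius_px maximum |dy|, |dx| searched.
#' @return integer vector `c(dy, dx)` such that the frame content equals the
#'   reference translated by `(dy, dx)`; correction applies the negation.
#'   Zero-variance inputs return `c(0, 0)` with a warning.
#' @export
estimate_shift <- function(frame, reference, search_radius_px = 10) {
  stopifnot(all(dim(frame) == dim(reference)))
  if (search_radius_px < 0) stop("search_radius_px must be >= 0", call. = FALSE)
  if (stats::sd(frame) == 0 || stats::sd(reference) == 0) {
    warning("zero-variance frame or reference: shift (0, 0)", call. = FALSE)
    return(c(dy = 0L, dx = 0L))
  }
  r <- as.integer(search_radius_px)
  if (r == 0) return(c(dy = 0L, dx = 0L))
  h <- nrow(frame); w <- ncol(frame)
  p1 <- h + r; p2 <- w + r
  fp <- matrix(0, p1, p2); fp[1:h, 1:w] <- frame
  rp <- matrix(0, p1, p2); rp[1:h, 1:w] <- reference
  cross <- Re(stats::fft(stats::fft(fp) * Conj(stats::fft(rp)),
                         inverse = TRUE)) / (p1 * p2)
  ia <- .integral(frame); ia2 <- .integral(frame^2)
  ib <- .integral(reference); ib2 <- .integral(reference^2)
  best <- c(0L, 0L); best_cc <- -Inf; best_norm <- Inf
  for (dy in -r:r) {
    r1 <- max(1, 1 + dy); r2 <- min(h, h + dy)
    for (dx in -r:r) {
      c1 <- max(1, 1 + dx); c2 <- min(w, w + dx)
      n <- (r2 - r1 + 1) * (c2 - c1 + 1)
      sab <- cross[1 + (dy %% p1), 1 + (dx %% p2)]
      sa <- .rect_sum(ia, r1, r2, c1, c2)
      sa2 <- .rect_sum(ia2, r1, r2, c1, c2)
      sb <- .rect_sum(ib, r1 - dy, r2 - dy, c1 - dx, c2 - dx)
      sb2 <- .rect_sum(ib2, r1 - dy, r2 - dy, c1 - dx, c2 - dx)
      va <- sa2 - sa^2 / n; vb <- sb2 - sb^2 / n
      cc <- if (va <= 1e-12 || vb <= 1e-12) -Inf
            else (sab - sa * sb / n) / sqrt(va * vb)
      nrm <- dy * dy + dx * dx
      if (cc > best_cc + 1e-9 ||
          (cc > best_cc - 1e-9 && nrm < best_norm)) {
        best <- c(dy, dx); best_cc <- cc; best_norm <- nrm
      }
    }
  }
  c(dy = as.integer(best[1]), dx = as.integer(best[2]))
}

#' Rigid motion correction of a movie
#'
#' Aligns every frame to a maximum-projection reference of the first
#' `n_ref_frames` frames by integer-pixel translation: each frame is shifted
#' by the negated estimated shift, border pixels filled with the frame
#' median. Timestamps are unchanged; interior pixel values are moved, never
#' altered.
#'
#' With `prealign_reference = TRUE` (default) the reference frames are first
#' registered to frame 1 before projecting, so the template stays sharp and
#' anchored at the frame-1 position even when the movie moves during the
#' reference window; a max projection over unaligned moving frames would
#' smear the template and bias every shift estimate by the smear's offset.
#'
#' @param movie a `ca_movie`.
#' @param n_ref_frames frames in the reference projection (default 30).
#' @param search_radius_px shift search radius, pixels (default 10).
#' @param prealign_reference logical, see above.
#' @return list with `movie` (corrected `ca_movie`) and `shifts` (data.frame
#'   with per-frame `dy`, `dx`).
#' @export
register <- function(movie, n_ref_frames = 30, search_radius_px = 10,
                     prealign_reference = TRUE) {
  stopifnot(inherits(movie, "ca_movie"))
  nt <- n_frames(movie)
  n_ref <- min(n_ref_frames, nt)
  if (prealign_reference && search_radius_px > 0 && n_ref > 1) {
    ref0 <- movie$frames[, , 1]
    aligned <- array(0, dim = c(dim(ref0), n_ref))
    aligned[, , 1] <- ref0
    for (k in 2:n_ref) {
      fr <- movie$frames[, , k]
      s <- estimate_shift(fr, ref0, search_radius_px)
      aligned[, , k] <- if (any(s != 0)) {
        .shift_image(fr, -s[1], -s[2], fill = stats::median(fr))
      } else fr
    }
    ref <- apply(aligned, c(1, 2), max)
  } else {
    ref <- make_reference(movie, n_ref_frames)
  }
  shifts <- matrix(0L, nt, 2)
  frames <- movie$frames
  if (search_radius_px > 0) {
    for (k in seq_len(nt)) {
      s <- estimate_shift(frames[, , k], ref, search_radius_px)
      shifts[k, ] <- s
      if (any(s != 0)) {
        frames[, , k] <- .shift_image(frames[, , k], -s[1], -s[2],
                                      fill = stats::median(frames[, , k]))
      }
    }
  }
  list(movie = ca_movie(frames, movie$times),
       shifts = data.frame(frame = seq_len(nt), dy = shifts[, 1],
                           dx = shifts[, 2],
                           search_radius_px = search_radius_px))
}
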