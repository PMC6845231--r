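#' ROI inclusion policy
#'
#' The rule set applied to trial-averaged flash responses before
#' quantification: a stimulus-correlation rule (Pearson r with the contrast
#' square wave > 0), a pre-stimulus noise rule (s.d. of the 2 s window before
#' stimulation onset must not exceed `prestim_sd_threshold`), and a response
#' rule (peak |dF/F| must reach `abs_response_threshold`). Surviving ROIs are
#' the intersection of the enabled rules.
#'
#' @param use_correlation_filter logical.
#' @param prestim_sd_threshold dF/F units, or `NA` to disable.
#' @param abs_response_threshold dF/F units, or `NA` to disable.
#' @param paired logical: ROI identities are carried to a post-drug
#'   recording of the same cells.
#' @param name policy label.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(use_correlation_filter = TRUE,
                          prestim_sd_threshold = NA_real_,
                          abs_response_threshold = NA_real_,
                          paired = FALSE, name = "custom") {
  for (th in c(prestim_sd_threshold, abs_response_threshold)) {
    if (!is.na(th) && th < 0) stop("thresholds must be >= 0", call. = FALSE)
  }
  structure(list(use_correlation_filter = isTRUE(use_correlation_filter),
                 prestim_sd_threshold = prestim_sd_threshold,
                 abs_response_threshold = abs_response_threshold,
                 paired = isTRUE(paired), name = name),
            class = "filter_policy")
}

#' Named policy presets
#'
#' The four experiment-specific rule sets:
#' \describe{
#'   \item{`mi1_pharma`}{paired pharmacology in Mi1/Tm3: correlation rule,
#'     pre-stimulus s.d. 0.2, absolute response threshold 0.5.}
#'   \item{`unpaired`}{unpaired genotype comparisons: correlation and s.d.
#'     rules, no absolute threshold.}
#'   \item{`t4t5`}{single-ROI T4/T5 responses: no correlation rule (both
#'     response polarities are expected).}
#'   \item{`iglusnfr`}{glutamate-sensor recordings: absolute response
#'     threshold only.}
#' }
#'
#' @param name one of `"mi1_pharma"`, `"unpaired"`, `"t4t5"`, `"iglusnfr"`.
#' @return a [filter_policy()].
#' @export
policy_preset <- function(name = c("mi1_pharma", "unpaired", "t4t5",
                                   "iglusnfr")) {
  name <- match.arg(name)
  switch(name,
    mi1_pharma = filter_policy(TRUE, 0.2, 0.5, paired = TRUE,
                               name = "mi1_pharma"),
    unpaired   = filter_policy(TRUE, 0.2, NA_real_, name = "unpaired"),
    t4t5       = filter_policy(FALSE, 0.2, 0.5, name = "t4t5"),
    iglusnfr   = filter_policy(FALSE, NA_real_, 0.5, name = "iglusnfr")
  )
}

#' Contrast square-wave stimulus regressor
#'
#' The reference trace against which ROI responses are correlated: +1 during
#' ON flashes, -1 during OFF flashes, on the stimulus-locked grid. Only
#' defined for flash protocols.
#'
#' @param protocol a flash `stimulus_protocol`.
#' @param rate_hz grid rate, Hz.
#' @return numeric vector over the concatenated flash epochs, with
#'   attribute `kinds` giving the epoch kind of each sample.
#' @export
stimulus_regressor <- function(protocol, rate_hz = 10) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  ep <- protocol$epochs
  if (!nrow(ep)) stop("empty protocol", call. = FALSE)
  if (any(ep$kind == "edge")) {
    stop("stimulus regressor is defined for flash protocols only",
         call. = FALSE)
  }
  flash <- ep[ep$kind %in% c("flash_on", "flash_off"), , drop = FALSE]
  if (!nrow(flash)) stop("protocol contains no flash epochs", call. = FALSE)
  vals <- unlist(lapply(seq_len(nrow(flash)), function(i) {
    rep(ifelse(flash$kind[i] == "flash_on", 1, -1),
        round(flash$duration_s[i] * rate_hz))
  }))
  kinds <- unlist(lapply(seq_len(nrow(flash)), function(i) {
    rep(flash$kind[i], round(flash$duration_s[i] * rate_hz))
  }))
  attr(vals, "kinds") <- kinds
  vals
}

# trial-averaged trace of one ROI concatenated over flash epoch kinds,
# epoch samples only, in protocol order (on, off)
.avg_flash_concat <- function(dff, roi) {
  g <- dff$avg$groups
  kinds <- intersect(c("flash_on", "flash_off"), names(g))
  vals <- unlist(lapply(kinds, function(k) {
    s <- g[[k]]
    s$values[s$t_rel >= 0, roi]
  }))
  kind_lab <- unlist(lapply(kinds, function(k) {
    rep(k, sum(g[[k]]$t_rel >= 0))
  }))
  list(values = vals, kinds = kind_lab)
}

#' Apply an ROI inclusion policy
#'
#' Evaluates the enabled rules on a flash `dff_trace_set` and returns the
#' surviving subset plus a per-ROI report.
#'
#' Rules: (i) Pearson correlation between the trial-averaged dF/F
#' (concatenated ON + OFF epochs) and the contrast square wave must be > 0;
#' zero-variance traces fail with a warning. (ii) the s.d. of the 2 s
#' window before the onset of visual stimulation (pre-onset context of the
#' first stimulus epoch) must be <= `prestim_sd_threshold`. (iii) the peak
#' |dF/F| of the trial-averaged response must be >= `abs_response_threshold`.
#'
#' @param dff a `dff_trace_set` from a flash protocol.
#' @param policy a [filter_policy()].
#' @param protocol the protocol (defaults to the one attached to `dff`).
#' @return list with `dff` (filtered), `report` (data.frame: roi, pass per
#'   rule, pass overall) and `counts` (before/after).
#' @export
apply_policy <- function(dff, policy, protocol = NULL) {
  stopifnot(inherits(dff, "dff_trace_set"), inherits(policy, "filter_policy"))
  if (is.null(protocol)) protocol <- dff$protocol
  if (policy$use_correlation_filter &&
      any(protocol$epochs$kind == "edge")) {
    stop("correlation filter is undefined for edge protocols", call. = FALSE)
  }
  rois <- dff$roi_ids
  n <- length(rois)

  pass_corr <- rep(TRUE, n)
  if (policy$use_correlation_filter) {
    for (j in seq_len(n)) {
      tr <- .avg_flash_concat(dff, rois[j])
      reg <- ifelse(tr$kinds == "flash_on", 1, -1)
      if (stats::sd(tr$values) == 0) {
        warning("ROI ", rois[j],
                " has a zero-variance trace: fails correlation rule",
                call. = FALSE)
        pass_corr[j] <- FALSE
      } else {
        pass_corr[j] <- stats::cor(tr$values, reg) > 0
      }
    }
  }

  pass_sd <- rep(TRUE, n)
  if (!is.na(policy$prestim_sd_threshold)) {
    first_seg <- dff$segments$segments[[1]]
    pre_idx <- which(first_seg$t_rel < 0)
    if (length(pre_idx) < 2) {
      stop("pre-stimulus context required by the s.d. rule is missing",
           call. = FALSE)
    }
    for (j in seq_len(n)) {
      pre_sd <- stats::sd(first_seg$values[pre_idx, rois[j]])
      pass_sd[j] <- pre_sd <= policy$prestim_sd_threshold
    }
  }

  pass_abs <- rep(TRUE, n)
  if (!is.na(policy$abs_response_threshold)) {
    for (j in seq_len(n)) {
      tr <- .avg_flash_concat(dff, rois[j])
      pass_abs[j] <- max(abs(tr$values)) >= policy$abs_response_threshold
    }
  }

  keep <- pass_corr & pass_sd & pass_abs
  report <- data.frame(roi = rois, pass_correlation = pass_corr,
                       pass_prestim_sd = pass_sd, pass_abs = pass_abs,
                       pass = keep, stringsAsFactors = FALSE)
  list(dff = .subset_dff(dff, rois[keep]),
       report = report,
       counts = c(before = n, after = sum(keep)),
       policy = policy)
}

.subset_dff <- function(dff, keep_ids) {
  keep_ids <- as.character(keep_ids)
  dff$roi_ids <- keep_ids
  dff$segments$roi_ids <- keep_ids
  dff$segments$segments <- lapply(dff$segments$segments, function(s) {
    s$values <- s$values[, keep_ids, drop = FALSE]
    s
  })
  dff$avg$roi_ids <- keep_ids
  dff$avg$groups <- lapply(dff$avg$groups, function(g) {
    g$values <- g$values[, keep_ids, drop = FALSE]
    g
  })
  if (is.matrix(dff$f0)) {
    dff$f0 <- dff$f0[, keep_ids, drop = FALSE]
  } else {
    dff$f0 <- dff$f0[keep_ids]
  }
  dff
}

#' Pair ROIs across pre/post drug conditions
#'
#' The same cells are imaged before and after toxin application; inclusion
#' is decided on the pre-drug recording and the identical ROI ids are then
#' carried to the post-drug recording without re-applying the filters.
#'
#' @param pre,post `dff_trace_set`s sharing ROI ids (pre already filtered).
#' @return list with `pre` and `post` restricted to the common ROI ids.
#' @export
pair_rois <- function(pre, post) {
  stopifnot(inherits(pre, "dff_trace_set"), inherits(post, "dff_trace_set"))
  common <- intersect(pre$roi_ids, post$roi_ids)
  if (!length(common)) stop("no common ROI ids between conditions",
                            call. = FALSE)
  list(pre = .subset_dff(pre, common), post = .subset_dff(post, common))
}
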