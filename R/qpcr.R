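#' Default primer efficiencies
#'
#' Amplification efficiencies (fold per cycle, ~2 for perfect doubling)
#' measured from standard curves for the target (GluCla) and reference
#' (GAPDH2) primer pairs.
#'
#' @return named numeric vector.
#' @export
default_primer_efficiencies <- function() {
  c(GluCla = 1.91, GAPDH2 = 1.96)
}

#' Read a Ct table from CSV
#'
#' Expected columns: `sample`, `condition`, `gene`, `bio_rep`, `tech_rep`,
#' `ct` (threshold cycles, > 0).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("condition", "gene", "bio_rep", "tech_rep", "ct")
  if (!all(needed %in% names(x))) {
    stop("Ct table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$ct <= 0)) stop("Ct values must be > 0", call. = FALSE)
  x
}

#' Average technical replicates
#'
#' Arithmetic mean Ct over technical replicates for every
#' (condition, biological replicate, gene) cell; cells with a single reading
#' are kept with a low-replicate warning.
#'
#' @param ct_table data.frame with columns `condition`, `gene`, `bio_rep`,
#'   `ct` (and optionally `tech_rep`).
#' @return data.frame: condition, bio_rep, gene, ct (mean), n_tech.
#' @export
mean_ct <- function(ct_table) {
  needed <- c("condition", "gene", "bio_rep", "ct")
  if (!all(needed %in% names(ct_table))) {
    stop("Ct table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(ct_table$ct <= 0)) stop("Ct values must be > 0", call. = FALSE)
  agg <- aggregate(ct ~ condition + bio_rep + gene, data = ct_table,
                   FUN = mean)
  cnt <- aggregate(ct ~ condition + bio_rep + gene, data = ct_table,
                   FUN = length)
  agg$n_tech <- cnt$ct
  if (any(agg$n_tech < 2)) {
    warning("some (condition, replicate, gene) cells have a single reading",
            call. = FALSE)
  }
  agg[order(agg$condition, agg$bio_rep, agg$gene), ]
}

#' Percent transcript difference by the delta-delta-Ct method
#'
#' `100 * 2^((Ct_ND,target - Ct_ND,reference) - (Ct_D,target -
#' Ct_D,reference))`, i.e. the expression of the disrupted (D) condition as
#' a percentage of the non-disrupted (ND) control, assuming perfect doubling
#' per cycle. Computed per biological replicate of the D condition against
#' the mean delta-Ct of the ND condition, then summarized as mean +/- SEM.
#' With `efficiencies` given, the Pfaffl-style efficiency-corrected ratio
#' `E_target^dCt_target / E_reference^dCt_reference` is used instead;
#' setting both efficiencies to 2 reproduces the base-2 formula exactly.
#'
#' @param mean_cts output of [mean_ct()] (one mean Ct per condition x
#'   replicate x gene).
#' @param target,reference gene names.
#' @param condition_d,condition_nd condition labels of the disrupted and
#'   control genotype.
#' @param efficiencies optional numeric length-2 `c(target, reference)`
#'   amplification efficiencies.
#' @return list of class `ddct_result`: `per_rep` (percent per D
#'   biological replicate), `mean`, `sem`.
#' @export
ddct_percent <- function(mean_cts, target, reference,
                         condition_d = "D", condition_nd = "ND",
                         efficiencies = NULL) {
  pick <- function(cond, gene) {
    v <- mean_cts$ct[mean_cts$condition == cond & mean_cts$gene == gene]
    if (!length(v)) {
      stop("missing mean Ct for condition '", cond, "', gene '", gene, "'",
           call. = FALSE)
    }
    v
  }
  nd_t <- pick(condition_nd, target); nd_r <- pick(condition_nd, reference)
  d_t <- pick(condition_d, target);  d_r <- pick(condition_d, reference)
  if (length(d_t) != length(d_r)) {
    stop("unequal replicate counts for target and reference in condition '",
         condition_d, "'", call. = FALSE)
  }
  if (is.null(efficiencies)) {
    ddct <- (mean(nd_t) - mean(nd_r)) - (d_t - d_r)
    per_rep <- 100 * 2^ddct
  } else {
    if (length(efficiencies) != 2 || any(efficiencies <= 1)) {
      stop("efficiencies must be two values > 1 (target, reference)",
           call. = FALSE)
    }
    per_rep <- 100 * efficiencies[[1]]^(mean(nd_t) - d_t) /
      efficiencies[[2]]^(mean(nd_r) - d_r)
  }
  structure(list(per_rep = unname(per_rep), mean = mean(per_rep),
                 sem = if (length(per_rep) > 1)
                   stats::sd(per_rep) / sqrt(length(per_rep)) else NA_real_,
                 target = target, reference = reference,
                 condition_d = condition_d, condition_nd = condition_nd,
                 efficiency_corrected = !is.null(efficiencies)),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("%s vs %s (%s/%s): %.3g%% +/- %.3g SEM (n = %d)\n",
              x$condition_d, x$condition_nd, x$target, x$reference,
              x$mean, x$sem, length(x$per_rep)))
  invisible(x)
}

#' Normalize per-replicate values to a control group
#'
#' Every value is divided by the mean of the control group, so the control
#' mean maps to 1 (reported as 100%).
#'
#' @param values numeric per-replicate values.
#' @param groups group label per value.
#' @param control control group label.
#' @return numeric normalized values.
#' @export
normalize_to_control <- function(values, groups, control) {
  ctrl <- values[groups == control]
  if (!length(ctrl)) stop("control group '", control, "' is empty",
                          call. = FALSE)
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive",
                                    call. = FALSE)
  values / m
}

#' Primer efficiency from a dilution series
#'
#' Standard-curve estimate: Ct is regressed on log10 of the template
#' dilution; the efficiency is `10^(-1/slope)` (2 for perfect doubling).
#'
#' @param log10_dilution log10 relative template amounts.
#' @param ct measured Ct values.
#' @return scalar efficiency estimate.
#' @export
efficiency_from_dilution <- function(log10_dilution, ct) {
  if (length(log10_dilution) < 3) stop("need >= 3 dilution points",
                                       call. = FALSE)
  slope <- stats::coef(stats::lm(ct ~ log10_dilution))[[2]]
  10^(-1 / slope)
}
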