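#' Significance stars at the conventional thresholds
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `ns` otherwise.
#' @param p numeric p values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

.stat_result <- function(test, statistic, df, p, p_adj = NA_real_,
                         method_adjust = NA_character_, groups = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(p), p_adj = p_adj,
                 method_adjust = method_adjust, groups = groups,
                 stars = significance_stars(if (is.na(p_adj)) p else p_adj)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g %s\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = ", "), x$p,
              x$stars))
  invisible(x)
}

#' Two-tailed Student t test
#'
#' Classical Student t test for paired or independent samples; the unpaired
#' test uses the pooled-variance statistic (a Welch option exists but is not
#' the default).
#'
#' @param x,y numeric samples (equal length when paired).
#' @param paired logical.
#' @param welch logical, unpaired only: Welch correction instead of pooled
#'   variance.
#' @return a `stat_result` with t, df and the two-tailed p.
#' @export
t_test_student <- function(x, y, paired = FALSE, welch = FALSE) {
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length",
                                     call. = FALSE)
    if (length(x) < 2) stop("need n >= 2", call. = FALSE)
    if (stats::sd(x - y) == 0) {
      stop("zero variance of paired differences: t undefined", call. = FALSE)
    }
    res <- stats::t.test(x, y, paired = TRUE)
  } else {
    if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group",
                                             call. = FALSE)
    res <- stats::t.test(x, y, var.equal = !welch)
  }
  .stat_result(if (paired) "paired t" else if (welch) "Welch t" else
                 "Student t",
               res$statistic, res$parameter, res$p.value)
}

#' Bonferroni-Holm adjustment
#'
#' Step-down Holm correction: sort p ascending, multiply the i-th smallest
#' by (m - i + 1), take the running maximum, cap at 1, restore input order.
#'
#' @param pvals numeric p values in \[0, 1\].
#' @return adjusted p values, same order.
#' @export
holm_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "holm")
}

#' One-way ANOVA with Holm-corrected pairwise t tests
#'
#' Omnibus F test over all groups followed by all pairwise two-tailed
#' pooled-variance Student t tests with Bonferroni-Holm adjustment.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `omnibus` (a `stat_result` with F, df and p) and
#'   `pairwise` (data.frame: group1, group2, t, df, p, p_adj, stars).
#' @export
one_way_anova_holm <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(value ~ group, data = df)
  an <- stats::anova(fit)
  omnibus <- .stat_result("one-way ANOVA F", an[["F value"]][1],
                          c(an[["Df"]][1], an[["Df"]][2]),
                          an[["Pr(>F)"]][1])
  pairs <- utils::combn(names(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    r <- t_test_student(groups[[pairs[1, i]]], groups[[pairs[2, i]]])
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               t = r$statistic, df = r$df, p = r$p,
               stringsAsFactors = FALSE)
  }))
  pw$p_adj <- holm_adjust(pw$p)
  pw$stars <- significance_stars(pw$p_adj)
  list(omnibus = omnibus, pairwise = pw)
}

#' Unbalanced two-way ANOVA with Tukey-Kramer pairwise comparisons
#'
#' Main effects and (when estimable) the interaction are tested with Type II
#' sums of squares; pairwise comparisons of the cell means use the
#' Tukey-Kramer studentized-range procedure with the model MSE and the
#' per-pair harmonic mean of the cell sizes.
#'
#' @param data data.frame.
#' @param response,factor_a,factor_b column names.
#' @return list with `effects` (data.frame: term, SS, df, F, p) and `tukey`
#'   (data.frame: cell1, cell2, diff, q, p_adj, stars).
#' @export
two_way_anova_tukey <- function(data, response, factor_a, factor_b) {
  a <- factor(data[[factor_a]]); b <- factor(data[[factor_b]])
  y <- data[[response]]
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  cells <- table(a, b)
  with_int <- all(cells > 0)
  if (!with_int) {
    warning("empty cells: interaction dropped", call. = FALSE)
  }
  d <- data.frame(y = y, a = a, b = b)
  fit <- if (with_int) stats::lm(y ~ a * b, data = d)
         else stats::lm(y ~ a + b, data = d)
  an <- car::Anova(fit, type = 2)
  terms <- rownames(an)
  eff <- data.frame(term = terms, SS = an[["Sum Sq"]], df = an[["Df"]],
                    F = an[["F value"]], p = an[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  eff$term[eff$term == "a"] <- factor_a
  eff$term[eff$term == "b"] <- factor_b
  eff$term[eff$term == "a:b"] <- paste0(factor_a, ":", factor_b)

  # Tukey-Kramer over the a x b cell means
  cell <- interaction(a, b, sep = ":", drop = TRUE)
  means <- tapply(y, cell, mean)
  ns <- tapply(y, cell, length)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  df_err <- stats::df.residual(fit)
  k <- length(means)
  pr <- utils::combn(names(means), 2)
  tk <- do.call(rbind, lapply(seq_len(ncol(pr)), function(i) {
    g1 <- pr[1, i]; g2 <- pr[2, i]
    se <- sqrt(mse / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- abs(means[[g1]] - means[[g2]]) / se
    p <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    data.frame(cell1 = g1, cell2 = g2, diff = means[[g1]] - means[[g2]],
               q = q, p_adj = p, stringsAsFactors = FALSE)
  }))
  tk$stars <- significance_stars(tk$p_adj)
  list(effects = eff, tukey = tk, mse = mse, df_error = df_err)
}

#' Lilliefors statistic
#'
#' Kolmogorov-Smirnov distance between the empirical distribution and a
#' normal with the sample's estimated mean and s.d.
#'
#' @param x numeric sample, n >= 4, nonzero variance.
#' @return scalar D.
#' @export
lilliefors_stat <- function(x) {
  n <- length(x)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance sample", call. = FALSE)
  z <- sort(stats::pnorm(x, mean(x), s))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

# null D statistics for given n (matrix draw, vectorized over replicates)
.lilliefors_null <- function(n, n_mc) {
  m <- matrix(stats::rnorm(n * n_mc), nrow = n)
  mu <- colMeans(m)
  s <- sqrt(colSums(sweep(m, 2, mu)^2) / (n - 1))
  z <- stats::pnorm(sweep(sweep(m, 2, mu), 2, s, "/"))
  z <- apply(z, 2, sort)
  i <- seq_len(n)
  pmax(apply(i / n - z, 2, max), apply(z - (i - 1) / n, 2, max))
}

#' Lilliefors normality test with a Monte Carlo null
#'
#' The D statistic's null distribution is simulated from `n_mc` standard
#' normal samples of the same size (seeded, so results are reproducible);
#' the p value is the usual add-one Monte Carlo estimate.
#'
#' @param x numeric sample, n >= 4.
#' @param n_mc Monte Carlo replicates (default 10000).
#' @param seed RNG seed for the null simulation.
#' @return a `stat_result` with the D statistic and Monte Carlo p.
#' @export
lilliefors <- function(x, n_mc = 10000, seed = 1L) {
  d <- lilliefors_stat(x)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  d0 <- .lilliefors_null(length(x), n_mc)
  p <- (1 + sum(d0 >= d)) / (n_mc + 1)
  .stat_result("Lilliefors (Monte Carlo)", d, length(x), p)
}

#' Monte Carlo critical value of the Lilliefors statistic
#'
#' Upper `alpha` quantile of the simulated null distribution of D for sample
#' size `n`; comparing observed statistics to this value reproduces the
#' alpha-level test without re-simulating the null per sample.
#'
#' @param n sample size.
#' @param alpha test level (default 0.05).
#' @param n_mc Monte Carlo replicates.
#' @param seed RNG seed.
#' @return scalar critical value.
#' @export
lilliefors_critical <- function(n, alpha = 0.05, n_mc = 10000, seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  stats::quantile(.lilliefors_null(n, n_mc), 1 - alpha, names = FALSE)
}
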