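test_that("paired and unpaired Student t match hand computation", {
  # differences [0.5, 0.5, 0]: mean 1/3, sd sqrt(1/12) -> t = 2, df = 2
  r <- t_test_student(c(1.5, 2.5, 3.0), c(1, 2, 3), paired = TRUE)
  expect_equal(r$statistic, 2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  # antisymmetry: swapping samples flips t, keeps p
  a <- c(1.2, 3.1, 2.2, 4.5); b <- c(0.7, 1.1, 2.0, 1.9)
  r1 <- t_test_student(a, b); r2 <- t_test_student(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p, r2$p)
  # pooled-variance df = n1 + n2 - 2
  expect_equal(r1$df, 6)
  # identical paired samples: zero difference variance errors
  expect_error(t_test_student(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
               "zero variance")
})

test_that("one-way ANOVA reproduces the closed-form F and Holm post hocs", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  r <- one_way_anova_holm(groups)
  # SSB = 6, SSW = 6 -> F = (6/2)/(6/6) = 3 on df (2, 6)
  expect_equal(r$omnibus$statistic, 3, tolerance = 1e-12)
  expect_equal(r$omnibus$df, c(2, 6))
  expect_equal(nrow(r$pairwise), 3)
  expect_equal(r$pairwise$p_adj, holm_adjust(r$pairwise$p))

  # identical groups: F = 0, p = 1
  same <- list(x = c(1, 2, 3), y = c(1, 2, 3))
  r0 <- suppressWarnings(one_way_anova_holm(same))
  expect_equal(r0$omnibus$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$omnibus$p, 1, tolerance = 1e-12)
  expect_error(one_way_anova_holm(list(a = 1:3)), "2 groups")
})

test_that("Holm adjustment follows the step-down definition", {
  # brute-force definition: sort, multiply by m - i + 1, running max, cap
  brute_holm <- function(p) {
    o <- order(p); m <- length(p)
    adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
    out <- numeric(m); out[o] <- adj; out
  }
  cases <- list(c(0.01, 0.04, 0.03), c(0.5, 0.5), c(0.2),
                c(0.001, 0.2, 0.04, 0.9, 0.03))
  for (p in cases) expect_equal(holm_adjust(p), brute_holm(p))
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(0.5, 0.5)), c(1, 1))
  expect_equal(holm_adjust(0.2), 0.2)
  # Holm never exceeds Bonferroni and is monotone in the raw p
  set.seed(2)
  for (i in 1:20) {
    p <- runif(6)
    h <- holm_adjust(p)
    expect_true(all(h <= pmin(1, length(p) * p) + 1e-12))
    expect_true(all(diff(h[order(p)]) >= -1e-12))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("two-way ANOVA: additive cell means kill the interaction", {
  d <- expand.grid(rep = 1:3, A = c("a1", "a2"), B = c("b1", "b2"))
  means <- c(a1.b1 = 0, a2.b1 = 1, a1.b2 = 1, a2.b2 = 2)
  # additive cell means, nonzero within-cell spread that cancels per cell
  d$y <- means[paste(d$A, d$B, sep = ".")] + rep(c(-0.1, 0, 0.1), 4)
  r <- suppressWarnings(two_way_anova_tukey(d, "y", "A", "B"))
  int_ss <- r$effects$SS[r$effects$term == "A:B"]
  expect_equal(int_ss, 0, tolerance = 1e-12)
})

test_that("Type II SS equal classical SS on balanced designs (oracle)", {
  set.seed(11)
  d <- expand.grid(rep = 1:4, A = c("a1", "a2", "a3"), B = c("b1", "b2"))
  d$y <- rnorm(nrow(d)) + as.numeric(d$A) + 0.5 * as.numeric(d$B)
  r <- two_way_anova_tukey(d, "y", "A", "B")
  cl <- anova(lm(y ~ A * B, data = d))
  for (trm in c("A", "B")) {
    expect_equal(r$effects$SS[r$effects$term == trm],
                 cl[trm, "Sum Sq"], tolerance = 1e-10)
  }
  # Tukey p values agree with TukeyHSD on the balanced cell-means model
  th <- TukeyHSD(aov(y ~ interaction(A, B, sep = ":"), data = d))[[1]]
  key <- function(c1, c2) paste(c1, c2, sep = "-")
  for (i in seq_len(nrow(r$tukey))) {
    row <- r$tukey[i, ]
    hit <- which(rownames(th) %in% c(key(row$cell1, row$cell2),
                                     key(row$cell2, row$cell1)))
    expect_equal(row$p_adj, th[hit, "p adj"], tolerance = 1e-4)
  }
})

test_that("two-group Tukey q reduces to t * sqrt(2)", {
  set.seed(3)
  d <- data.frame(y = rnorm(14), A = rep(c("g1", "g2"), each = 7),
                  B = rep(c("u", "v"), 7))
  # single varying factor: compare q over cells of A at fixed B by hand
  x <- d$y[d$A == "g1"]; y <- d$y[d$A == "g2"]
  tt <- t_test_student(x, y)
  mse <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 12
  q <- abs(mean(x) - mean(y)) / sqrt(mse / 2 * (1 / 7 + 1 / 7))
  expect_equal(q, abs(tt$statistic) * sqrt(2), tolerance = 1e-10)
  expect_error(two_way_anova_tukey(data.frame(y = 1:4, A = "a", B = c("u", "v")),
                                   "y", "A", "B"), "levels")
})

test_that("Lilliefors statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(6)
  for (n in c(10, 50, 120)) {
    x <- rnorm(n, 2, 3)
    expect_equal(lilliefors_stat(x),
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
  expect_error(lilliefors_stat(c(1, 1, 1, 1)), "variance")
  expect_error(lilliefors_stat(c(1, 2)), "n >= 4")
})

test_that("Monte Carlo Lilliefors p is seeded and detects non-normality", {
  set.seed(9)
  x <- rnorm(40)
  p1 <- lilliefors(x, n_mc = 2000, seed = 5)$p
  p2 <- lilliefors(x, n_mc = 2000, seed = 5)$p
  expect_identical(p1, p2)
  expect_gt(p1, 0.05)
  u <- runif(100)
  expect_lt(lilliefors(u, n_mc = 2000, seed = 5)$p, 0.01)
})
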