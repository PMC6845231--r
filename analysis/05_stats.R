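#!/usr/bin/env Rscript
# Step 5 — the statistical battery on per-fly metrics: normality check,
# two-group t test, dose-response one-way ANOVA + Holm, and the unbalanced
# two-way design (dose x genotype) with Type II SS and Tukey HSD.

suppressPackageStartupMessages(library(calcifly))
dir.create("results", showWarnings = FALSE)
seed <- 1L

# simulated per-fly ON-step means for a dose x genotype design; the
# block-insensitive genotype is unaffected by the drug (full rescue)
set.seed(seed + 50)
doses <- c("0uM", "5uM", "25uM")
genos <- c("wt", "insensitive")
block_at <- c("0uM" = 0, "5uM" = 0.6, "25uM" = 1)
rows <- list()
for (g in genos) {
  for (d in doses) {
    n <- sample(5:8, 1)                       # unbalanced by design
    eff <- if (g == "insensitive") 1 else 1 - block_at[[d]]
    rows[[paste(g, d)]] <- data.frame(
      genotype = g, dose = d,
      step = pmax(0, rnorm(n, mean = eff, sd = 0.12)))
  }
}
d5 <- do.call(rbind, rows)
write.csv(d5, "results/05_perfly_steps.csv", row.names = FALSE)

# normality of the control group
ctrl <- d5$step[d5$dose == "0uM" & d5$genotype == "wt"]
lt <- lilliefors(ctrl, n_mc = 5000, seed = seed)
cat(sprintf("Lilliefors on control steps: D = %.3f, Monte Carlo p = %.3f\n",
            lt$statistic, lt$p))

# two-group comparison at the highest dose
tt <- t_test_student(d5$step[d5$dose == "25uM" & d5$genotype == "wt"],
                     d5$step[d5$dose == "25uM" & d5$genotype == "insensitive"])
cat(sprintf("wt vs insensitive at 25uM: t(%d) = %.2f, p = %.2g %s\n",
            tt$df, tt$statistic, tt$p, tt$stars))

# dose response within wt: one-way ANOVA + Holm
wt <- split(d5$step[d5$genotype == "wt"], d5$dose[d5$genotype == "wt"])
an <- one_way_anova_holm(wt)
cat(sprintf("wt dose response: F(%d,%d) = %.1f, p = %.2g\n",
            an$omnibus$df[1], an$omnibus$df[2], an$omnibus$statistic,
            an$omnibus$p))
write.csv(an$pairwise, "results/05_dose_posthoc.csv", row.names = FALSE)

# full unbalanced two-way design
tw <- two_way_anova_tukey(d5, "step", "dose", "genotype")
write.csv(tw$effects, "results/05_twoway_effects.csv", row.names = FALSE)
write.csv(tw$tukey, "results/05_twoway_tukey.csv", row.names = FALSE)
print(tw$effects, row.names = FALSE)
sig <- tw$tukey[tw$tukey$p_adj < 0.05, c("cell1", "cell2", "p_adj", "stars")]
cat(sprintf("Tukey HSD: %d of %d cell contrasts significant at 0.05\n",
            nrow(sig), nrow(tw$tukey)))
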