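#!/usr/bin/env Rscript
# Step 6 — delta-delta-Ct quantification of a simulated knockdown series
# (wild type, heterozygous disruption, homozygous null), three biological x
# three technical replicates, normalized to the wild-type mean.

suppressPackageStartupMessages(library(calcifly))
dir.create("results", showWarnings = FALSE)
set.seed(61)

# simulate Ct readings: reference gene ~18 cycles everywhere; target at
# 20 cycles in WT, shifted by -log2(fraction) in the mutants
true_frac <- c(WT = 1, het = 0.4, null = 0.04)
mk_cond <- function(cond) {
  do.call(rbind, lapply(1:3, function(rep) {
    ct_t <- 20 - log2(true_frac[[cond]]) + rnorm(1, 0, 0.15)
    ct_r <- 18 + rnorm(1, 0, 0.15)
    data.frame(condition = cond, bio_rep = rep,
               gene = rep(c("GluCla", "GAPDH2"), each = 3),
               tech_rep = rep(1:3, 2),
               ct = c(ct_t + rnorm(3, 0, 0.05), ct_r + rnorm(3, 0, 0.05)))
  }))
}
ct_tab <- rbind(mk_cond("WT"), mk_cond("het"), mk_cond("null"))
write.csv(ct_tab, "results/06_ct_table.csv", row.names = FALSE)

m <- mean_ct(ct_tab)
res <- lapply(c("het", "null"), function(cond) {
  ddct_percent(m, "GluCla", "GAPDH2", condition_d = cond,
               condition_nd = "WT",
               efficiencies = unname(default_primer_efficiencies()))
})
names(res) <- c("het", "null")

# normalize every replicate (incl. WT against itself) to the WT mean
wt_rep <- ddct_percent(m, "GluCla", "GAPDH2", condition_d = "WT",
                       condition_nd = "WT",
                       efficiencies = unname(default_primer_efficiencies()))
vals <- c(wt_rep$per_rep, res$het$per_rep, res$null$per_rep)
grp <- rep(c("WT", "het", "null"), each = 3)
norm <- 100 * normalize_to_control(vals, grp, "WT")
out <- data.frame(condition = grp, replicate = rep(1:3, 3),
                  percent_of_wt = norm)
write.csv(out, "results/06_ddct_normalized.csv", row.names = FALSE)

for (cond in c("WT", "het", "null")) {
  v <- out$percent_of_wt[out$condition == cond]
  cat(sprintf("%-5s %.1f%% +/- %.1f%% of WT (true %.0f%%)\n", cond,
              mean(v), sd(v) / sqrt(length(v)), 100 * true_frac[[cond]]))
}
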