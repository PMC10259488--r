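#!/usr/bin/env Rscript
# Step 6 — the group-comparison report: Friedman test of intake across
# concentrations, avoider vs non-avoider contrasts per concentration with
# Holm-Bonferroni correction, and the minipump percent-consumption
# comparison.

suppressPackageStartupMessages(library(bottlechoice))

summaries <- read.csv("results/condition_summaries.csv")
ph <- read.csv("results/phenotypes.csv")
lab <- setNames(ph$label, ph$mouse_id)

# intake matrix: mice x drug concentrations
drug <- summaries[summaries$concentration > 0, ]
mat <- reshape(drug[c("mouse_id", "concentration", "mean_intake")],
               idvar = "mouse_id", timevar = "concentration",
               direction = "wide")
m <- as.matrix(mat[-1])
fr <- friedman_test(m)
message(sprintf("Friedman on intake across concentrations: chi2 = %.1f, df = %d, n = %d, p = %.2g",
                fr$statistic, fr$df, fr$n, fr$p_value))

# avoider vs non-avoider intake per concentration, Holm-corrected
concs <- sort(unique(drug$concentration))
tests <- do.call(rbind, lapply(concs, function(cc) {
  s <- drug[drug$concentration == cc, ]
  g <- lab[s$mouse_id]
  mw <- mann_whitney(s$mean_intake[g == "avoider"],
                     s$mean_intake[g == "non_avoider"])
  data.frame(family = "intake_by_group", label = paste0("nic", cc),
             statistic = mw$statistic, p_raw = mw$p_value)
}))
rep1 <- family_report(tests)
write.csv(rep1, "results/group_comparisons.csv", row.names = FALSE)
message("Avoider vs non-avoider intake (Holm-adjusted p):")
print(rep1[c("label", "statistic", "p_raw", "p_adjusted")])

# minipump protocol: saline vs nicotine percent consumption at 100 µg/ml
pct_at_100 <- function(tr, seed) {
  mp <- minipump_cohort(tr, seed = seed)
  sm <- cohort_pipeline(mp)$summaries
  sm$mean_pct[sm$concentration == 100]
}
sal <- pct_at_100("saline", 102)
nic <- pct_at_100("nicotine", 103)
mw <- mann_whitney(sal, nic)
message(sprintf(
  "Single-step task: saline %.1f%% vs nicotine-pretreated %.1f%% (U = %g, p = %.2g)",
  mean(sal), mean(nic), mw$statistic, mw$p_value))
write.csv(data.frame(group = c("saline", "nicotine"),
                     mean_pct = c(mean(sal), mean(nic)),
                     n = c(length(sal), length(nic)),
                     p_value = mw$p_value),
          "results/minipump_comparison.csv", row.names = FALSE)
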