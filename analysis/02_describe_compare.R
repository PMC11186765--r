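#!/usr/bin/env Rscript
# Stage 2 — descriptive summaries and nonparametric group comparisons.
#
# Median/IQR per diagnostic group and marker, then Kruskal-Wallis across
# groups with Dunn's Bonferroni-corrected pairwise z tests — the comparison
# design used for every marker panel in the study.

library(evdx)

for (cohort in c("describe2", "santpau")) {
  tab <- read_cohort(sprintf("results/cohort_%s.csv", cohort))
  groups <- split(tab, tab$diagnosis)

  desc <- do.call(rbind, lapply(c("tau_ratio", "tdp43", "nfl"), function(m) {
    do.call(rbind, lapply(names(groups), function(g) {
      s <- median_iqr(groups[[g]][[m]])
      data.frame(cohort = cohort, marker = m, diagnosis = g,
                 n = nrow(groups[[g]]), median = s[["median"]],
                 q1 = s[["q1"]], q3 = s[["q3"]])
    }))
  }))
  write.csv(desc, sprintf("results/descriptives_%s.csv", cohort), row.names = FALSE)

  comp <- do.call(rbind, lapply(c("tau_ratio", "tdp43"), function(m) {
    d <- dunn_pairwise(lapply(groups, `[[`, m), adjust = "bonferroni")
    cbind(cohort = cohort, marker = m, h = d$h, p_global = d$p_global, d$pairwise)
  }))
  write.csv(comp, sprintf("results/comparisons_%s.csv", cohort), row.names = FALSE)

  cat(sprintf("\n== %s ==\n", cohort))
  key <- desc[desc$marker == "tau_ratio", c("diagnosis", "median", "q1", "q3")]
  print(key, row.names = FALSE, digits = 3)
  sig <- comp[comp$p_adjusted < 0.05, ]
  cat(sprintf("%d of %d pairwise comparisons significant after Bonferroni\n",
              nrow(sig), nrow(comp)))
}
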