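#!/usr/bin/env Rscript
# Stage 3 — marker / NfL correlation structure and monotone trends.
#
# Spearman correlation matrices within each diagnostic group (the heat-map
# panels of the study), plus an isotonic trend fit of NfL on the tau ratio
# inside PSP, where the association is negative (4R-predominant pathology).

library(evdx)

tab <- read_cohort("results/cohort_describe2.csv")

rows <- list()
for (g in unique(tab$diagnosis)) {
  cm <- spearman_matrix(tab, c("tau_ratio", "tdp43", "nfl"), within = g)
  for (i in 1:2) for (j in (i + 1):3) {
    v1 <- cm$variables[i]; v2 <- cm$variables[j]
    rows[[length(rows) + 1]] <- data.frame(
      diagnosis = g, var_a = v1, var_b = v2,
      rho = cm$r[v1, v2], p = cm$p[v1, v2], n = cm$n[v1, v2])
  }
}
corr <- do.call(rbind, rows)
write.csv(corr, "results/correlations_describe2.csv", row.names = FALSE)

cat("Within-group Spearman correlations (discovery cohort):\n")
print(corr, row.names = FALSE, digits = 2)

# monotone (decreasing) trend of tau ratio against NfL in PSP
psp <- tab[tab$diagnosis == "PSP", ]
fit <- monotone_fit(psp$nfl, psp$tau_ratio, direction = "auto")
cat(sprintf("\nPSP tau-ratio ~ NfL isotonic fit: direction %s, RSS %.2f (n = %d)\n",
            fit$direction, fit$rss, nrow(psp)))
write.csv(data.frame(nfl = fit$x, tau_ratio = psp$tau_ratio, fitted = fit$fitted),
          "results/monotone_psp.csv", row.names = FALSE)
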