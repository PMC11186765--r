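#!/usr/bin/env Rscript
# Stage 6 — two-marker classification grid, diagnostic performance against
# confirmed pathology, and cross-cohort cut-off transfer.
#
# Each cohort is classified with its own mixture-derived rule; sensitivity
# and specificity carry exact Clopper-Pearson intervals. The transfer stage
# applies the discovery-cohort rule to the validation cohort, the study's
# generalizability check.

library(evdx)

cuts <- jsonlite::read_json("results/cutoffs.json", simplifyVector = TRUE)
rule_of <- function(cohort) {
  classification_rule(
    c(cuts[[paste0(cohort, ".tau_ratio")]]$lower, cuts[[paste0(cohort, ".tau_ratio")]]$upper),
    c(cuts[[paste0(cohort, ".tdp43")]]$lower, cuts[[paste0(cohort, ".tdp43")]]$upper),
    cohort = cohort)
}
rules <- list(describe2 = rule_of("describe2"), santpau = rule_of("santpau"))

perf_out <- list()
for (cohort in names(rules)) {
  tab <- read_cohort(sprintf("results/cohort_%s.csv", cohort))
  rule <- rules[[cohort]]
  ct <- classify_table(tab, rule)
  write.csv(ct, sprintf("results/classified_%s.csv", cohort), row.names = FALSE)

  tdp <- evaluate_rule(tab, rule, truth_spec_tdp(among = "confirmed"))
  psp <- evaluate_rule(tab, rule, truth_spec_psp())
  perf_out[[cohort]] <- list(tdp_detection = unclass(tdp),
                             psp_discrimination = unclass(psp))
  cat(sprintf("\n== %s (rule %.3f/%.3f | %.2f/%.2f) ==\n", cohort,
              rule$tau[1], rule$tau[2], rule$tdp[1], rule$tdp[2]))
  cat("TDP-43 detection among confirmed: "); print(tdp)
  cat("PSP discrimination (all subjects): "); print(psp)
  cat(sprintf("grid cells: %s\n",
              paste(names(table(ct$ev_class)), table(ct$ev_class),
                    sep = "=", collapse = ", ")))
}

# cross-cohort transfer: discovery rule applied to the validation cohort
tab_val <- read_cohort("results/cohort_santpau.csv")
tr <- transfer_cutoffs(rules$describe2, tab_val,
                       truth_spec_tdp(among = "confirmed"),
                       native_rule = rules$santpau)
cat("\n== transfer: discovery rule on validation cohort ==\n")
cat("transferred: "); print(tr$transferred)
cat("native:      "); print(tr$native)
perf_out$transfer <- list(transferred = unclass(tr$transferred),
                          native = unclass(tr$native))

jsonlite::write_json(perf_out, "results/performance.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
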