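# Cohort calibrations
#
# The generator is calibrated to published group-level summaries of plasma
# small-EV (sEV) markers: median [q1-q3] of the 3R/4R tau ratio (unitless)
# and TDP-43 (pg/ml). Plasma NfL group levels are not published as
# median/IQR; the values below are field-realistic defaults (documented in
# the methods vignette) whose role is only to give the correlation and ROC
# benchmarking stages signal.

comp <- function(weight, tau_ratio, tdp43, nfl, mutation = NULL) {
  c(list(weight = weight, tau_ratio = tau_ratio, tdp43 = tdp43, nfl = nfl),
    if (!is.null(mutation)) list(mutation = mutation))
}

#' Discovery-cohort calibration (four-group, 563 subjects)
#'
#' Returns the generating spec for a synthetic cohort shaped like the
#' discovery subcohort used for cut-off derivation: HC (n = 56), ALS
#' (n = 165), bvFTD (n = 179) and PSP (n = 163). bvFTD is a two-component
#' mixture of a putative FTLD-tau-like half (high tau ratio, low TDP-43) and
#' an FTLD-TDP-like half (tau ratio near 1, elevated TDP-43).
#'
#' Two published tau-ratio summaries exist for bvFTD: a whole-group
#' median/IQR (1.10 \[0.99-1.76\]) and a higher tau-subgroup value
#' (2.28 \[1.13-2.4\]). Both calibrations are exposed; the default uses the
#' subgroup value for the tau-like component, which is what produces the
#' clearly bimodal tau-ratio histogram the two-marker grid relies on.
#'
#' @param bvftd_weights Length-2 weights `c(tau, tdp)` of the bvFTD
#'   components; default 50/50, set to `c(0.3855, 0.6145)` to match the
#'   published share of high-tau-ratio bvFTD cases.
#' @param bvftd_tau_calibration `"subgroup"` (default) or `"whole"`; see
#'   Details.
#' @param tdp43_lloq Optional TDP-43 lower limit of quantification applied as
#'   a floor (left-censoring), default off.
#' @return An `ev_cohort_spec`: a list with `cohort` and `groups`.
#' @export
describe_subcohort2_spec <- function(bvftd_weights = c(0.5, 0.5),
                                     bvftd_tau_calibration = c("subgroup", "whole"),
                                     tdp43_lloq = NULL) {
  bvftd_tau_calibration <- match.arg(bvftd_tau_calibration)
  stopifnot(length(bvftd_weights) == 2, abs(sum(bvftd_weights) - 1) < 1e-9)
  tau_hi <- switch(bvftd_tau_calibration,
                   subgroup = c(2.28, 1.13, 2.40),
                   whole    = c(1.10, 0.99, 1.76))

  # Pathology-group marker summaries (published): confirmed TDP-43 cases
  # 0.95 [0.92-0.97] / 63.95 [42.89-86.63]; PSP/GGT-type tau 0.42 [0.35-0.60]
  # / 2.85 [2.10-3.52]; MAPT carriers 3.96 [3.81-4.12] / 2.86 [2.53-3.02];
  # non-tau/non-TDP 0.96 [0.90-1.03] / 11.35 [10.62-12.05].
  path_tdp  <- comp(1, c(0.95, 0.92, 0.97), c(63.95, 42.89, 86.63), c(60, 40, 90), "C9orf72")
  path_tau  <- comp(1, c(0.42, 0.35, 0.60), c(2.85, 2.10, 3.52), c(30, 20, 45))
  path_mapt <- comp(1, c(3.96, 3.81, 4.12), c(2.86, 2.53, 3.02), c(25, 15, 40), "MAPT")
  path_non  <- comp(1, c(0.96, 0.90, 1.03), c(11.35, 10.62, 12.05), c(60, 40, 90), "SOD1")

  groups <- list(
    group_spec("HC", 56,
               list(comp(1, c(0.99, 0.91, 1.03), c(9.47, 7.63, 13.33), c(10, 8, 14))),
               tdp43_lloq = tdp43_lloq),
    group_spec("ALS", 165,
               list(comp(1, c(0.95, 0.88, 1.01), c(45.45, 28.88, 83.21), c(60, 40, 90))),
               rho_nfl = c(tdp43 = 0.67),
               pathology_counts = c("TDP-43" = 28, "non-tau-non-TDP" = 5),
               pathology_components = list("TDP-43" = path_tdp, "non-tau-non-TDP" = path_non),
               tdp43_lloq = tdp43_lloq),
    group_spec("bvFTD", 179,
               list(comp(bvftd_weights[1], tau_hi, c(9.47, 7.63, 13.33), c(25, 15, 40)),
                    comp(bvftd_weights[2], c(0.95, 0.92, 0.97), c(36.15, 20.0, 55.0), c(25, 15, 40))),
               rho_nfl = c(tau_ratio = 0.28, tdp43 = 0.42),
               pathology_counts = c("TDP-43" = 22, "tau-MAPT" = 3, "non-tau-non-TDP" = 1),
               pathology_components = list("TDP-43" = path_tdp, "tau-MAPT" = path_mapt,
                                           "non-tau-non-TDP" = path_non),
               tdp43_lloq = tdp43_lloq),
    group_spec("PSP", 163,
               list(comp(1, c(0.45, 0.34, 0.60), c(9.09, 7.73, 13.27), c(30, 20, 45))),
               rho_nfl = c(tau_ratio = -0.33),
               pathology_counts = c("tau-PSP/GGT" = 4),
               pathology_components = list("tau-PSP/GGT" = path_tau),
               tdp43_lloq = tdp43_lloq)
  )
  structure(list(cohort = "DESCRIBE-2", groups = groups), class = "ev_cohort_spec")
}

#' Validation-cohort calibration (five-group, 264 subjects)
#'
#' Generating spec shaped like the independent validation cohort: HC
#' (n = 50), ALS (n = 65), ALS-FTD (n = 58), bvFTD (n = 50) and PSP
#' (n = 41), with 34 genetically confirmed cases (27 TDP-43,
#' 7 non-tau/non-TDP). bvFTD uses the published 58/42 split of
#' high-tau-ratio versus TDP-like cases.
#'
#' @inheritParams describe_subcohort2_spec
#' @export
sant_pau_spec <- function(tdp43_lloq = NULL) {
  path_tdp <- comp(1, c(1.15, 1.07, 1.23), c(55.0, 35.0, 66.4), c(60, 40, 90), "C9orf72")
  path_non <- comp(1, c(0.92, 0.84, 1.15), c(12.7, 11.3, 15.7), c(60, 40, 90), "SOD1")
  groups <- list(
    group_spec("HC", 50,
               list(comp(1, c(1.02, 0.96, 1.06), c(10.41, 8.50, 14.65), c(10, 8, 14))),
               tdp43_lloq = tdp43_lloq),
    group_spec("ALS", 65,
               list(comp(1, c(1.02, 0.92, 1.11), c(45.60, 31.55, 64.45), c(60, 40, 90))),
               rho_nfl = c(tdp43 = 0.5),
               pathology_counts = c("TDP-43" = 3, "non-tau-non-TDP" = 6),
               pathology_components = list("TDP-43" = path_tdp, "non-tau-non-TDP" = path_non),
               tdp43_lloq = tdp43_lloq),
    group_spec("ALS-FTD", 58,
               list(comp(1, c(0.95, 0.84, 1.00), c(52.40, 39.18, 73.43), c(70, 45, 100))),
               rho_nfl = c(tdp43 = 0.5),
               pathology_counts = c("TDP-43" = 1, "non-tau-non-TDP" = 1),
               pathology_components = list("TDP-43" = path_tdp, "non-tau-non-TDP" = path_non),
               tdp43_lloq = tdp43_lloq),
    group_spec("bvFTD", 50,
               list(comp(0.58, c(2.00, 1.40, 2.80), c(10.41, 8.50, 14.65), c(25, 15, 40)),
                    comp(0.42, c(0.95, 0.88, 1.02), c(40.0, 25.0, 55.0), c(25, 15, 40))),
               rho_nfl = c(tau_ratio = 0.3, tdp43 = 0.513),
               pathology_counts = c("TDP-43" = 23),
               pathology_components = list("TDP-43" = path_tdp),
               tdp43_lloq = tdp43_lloq),
    group_spec("PSP", 41,
               list(comp(1, c(0.38, 0.33, 0.50), c(10.20, 8.30, 12.35), c(30, 20, 45))),
               rho_nfl = c(tau_ratio = -0.3),
               tdp43_lloq = tdp43_lloq)
  )
  structure(list(cohort = "SantPau", groups = groups), class = "ev_cohort_spec")
}
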