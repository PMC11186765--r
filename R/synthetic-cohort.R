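#' Log-normal parameters from a printed median and interquartile range
#'
#' Publications in the biomarker field report group summaries as
#' `median [q1-q3]`. For a log-normal variable the median fixes the log-scale
#' location and the IQR fixes the log-scale spread, so the generator can be
#' calibrated directly to printed tables:
#' `mu = log(median)`, `sigma = log(q3/q1) / (2 * qnorm(0.75))`.
#' A log-normal with these parameters has exactly the given median and, when
#' the quartiles are symmetric on the log scale, exactly the given quartiles.
#'
#' @param median,q1,q3 Marker summary values, all strictly positive with
#'   `q1 <= median <= q3`.
#' @return A list with elements `mu` and `sigma` (log-scale units).
#' @examples
#' lognormal_params_from_quartiles(0.99, 0.91, 1.03)
#' @export
lognormal_params_from_quartiles <- function(median, q1, q3) {
  if (!all(is.finite(c(median, q1, q3))) || any(c(median, q1, q3) <= 0)) {
    stop_invalid("median/q1/q3 must be finite and strictly positive (got %s, %s, %s)",
                 median, q1, q3)
  }
  if (q1 > q3) stop_invalid("q1 (%s) must not exceed q3 (%s)", q1, q3)
  if (median < q1 || median > q3) {
    stop_invalid("median (%s) must lie inside [q1, q3] = [%s, %s]", median, q1, q3)
  }
  list(mu = log(median), sigma = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

quartiles_ok <- function(x) {
  is.numeric(x) && length(x) == 3 && all(is.finite(x)) && all(x > 0) &&
    x[2] <= x[1] && x[1] <= x[3]
}

#' Specify one diagnostic group of a synthetic cohort
#'
#' A group is described by its size and one or more mixture components, each
#' holding per-marker `(median, q1, q3)` calibration triples. Multi-component
#' groups (behavioural-variant FTD with putative FTLD-tau and FTLD-TDP halves)
#' induce the joint tau-ratio/TDP-43 dependence through component membership:
#' the tau-like component carries high tau ratios and low TDP-43, the TDP-like
#' component the reverse, which reproduces the negative within-group Spearman
#' correlation between the two markers without an explicit bivariate copula.
#'
#' @param group_name Diagnosis label (`"HC"`, `"AD"`, `"svPPA"`, `"bvFTD"`,
#'   `"PSP"`, `"ALS"`, `"ALS-FTD"`).
#' @param n Number of subjects.
#' @param components List of components; each component is a list with a
#'   `weight` and marker calibration triples `c(median, q1, q3)` named
#'   `tau_ratio`, `tdp43` and `nfl` (tau ratio unitless, the others pg/ml).
#'   Weights must sum to 1.
#' @param rho_nfl Named numeric vector of target Spearman correlations of
#'   `tau_ratio` and `tdp43` with plasma NfL (Gaussian copula on the latent
#'   scale).
#' @param pathology_counts Optional named integer vector mapping a pathology
#'   label (`"TDP-43"`, `"tau-PSP/GGT"`, `"tau-MAPT"`, `"non-tau-non-TDP"`)
#'   to the number of confirmed cases inside this group.
#' @param pathology_components Optional named list giving, per pathology
#'   label, the marker calibration triples the labelled subjects are redrawn
#'   from, plus an optional `mutation` gene symbol.
#' @param tdp43_lloq Optional assay lower limit of quantification; generated
#'   TDP-43 values below it are floored (left-censoring), default off.
#' @return A validated `ev_group_spec` list.
#' @export
group_spec <- function(group_name, n, components,
                       rho_nfl = c(tau_ratio = 0, tdp43 = 0),
                       pathology_counts = NULL,
                       pathology_components = NULL,
                       tdp43_lloq = NULL) {
  stopifnot(is.character(group_name), length(group_name) == 1L,
            is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.list(components) || length(components) == 0) {
    stop_invalid("`components` must be a non-empty list")
  }
  w <- vapply(components, function(cc) cc$weight %||% NA_real_, numeric(1))
  if (anyNA(w) || abs(sum(w) - 1) > 1e-9) {
    stop_invalid("component weights for group %s must sum to 1 (got %s)",
                 group_name, sum(w))
  }
  for (cc in components) {
    for (m in c("tau_ratio", "tdp43", "nfl")) {
      if (!quartiles_ok(cc[[m]])) {
        stop_invalid("component of group %s: `%s` must be c(median, q1, q3) with 0 < q1 <= median <= q3",
                     group_name, m)
      }
    }
  }
  rho <- c(tau_ratio = 0, tdp43 = 0)
  rho[names(rho_nfl)] <- rho_nfl
  if (any(abs(rho) >= 1)) stop_invalid("rho_nfl entries must be in (-1, 1)")
  if (!is.null(pathology_counts)) {
    stopifnot(!is.null(names(pathology_counts)), all(pathology_counts >= 0))
    if (sum(pathology_counts) > n) {
      stop_invalid("group %s: pathology counts (%d) exceed group size (%d)",
                   group_name, sum(pathology_counts), n)
    }
    missing_comp <- setdiff(names(pathology_counts)[pathology_counts > 0],
                            names(pathology_components %||% list()))
    if (length(missing_comp)) {
      stop_invalid("group %s: no pathology_components entry for %s",
                   group_name, paste(missing_comp, collapse = ", "))
    }
  }
  structure(list(group_name = group_name, n = as.integer(n),
                 components = components, rho_nfl = rho,
                 pathology_counts = pathology_counts,
                 pathology_components = pathology_components,
                 tdp43_lloq = tdp43_lloq),
            class = "ev_group_spec")
}

# Spearman -> Pearson correlation on the Gaussian latent scale, so that the
# copula reproduces the requested rank correlation after any monotone
# marginal transform (here exp()).
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

draw_component_markers <- function(comp, z_tau, z_tdp, z_nfl) {
  p_tau <- lognormal_params_from_quartiles(comp$tau_ratio[1], comp$tau_ratio[2], comp$tau_ratio[3])
  p_tdp <- lognormal_params_from_quartiles(comp$tdp43[1], comp$tdp43[2], comp$tdp43[3])
  p_nfl <- lognormal_params_from_quartiles(comp$nfl[1], comp$nfl[2], comp$nfl[3])
  list(tau_ratio = exp(p_tau$mu + p_tau$sigma * z_tau),
       tdp43     = exp(p_tdp$mu + p_tdp$sigma * z_tdp),
       nfl       = exp(p_nfl$mu + p_nfl$sigma * z_nfl))
}

generate_group <- function(spec, cohort, id_offset, tau4r_quartiles) {
  n <- spec$n
  k <- length(spec$components)
  w <- vapply(spec$components, `[[`, numeric(1), "weight")
  comp_id <- sample.int(k, n, replace = TRUE, prob = w)

  # Latent Gaussians: markers independent given the component; NfL is a
  # linear blend of both marker latents targeting the requested Spearman
  # correlations (valid because the marker latents are independent).
  a <- spearman_to_pearson(spec$rho_nfl)
  if (sum(a^2) >= 1) stop_invalid("group %s: rho_nfl targets jointly infeasible", spec$group_name)
  z_tau <- stats::rnorm(n)
  z_tdp <- stats::rnorm(n)
  z_nfl <- a[["tau_ratio"]] * z_tau + a[["tdp43"]] * z_tdp +
    sqrt(1 - sum(a^2)) * stats::rnorm(n)

  tau_ratio <- tdp43 <- nfl <- numeric(n)
  for (ci in seq_len(k)) {
    idx <- comp_id == ci
    if (!any(idx)) next
    m <- draw_component_markers(spec$components[[ci]], z_tau[idx], z_tdp[idx], z_nfl[idx])
    tau_ratio[idx] <- m$tau_ratio
    tdp43[idx] <- m$tdp43
    nfl[idx] <- m$nfl
  }
  if (!is.null(spec$tdp43_lloq)) tdp43 <- pmax(tdp43, spec$tdp43_lloq)

  p4 <- lognormal_params_from_quartiles(tau4r_quartiles[1], tau4r_quartiles[2], tau4r_quartiles[3])
  tau4r <- exp(p4$mu + p4$sigma * stats::rnorm(n))
  data.frame(
    subject_id = sprintf("%s-%04d", gsub("[^A-Za-z0-9]", "", cohort), id_offset + seq_len(n)),
    cohort = cohort,
    diagnosis = spec$group_name,
    fraction = "sEV",
    tau3r = tau_ratio * tau4r,
    tau4r = tau4r,
    tau_ratio = tau_ratio,
    tdp43 = tdp43,
    nfl = nfl,
    pathology = "unknown",
    mutation = NA_character_,
    component = comp_id,
    stringsAsFactors = FALSE
  )
}

#' Generate a seeded synthetic cohort
#'
#' Draws one row per subject from the per-group log-normal (mixtures of)
#' marker distributions of `specs`, with plasma NfL coupled to the markers
#' through a Gaussian copula. The 3R/4R tau ratio is decomposed into 3R and 4R
#' concentrations by drawing an independent 4R level and setting
#' `tau3r = tau_ratio * tau4r`. Identical `(specs, seed)` yield a
#' byte-identical table.
#'
#' @param specs A list of [group_spec()] objects (or an `ev_cohort_spec` as
#'   returned by [describe_subcohort2_spec()]).
#' @param seed Integer seed; mandatory, there is no default.
#' @param cohort Cohort name recorded in every row (taken from an
#'   `ev_cohort_spec` when one is supplied).
#' @param tau4r_quartiles `(median, q1, q3)` of the 4R tau concentration
#'   (pg/ml) used to decompose the ratio.
#' @return A data frame of subject records, one row per subject-fraction.
#' @export
generate_cohort <- function(specs, seed, cohort = "synthetic",
                            tau4r_quartiles = c(25, 18, 35)) {
  if (inherits(specs, "ev_cohort_spec")) {
    cohort <- specs$cohort
    specs <- specs$groups
  }
  if (!is.list(specs) || length(specs) == 0) stop_invalid("`specs` must be a non-empty list")
  for (s in specs) {
    if (!inherits(s, "ev_group_spec")) stop_invalid("every spec must come from group_spec()")
  }
  with_seed(seed, {
    offset <- 0L
    out <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      out[[i]] <- generate_group(specs[[i]], cohort, offset, tau4r_quartiles)
      offset <- offset + specs[[i]]$n
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    attr(tab, "seed") <- as.integer(seed)
    tab
  })
}

#' Assign confirmed-pathology labels to a generated cohort
#'
#' Randomly selects, inside each diagnostic group, the number of subjects the
#' cohort spec declares as genetically or neuropathologically confirmed, sets
#' their pathology label, and redraws their markers from the pathology-group
#' calibration (e.g. MAPT mutation carriers from the high-ratio component).
#' Counts match the spec exactly; all other rows keep `pathology = "unknown"`.
#'
#' @inheritParams generate_cohort
#' @param table A cohort table from [generate_cohort()].
#' @return The table with pathology labels and redrawn labelled markers.
#' @export
inject_pathology_labels <- function(table, specs, seed) {
  if (inherits(specs, "ev_cohort_spec")) specs <- specs$groups
  with_seed(seed, {
    for (s in specs) {
      pc <- s$pathology_counts
      if (is.null(pc) || sum(pc) == 0) next
      rows <- which(table$diagnosis == s$group_name & table$pathology == "unknown")
      if (length(rows) < sum(pc)) {
        stop_invalid("group %s: requested %d pathology labels but only %d rows",
                     s$group_name, sum(pc), length(rows))
      }
      picked <- sample(rows, sum(pc))
      at <- 0L
      for (lab in names(pc)) {
        cnt <- pc[[lab]]
        if (cnt == 0) next
        idx <- picked[(at + 1L):(at + cnt)]
        at <- at + cnt
        comp <- s$pathology_components[[lab]]
        z_tau <- stats::rnorm(cnt)
        z_tdp <- stats::rnorm(cnt)
        z_nfl <- stats::rnorm(cnt)
        m <- draw_component_markers(comp, z_tau, z_tdp, z_nfl)
        table$tau_ratio[idx] <- m$tau_ratio
        table$tdp43[idx] <- m$tdp43
        table$tau3r[idx] <- m$tau_ratio * table$tau4r[idx]
        table$pathology[idx] <- lab
        table$mutation[idx] <- comp$mutation %||% NA_character_
      }
    }
    table
  })
}

#' Write / read a cohort table as tidy CSV with a JSON sidecar
#'
#' The CSV holds one row per subject-fraction with a `.` decimal separator;
#' the sidecar records the generating seed so a table on disk stays
#' reproducible.
#'
#' @param table Cohort table.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, meta = list()) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  side <- c(list(seed = attr(table, "seed"), n = nrow(table),
                 columns = names(table)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
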