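#' Validate a cohort table against the subject-record schema
#'
#' Checks column presence and types, non-negativity of marker
#' concentrations, consistency of the tau ratio with its components
#' (`tau_ratio == tau3r / tau4r` within 1e-9 relative), and duplicate
#' (subject, fraction) keys. Returns a machine-readable issue list rather
#' than failing on first error.
#'
#' @param x A data frame or a CSV path.
#' @return Data frame of issues (`row`, `column`, `issue`); zero rows when
#'   the table is clean.
#' @export
validate_table <- function(x) {
  tab <- if (is.character(x)) {
    if (!file.exists(x)) stop_invalid("cannot read %s", x)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else x
  issues <- list()
  note <- function(row, column, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(row = row, column = column,
                                                 issue = issue, stringsAsFactors = FALSE)
  }
  required <- c("subject_id", "cohort", "diagnosis", "fraction",
                "tau3r", "tau4r", "tau_ratio", "tdp43")
  for (col in setdiff(required, names(tab))) note(NA_integer_, col, "missing column")
  numeric_cols <- intersect(c("tau3r", "tau4r", "tau_ratio", "tdp43", "nfl"), names(tab))
  for (col in numeric_cols) {
    if (!is.numeric(tab[[col]])) { note(NA_integer_, col, "not numeric"); next }
    bad <- which(is.finite(tab[[col]]) & tab[[col]] < 0)
    for (r in bad) note(r, col, "negative value")
  }
  if (all(c("tau3r", "tau4r", "tau_ratio") %in% names(tab)) &&
      all(vapply(tab[c("tau3r", "tau4r", "tau_ratio")], is.numeric, logical(1)))) {
    ok <- is.finite(tab$tau3r) & is.finite(tab$tau4r) & is.finite(tab$tau_ratio) &
      tab$tau4r > 0
    mismatch <- which(ok & abs(tab$tau_ratio - tab$tau3r / tab$tau4r) >
                        1e-9 * pmax(1, abs(tab$tau_ratio)))
    for (r in mismatch) note(r, "tau_ratio", "tau_ratio != tau3r / tau4r")
  }
  if (all(c("subject_id", "fraction") %in% names(tab))) {
    key <- paste(tab$subject_id, tab$fraction)
    dup <- which(duplicated(key))
    for (r in dup) note(r, "subject_id", "duplicate (subject, fraction) key")
  }
  if (length(issues) == 0) {
    data.frame(row = integer(), column = character(), issue = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}

#' Run the end-to-end analysis
#'
#' Orchestrates the full pipeline on one cohort: generate (or load) the
#' table, describe each marker per group, compare groups (Kruskal-Wallis +
#' Dunn), correlate markers with NfL per group, compute the requested ROC
#' curves, derive mixture cut-offs per marker, classify the cohort on the
#' two-marker grid and score it against confirmed pathology. Every
#' stochastic stage receives a seed derived from the single root seed, so
#' stage-level reruns reproduce independently. Artifacts (CSV/JSON) are
#' written under `output_dir` together with a manifest of file hashes.
#'
#' @param config List with elements:
#'   `cohort_spec` (an `ev_cohort_spec`) or `table` (a cohort data frame) or
#'   `table_path` (CSV path); `seed` (root seed, mandatory);
#'   `markers` (default `c("tau_ratio", "tdp43")`); `fraction` filter
#'   (default `"sEV"`); `roc_pairs` (list of `c(positive, negative, marker)`
#'   triples); `prevalence` (named list marker -> prevalence for PR curves,
#'   optional); `n_boot` (bootstrap replicates for component selection,
#'   default 100); `run_boot` (default TRUE); `conf_level` (default 0.95);
#'   `alpha` (default 0.05); `output_dir` (optional; no files written when
#'   NULL).
#' @return List with `table`, `descriptives`, `comparisons`, `correlations`,
#'   `roc`, `cutoffs`, `rule`, `classified`, `performance` and `manifest`.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed
  if (is.null(seed)) stop_invalid("config$seed is mandatory")
  conf_level <- config$conf_level %||% 0.95
  markers <- config$markers %||% c("tau_ratio", "tdp43")

  # --- input stage -----------------------------------------------------
  tab <- if (!is.null(config$table)) {
    config$table
  } else if (!is.null(config$table_path)) {
    utils::read.csv(config$table_path, stringsAsFactors = FALSE)
  } else if (!is.null(config$cohort_spec)) {
    t0 <- generate_cohort(config$cohort_spec, seed = derive_seed(seed, "generate"))
    inject_pathology_labels(t0, config$cohort_spec, seed = derive_seed(seed, "pathology"))
  } else {
    stop_invalid("config needs one of cohort_spec / table / table_path")
  }
  issues <- validate_table(tab)
  if (nrow(issues) > 0) {
    stop_invalid("cohort table failed validation (%d issues; first: row %s, %s: %s)",
                 nrow(issues), issues$row[1], issues$column[1], issues$issue[1])
  }
  fraction <- config$fraction %||% "sEV"
  tab <- tab[tab$fraction == fraction, , drop = FALSE]
  if (nrow(tab) == 0) stop_invalid("no rows left after fraction filter '%s'", fraction)
  unknown <- setdiff(markers, names(tab))
  if (length(unknown)) stop_invalid("unknown marker(s): %s", paste(unknown, collapse = ", "))

  groups <- split(tab, tab$diagnosis)

  # --- descriptive stage -----------------------------------------------
  descriptives <- do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(markers, function(m) {
      s <- median_iqr(groups[[g]][[m]])
      data.frame(diagnosis = g, marker = m, n = sum(is.finite(groups[[g]][[m]])),
                 median = s[["median"]], q1 = s[["q1"]], q3 = s[["q3"]])
    }))
  }))

  # --- group comparison stage ------------------------------------------
  comparisons <- lapply(markers, function(m) {
    dunn_pairwise(lapply(groups, `[[`, m), adjust = "bonferroni")
  })
  names(comparisons) <- markers

  # --- correlation stage -----------------------------------------------
  corr_vars <- intersect(c(markers, "nfl"), names(tab))
  correlations <- lapply(names(groups), function(g) {
    spearman_matrix(tab, corr_vars, within = g)
  })
  names(correlations) <- names(groups)

  # --- ROC / PR stage --------------------------------------------------
  roc_pairs <- config$roc_pairs %||% list()
  roc <- lapply(roc_pairs, function(pr) {
    pos <- tab[[pr[[3]]]][tab$diagnosis == pr[[1]]]
    neg <- tab[[pr[[3]]]][tab$diagnosis == pr[[2]]]
    r <- auc_mann_whitney(pos, neg, orientation = "auto", conf_level = conf_level)
    prev <- config$prevalence[[pr[[3]]]]
    pr_curve <- if (!is.null(prev)) {
      pr_with_prevalence(r, prev, n_boot = config$pr_boot %||% 200,
                         seed = derive_seed(seed, paste0("pr-", paste(pr, collapse = "-"))))
    } else NULL
    list(positive = pr[[1]], negative = pr[[2]], marker = pr[[3]],
         roc = r, pr = pr_curve)
  })

  # --- cut-off stage ----------------------------------------------------
  cutoffs <- lapply(markers, function(m) {
    cutoffs_from_cohort(tab, m, seed = derive_seed(seed, paste0("cutoffs-", m)),
                        exclude_confirmed = TRUE,
                        run_boot = config$run_boot %||% TRUE,
                        n_boot = config$n_boot %||% 100,
                        alpha = config$alpha %||% 0.05)
  })
  names(cutoffs) <- markers

  # --- classification stage --------------------------------------------
  rule <- classified <- performance <- NULL
  if (all(c("tau_ratio", "tdp43") %in% markers)) {
    rule <- classification_rule(cutoffs[["tau_ratio"]], cutoffs[["tdp43"]],
                                cohort = tab$cohort[1])
    classified <- classify_table(tab, rule)
    performance <- list(
      tdp_detection = evaluate_rule(tab, rule, truth_spec_tdp(), conf_level),
      psp_discrimination = evaluate_rule(tab, rule, truth_spec_psp(), conf_level)
    )
  }

  result <- list(table = tab, descriptives = descriptives, comparisons = comparisons,
                 correlations = correlations, roc = roc, cutoffs = cutoffs,
                 rule = rule, classified = classified, performance = performance,
                 seed = seed)

  # --- artifact stage ---------------------------------------------------
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    result$manifest <- write_pipeline_artifacts(result, config$output_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, dir) {
  files <- character()
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files[[length(files) + 1L]] <<- p
  }
  wjson <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files[[length(files) + 1L]] <<- p
  }
  wcsv(result$table, "cohort.csv")
  wcsv(result$descriptives, "descriptives.csv")
  wcsv(do.call(rbind, lapply(names(result$comparisons), function(m) {
    cbind(marker = m, result$comparisons[[m]]$pairwise)
  })), "comparisons.csv")
  if (length(result$roc)) {
    wcsv(do.call(rbind, lapply(result$roc, function(r) {
      data.frame(positive = r$positive, negative = r$negative, marker = r$marker,
                 auc = r$roc$auc, se = r$roc$se,
                 ci_low = r$roc$ci_low, ci_high = r$roc$ci_high,
                 n_pos = r$roc$n_pos, n_neg = r$roc$n_neg,
                 auprc = if (is.null(r$pr)) NA_real_ else r$pr$auprc)
    })), "roc.csv")
  }
  wjson(lapply(result$cutoffs, function(cf) {
    list(marker = cf$marker, cohort = cf$cohort, lower = cf$lower, upper = cf$upper,
         weighted = cf$weighted, log_scale = cf$log_scale %||% FALSE,
         boot_k = if (is.null(cf$boot)) NA else cf$boot$k,
         model = cf$model[c("k", "weights", "means", "sds", "loglik", "n")])
  }), "cutoffs.json")
  if (!is.null(result$classified)) {
    wcsv(result$classified, "classified.csv")
  }
  if (!is.null(result$performance)) {
    wjson(lapply(result$performance, unclass), "performance.json")
  }
  manifest <- data.frame(file = basename(unlist(files)),
                         md5 = unname(tools::md5sum(unlist(files))),
                         stringsAsFactors = FALSE)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  manifest
}
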