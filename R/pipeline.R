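#' Analyze a single transition-matrix fixture
#'
#' Full matrix-level analysis of one cohort: quasi-independence fit, G test,
#' Freeman-Tukey deviates, significant-transition list, high-intensity
#' classification and kinematic DOT export, written as a report bundle.
#'
#' @param matrix_path path to a transition-matrix TSV.
#' @param out_dir output directory (created if missing).
#' @param ethogram an [ethogram] (default the packaged paired-male one).
#' @param alpha significance level.
#' @param tol IPF tolerance.
#' @return The [qi_fit], invisibly; writes `fit.json`, `deviates.tsv`,
#'   `significant.csv`, `hi_summary.json` and `kinematic.dot` in `out_dir`.
#' @export
run_matrix_analysis <- function(matrix_path, out_dir,
                                ethogram = default_ethogram(),
                                alpha = 0.05, tol = 1e-10) {
  tc <- read_transition_matrix(matrix_path, ethogram)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- qi_fit(tc, alpha = alpha, tol = tol)
  write_fit_json(fit, file.path(out_dir, "fit.json"))
  dev <- fit$deviates
  dev[is.na(dev)] <- 0
  utils::write.table(round(dev, 6), file.path(out_dir, "deviates.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  sig <- significant_transitions(fit)
  utils::write.csv(sig, file.path(out_dir, "significant.csv"),
                   row.names = FALSE)
  hi <- classify_hi_involvement(sig, ethogram)
  jsonlite::write_json(hi[c("involving_hi", "hi_to_hi", "to_hi", "from_hi",
                            "distinct_non_hi_precursors")],
                       file.path(out_dir, "hi_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  export_dot(fit, ethogram, file.path(out_dir, "kinematic.dot"))
  invisible(fit)
}

#' Analyze event-log cohorts end to end
#'
#' Reads event-log CSVs grouped by cohort age, builds per-cohort transition
#' matrices, fits the quasi-independence model, writes per-cohort report
#' bundles (matrix TSV, fit JSON, deviate TSV, significant list, DOT
#' diagram) plus cross-cohort ontogeny statistics, and returns the fits.
#'
#' @param log_paths_by_cohort named list (cohort age -> character vector of
#'   event-log CSV paths).
#' @param out_dir output directory.
#' @param ethogram an [ethogram].
#' @param alpha significance level.
#' @param single_male treat logs as trimmed single-male controls.
#' @return Named list of [qi_fit] objects, invisibly.
#' @export
run_cohort_analysis <- function(log_paths_by_cohort, out_dir,
                                ethogram = default_ethogram(), alpha = 0.05,
                                single_male = FALSE) {
  if (length(log_paths_by_cohort) == 0 ||
      all(lengths(log_paths_by_cohort) == 0)) {
    stop("no input: empty set of event logs")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logs_by_cohort <- lapply(log_paths_by_cohort, function(paths) {
    lapply(paths, read_event_log, ethogram = ethogram,
           single_male = single_male)
  })
  fits <- list()
  for (age in names(logs_by_cohort)) {
    sub <- file.path(out_dir, paste0("cohort_", age))
    dir.create(sub, showWarnings = FALSE)
    tc <- build_transition_counts(logs_by_cohort[[age]], ethogram)
    write_transition_matrix(tc, file.path(sub, "transitions.tsv"))
    fit <- qi_fit(tc, alpha = alpha)
    write_fit_json(fit, file.path(sub, "fit.json"))
    utils::write.csv(significant_transitions(fit),
                     file.path(sub, "significant.csv"), row.names = FALSE)
    export_dot(fit, ethogram, file.path(sub, "kinematic.dot"))
    fits[[age]] <- fit
  }
  if (length(logs_by_cohort) >= 2) {
    stats_df <- ontogeny_rate_stats(logs_by_cohort, alpha = alpha)
    utils::write.csv(stats_df, file.path(out_dir, "ontogeny_stats.csv"),
                     row.names = FALSE)
  }
  if (length(fits) >= 2) {
    pers <- cohort_persistence_classes(fits)
    jsonlite::write_json(pers, file.path(out_dir, "persistence.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(fits)
}

#' Simulate cohort event logs to disk
#'
#' Generates the configured number of sessions per age with the default
#' age profiles and writes one event-log CSV per session.
#'
#' @param out_dir output directory.
#' @param ages cohort ages to simulate.
#' @param n_pairs sessions per cohort (the study used 11, with 10 on day 4).
#' @param seed base seed; cohorts use `seed`, `seed + 1000`, ...
#' @param single_male simulate isolated single males.
#' @return Named list (age -> character vector of written paths), invisibly.
#' @export
simulate_cohort_logs <- function(out_dir, ages = c(1, 2, 3, 4, 6),
                                 n_pairs = 11, seed = 1,
                                 single_male = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (i in seq_along(ages)) {
    cfg <- default_parameters(ages[i], single_male = single_male)
    np <- if (ages[i] == 4 && n_pairs == 11) 10 else n_pairs
    logs <- generate_cohort(cfg, np, seed + (i - 1) * 1000)
    paths <- vapply(seq_along(logs), function(j) {
      p <- file.path(out_dir, sprintf("age%s_pair%02d.csv", ages[i], j))
      write_event_log(logs[[j]], p)
      p
    }, "")
    out[[as.character(ages[i])]] <- paths
  }
  invisible(out)
}
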