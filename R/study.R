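# Study-level orchestration: configuration, the end-to-end synthetic study,
# S3 methods, artifact writing, and miniature fixtures.

#' Study configuration
#'
#' Defaults reproduce the full synthetic study: 15 participants, 5 trials per
#' activity, all six activities, all eight tear scenarios.
#'
#' @param master_seed Seed driving every source of randomness in the study.
#' @param n_participants Cohort size.
#' @param n_trials Trials per participant and activity.
#' @param activities Activity subset.
#' @param scenarios Scenario subset.
#' @param model_config Path to a model YAML, or `NULL` for the packaged model.
#' @param solver_tol Recruitment solver tolerance.
#' @param anthropometrics Overrides for [generate_cohort()].
#' @return A list of class `glenosim_config`.
#' @export
study_config <- function(master_seed = 1, n_participants = 15, n_trials = 5,
                         activities = names(activity_registry()),
                         scenarios = names(tear_scenarios()),
                         model_config = NULL, solver_tol = 1e-8,
                         anthropometrics = list()) {
  structure(list(master_seed = master_seed, n_participants = n_participants,
                 n_trials = n_trials, activities = activities,
                 scenarios = scenarios, model_config = model_config,
                 solver_tol = solver_tol, anthropometrics = anthropometrics),
            class = "glenosim_config")
}

#' Simulate the full synthetic study
#'
#' Generates the virtual cohort, runs the tear-severity sweep
#' (generate -> filter -> net moments -> recruitment -> stability) over every
#' participant, trial, activity, scenario, and 10-degree elevation bin, and
#' returns a study object. The whole study is a pure function of the
#' configuration (and in particular of its master seed).
#'
#' @param config A [study_config()].
#' @return An object of class `glenosim_study` with the configuration, the
#'   cohort, and the sweep results.
#' @export
#' @examples
#' \donttest{
#' study <- simulate_study(study_config(n_participants = 3, n_trials = 2,
#'                                      activities = "UpL",
#'                                      scenarios = c("Intact", "S0")))
#' summary(study)
#' }
simulate_study <- function(config = study_config()) {
  t0 <- proc.time()[["elapsed"]]
  model <- load_model(config$model_config)
  cohort <- generate_cohort(config$n_participants,
                            seed = derive_seed(config$master_seed, 1L),
                            anthropometrics = config$anthropometrics,
                            n_trials = config$n_trials)
  sweep <- tear_severity_sweep(model, config$activities, config$scenarios,
                               cohort, n_trials = config$n_trials,
                               seed = derive_seed(config$master_seed, 2L),
                               tol = config$solver_tol)
  structure(list(config = config, model = model, cohort = cohort,
                 sweep = sweep, elapsed_s = proc.time()[["elapsed"]] - t0),
            class = "glenosim_study")
}

#' Run the statistical battery on a study
#'
#' @param study A `glenosim_study`.
#' @param ... Passed to [analyze_study()].
#' @return A `glenosim_stats`.
#' @export
analyze <- function(study, ...) {
  analyze_study(study$sweep, ...)
}

#' @export
print.glenosim_study <- function(x, ...) {
  cat("<glenosim_study> seed", x$config$master_seed, "\n")
  cat(" ", x$cohort$n, "participants x", x$config$n_trials, "trials x",
      length(x$config$activities), "activities x",
      length(x$config$scenarios), "scenarios\n")
  cat("  cells:", nrow(x$sweep$cells), " infeasible:", x$sweep$n_infeasible,
      sprintf("  (%.1f s)\n", x$elapsed_s))
  invisible(x)
}

#' @export
summary.glenosim_study <- function(object, ...) {
  prof <- stability_profile(object$sweep)
  stab <- stats::aggregate(stability ~ activity + scenario, data = prof,
                           FUN = mean, na.rm = TRUE)
  stab_wide <- stats::reshape(stab, idvar = "activity", timevar = "scenario",
                              direction = "wide")
  names(stab_wide) <- sub("^stability\\.", "", names(stab_wide))
  out <- list(config = object$config,
              n_cells = nrow(object$sweep$cells),
              n_infeasible = object$sweep$n_infeasible,
              mean_stability = stab_wide,
              elapsed_s = object$elapsed_s)
  class(out) <- "summary.glenosim_study"
  out
}

#' @export
print.summary.glenosim_study <- function(x, ...) {
  cat("Synthetic tear-severity study (seed", x$config$master_seed, ")\n")
  cat("cells:", x$n_cells, " infeasible:", x$n_infeasible, "\n")
  cat("mean stability by activity and scenario:\n")
  num <- vapply(x$mean_stability, is.numeric, TRUE)
  tab <- x$mean_stability
  tab[num] <- lapply(tab[num], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Stability profiles per activity
#'
#' Plots mean stability against the elevation bin, one line per tear
#' scenario, one panel per activity.
#'
#' @param x A `glenosim_study`.
#' @param ... Unused.
#' @export
plot.glenosim_study <- function(x, ...) {
  prof <- stability_profile(x$sweep)
  acts <- unique(prof$activity)
  scens <- intersect(names(tear_scenarios()), unique(prof$scenario))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(acts)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(length(scens), "Zissou 1")
  for (a in acts) {
    sub <- prof[prof$activity == a, ]
    agg <- stats::aggregate(stability ~ bin_deg + scenario, sub, mean,
                            na.rm = TRUE)
    graphics::plot(NULL, xlim = range(agg$bin_deg), ylim = c(0, 1),
                   xlab = "elevation (deg)", ylab = "stability", main = a)
    for (i in seq_along(scens)) {
      s <- agg[agg$scenario == scens[i], ]
      graphics::lines(s$bin_deg, s$stability, col = cols[i], lwd = 2)
    }
    if (a == acts[1]) {
      graphics::legend("bottomright", legend = scens, col = cols, lwd = 2,
                       cex = 0.6, bty = "n")
    }
  }
  invisible(x)
}

#' Run a study end to end and write its artifacts
#'
#' Simulates, analyzes, and writes to `out_dir`: the trial-level and
#' participant-mean results CSVs, the omnibus/post hoc/correlation stats
#' CSVs, a Markdown report of significant effects, and a JSON manifest
#' (configuration, seed, package version). Idempotent for a fixed
#' configuration.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the study, stats, and file paths.
#' @export
run_study <- function(config = study_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config)
  st <- analyze(study)
  paths <- c(
    cells = file.path(out_dir, "results_trials.csv"),
    results = file.path(out_dir, "results_participant_means.csv"),
    omnibus = file.path(out_dir, "stats_omnibus.csv"),
    posthoc = file.path(out_dir, "stats_posthoc.csv"),
    correlations = file.path(out_dir, "stats_correlations.csv"),
    report = file.path(out_dir, "report.md"),
    manifest = file.path(out_dir, "manifest.json")
  )
  wcsv <- function(d, p, template = NULL) {
    if (is.null(d)) d <- template # empty table keeps the artifact set complete
    utils::write.csv(d, p, row.names = FALSE)
  }
  empty <- function(...) {
    d <- data.frame(matrix(nrow = 0, ncol = length(c(...))))
    names(d) <- c(...)
    d
  }
  wcsv(study$sweep$cells, paths[["cells"]])
  wcsv(study$sweep$results, paths[["results"]])
  wcsv(st$omnibus, paths[["omnibus"]],
       empty("activity", "bin_deg", "variable", "route", "test", "statistic",
             "p", "effect_name", "effect_value", "n", "n_excluded"))
  wcsv(st$posthoc, paths[["posthoc"]],
       empty("activity", "bin_deg", "variable", "scenario", "statistic",
             "p_raw", "p_bonferroni", "direction"))
  wcsv(st$correlations, paths[["correlations"]],
       empty("activity", "bin_deg", "muscle", "method", "rho", "p", "n",
             "classification", "note", "p_adj"))
  writeLines(study_report(study, st), paths[["report"]])
  manifest <- list(
    package = "glenosim",
    version = as.character(utils::packageVersion("glenosim")),
    master_seed = config$master_seed,
    config = unclass(config),
    n_cells = nrow(study$sweep$cells),
    n_infeasible = study$sweep$n_infeasible
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(list(study = study, stats = st, paths = paths))
}

# Compact Markdown report: per activity/variable, which bins changed
# significantly in which direction, mirroring significance-bar summaries.
study_report <- function(study, st) {
  lines <- c("# Synthetic rotator-cuff-tear study report", "",
             sprintf("- participants: %d, trials: %d, seed: %d",
                     study$cohort$n, study$config$n_trials,
                     study$config$master_seed),
             sprintf("- cells: %d, infeasible: %d", nrow(study$sweep$cells),
                     study$sweep$n_infeasible), "")
  if (is.null(st$omnibus)) {
    return(c(lines, paste("Statistics skipped:", st$note)))
  }
  ph <- st$posthoc
  sig <- ph[ph$p_bonferroni < 0.05, ]
  lines <- c(lines, "## Significant scenario-vs-intact changes (Bonferroni p < 0.05)", "")
  if (nrow(sig) == 0) {
    lines <- c(lines, "none")
  } else {
    for (v in unique(sig$variable)) {
      sv <- sig[sig$variable == v, ]
      for (a in unique(sv$activity)) {
        sa <- sv[sv$activity == a, ]
        for (dir in c("increase", "decrease")) {
          sd_ <- sa[sa$direction == dir, ]
          if (nrow(sd_) == 0) next
          bins <- sort(unique(sd_$bin_deg))
          scn <- sort(unique(sd_$scenario))
          lines <- c(lines, sprintf("- %s / %s: %s at %s deg (%s)", v, a, dir,
                                    paste(bins, collapse = ","),
                                    paste(scn, collapse = ", ")))
        }
      }
    }
  }
  if (!is.null(st$correlations)) {
    comp <- st$correlations[st$correlations$classification == "compensatory", ]
    lines <- c(lines, "", "## Compensatory classifications (negative delta-correlation)", "")
    if (nrow(comp) == 0) lines <- c(lines, "none") else {
      for (i in seq_len(nrow(comp))) {
        lines <- c(lines, sprintf("- %s / %s at %d deg: rho = %.2f (p_adj = %.3g)",
                                  comp$muscle[i], comp$activity[i],
                                  comp$bin_deg[i], comp$rho[i], comp$p_adj[i]))
      }
    }
  }
  lines
}

#' Write a miniature deterministic study to disk
#'
#' A reduced study (3 participants, 2 trials, two activities, three
#' scenarios) whose artifacts the test suite and examples can load; the same
#' seed always writes an identical tree.
#'
#' @param seed Master seed.
#' @param dir Output directory.
#' @return Invisibly, the artifact paths.
#' @export
make_fixtures <- function(seed = 1, dir) {
  cfg <- study_config(master_seed = seed, n_participants = 3, n_trials = 2,
                      activities = c("Flexion", "UpL"),
                      scenarios = c("Intact", "S0", "S0/IS25/SS50"))
  out <- run_study(cfg, dir)
  co <- out$study$cohort
  cohort_df <- data.frame(
    id = vapply(co$participants, `[[`, "", "id"),
    mass_kg = vapply(co$participants, `[[`, 0, "mass"),
    height_m = vapply(co$participants, `[[`, 0, "height"),
    motor_noise_deg = vapply(co$participants, `[[`, 0, "motor_noise_scale")
  )
  utils::write.csv(cohort_df, file.path(dir, "cohort.csv"), row.names = FALSE)
  tr <- generate_trajectory("Flexion", co$participants[[1]],
                            seed = derive_seed(derive_seed(derive_seed(seed, 2L), 11L, 1L, 1L), 1L))
  utils::write.csv(as.data.frame(tr), file.path(dir, "trajectory_example.csv"),
                   row.names = FALSE)
  invisible(c(out$paths, cohort = file.path(dir, "cohort.csv"),
              trajectory = file.path(dir, "trajectory_example.csv")))
}
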