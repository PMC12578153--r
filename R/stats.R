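# Repeated-measures statistical battery: Shapiro-Wilk gated omnibus tests per
# elevation bin, Bonferroni-corrected post hoc comparisons against the intact
# model, effect sizes, and delta-correlation classification of compensatory
# muscles.

#' Choose the parametric or nonparametric route for a cell
#'
#' Applies the Shapiro-Wilk test to each scenario's sample of participant
#' values; the parametric route (RM-ANOVA, paired t) is taken only if every
#' sample is compatible with normality at p >= 0.05, otherwise the rank-based
#' route (Friedman, Wilcoxon signed-rank) is used. Constant samples, for which
#' Shapiro-Wilk is undefined, force the nonparametric route with a degeneracy
#' note.
#'
#' @param cell_data Numeric matrix, participants x scenarios.
#' @param alpha Normality threshold (default 0.05).
#' @return List with `route` ("parametric"/"nonparametric"), per-scenario
#'   `shapiro_p`, and `degenerate` flags.
#' @export
normality_gate <- function(cell_data, alpha = 0.05) {
  cell_data <- as.matrix(cell_data)
  if (nrow(cell_data) < 3) stop("normality gate needs at least 3 values per scenario")
  k <- ncol(cell_data)
  p <- rep(NA_real_, k)
  degen <- logical(k)
  for (j in seq_len(k)) {
    x <- cell_data[, j]
    if (stats::sd(x) < 1e-12 * max(1, abs(mean(x)))) {
      degen[j] <- TRUE
    } else {
      p[j] <- stats::shapiro.test(x)$p.value
    }
  }
  route <- if (any(degen) || any(p < alpha, na.rm = TRUE)) "nonparametric" else "parametric"
  names(p) <- colnames(cell_data)
  list(route = route, shapiro_p = p, degenerate = degen)
}

#' Omnibus repeated-measures test across scenarios
#'
#' Parametric route: one-way repeated-measures ANOVA (scenario as the
#' within-subject factor), with plain eta squared
#' (`SS_scenario / (SS_scenario + SS_subject + SS_error)`). Nonparametric
#' route: Friedman chi-squared with Kendall's
#' `W = chi^2 / (n (k - 1))`.
#'
#' @param cell_data Numeric matrix, participants x scenarios (complete block:
#'   no missing values).
#' @param route "parametric" or "nonparametric", from [normality_gate()].
#' @return List: `test`, `statistic`, `df`, `p`, `effect_name`,
#'   `effect_value`.
#' @export
omnibus <- function(cell_data, route) {
  cell_data <- as.matrix(cell_data)
  if (anyNA(cell_data)) {
    stop("omnibus requires complete blocks; resolve aborted cells upstream")
  }
  n <- nrow(cell_data); k <- ncol(cell_data)
  if (k < 2) stop("omnibus needs at least 2 scenarios")
  if (route == "parametric") {
    df <- data.frame(
      y = as.vector(cell_data),
      scenario = factor(rep(colnames(cell_data) %||% seq_len(k), each = n)),
      subject = factor(rep(seq_len(n), times = k))
    )
    fit <- stats::aov(y ~ scenario + Error(subject), data = df)
    sm <- summary(fit)
    within <- sm[["Error: Within"]][[1]]
    subj <- sm[["Error: subject"]][[1]]
    rw <- trimws(rownames(within)); rs <- trimws(rownames(subj))
    ss_eff <- within[rw == "scenario", "Sum Sq"]
    ss_err <- within[rw == "Residuals", "Sum Sq"]
    ss_subj <- subj[rs == "Residuals", "Sum Sq"]
    Fv <- within[rw == "scenario", "F value"]
    p <- within[rw == "scenario", "Pr(>F)"]
    if (ss_eff < 1e-24 * max(1, ss_subj)) { # no scenario effect at all
      Fv <- 0; p <- 1
    }
    ss_tot <- ss_eff + ss_err + ss_subj
    list(test = "rm_anova", statistic = unname(Fv),
         df = c(within[rw == "scenario", "Df"], within[rw == "Residuals", "Df"]),
         p = unname(p), effect_name = "eta_squared",
         effect_value = if (ss_tot > 0) unname(ss_eff / ss_tot) else 0)
  } else {
    spread <- apply(cell_data, 1, function(r) max(r) - min(r))
    if (all(spread < 1e-12)) { # every block tied: no effect, chi^2 of 0
      return(list(test = "friedman", statistic = 0, df = k - 1, p = 1,
                  effect_name = "kendalls_w", effect_value = 0))
    }
    ft <- stats::friedman.test(cell_data)
    chi <- unname(ft$statistic)
    list(test = "friedman", statistic = chi, df = unname(ft$parameter),
         p = unname(ft$p.value), effect_name = "kendalls_w",
         effect_value = chi / (n * (k - 1)))
  }
}

#' Post hoc comparisons of each tear scenario against the intact model
#'
#' Paired t-tests (parametric route) or Wilcoxon signed-rank tests
#' (nonparametric route) of every non-intact scenario against the intact one,
#' with Bonferroni adjustment over the number of comparisons
#' (`p_adj = min(1, m * p_raw)`).
#'
#' @param cell_data Numeric matrix, participants x scenarios; one column must
#'   be the intact reference.
#' @param route "parametric" or "nonparametric".
#' @param intact Name of the reference column (default "Intact").
#' @return data.frame: `scenario`, `statistic`, `p_raw`, `p_bonferroni`,
#'   `direction` ("increase"/"decrease"/"none" of the scenario mean relative
#'   to intact).
#' @export
posthoc_vs_intact <- function(cell_data, route, intact = "Intact") {
  cell_data <- as.matrix(cell_data)
  if (!intact %in% colnames(cell_data)) {
    stop("intact reference column '", intact, "' not found")
  }
  ref <- cell_data[, intact]
  others <- setdiff(colnames(cell_data), intact)
  m <- length(others)
  out <- lapply(others, function(sc) {
    d <- cell_data[, sc] - ref
    if (all(abs(d) < 1e-12)) {
      return(data.frame(scenario = sc, statistic = 0, p_raw = 1,
                        p_bonferroni = 1, direction = "none"))
    }
    if (route == "parametric") {
      tt <- stats::t.test(cell_data[, sc], ref, paired = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      wt <- stats::wilcox.test(cell_data[, sc], ref, paired = TRUE,
                               exact = FALSE, correct = TRUE)
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(scenario = sc, statistic = stat, p_raw = p,
               p_bonferroni = min(1, m * p),
               direction = if (mean(d) > 0) "increase" else "decrease")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Delta-correlation of a muscle's force change with stability change
#'
#' Pairs, across participants and tear scenarios at one activity and bin, the
#' change in a muscle's normalized force against the change in stability
#' (both relative to the intact model). Pearson's correlation is used when
#' both margins pass Shapiro-Wilk normality, Spearman's otherwise. A negative
#' correlation significant at p < 0.05 (force rises as stability falls) is
#' classified `compensatory`.
#'
#' @param results A `glenosim_results` or its long results table.
#' @param muscle Muscle name.
#' @param activity Activity name.
#' @param bin Bin centre, deg.
#' @param alpha Significance level for classification.
#' @return One-row data.frame: `activity`, `bin_deg`, `muscle`, `method`,
#'   `rho`, `p`, `n`, `classification`, `note`.
#' @export
delta_correlation <- function(results, muscle, activity, bin, alpha = 0.05) {
  tab <- if (inherits(results, "glenosim_results")) results$results else results
  sub <- tab[tab$muscle == muscle & tab$activity == activity &
               tab$bin_deg == bin, ]
  if (nrow(sub) == 0) stop("no rows for ", muscle, " / ", activity, " / ", bin)
  intact <- sub[sub$scenario == "Intact", ]
  ref_st <- stats::setNames(intact$stability, intact$participant)
  ref_f <- stats::setNames(intact$force_N_per_kg, intact$participant)
  oth <- sub[sub$scenario != "Intact", ]
  d_stab <- oth$stability - ref_st[oth$participant]
  d_force <- oth$force_N_per_kg - ref_f[oth$participant]
  ok <- !is.na(d_stab) & !is.na(d_force)
  d_stab <- d_stab[ok]; d_force <- d_force[ok]
  if (length(d_stab) < 3) stop("fewer than 3 paired delta observations")
  row <- data.frame(activity = activity, bin_deg = bin, muscle = muscle,
                    method = NA_character_, rho = NA_real_, p = NA_real_,
                    n = length(d_stab), classification = "none", note = "")
  if (stats::sd(d_stab) < 1e-12 || stats::sd(d_force) < 1e-12) {
    row$note <- "degenerate: zero-variance margin"
    return(row)
  }
  sw <- function(x) tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  method <- if (sw(d_stab) >= alpha && sw(d_force) >= alpha) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(d_force, d_stab, method = method,
                                         exact = FALSE))
  row$method <- method
  row$rho <- unname(ct$estimate)
  row$p <- ct$p.value
  if (!is.na(row$rho) && row$rho < 0 && row$p < alpha) {
    row$classification <- "compensatory"
  } else if (!is.na(row$rho) && row$rho > 0 && row$p < alpha) {
    row$classification <- "co-varying"
  }
  row
}

#' Classify compensatory muscles across bins
#'
#' Runs [delta_correlation()] for the humeral-head depressor muscles at every
#' activity and bin and classifies each muscle after a Bonferroni adjustment
#' across the muscles tested within the same (activity, bin) family.
#'
#' @param results A `glenosim_results` or its long results table.
#' @param muscles Muscles tested (default the depressors ISP, SSC, Tm, LHB).
#' @param alpha Family significance level.
#' @param p_adjust "bonferroni" (default) or "none".
#' @return data.frame of [delta_correlation()] rows with `p_adj` and
#'   family-corrected `classification`.
#' @export
classify_compensation <- function(results,
                                  muscles = c("ISP", "SSC", "Tm", "LHB"),
                                  alpha = 0.05, p_adjust = "bonferroni") {
  tab <- if (inherits(results, "glenosim_results")) results$results else results
  combos <- unique(tab[tab$muscle == tab$muscle[1], c("activity", "bin_deg")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    fam <- lapply(muscles, function(m) {
      tryCatch(delta_correlation(tab, m, combos$activity[i], combos$bin_deg[i],
                                 alpha = alpha),
               error = function(e) NULL)
    })
    fam <- do.call(rbind, fam[!vapply(fam, is.null, TRUE)])
    if (is.null(fam)) next
    mult <- if (p_adjust == "bonferroni") nrow(fam) else 1
    fam$p_adj <- pmin(1, fam$p * mult)
    fam$classification <- ifelse(
      !is.na(fam$rho) & fam$rho < 0 & fam$p_adj < alpha, "compensatory",
      ifelse(!is.na(fam$rho) & fam$rho > 0 & fam$p_adj < alpha, "co-varying",
             "none"))
    out[[length(out) + 1]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full statistical battery over sweep results
#'
#' For every (activity, bin) and every variable (stability and each muscle's
#' normalized force): gates on normality, runs the omnibus repeated-measures
#' test with its effect size, and the Bonferroni-corrected post hoc
#' comparisons against the intact model. Participants with aborted cells are
#' excluded from that cell (complete-block requirement) and counted.
#'
#' @param results A `glenosim_results` from [tear_severity_sweep()].
#' @param variables Variables to analyze; default stability plus every muscle.
#' @param cor_muscles Muscles for the delta-correlation stage.
#' @return An object of class `glenosim_stats` with `$omnibus`, `$posthoc`,
#'   and `$correlations` tables.
#' @export
analyze_study <- function(results,
                          variables = NULL,
                          cor_muscles = c("ISP", "SSC", "Tm", "LHB")) {
  tab <- if (inherits(results, "glenosim_results")) results$results else results
  muscles <- unique(tab$muscle)
  scenarios <- unique(tab$scenario)
  if (length(scenarios) < 2 || !"Intact" %in% scenarios) {
    out <- structure(list(omnibus = NULL, posthoc = NULL, correlations = NULL,
                          note = "nothing to compare: need Intact plus at least one tear scenario"),
                     class = "glenosim_stats")
    return(out)
  }
  if (is.null(variables)) variables <- c("stability", muscles)
  combos <- unique(tab[tab$muscle == muscles[1], c("activity", "bin_deg")])
  omn <- list(); ph <- list()
  for (i in seq_len(nrow(combos))) {
    act <- combos$activity[i]; bin <- combos$bin_deg[i]
    for (v in variables) {
      cm <- cell_matrix(tab, v, act, bin, scenarios)
      n_excl <- attr(cm, "n_excluded")
      if (is.null(cm) || nrow(cm) < 3) next
      gate <- normality_gate(cm)
      ob <- omnibus(cm, gate$route)
      pc <- posthoc_vs_intact(cm, gate$route)
      omn[[length(omn) + 1]] <- data.frame(
        activity = act, bin_deg = bin, variable = v, route = gate$route,
        test = ob$test, statistic = ob$statistic, p = ob$p,
        effect_name = ob$effect_name, effect_value = ob$effect_value,
        n = nrow(cm), n_excluded = n_excl)
      pc$activity <- act; pc$bin_deg <- bin; pc$variable <- v
      ph[[length(ph) + 1]] <- pc
    }
  }
  omn <- do.call(rbind, omn)
  ph <- do.call(rbind, ph)
  if (!is.null(ph)) {
    ph <- ph[, c("activity", "bin_deg", "variable", "scenario", "statistic",
                 "p_raw", "p_bonferroni", "direction")]
  }
  cors <- tryCatch(classify_compensation(tab, muscles = cor_muscles),
                   error = function(e) NULL)
  note <- if (is.null(omn)) {
    "no cells with at least 3 complete participants"
  } else ""
  structure(list(omnibus = omn, posthoc = ph, correlations = cors, note = note),
            class = "glenosim_stats")
}

# Participants x scenarios matrix for one variable at one activity/bin;
# participants with any missing scenario value are dropped (complete blocks).
cell_matrix <- function(tab, variable, activity, bin, scenarios) {
  if (variable == "stability") {
    sub <- tab[tab$activity == activity & tab$bin_deg == bin &
                 tab$muscle == tab$muscle[1], ]
    val <- sub$stability
  } else {
    sub <- tab[tab$activity == activity & tab$bin_deg == bin &
                 tab$muscle == variable, ]
    val <- sub$force_N_per_kg
  }
  if (nrow(sub) == 0) return(NULL)
  parts <- sort(unique(sub$participant))
  cm <- matrix(NA_real_, nrow = length(parts), ncol = length(scenarios),
               dimnames = list(parts, scenarios))
  cm[cbind(match(sub$participant, parts), match(sub$scenario, scenarios))] <- val
  complete <- stats::complete.cases(cm)
  out <- cm[complete, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!complete)
  out
}

#' @export
print.glenosim_stats <- function(x, ...) {
  if (is.null(x$omnibus)) {
    cat("<glenosim_stats>", x$note, "\n")
    return(invisible(x))
  }
  cat("<glenosim_stats>", nrow(x$omnibus), "omnibus cells,",
      nrow(x$posthoc), "post hoc comparisons\n")
  sig <- x$posthoc[x$posthoc$p_bonferroni < 0.05, ]
  cat("  significant post hoc (Bonferroni p < 0.05):", nrow(sig), "\n")
  if (!is.null(x$correlations)) {
    comp <- x$correlations[x$correlations$classification == "compensatory", ]
    cat("  compensatory classifications:", nrow(comp),
        if (nrow(comp) > 0) paste0("(", paste(sort(unique(comp$muscle)),
                                              collapse = ", "), ")") else "", "\n")
  }
  invisible(x)
}
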