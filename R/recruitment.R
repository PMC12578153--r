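# Static-optimization muscle recruitment: minimize the sum of cubed muscle
# load ratios subject to moment equilibrium and the glenoid containment
# constraint on the joint reaction force.

#' Build a recruitment problem
#'
#' Collects the quantities the per-posture recruitment optimization needs:
#' the moment-arm matrix, the required net moment, post-tear maximum
#' strengths, lines of action, the non-muscular force transmitted at the
#' joint, and the glenoid ellipse.
#'
#' @param R 3 x n moment-arm matrix, m.
#' @param M_net Required net moment 3-vector, N m.
#' @param f_max Maximum strengths, N (after tear scaling), length n.
#' @param U 3 x n line-of-action matrix, unit columns.
#' @param F_ext Non-muscular force at the joint (gravity/load reaction), N.
#' @param glenoid A [glenoid_ellipse()], or `NULL` to drop the containment
#'   constraint.
#' @param joint_center Glenohumeral centre, m.
#' @return A list of class `recruitment_problem`.
#' @export
recruitment_problem <- function(R, M_net, f_max, U, F_ext = c(0, 0, 0),
                                glenoid = NULL, joint_center = c(0, 0, 0)) {
  n <- length(f_max)
  stopifnot(ncol(R) == n, ncol(U) == n, nrow(R) == 3, nrow(U) == 3)
  if (any(f_max < 0)) stop("f_max must be non-negative")
  un <- sqrt(colSums(U^2))
  if (any(f_max > 0 & abs(un - 1) > 1e-6)) {
    stop("columns of U must be unit vectors")
  }
  structure(list(R = R, M_net = as.numeric(M_net), f_max = as.numeric(f_max),
                 U = U, F_ext = as.numeric(F_ext), glenoid = glenoid,
                 joint_center = as.numeric(joint_center)),
            class = "recruitment_problem")
}

# Glenoid cone coefficients: the containment of the joint-reaction
# intersection inside the ellipse, multiplied through by the (negative) normal
# component of the glenoid-directed force w, is the convex cone constraint
#   sqrt(xA(w)^2 + xS(w)^2) + n.w <= 0,
# with xA, xS linear in w. Returns the two linear forms as rows.
cone_coefs <- function(glenoid, joint_center) {
  a <- glenoid$ap_diameter_mm / 2000 # semi-axes, m
  b <- glenoid$si_diameter_mm / 2000
  nrm <- glenoid$normal
  h <- sum((glenoid$center_m - joint_center) * nrm)
  oA <- sum((joint_center - glenoid$center_m) * glenoid$ap_axis)
  oS <- sum((joint_center - glenoid$center_m) * glenoid$si_axis)
  LA <- (oA * nrm + h * glenoid$ap_axis) / a
  LS <- (oS * nrm + h * glenoid$si_axis) / b
  list(LA = LA, LS = LS, n = nrm)
}

#' Solve the muscle-recruitment optimization at one posture
#'
#' Minimizes the sum of cubed muscle loads, `sum((f_i / f_max_i)^3)`, over
#' `0 <= f <= f_max`, subject to moment equilibrium `R f = M_net` and, when a
#' glenoid is present, the requirement that the joint reaction force pass
#' through the glenoid ellipse (a convex cone constraint on the muscle
#' forces). Solved by an augmented-Lagrangian outer loop around box-constrained
#' L-BFGS-B inner minimizations with analytic gradients; the problem is convex,
#' so the optimum is unique whenever `f_max > 0`.
#'
#' Muscles with `f_max = 0` (fully torn) are removed from the optimization and
#' reported with zero force. When no feasible activation exists the solution
#' is flagged `feasible = FALSE` with an `aborted_reason`, mirroring the abort
#' of a simulation whose joint reaction force leaves the glenoid.
#'
#' @param problem A [recruitment_problem()].
#' @param tol Relative feasibility/optimality tolerance.
#' @param warm Optional warm start: a previous solution's `warm` field.
#' @param max_outer Maximum augmented-Lagrangian outer iterations.
#' @return A list of class `recruitment_solution`: muscle forces `f` (N),
#'   `activations`, joint reaction force `jrf` (N), `feasible`,
#'   `aborted_reason`, the objective value, the equilibrium residual, and a
#'   `warm` field for chaining solves along a trajectory.
#' @export
solve_recruitment <- function(problem, tol = 1e-8, warm = NULL,
                              max_outer = 60) {
  p <- problem
  n_all <- length(p$f_max)
  active <- p$f_max > 0
  fmax <- p$f_max[active]
  n <- length(fmax)
  R <- p$R[, active, drop = FALSE]
  U <- p$U[, active, drop = FALSE]
  M <- p$M_net
  F_ext <- p$F_ext
  Mscale <- max(1, vnorm(M))
  Fscale <- max(1, vnorm(F_ext), max(fmax) / 100)

  cone <- if (!is.null(p$glenoid)) cone_coefs(p$glenoid, p$joint_center) else NULL
  if (!is.null(cone)) {
    # linear forms in f: xA = cA . f + dA etc.
    cA <- as.numeric(crossprod(U, cone$LA)); dA <- sum(cone$LA * F_ext)
    cS <- as.numeric(crossprod(U, cone$LS)); dS <- sum(cone$LS * F_ext)
    cn <- as.numeric(crossprod(U, cone$n)); dn <- sum(cone$n * F_ext)
  }
  gval <- function(f) {
    xA <- sum(cA * f) + dA; xS <- sum(cS * f) + dS
    q <- sqrt(xA^2 + xS^2 + 1e-12)
    list(g = q + sum(cn * f) + dn, xA = xA, xS = xS, q = q)
  }

  if (n == 0) {
    feas_eq <- vnorm(M) <= tol * Mscale
    g0 <- if (!is.null(cone)) gval(numeric(0))$g else -Inf
    ok <- feas_eq && g0 <= tol * Fscale
    return(finish_solution(p, numeric(n_all), active, ok,
                           if (ok) "" else "no active muscles can balance the demand",
                           warm = NULL, tol = tol))
  }

  c3 <- 1 / fmax^3
  f <- if (!is.null(warm) && length(warm$f) == n) pmin(pmax(warm$f, 0), fmax)
       else pmin(fmax * 0.05, 10)
  lam <- if (!is.null(warm)) warm$lam else numeric(3)
  mu <- if (!is.null(warm)) warm$mu else 0
  rho <- 100

  h_res <- g_res <- Inf
  for (outer in seq_len(max_outer)) {
    objfn <- function(f) {
      h <- as.numeric(R %*% f) - M
      val <- sum(c3 * f^3) + sum(lam * h) + 0.5 * rho * sum(h^2)
      if (!is.null(cone)) {
        pg <- max(0, mu + rho * gval(f)$g)
        val <- val + (pg^2 - mu^2) / (2 * rho)
      }
      val
    }
    gradfn <- function(f) {
      h <- as.numeric(R %*% f) - M
      gg <- 3 * c3 * f^2 + as.numeric(crossprod(R, lam + rho * h))
      if (!is.null(cone)) {
        gw <- gval(f)
        pg <- max(0, mu + rho * gw$g)
        if (pg > 0) gg <- gg + pg * (gw$xA * cA / gw$q + gw$xS * cS / gw$q + cn)
      }
      gg
    }
    opt <- stats::optim(f, objfn, gradfn, method = "L-BFGS-B",
                        lower = rep(0, n), upper = fmax,
                        control = list(maxit = 500, factr = 10))
    f <- opt$par
    h <- as.numeric(R %*% f) - M
    h_res <- max(abs(h))
    g_res <- if (!is.null(cone)) gval(f)$g else -Inf
    if (h_res <= tol * Mscale && g_res <= tol * Fscale) {
      f_all <- numeric(n_all); f_all[active] <- f
      return(finish_solution(p, f_all, active, TRUE, "",
                             warm = list(f = f, lam = lam, mu = mu), tol = tol))
    }
    lam <- lam + rho * h
    if (!is.null(cone)) mu <- max(0, mu + rho * g_res)
    rho <- min(rho * 4, 1e10)
  }

  # Did not converge: decide between genuine infeasibility and numerical
  # failure by minimizing pure constraint violation.
  viol <- function(f) {
    h <- as.numeric(R %*% f) - M
    v <- sum((h / Mscale)^2)
    if (!is.null(cone)) v <- v + max(0, gval(f)$g / Fscale)^2
    v
  }
  best <- Inf
  for (f0 in list(numeric(n), fmax / 2, fmax)) {
    fv <- stats::optim(f0, viol, method = "L-BFGS-B", lower = rep(0, n),
                       upper = fmax, control = list(maxit = 1000))
    best <- min(best, fv$value)
  }
  if (sqrt(best) > 100 * tol) {
    f_all <- numeric(n_all); f_all[active] <- f
    reason <- sprintf(paste0("infeasible: no activation satisfies the demand ",
                             "(best constraint violation %.3g; equilibrium residual %.3g, ",
                             "glenoid margin %.3g)"), sqrt(best), h_res, g_res)
    return(finish_solution(p, f_all, active, FALSE, reason, warm = NULL, tol = tol))
  }
  stop(structure(class = c("glenosim_numerical_error", "error", "condition"),
                 list(message = sprintf(paste0("recruitment solver failed to converge on a ",
                                               "feasible problem (residuals %.3g / %.3g)"),
                                        h_res, g_res),
                      call = sys.call(-1))))
}

finish_solution <- function(problem, f, active, feasible, reason, warm, tol) {
  fmax <- problem$f_max
  act <- ifelse(fmax > 0, f / pmax(fmax, .Machine$double.eps), 0)
  jrf <- compute_jrf(f, problem$U, problem$F_ext)
  res <- as.numeric(problem$R %*% f) - problem$M_net
  structure(list(
    f = stats::setNames(f, colnames(problem$R)),
    activations = stats::setNames(act, colnames(problem$R)),
    jrf = jrf,
    feasible = feasible,
    aborted_reason = reason,
    objective = sum((f[fmax > 0] / fmax[fmax > 0])^3),
    equilibrium_residual = vnorm(res) / max(1, vnorm(problem$M_net)),
    warm = warm,
    tol = tol
  ), class = "recruitment_solution")
}

#' Joint reaction force from muscle forces
#'
#' The reaction transmitted at the glenohumeral joint that balances the muscle
#' pulls and the non-muscular load: `jrf = -(U f + F_ext)`, in the
#' ISB-style scapular frame.
#'
#' @param f Muscle force vector, N.
#' @param U 3 x n line-of-action matrix.
#' @param F_ext Non-muscular force at the joint, N.
#' @return Joint reaction force 3-vector, N.
#' @export
compute_jrf <- function(f, U, F_ext = c(0, 0, 0)) {
  as.numeric(-(U %*% f + F_ext))
}

#' @export
print.recruitment_solution <- function(x, ...) {
  cat("<recruitment_solution>", if (x$feasible) "feasible" else
    paste("ABORTED:", x$aborted_reason), "\n")
  cat("  objective sum((f/fmax)^3) =", signif(x$objective, 5),
      " equilibrium residual =", signif(x$equilibrium_residual, 3), "\n")
  print(round(x$f, 2))
  invisible(x)
}

#' Run the full tear-severity sweep
#'
#' For every participant, trial, scenario, and 10-degree elevation bin of the
#' requested activities: generates the synthetic trajectory, computes the
#' quasi-static net moment, solves the recruitment optimization, and evaluates
#' glenohumeral stability. Muscle forces are normalized to each participant's
#' body mass (N/kg) and averaged over trials.
#'
#' @param model A `shoulder_model` (intact strengths).
#' @param activities Character vector of activity names (default all six).
#' @param scenarios Character vector of scenario names (default all eight).
#' @param cohort A cohort from [generate_cohort()].
#' @param n_trials Trials per participant and activity.
#' @param seed Master seed for trajectory noise.
#' @param tol Solver tolerance.
#' @return An object of class `glenosim_results`: `$cells` (trial-level wide
#'   table), `$results` (trial-mean long table: activity, scenario,
#'   participant, bin_deg, muscle, force_N_per_kg, jrf components, stability,
#'   feasible), and `$n_infeasible`.
#' @export
tear_severity_sweep <- function(model, activities = names(activity_registry()),
                                scenarios = names(tear_scenarios()),
                                cohort, n_trials = cohort$n_trials %||% 5,
                                seed = cohort$seed %||% 1, tol = 1e-8) {
  reg <- tear_scenarios()
  unknown <- setdiff(scenarios, names(reg))
  if (length(unknown) > 0) stop("unknown scenario(s): ", paste(unknown, collapse = ", "))
  scen_list <- reg[scenarios]
  fmax0 <- fmax_vector(model)
  m_names <- model$muscle_names
  scen_fmax <- lapply(scen_list, function(s) {
    fr <- stats::setNames(rep(1, length(m_names)), m_names)
    fr[names(s$fractions)] <- s$fractions
    fmax0 * fr
  })

  rows <- vector("list", 50000L)
  nr <- 0L
  for (pi in seq_along(cohort$participants)) {
    part <- cohort$participants[[pi]]
    for (ai in seq_along(activities)) {
      act <- get_activity(activities[ai])
      trials <- generate_trials(part, act, n_trials,
                                seed = derive_seed(seed, 11L, pi, ai))
      for (ti in seq_len(n_trials)) {
        traj <- trials[[ti]]
        bins <- bin_by_elevation(
          traj, traj[, c("elevation_deg", "plane_deg", "rotation_deg", "load_kg")], act)
        # moment arms / lines of action are scenario-independent: build once
        geo <- lapply(seq_len(nrow(bins)), function(bi) {
          po <- make_posture(model, bins$elevation_deg[bi], bins$plane_deg[bi],
                             bins$rotation_deg[bi])
          list(posture = po,
               R = moment_arm_matrix(model, po),
               U = line_of_action_matrix(model, po),
               M = net_moments(model, po, part, bins$load_kg[bi]),
               F_ext = external_joint_force(po, part, bins$load_kg[bi]))
        })
        for (si in seq_along(scen_list)) {
          fmax_s <- scen_fmax[[si]]
          warm <- NULL
          for (bi in seq_len(nrow(bins))) {
            g <- geo[[bi]]
            prob <- recruitment_problem(g$R, g$M, fmax_s, g$U, g$F_ext,
                                        glenoid = model$glenoid,
                                        joint_center = model$joint_center)
            sol <- solve_recruitment(prob, tol = tol, warm = warm)
            warm <- sol$warm
            st <- NA_real_
            if (sol$feasible) {
              p2 <- glenoid_intersection(sol$jrf, model$glenoid, model$joint_center)
              st <- stability_index(p2, model$glenoid, clamp_tol = 1e-4)
            }
            nr <- nr + 1L
            if (nr > length(rows)) rows <- c(rows, vector("list", 50000L))
            rows[[nr]] <- c(list(activity = act$name,
                                 scenario = scen_list[[si]]$name,
                                 participant = part$id, trial = ti,
                                 bin_deg = bins$bin_deg[bi],
                                 mass_kg = part$mass,
                                 feasible = sol$feasible,
                                 eq_residual = sol$equilibrium_residual,
                                 stability = as.numeric(st),
                                 jrf_x = sol$jrf[1], jrf_y = sol$jrf[2],
                                 jrf_z = sol$jrf[3]),
                            as.list(sol$f / part$mass))
          }
        }
      }
    }
  }
  rows <- rows[seq_len(nr)]
  cols <- names(rows[[1]])
  cells <- as.data.frame(lapply(stats::setNames(cols, cols), function(k)
    unlist(lapply(rows, `[[`, k), use.names = FALSE)),
    check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(
    cells = cells,
    results = summarize_cells(cells, m_names),
    muscles = m_names,
    n_infeasible = sum(!cells$feasible)
  ), class = "glenosim_results")
}

# Collapse trial-level cells to participant-level 5-trial means and reshape to
# the long results schema. Infeasible trials are excluded from the means and
# counted; a cell is flagged infeasible if any of its trials aborted.
summarize_cells <- function(cells, muscles) {
  key <- interaction(cells$activity, cells$scenario, cells$participant,
                     cells$bin_deg, drop = TRUE)
  agg <- function(v, f) tapply(v, key, f)
  first <- function(v) agg(v, function(x) x[1])
  feas <- agg(cells$feasible, all)
  n_excl <- agg(cells$feasible, function(x) sum(!x))
  mean_feas <- function(v) {
    out <- tapply(seq_along(v), key, function(ix) {
      ok <- cells$feasible[ix]
      if (!any(ok)) NA_real_ else mean(v[ix][ok])
    })
    as.numeric(out)
  }
  base <- data.frame(
    activity = as.character(first(cells$activity)),
    scenario = as.character(first(cells$scenario)),
    participant = as.character(first(cells$participant)),
    bin_deg = as.numeric(first(cells$bin_deg)),
    stability = mean_feas(cells$stability),
    jrf_x = mean_feas(cells$jrf_x), jrf_y = mean_feas(cells$jrf_y),
    jrf_z = mean_feas(cells$jrf_z),
    feasible = as.logical(feas),
    n_trials_excluded = as.numeric(n_excl),
    stringsAsFactors = FALSE
  )
  long <- do.call(rbind, lapply(muscles, function(m) {
    df <- base
    df$muscle <- m
    df$force_N_per_kg <- mean_feas(cells[[m]])
    df
  }))
  long <- long[, c("activity", "scenario", "participant", "bin_deg", "muscle",
                   "force_N_per_kg", "jrf_x", "jrf_y", "jrf_z", "stability",
                   "feasible", "n_trials_excluded")]
  rownames(long) <- NULL
  long
}
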