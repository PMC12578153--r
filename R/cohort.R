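# Synthetic participant cohort: anthropometrics, per-trial motor variability,
# and ground-truth compensation injection for power-testing the statistics.

#' Generate a virtual participant cohort
#'
#' Draws participant masses and heights from truncated normal distributions
#' matching a cohort of young healthy adult males (mass 63.5 +/- 7.1 kg,
#' height 1.715 +/- 0.063 m, truncated at +/- 3 SD), derives arm segment
#' parameters from standard anthropometric proportions, and assigns each
#' participant a motor-noise scale governing trial-to-trial kinematic
#' variability.
#'
#' @param n Number of participants (default 15; at least 2, or the
#'   repeated-measures statistics are undefined).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param anthropometrics List of `mass_kg`, `mass_sd_kg`, `height_m`,
#'   `height_sd_m`, `noise_deg`, `noise_sd_deg`.
#' @param n_trials Default trials per activity carried by the cohort.
#' @return An object of class `glenosim_cohort`.
#' @export
#' @examples
#' co <- generate_cohort(15, seed = 42)
#' co$participants[[1]]$mass
generate_cohort <- function(n = 15, seed = 1,
                            anthropometrics = list(),
                            n_trials = 5) {
  if (n < 2) stop("a cohort needs at least 2 participants")
  a <- utils::modifyList(list(mass_kg = 63.5, mass_sd_kg = 7.1,
                              height_m = 1.715, height_sd_m = 0.063,
                              noise_deg = 2, noise_sd_deg = 0.5), anthropometrics)
  if (a$mass_sd_kg < 0 || a$height_sd_m < 0) stop("SDs must be non-negative")
  draws <- with_seed(seed, function() {
    list(mass = rnorm_trunc(n, a$mass_kg, a$mass_sd_kg, 3),
         height = rnorm_trunc(n, a$height_m, a$height_sd_m, 3),
         noise = abs(stats::rnorm(n, a$noise_deg, a$noise_sd_deg)))
  })
  participants <- lapply(seq_len(n), function(i) {
    make_participant(id = sprintf("P%02d", i), mass = draws$mass[i],
                     height = draws$height[i],
                     motor_noise_scale = draws$noise[i])
  })
  structure(list(participants = participants, n = n, seed = seed,
                 n_trials = n_trials, anthropometrics = a),
            class = "glenosim_cohort")
}

# Normal draws rejected outside +/- k SD (redrawn deterministically).
rnorm_trunc <- function(n, mean, sd, k) {
  x <- stats::rnorm(n, mean, sd)
  bad <- abs(x - mean) > k * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > k * sd
  }
  x
}

#' Build a participant
#'
#' Arm segment parameters follow standard anthropometric proportions: the
#' whole upper limb is lumped as 5% of body mass with its centre of mass at
#' 16.8% of stature from the shoulder, and a handheld load acts at 35.5% of
#' stature (the hand).
#'
#' @param id Participant identifier.
#' @param mass Body mass, kg.
#' @param height Stature, m.
#' @param motor_noise_scale Trial-to-trial kinematic noise amplitude, deg.
#' @return A participant list.
#' @export
make_participant <- function(id, mass, height, motor_noise_scale = 2) {
  if (mass <= 0 || height <= 0) stop("mass and height must be positive")
  list(id = id, mass = mass, height = height,
       motor_noise_scale = motor_noise_scale,
       arm = list(mass_kg = 0.05 * mass,
                  com_m = 0.168 * height,
                  hand_m = 0.355 * height))
}

#' Generate repeated trials for one participant and activity
#'
#' Each trial shares the participant's base minimum-jerk profile with
#' independent smooth noise (amplitude set by the participant's
#' `motor_noise_scale`); with zero noise all trials are identical.
#'
#' @param participant A participant from [generate_cohort()].
#' @param activity Activity name or definition.
#' @param n_trials Number of trials (default 5).
#' @param seed Integer seed.
#' @return List of `n_trials` trajectories.
#' @export
generate_trials <- function(participant, activity, n_trials = 5, seed = 1) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  lapply(seq_len(n_trials), function(k) {
    generate_trajectory(activity, participant, seed = derive_seed(seed, k))
  })
}

#' Inject a known compensatory structure into sweep results
#'
#' Adds, to the named muscles' normalized forces, increments proportional to
#' each cell's stability loss relative to the intact scenario
#' (`slope * (stability_scenario - stability_intact)`) plus Gaussian noise.
#' A negative slope therefore raises a muscle's force where stability drops,
#' creating a ground-truth negative delta-force/delta-stability correlation
#' that the downstream correlation stage should classify as compensatory.
#' Used to power-test the statistics; intact rows are unchanged.
#'
#' @param results A `glenosim_results` or its long results table.
#' @param effect Named numeric vector of per-muscle slopes (N/kg per unit
#'   stability).
#' @param seed Integer seed for the noise.
#' @param noise_sd Noise standard deviation, N/kg (default 0.3).
#' @return The results table with modified `force_N_per_kg`.
#' @export
inject_compensation_structure <- function(results, effect, seed = 1,
                                          noise_sd = 0.3) {
  tab <- if (inherits(results, "glenosim_results")) results$results else results
  effect <- unlist(effect)
  unknown <- setdiff(names(effect), unique(tab$muscle))
  if (length(unknown) > 0) {
    stop("effect names muscle(s) absent from results: ",
         paste(unknown, collapse = ", "))
  }
  intact <- tab[tab$scenario == "Intact", ]
  key <- function(d) paste(d$activity, d$participant, d$bin_deg, d$muscle)
  stab_intact <- stats::setNames(intact$stability, key(intact))
  d_stab <- tab$stability - stab_intact[key(tab)]
  tab <- with_seed(seed, function() {
    for (m in names(effect)) {
      ix <- which(tab$muscle == m & tab$scenario != "Intact" & !is.na(d_stab))
      tab$force_N_per_kg[ix] <- tab$force_N_per_kg[ix] +
        effect[[m]] * d_stab[ix] + stats::rnorm(length(ix), 0, noise_sd)
    }
    tab
  })
  tab
}

#' @export
print.glenosim_cohort <- function(x, ...) {
  mass <- vapply(x$participants, function(p) p$mass, 0)
  ht <- vapply(x$participants, function(p) p$height, 0)
  cat("<glenosim_cohort>", x$n, "participants,", x$n_trials,
      "trials/activity, seed", x$seed, "\n")
  cat(sprintf("  mass %.1f +/- %.1f kg, height %.3f +/- %.3f m\n",
              mean(mass), stats::sd(mass), mean(ht), stats::sd(ht)))
  invisible(x)
}
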