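# Activity definitions, synthetic elevation trajectories, filtering,
# quasi-static net joint moments, and 10-degree elevation binning.

#' The six activities of daily living
#'
#' Arm elevation (Flexion, Abduction), contralateral shoulder reaching
#' (Shoulder), head reaching (Head), and lifting a 1 kg object between a low
#' and a high shelf (UpL, UpH). Each activity carries its plane of elevation,
#' the elevation range analyzed in 10-degree bins, the handheld load, the
#' movement duration, and an axial-rotation profile (slope per degree of
#' elevation; reaches behind the head rotate externally, cross-body reaches
#' internally).
#'
#' @return Named list of activity definitions.
#' @export
activity_registry <- function() {
  act <- function(name, plane, range, lo, hi, duration, load, rot_slope) {
    list(name = name, plane_of_elevation_deg = plane,
         analysis_range_deg = range,
         traj_start_deg = lo, traj_end_deg = hi,
         duration_s = duration, external_load_kg = load,
         rotation_slope = rot_slope)
  }
  list(
    Flexion   = act("Flexion",   90, c(10, 120),  0, 130, 5.0, 0, 0.00),
    Abduction = act("Abduction",  0, c(10, 120),  0, 130, 5.0, 0, 0.15),
    Shoulder  = act("Shoulder", 120, c(10, 40),   0,  50, 2.5, 0, -0.60),
    Head      = act("Head",      70, c(10, 110),  0, 120, 4.0, 0, 0.12),
    UpL       = act("UpL",       80, c(40, 60),  30,  70, 2.0, 1, 0.00),
    UpH       = act("UpH",       80, c(80, 100), 70, 105, 2.5, 1, 0.00)
  )
}

get_activity <- function(activity) {
  if (is.character(activity)) {
    reg <- activity_registry()
    if (!activity %in% names(reg)) {
      stop("unknown activity '", activity, "'")
    }
    activity <- reg[[activity]]
  }
  activity
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) second-order Butterworth filter, the standard
#' smoothing applied to motion-capture kinematics. DC gain is 1; a sinusoid at
#' the cut-off frequency is attenuated to about half its amplitude by the two
#' passes.
#'
#' @param x Uniformly sampled numeric series.
#' @param cutoff_hz Cut-off frequency, Hz (default 6).
#' @param fs_hz Sampling frequency, Hz (default 100).
#' @param order Filter order per pass (default 2).
#' @return Filtered series of the same length.
#' @export
lowpass_filter <- function(x, cutoff_hz = 6, fs_hz = 100, order = 2) {
  if (cutoff_hz >= fs_hz / 2) {
    stop("cutoff must be below the Nyquist frequency (fs/2)")
  }
  n <- length(x)
  if (n < 3 * (order + 1)) stop("series too short to filter")
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  # odd-symmetric end reflection suppresses start-up transients of the
  # forward-backward pass
  k <- min(n - 1, max(12, ceiling(6 * fs_hz / cutoff_hz)))
  xp <- c(2 * x[1] - x[(k + 1):2], x, 2 * x[n] - x[(n - 1):(n - k)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  yp[(k + 1):(k + n)]
}

# Minimum-jerk scalar profile from 0 to 1 over normalized time in [0, 1].
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Generate a synthetic trajectory for one trial
#'
#' Emulates a filtered motion-capture elevation trace: a minimum-jerk
#' thoracohumeral elevation profile spanning the activity's movement range
#' (5 s for Flexion/Abduction), with smooth participant-scaled motor noise
#' added to elevation and plane, sampled at 100 Hz and low-pass filtered at
#' 6 Hz. Deterministic given `(activity, participant, seed)`.
#'
#' @param activity An activity name or definition from [activity_registry()].
#' @param participant A participant from [generate_cohort()]; its
#'   `motor_noise_scale` (deg) sets the noise amplitude. `NULL` gives a
#'   noise-free trajectory.
#' @param seed Integer seed fixing all randomness of this trial.
#' @param fs_hz Sampling frequency, Hz.
#' @return A data.frame (`time_s`, `elevation_deg`, `plane_deg`,
#'   `rotation_deg`, `load_kg`) of class `glenosim_trajectory`.
#' @export
generate_trajectory <- function(activity, participant = NULL, seed = 1,
                                fs_hz = 100) {
  a <- get_activity(activity)
  n <- round(a$duration_s * fs_hz) + 1
  t <- seq(0, a$duration_s, length.out = n)
  elev <- a$traj_start_deg + (a$traj_end_deg - a$traj_start_deg) *
    min_jerk(t / a$duration_s)

  scale <- if (is.null(participant)) 0 else participant$motor_noise_scale
  plane <- rep(a$plane_of_elevation_deg, n)
  if (scale > 0) {
    pars <- with_seed(seed, function() {
      list(f = stats::runif(6, 0.2, 1.5), ph = stats::runif(6, 0, 2 * pi),
           amp = stats::rnorm(6))
    })
    elev <- elev + smooth_noise(t, scale, pars$f[1:3], pars$ph[1:3], pars$amp[1:3])
    plane <- plane + smooth_noise(t, scale / 2, pars$f[4:6], pars$ph[4:6], pars$amp[4:6])
  }

  elev <- lowpass_filter(elev, 6, fs_hz)
  plane <- lowpass_filter(plane, 6, fs_hz)
  rot <- a$rotation_slope * elev

  structure(data.frame(
    time_s = t,
    elevation_deg = elev,
    plane_deg = plane,
    rotation_deg = rot,
    load_kg = rep(a$external_load_kg, n)
  ), class = c("glenosim_trajectory", "data.frame"), activity = a$name)
}

# Smooth low-frequency noise: three random sinusoids, scaled to `scale`
# degrees and tapered to zero at both ends so endpoint coverage of the
# movement range is preserved.
smooth_noise <- function(t, scale, f, ph, amp) {
  w <- numeric(length(t))
  for (k in seq_along(f)) w <- w + amp[k] * sin(2 * pi * f[k] * t + ph[k])
  scale * (w / sqrt(length(f))) * sin(pi * t / max(t))
}

#' Quasi-static net glenohumeral moment
#'
#' The moment the scapulohumeral muscles must produce to hold the arm (plus
#' any handheld load) against gravity at a posture, in the scapular frame.
#' Inertial terms are neglected: the activities are slow, and the per-bin
#' analysis is effectively quasi-static.
#'
#' @param model A `shoulder_model` (supplies the scapulohumeral rhythm used to
#'   tilt gravity into the scapular frame).
#' @param posture A posture from [make_posture()].
#' @param participant A participant (supplies arm segment mass and lumped
#'   centre-of-mass distance); see [generate_cohort()].
#' @param external_load_kg Handheld mass, kg, acting at the hand.
#' @return Net moment 3-vector, N m, scapular frame.
#' @export
#' @examples
#' m <- load_model()
#' p <- list(arm = list(mass_kg = 3.5, com_m = 0.3, hand_m = 0.6))
#' M <- net_moments(m, make_posture(m, 90, plane_deg = 0), p, 0)
#' sqrt(sum(M^2))  # 3.5 * 9.81 * 0.3
net_moments <- function(model, posture, participant, external_load_kg = 0) {
  arm <- participant$arm
  a_hat <- arm_axis(posture$elevation_gh_deg, posture$plane_deg)
  g_hat <- gravity_dir_scap(posture)
  lever <- arm$mass_kg * arm$com_m + external_load_kg * arm$hand_m
  # muscles must cancel the gravity moment (L a) x (m g g_hat)
  -GRAV * lever * cross3(a_hat, g_hat)
}

# Non-muscular force transmitted to the joint (gravity on arm + load), N,
# scapular frame. Paired with net_moments in the recruitment problem.
external_joint_force <- function(posture, participant, external_load_kg = 0) {
  m_tot <- participant$arm$mass_kg + external_load_kg
  m_tot * GRAV * gravity_dir_scap(posture)
}

#' Bin per-sample values every 10 degrees of elevation
#'
#' For each 10-degree bin centre within the activity's analysis range, takes
#' the value at the first sample whose elevation crosses that centre during
#' the ascending phase of the movement.
#'
#' @param trajectory A trajectory from [generate_trajectory()].
#' @param per_sample_values Numeric vector aligned with the trajectory
#'   samples, or a data.frame of aligned columns.
#' @param activity Activity name or definition (sets the analysis range).
#' @return A data.frame with `bin_deg`, `sample`, and the binned value(s).
#' @export
bin_by_elevation <- function(trajectory, per_sample_values, activity) {
  a <- get_activity(activity)
  rng <- a$analysis_range_deg
  centers <- seq(rng[1], rng[2], by = 10)
  elev <- trajectory$elevation_deg
  n <- length(elev)
  vals_df <- if (is.data.frame(per_sample_values)) per_sample_values else
    data.frame(value = per_sample_values)
  if (nrow(vals_df) != n) {
    stop("per_sample_values must align with the trajectory samples")
  }
  idx <- vapply(centers, function(ctr) {
    hits <- which(elev[-1] >= ctr & elev[-n] < ctr)
    if (length(hits) == 0) {
      if (elev[1] >= ctr && any(elev >= ctr)) 1L else NA_integer_
    } else {
      hits[1] + 1L
    }
  }, 1L)
  if (anyNA(idx)) {
    stop("elevation never crosses bin centre(s): ",
         paste(centers[is.na(idx)], collapse = ", "), " deg")
  }
  out <- cbind(data.frame(bin_deg = centers, sample = idx),
               vals_df[idx, , drop = FALSE])
  rownames(out) <- NULL
  out
}
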