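# Simplified glenohumeral model: muscle set, glenoid ellipse, tear scenarios.

REQUIRED_MUSCLES <- c("SSP", "ISP", "SSC", "Tm", "AD", "MD", "PD", "LHB")

#' Load a shoulder model from a configuration file
#'
#' Reads a YAML model description (muscle maximum strengths, posture-dependent
#' moment-arm polynomials, lines of action, glenoid ellipse, scapulohumeral
#' rhythm) and validates it. The packaged default describes a simplified
#' eight-element scapulohumeral muscle set: the rotator cuff (SSP, ISP, SSC,
#' Tm), the three deltoid segments (AD, MD, PD), and the long head of biceps
#' (LHB), each reduced to an elevation-dependent moment-arm vector and unit
#' line of action at the humeral head.
#'
#' @param config Path to a YAML model configuration, or an already-parsed list
#'   with the same structure. Defaults to the packaged model.
#' @return An object of class `shoulder_model`.
#' @export
#' @examples
#' m <- load_model()
#' m$glenoid$si_diameter_mm
load_model <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "shoulder_model.yaml", package = "glenosim")
  }
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config

  gl_cfg <- cfg$glenoid %||% list()
  glenoid <- glenoid_ellipse(
    ap_diameter_mm = gl_cfg$ap_diameter_mm %||% 28,
    si_diameter_mm = gl_cfg$si_diameter_mm %||% 38,
    center_m = as.numeric(gl_cfg$center_m %||% c(0, 0, -0.025)),
    normal = as.numeric(gl_cfg$normal %||% c(0, 0, 1)),
    si_axis = as.numeric(gl_cfg$si_axis %||% c(0, 1, 0))
  )

  muscles <- cfg$muscles
  if (is.null(muscles)) stop("model configuration has no 'muscles' section")
  names(muscles) <- vapply(muscles, function(m) as.character(m$name), "")
  missing <- setdiff(REQUIRED_MUSCLES, names(muscles))
  if (length(missing) > 0) {
    stop("model configuration is missing required muscle(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(names(muscles))) stop("duplicate muscle names in configuration")
  for (m in muscles) {
    if (is.null(m$fmax_n) || m$fmax_n <= 0) {
      stop("muscle ", m$name, ": fmax_n must be > 0")
    }
    type <- m$type %||% "parametric"
    if (type == "parametric") {
      if (!is_unit(unitize(as.numeric(m$u0)))) stop("bad line of action for ", m$name)
    } else if (type == "two_point") {
      if (is.null(m$origin_m) || is.null(m$insertion_radius_m)) {
        stop("two_point muscle ", m$name, " needs origin_m and insertion_radius_m")
      }
    } else {
      stop("unknown muscle type '", type, "' for ", m$name)
    }
  }

  rhythm <- cfg$rhythm %||% list()
  model <- structure(list(
    muscles = muscles,
    muscle_names = names(muscles),
    glenoid = glenoid,
    rhythm = list(threshold_deg = rhythm$threshold_deg %||% 30,
                  gh_fraction = rhythm$gh_fraction %||% (2 / 3)),
    joint_center = as.numeric(cfg$joint_center_m %||% c(0, 0, 0)),
    envelope_gh_deg = as.numeric(cfg$envelope_gh_deg %||% c(0, 135)),
    max_moment_arm_m = cfg$max_moment_arm_m %||% 0.06
  ), class = "shoulder_model")
  model
}

#' Construct a glenoid ellipse
#'
#' The glenoid articular surface is idealized as a planar ellipse, 28 mm in
#' the anterior-posterior direction and 38 mm superior-inferior by default,
#' fixed in the scapular frame.
#'
#' @param ap_diameter_mm,si_diameter_mm Ellipse diameters, mm.
#' @param center_m Ellipse centre in the scapular frame, m.
#' @param normal Unit normal of the glenoid plane (points toward the humeral
#'   head).
#' @param si_axis Unit superior direction within the plane; must be orthogonal
#'   to `normal`.
#' @return An object of class `glenoid_ellipse` with the derived anterior
#'   (`ap_axis`) in-plane axis.
#' @export
glenoid_ellipse <- function(ap_diameter_mm = 28, si_diameter_mm = 38,
                            center_m = c(0, 0, -0.025),
                            normal = c(0, 0, 1), si_axis = c(0, 1, 0)) {
  if (ap_diameter_mm <= 0 || si_diameter_mm <= 0) {
    stop("glenoid diameters must be positive")
  }
  if (!is_unit(normal)) stop("glenoid normal must be unit length")
  if (!is_unit(si_axis)) stop("glenoid si_axis must be unit length")
  if (abs(sum(normal * si_axis)) > 1e-6) {
    stop("glenoid si_axis must be orthogonal to the plane normal")
  }
  structure(list(
    ap_diameter_mm = ap_diameter_mm,
    si_diameter_mm = si_diameter_mm,
    center_m = center_m,
    normal = normal,
    si_axis = si_axis,
    ap_axis = cross3(si_axis, normal)
  ), class = "glenoid_ellipse")
}

#' @export
print.shoulder_model <- function(x, ...) {
  cat("<shoulder_model>", length(x$muscles), "muscles:",
      paste(x$muscle_names, collapse = ", "), "\n")
  cat("  glenoid ellipse:", x$glenoid$ap_diameter_mm, "x",
      x$glenoid$si_diameter_mm, "mm (AP x SI)\n")
  cat("  F_max (N):", paste(sprintf("%s=%g", x$muscle_names,
      vapply(x$muscles, function(m) m$fmax_n, 0)), collapse = " "), "\n")
  invisible(x)
}

# --- posture ------------------------------------------------------------

#' Build a joint posture from a thoracohumeral elevation angle
#'
#' Applies the model's scapulohumeral rhythm: elevation below the threshold is
#' purely glenohumeral; above it each additional thoracohumeral degree is
#' split `gh_fraction` to the glenohumeral joint and the rest to
#' scapulothoracic upward rotation.
#'
#' @param model A `shoulder_model`.
#' @param elevation_th_deg Thoracohumeral elevation (angle between the vertical
#'   and the humeral long axis), degrees.
#' @param plane_deg Plane of elevation (0 = abduction, 90 = flexion), degrees.
#' @param rotation_deg Axial rotation (+ external), degrees.
#' @return A list with glenohumeral (`elevation_gh_deg`) and scapulothoracic
#'   (`elevation_st_deg`) partitions plus the inputs.
#' @export
make_posture <- function(model, elevation_th_deg, plane_deg = 0, rotation_deg = 0) {
  th <- elevation_th_deg
  thr <- model$rhythm$threshold_deg
  fr <- model$rhythm$gh_fraction
  gh <- ifelse(th <= thr, th, thr + fr * (th - thr))
  list(elevation_th_deg = th,
       elevation_gh_deg = gh,
       elevation_st_deg = th - gh,
       plane_deg = plane_deg,
       rotation_deg = rotation_deg)
}

# Unit arm long axis in the scapular frame (from joint centre toward the hand),
# at glenohumeral elevation `gh` (deg) in elevation plane `phi` (deg).
arm_axis <- function(gh, phi) {
  th <- gh * DEG; pl <- phi * DEG
  c(sin(th) * sin(pl), -cos(th), sin(th) * cos(pl))
}

# Gravity direction (unit, pointing down) expressed in the scapular frame. The
# scapula rotates upward with the arm by the scapulothoracic share, so gravity
# tilts by -elevation_st about the elevation axis.
gravity_dir_scap <- function(posture) {
  e <- elevation_axis(posture)
  rotate_about(c(0, -1, 0), e, -posture$elevation_st_deg * DEG)
}

# Axis about which positive moment elevates the arm in its current plane.
elevation_axis <- function(posture) {
  pl <- posture$plane_deg * DEG
  c(-cos(pl), 0, sin(pl))
}

# --- moment arms and lines of action ------------------------------------

muscle_moment_arm <- function(spec, posture) {
  gh <- posture$elevation_gh_deg
  type <- spec$type %||% "parametric"
  if (type == "two_point") {
    ins <- spec$insertion_radius_m * arm_axis(gh, posture$plane_deg)
    u <- unitize(as.numeric(spec$origin_m) - ins)
    return(cross3(ins, u))
  }
  t <- gh / 100
  co <- as.numeric(spec$r_el_poly_m)
  r_el <- sum(co * t^(seq_along(co) - 1))
  eff <- (1 - spec$plane_sens) +
    spec$plane_sens * cos((posture$plane_deg - spec$plane_pref_deg) * DEG)
  e_el <- elevation_axis(posture)
  a_hat <- arm_axis(gh, posture$plane_deg)
  e_pl <- cross3(a_hat, e_el)
  r_el * eff * e_el + spec$r_rot_m * a_hat + spec$r_plane_m * e_pl
}

muscle_line_of_action <- function(spec, posture) {
  gh <- posture$elevation_gh_deg
  type <- spec$type %||% "parametric"
  if (type == "two_point") {
    ins <- spec$insertion_radius_m * arm_axis(gh, posture$plane_deg)
    return(unitize(as.numeric(spec$origin_m) - ins))
  }
  unitize(as.numeric(spec$u0) + (gh / 90) * as.numeric(spec$du))
}

#' Moment-arm matrix at a posture
#'
#' Column `i` is the 3-vector moment arm (m) of muscle `i` about the
#' glenohumeral centre, in the scapular frame, so that the muscle's joint
#' moment is `f_i * R[, i]`.
#'
#' @param model A `shoulder_model`.
#' @param posture A posture from [make_posture()].
#' @return A 3 x n_muscles matrix with muscle names as column names.
#' @export
moment_arm_matrix <- function(model, posture) {
  gh <- posture$elevation_gh_deg
  env <- model$envelope_gh_deg
  if (gh < env[1] - 1e-9 || gh > env[2] + 1e-9) {
    stop("posture outside the model envelope: glenohumeral elevation ",
         signif(gh, 4), " deg not in [", env[1], ", ", env[2], "]")
  }
  R <- vapply(model$muscles, muscle_moment_arm, numeric(3), posture = posture)
  colnames(R) <- model$muscle_names
  R
}

#' Line-of-action matrix at a posture
#'
#' Column `i` is the unit direction of muscle `i`'s pull on the humeral head,
#' in the scapular frame.
#'
#' @inheritParams moment_arm_matrix
#' @return A 3 x n_muscles matrix of unit columns.
#' @export
line_of_action_matrix <- function(model, posture) {
  U <- vapply(model$muscles, muscle_line_of_action, numeric(3), posture = posture)
  colnames(U) <- model$muscle_names
  U
}

fmax_vector <- function(model) {
  vapply(model$muscles, function(m) m$fmax_n, 0)
}

# --- tear scenarios ------------------------------------------------------

#' Construct a tear scenario
#'
#' A tear scenario maps each cuff muscle to a residual maximum-strength
#' fraction; muscles not named keep full strength.
#'
#' @param name Scenario label.
#' @param fractions Named numeric vector of residual strength fractions in
#'   \[0, 1\].
#' @return An object of class `tear_scenario`.
#' @export
tear_scenario <- function(name, fractions) {
  fractions <- unlist(fractions)
  if (any(fractions < 0 | fractions > 1)) {
    stop("tear fractions must lie in [0, 1]")
  }
  structure(list(name = name, fractions = fractions), class = "tear_scenario")
}

#' The packaged rotator cuff tear scenario registry
#'
#' Eight scenarios of graded severity: the intact model, isolated partial and
#' full supraspinatus tears, a supraspinatus + subscapularis pattern, three
#' supraspinatus + infraspinatus patterns, and a massive three-muscle tear.
#' Teres minor keeps full strength in every scenario.
#'
#' @return Named list of [tear_scenario()] objects, ordered by severity chain.
#' @export
tear_scenarios <- function() {
  rows <- list(
    Intact          = c(SSP = 1.00, ISP = 1.00, SSC = 1.00, Tm = 1),
    S50             = c(SSP = 0.50, ISP = 1.00, SSC = 1.00, Tm = 1),
    S0              = c(SSP = 0.00, ISP = 1.00, SSC = 1.00, Tm = 1),
    `S0/SS50`       = c(SSP = 0.00, ISP = 1.00, SSC = 0.50, Tm = 1),
    `S0/IS75`       = c(SSP = 0.00, ISP = 0.75, SSC = 1.00, Tm = 1),
    `S0/IS50`       = c(SSP = 0.00, ISP = 0.50, SSC = 1.00, Tm = 1),
    `S0/IS25`       = c(SSP = 0.00, ISP = 0.25, SSC = 1.00, Tm = 1),
    `S0/IS25/SS50`  = c(SSP = 0.00, ISP = 0.25, SSC = 0.50, Tm = 1)
  )
  out <- lapply(names(rows), function(nm) tear_scenario(nm, rows[[nm]]))
  names(out) <- names(rows)
  out
}

#' Tear scenario registry as a table
#'
#' One row per scenario, one column per cuff muscle, fractions of intact
#' maximum strength.
#'
#' @param scenarios A list of [tear_scenario()] objects; defaults to the
#'   packaged registry.
#' @return A data.frame with columns `scenario`, `SSP`, `ISP`, `SSC`, `Tm`.
#' @export
scenario_table <- function(scenarios = tear_scenarios()) {
  muscles <- c("SSP", "ISP", "SSC", "Tm")
  tab <- data.frame(scenario = vapply(scenarios, function(s) s$name, ""))
  for (m in muscles) {
    tab[[m]] <- vapply(scenarios, function(s) {
      if (m %in% names(s$fractions)) unname(s$fractions[[m]]) else 1
    }, 0)
  }
  rownames(tab) <- NULL
  tab
}

#' Rebuild tear scenarios from a table
#'
#' Inverse of [scenario_table()]; used to round-trip scenario definitions
#' through plain-text serialization.
#'
#' @param tab A data.frame as produced by [scenario_table()].
#' @return Named list of [tear_scenario()] objects.
#' @export
scenarios_from_table <- function(tab) {
  muscles <- setdiff(names(tab), "scenario")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    tear_scenario(tab$scenario[i], unlist(tab[i, muscles]))
  })
  names(out) <- tab$scenario
  out
}

#' Apply a tear scenario to a model
#'
#' Returns a model identical to the input except that each muscle named in the
#' scenario has its maximum strength multiplied by the residual fraction.
#'
#' @param model A `shoulder_model`.
#' @param scenario A [tear_scenario()], or the name of a packaged scenario.
#' @return A new `shoulder_model`.
#' @export
#' @examples
#' m <- load_model()
#' torn <- apply_tear(m, "S0/IS25/SS50")
#' torn$muscles$SSP$fmax_n  # 0
apply_tear <- function(model, scenario) {
  if (is.character(scenario)) {
    reg <- tear_scenarios()
    if (!scenario %in% names(reg)) {
      stop("unknown scenario '", scenario, "'; packaged scenarios: ",
           paste(names(reg), collapse = ", "))
    }
    scenario <- reg[[scenario]]
  }
  fr <- scenario$fractions
  if (any(fr < 0 | fr > 1)) stop("tear fractions must lie in [0, 1]")
  unknown <- setdiff(names(fr), model$muscle_names)
  if (length(unknown) > 0) {
    stop("scenario names unknown muscle(s): ", paste(unknown, collapse = ", "))
  }
  for (m in names(fr)) {
    model$muscles[[m]]$fmax_n <- model$muscles[[m]]$fmax_n * unname(fr[[m]])
  }
  attr(model, "scenario") <- scenario$name
  model
}
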