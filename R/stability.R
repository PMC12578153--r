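# Joint stability: intersect the joint-reaction-force line with the glenoid
# plane and score its position inside the glenoid ellipse.

#' Intersect the joint reaction force line with the glenoid plane
#'
#' The joint reaction force defines a line through the glenohumeral centre;
#' its intersection with the glenoid plane, expressed in (AP, SI) in-plane
#' coordinates about the ellipse centre, locates where the load crosses the
#' articular surface. Only the line matters: scaling the force leaves the
#' intersection unchanged.
#'
#' @param jrf Joint reaction force 3-vector (any magnitude), scapular frame.
#' @param glenoid A [glenoid_ellipse()].
#' @param joint_center Point the force line passes through, m.
#' @return Length-2 vector `c(ap, si)` in mm.
#' @export
#' @examples
#' g <- glenoid_ellipse()
#' glenoid_intersection(c(0, 0, -100), g)  # axial force -> centre
glenoid_intersection <- function(jrf, glenoid, joint_center = c(0, 0, 0)) {
  v <- as.numeric(jrf)
  if (vnorm(v) < .Machine$double.eps) {
    stop("zero joint reaction force: intersection direction undefined")
  }
  denom <- sum(v * glenoid$normal)
  if (abs(denom) < 1e-12 * vnorm(v)) {
    stop("joint reaction force is parallel to the glenoid plane: no intersection")
  }
  t <- sum((glenoid$center_m - joint_center) * glenoid$normal) / denom
  p <- joint_center + t * v - glenoid$center_m
  1000 * c(ap = sum(p * glenoid$ap_axis), si = sum(p * glenoid$si_axis))
}

#' Glenohumeral stability index
#'
#' `1 - d_center / d_edge`: one minus the distance of the intersection point
#' from the glenoid centre, over the distance from the centre to the ellipse
#' rim along the same ray. The index is 1 when the joint reaction force passes
#' through the centre of the glenoid and falls to 0 at the rim; values near 0
#' indicate instability.
#'
#' For semi-axes `a` (AP) and `b` (SI), the rim distance along the ray at
#' angle `theta` is `a b / sqrt(b^2 cos^2 theta + a^2 sin^2 theta)`.
#'
#' @param intersection Length-2 `c(ap, si)` intersection, mm, from
#'   [glenoid_intersection()].
#' @param glenoid A [glenoid_ellipse()].
#' @param clamp_tol Intersections outside the ellipse by at most this
#'   normalized amount (solver feasibility tolerance) are clamped to the rim.
#' @return The stability index. Intersections beyond `clamp_tol` outside the
#'   ellipse return the (negative) index flagged with attribute
#'   `out_of_glenoid = TRUE`, mirroring the abort of a simulation whose joint
#'   reaction force leaves the glenoid.
#' @export
#' @examples
#' g <- glenoid_ellipse()
#' stability_index(c(0, 0), g)     # 1 at the centre
#' stability_index(c(0, 19), g)    # 0 at the superior rim
stability_index <- function(intersection, glenoid, clamp_tol = 1e-9) {
  a <- glenoid$ap_diameter_mm / 2
  b <- glenoid$si_diameter_mm / 2
  d_center <- vnorm(intersection)
  if (d_center == 0) return(1)
  ct <- intersection[1] / d_center
  st <- intersection[2] / d_center
  d_edge <- a * b / sqrt(b^2 * ct^2 + a^2 * st^2)
  frac <- d_center / d_edge
  if (frac > 1 && frac <= 1 + clamp_tol) frac <- 1
  s <- unname(1 - frac)
  if (frac > 1) attr(s, "out_of_glenoid") <- TRUE
  s
}

#' Per-bin, per-scenario stability summaries
#'
#' Extracts participant-level stability (already 5-trial means) from a sweep
#' results table, one row per (activity, bin, scenario, participant), ready
#' for the repeated-measures statistics. Cells whose trials all aborted are
#' reported with `NA` stability and counted.
#'
#' @param results A `glenosim_results` from [tear_severity_sweep()], or its
#'   long results table.
#' @return A data.frame `activity, bin_deg, scenario, participant, stability,
#'   feasible, n_trials_excluded` with attribute `n_aborted_cells`.
#' @export
stability_profile <- function(results) {
  tab <- if (inherits(results, "glenosim_results")) results$results else results
  one <- tab[tab$muscle == tab$muscle[1], ]
  prof <- one[, c("activity", "bin_deg", "scenario", "participant",
                  "stability", "feasible", "n_trials_excluded")]
  prof <- prof[order(prof$activity, prof$bin_deg, prof$scenario, prof$participant), ]
  rownames(prof) <- NULL
  attr(prof, "n_aborted_cells") <- sum(!prof$feasible)
  prof
}
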