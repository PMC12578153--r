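test_that("a single muscle takes the closed-form force M / r", {
  prob <- recruitment_problem(
    R = matrix(c(0.02, 0, 0), 3, 1), M_net = c(1, 0, 0),
    f_max = 200, U = matrix(c(0, 0, -1), 3, 1))
  sol <- solve_recruitment(prob)
  expect_true(sol$feasible)
  expect_equal(unname(sol$f), 50, tolerance = 1e-6)
})

test_that("identical muscles share the load equally (strict convexity)", {
  prob <- recruitment_problem(
    R = matrix(rep(c(0.02, 0, 0), 4), 3, 4), M_net = c(1.6, 0, 0),
    f_max = rep(100, 4), U = matrix(rep(c(0, 0, -1), 4), 3, 4))
  sol <- solve_recruitment(prob)
  expect_true(sol$feasible)
  expect_equal(max(sol$f) - min(sol$f), 0, tolerance = 1e-4)
  expect_equal(sum(sol$f) * 0.02, 1.6, tolerance = 1e-6)
})

test_that("solver matches the brute-force null-space grid oracle within 1%", {
  toy <- recruitment_toy()
  sol <- solve_recruitment(recruitment_problem(toy$R, toy$M, toy$fmax, toy$U))
  expect_true(sol$feasible)
  oracle <- recruitment_grid_oracle(toy, step = 0.1)
  expect_lt(abs(sol$objective - oracle) / oracle, 0.01)
  expect_lte(sol$equilibrium_residual, 1e-6)
})

test_that("local perturbations along the null space never lower the objective", {
  toy <- recruitment_toy()
  sol <- solve_recruitment(recruitment_problem(toy$R, toy$M, toy$fmax, toy$U))
  qrA <- qr(t(toy$R[1:2, ]))
  N <- qr.Q(qrA, complete = TRUE)[, -(1:qrA$rank), drop = FALSE]
  obj <- function(f) sum((f / toy$fmax)^3)
  set.seed(5)
  for (k in 1:30) {
    dirn <- N %*% rnorm(ncol(N))
    for (eps in c(1e-3, 1e-2)) {
      f2 <- sol$f + eps * dirn / sqrt(sum(dirn^2))
      if (all(f2 >= 0 & f2 <= toy$fmax)) {
        expect_gte(obj(f2), sol$objective - 1e-10)
      }
    }
  }
})

test_that("joint reaction force equals the summation oracle", {
  expect_equal(compute_jrf(numeric(0), matrix(0, 3, 0), c(0, 0, 0)), c(0, 0, 0))
  u <- glenosim:::unitize(c(0.2, -0.3, -0.9))
  expect_equal(compute_jrf(100, matrix(u, 3, 1), c(0, -10, 0)),
               -100 * u - c(0, -10, 0))
  set.seed(42)
  U <- matrix(rnorm(24), 3, 8)
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  f <- runif(8, 0, 300)
  F_ext <- rnorm(3, 0, 50)
  loop <- -F_ext
  for (i in 1:8) loop <- loop - f[i] * U[, i]
  expect_equal(compute_jrf(f, U, F_ext), loop, tolerance = 1e-9)
})

test_that("scaling all strengths up never increases the optimal objective", {
  toy <- recruitment_toy()
  obj1 <- solve_recruitment(recruitment_problem(toy$R, toy$M, toy$fmax, toy$U))$objective
  for (lam in c(1.5, 3)) {
    obj2 <- solve_recruitment(
      recruitment_problem(toy$R, toy$M, lam * toy$fmax, toy$U))$objective
    expect_lte(obj2, obj1 + 1e-10)
  }
})

test_that("solutions are bitwise reproducible", {
  m <- load_model()
  po <- make_posture(m, 35, plane_deg = 20)
  part <- test_participant()
  prob <- recruitment_problem(
    moment_arm_matrix(m, po), net_moments(m, po, part, 0.5),
    glenosim:::fmax_vector(m), line_of_action_matrix(m, po),
    glenosim:::external_joint_force(po, part, 0.5),
    glenoid = m$glenoid, joint_center = m$joint_center)
  s1 <- solve_recruitment(prob)
  s2 <- solve_recruitment(prob)
  expect_identical(s1$activations, s2$activations)
  expect_true(all(s1$activations >= 0 & s1$activations <= 1 + 1e-6))
})

test_that("fully torn muscles are excluded and carry zero force", {
  m <- apply_tear(load_model(), "S0")
  po <- make_posture(m, 30)
  part <- test_participant()
  prob <- recruitment_problem(
    moment_arm_matrix(m, po), net_moments(m, po, part, 0),
    glenosim:::fmax_vector(m), line_of_action_matrix(m, po),
    glenosim:::external_joint_force(po, part, 0),
    glenoid = m$glenoid)
  sol <- solve_recruitment(prob)
  expect_true(sol$feasible)
  expect_equal(unname(sol$f["SSP"]), 0)
  expect_equal(unname(sol$activations["SSP"]), 0)
})

test_that("an unbalanceable demand is flagged infeasible with a reason", {
  # every depressor and the deltoid zeroed: nothing can elevate the arm
  m <- load_model()
  sc <- tear_scenario("pathological",
                      c(SSP = 0, ISP = 0, SSC = 0, Tm = 0, AD = 0, MD = 0,
                        PD = 0, LHB = 0.02))
  torn <- apply_tear(m, sc)
  po <- make_posture(torn, 60)
  part <- test_participant()
  prob <- recruitment_problem(
    moment_arm_matrix(torn, po), net_moments(torn, po, part, 1),
    glenosim:::fmax_vector(torn), line_of_action_matrix(torn, po),
    glenosim:::external_joint_force(po, part, 1),
    glenoid = torn$glenoid)
  sol <- solve_recruitment(prob)
  expect_false(sol$feasible)
  expect_match(sol$aborted_reason, "infeasible")
})

test_that("the glenoid constraint keeps the reaction inside the ellipse", {
  m <- apply_tear(load_model(), "S0/IS25/SS50")
  po <- make_posture(m, 15)
  part <- test_participant()
  prob <- recruitment_problem(
    moment_arm_matrix(m, po), net_moments(m, po, part, 0),
    glenosim:::fmax_vector(m), line_of_action_matrix(m, po),
    glenosim:::external_joint_force(po, part, 0),
    glenoid = m$glenoid)
  sol <- solve_recruitment(prob)
  expect_true(sol$feasible)
  p2 <- glenoid_intersection(sol$jrf, m$glenoid)
  a <- m$glenoid$ap_diameter_mm / 2; b <- m$glenoid$si_diameter_mm / 2
  expect_lte((p2[1] / a)^2 + (p2[2] / b)^2, 1 + 1e-4)
  # without the containment constraint the same demand drifts outside
  free <- solve_recruitment(recruitment_problem(
    moment_arm_matrix(m, po), net_moments(m, po, part, 0),
    glenosim:::fmax_vector(m), line_of_action_matrix(m, po),
    glenosim:::external_joint_force(po, part, 0), glenoid = NULL))
  p3 <- glenoid_intersection(free$jrf, m$glenoid)
  expect_gt((p3[1] / a)^2 + (p3[2] / b)^2, 1)
})
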