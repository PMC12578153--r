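# Independent oracles and shared fixtures for the test suite.

# Friedman statistic straight from the rank formula (oracle, independent of
# stats::friedman.test).
friedman_stat_oracle <- function(M) {
  Rk <- t(apply(M, 1, rank))
  n <- nrow(M); k <- ncol(M)
  12 / (n * k * (k + 1)) * sum(colSums(Rk)^2) - 3 * n * (k + 1)
}

# Exact permutation p for a blocks x 3 table: enumerate all (3!)^n_blocks
# within-row rearrangements.
friedman_exact_p_oracle <- function(X) {
  stopifnot(ncol(X) == 3)
  P3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  obs <- friedman_stat_oracle(X)
  perms <- as.matrix(expand.grid(rep(list(1:6), nrow(X))))
  stats <- apply(perms, 1, function(ix) {
    M <- X
    for (r in seq_len(nrow(X))) M[r, ] <- X[r, P3[ix[r], ]]
    friedman_stat_oracle(M)
  })
  mean(stats >= obs - 1e-12)
}

# 4-blocks x 3-scenarios toy with a strong effect; frozen from a draw where
# the chi-square approximation sits in its accurate (tail) regime.
friedman_toy <- matrix(c(-0.305, 1.528, 1.478,
                         0.154, 1.343, 2.182,
                         -0.266, 1.123, 1.170,
                         -0.690, 1.663, 2.709),
                       nrow = 4, byrow = TRUE)

# Brute-force oracle for the 4-muscle planar recruitment toy: exhaustive grid
# over the 2-dimensional equality-constraint null space at `step` N.
recruitment_toy <- function() {
  list(R = rbind(c(0.02, 0.03, 0.015, 0.025),
                 c(0.01, -0.02, 0.02, -0.01),
                 c(0, 0, 0, 0)),
       M = c(1.2, 0.1, 0),
       fmax = rep(60, 4),
       U = cbind(c(0, 0, -1), c(0, 0, -1), c(0, 0, -1), c(0, 0, -1)))
}

recruitment_grid_oracle <- function(toy, step = 0.1) {
  A <- toy$R[1:2, 1:2]
  g <- seq(0, toy$fmax[3], by = step)
  gr <- expand.grid(f3 = g, f4 = g)
  rhs1 <- toy$M[1] - toy$R[1, 3] * gr$f3 - toy$R[1, 4] * gr$f4
  rhs2 <- toy$M[2] - toy$R[2, 3] * gr$f3 - toy$R[2, 4] * gr$f4
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  f1 <- (A[2, 2] * rhs1 - A[1, 2] * rhs2) / det
  f2 <- (-A[2, 1] * rhs1 + A[1, 1] * rhs2) / det
  ok <- f1 >= 0 & f1 <= toy$fmax[1] & f2 >= 0 & f2 <= toy$fmax[2]
  fm <- toy$fmax
  min((f1[ok] / fm[1])^3 + (f2[ok] / fm[2])^3 +
        (gr$f3[ok] / fm[3])^3 + (gr$f4[ok] / fm[4])^3)
}

# Default-model config as an editable list (for validation-failure fixtures).
model_config_list <- function() {
  yaml::read_yaml(system.file("extdata", "shoulder_model.yaml",
                              package = "glenosim"))
}

test_participant <- function(mass = 63.5, height = 1.715, noise = 2) {
  make_participant("T01", mass, height, motor_noise_scale = noise)
}

fmax_vector_of <- function(m) {
  vapply(m$muscles, function(x) x$fmax_n, 0)
}

with_seed_local <- function(seed, fn) {
  set.seed(seed)
  fn()
}

# Synthetic participant-mean results table with a controlled stability
# gradient across scenarios and flat baseline forces; used to exercise the
# injection + correlation stages without running the solver.
synthetic_results_table <- function(n_part = 15, seed = 1,
                                    muscles = c("Tm", "LHB"),
                                    activity = "Abduction", bin = 30) {
  scens <- names(glenosim::tear_scenarios())
  drops <- seq(0, 0.35, length.out = length(scens))
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_part)) {
    base_st <- rnorm(1, 0.6, 0.03)
    for (s in seq_along(scens)) {
      st <- base_st - drops[s] + rnorm(1, 0, 0.05)
      for (m in muscles) {
        rows[[length(rows) + 1]] <- data.frame(
          activity = activity, scenario = scens[s],
          participant = sprintf("P%02d", p), bin_deg = bin, muscle = m,
          force_N_per_kg = rnorm(1, 1, 0.1),
          jrf_x = 0, jrf_y = 0, jrf_z = 0,
          stability = st, feasible = TRUE, n_trials_excluded = 0)
      }
    }
  }
  do.call(rbind, rows)
}
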