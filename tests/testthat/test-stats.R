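test_that("constant cells force the nonparametric route with a degeneracy flag", {
  cell <- matrix(1.5, nrow = 10, ncol = 8,
                 dimnames = list(NULL, paste0("s", 1:8)))
  gate <- normality_gate(cell)
  expect_equal(gate$route, "nonparametric")
  expect_true(all(gate$degenerate))
})

test_that("the normality gate is calibrated on normal samples", {
  n_seeds <- 500
  per_model_pass <- 0
  n_models <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    cell <- matrix(rnorm(15 * 8), 15, 8, dimnames = list(NULL, paste0("m", 1:8)))
    gate <- normality_gate(cell)
    per_model_pass <- per_model_pass + sum(gate$shapiro_p >= 0.05)
    n_models <- n_models + 8
  }
  rate <- per_model_pass / n_models # should be about 1 - alpha per model
  expect_gt(rate, 0.92)
  expect_lt(rate, 0.98)
})

test_that("a heavy-tailed sample trips the gate most of the time", {
  n_trip <- 0
  n_seeds <- 200
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    cell <- cbind(matrix(rnorm(15 * 7), 15, 7), rlnorm(15, sdlog = 1))
    colnames(cell) <- paste0("m", 1:8)
    if (normality_gate(cell)$route == "nonparametric") n_trip <- n_trip + 1
  }
  expect_gte(n_trip / n_seeds, 0.8)
})

test_that("omnibus null cases give zero statistics and effect sizes", {
  one <- rnorm(12)
  cell <- matrix(rep(one, 8), ncol = 8, dimnames = list(NULL, paste0("s", 1:8)))
  par <- omnibus(cell, "parametric")
  expect_equal(par$statistic, 0)
  expect_equal(par$effect_value, 0)
  nonpar <- omnibus(cell, "nonparametric")
  expect_equal(nonpar$statistic, 0)
  expect_equal(nonpar$effect_value, 0)
})

test_that("perfectly consistent rankings give Kendall's W of 1", {
  set.seed(8)
  base <- matrix(rnorm(6 * 5, sd = 0.1), 6, 5)
  cell <- sweep(base * 0.01, 2, seq(1, 5), "+") # same ordering in every row
  colnames(cell) <- paste0("s", 1:5)
  res <- omnibus(cell, "nonparametric")
  expect_equal(res$effect_name, "kendalls_w")
  expect_equal(res$effect_value, 1, tolerance = 1e-12)
})

test_that("Friedman route matches the exhaustive permutation oracle", {
  X <- friedman_toy
  colnames(X) <- c("A", "B", "C")
  res <- omnibus(X, "nonparametric")
  expect_equal(res$statistic, friedman_stat_oracle(X), tolerance = 1e-12)
  p_exact <- friedman_exact_p_oracle(X)
  expect_lt(abs(res$p - p_exact), 0.01)
})

test_that("rank-based omnibus is invariant under monotone transforms", {
  set.seed(12)
  cell <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  r1 <- omnibus(cell, "nonparametric")
  r2 <- omnibus(exp(cell), "nonparametric")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)
})

test_that("post hoc comparisons apply exact Bonferroni arithmetic", {
  set.seed(21)
  cell <- matrix(rnorm(12 * 8), 12, 8)
  colnames(cell) <- c("Intact", paste0("T", 1:7))
  for (route in c("parametric", "nonparametric")) {
    ph <- posthoc_vs_intact(cell, route)
    expect_equal(nrow(ph), 7)
    expect_equal(ph$p_bonferroni, pmin(1, 7 * ph$p_raw))
    expect_true(all(ph$p_bonferroni >= ph$p_raw))
    expect_true(all(ph$p_raw >= 0 & ph$p_raw <= 1))
  }
  # p_raw = 0.01 with 7 comparisons must adjust to exactly 0.07
  expect_equal(min(1, 7 * 0.01), 0.07)

  same <- cbind(Intact = cell[, 1], T1 = cell[, 1], T2 = cell[, 2])
  ph0 <- posthoc_vs_intact(same, "parametric")
  expect_equal(ph0$statistic[ph0$scenario == "T1"], 0)
  expect_equal(ph0$p_bonferroni[ph0$scenario == "T1"], 1)
  expect_equal(ph0$direction[ph0$scenario == "T1"], "none")
})

test_that("paired t statistics match the closed-form oracle", {
  d <- c(0.31, -0.12, 0.48, 0.05, 0.27, 0.16) # fixture differences, n = 6
  intact <- c(1.1, 0.9, 1.3, 1.0, 1.2, 0.8)
  cell <- cbind(Intact = intact, T1 = intact + d)
  ph <- posthoc_vs_intact(cell, "parametric")
  oracle_t <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(ph$statistic, oracle_t, tolerance = 1e-10)
  expect_equal(ph$direction, "increase")
})

test_that("a perfect anti-monotone relation is classified compensatory", {
  scens <- names(tear_scenarios())
  rows <- list()
  for (p in 1:5) {
    st_int <- 0.8
    for (s in seq_along(scens)) {
      st <- st_int - 0.05 * (s - 1) - 0.002 * p
      rows[[length(rows) + 1]] <- data.frame(
        activity = "Flexion", scenario = scens[s],
        participant = sprintf("P%02d", p), bin_deg = 20, muscle = "Tm",
        force_N_per_kg = 1 - 2 * (st - (st_int - 0.002 * p)),
        jrf_x = 0, jrf_y = 0, jrf_z = 0, stability = st, feasible = TRUE,
        n_trials_excluded = 0)
    }
  }
  tab <- do.call(rbind, rows)
  res <- delta_correlation(tab, "Tm", "Flexion", 20)
  expect_equal(res$rho, -1, tolerance = 1e-9)
  expect_equal(res$classification, "compensatory")
})

test_that("independent deltas stay unclassified in most seeds", {
  n_pass <- 0
  n_seeds <- 200
  scens <- names(tear_scenarios())
  for (sd_ in seq_len(n_seeds)) {
    set.seed(sd_)
    rows <- expand.grid(participant = sprintf("P%02d", 1:15),
                        scenario = scens, stringsAsFactors = FALSE)
    rows$activity <- "Flexion"; rows$bin_deg <- 20; rows$muscle <- "Tm"
    rows$stability <- ifelse(rows$scenario == "Intact", 0.8, rnorm(nrow(rows), 0.5, 0.1))
    rows$force_N_per_kg <- rnorm(nrow(rows), 1, 0.2)
    rows$jrf_x <- rows$jrf_y <- rows$jrf_z <- 0
    rows$feasible <- TRUE; rows$n_trials_excluded <- 0
    res <- delta_correlation(rows, "Tm", "Flexion", 20)
    if (abs(res$rho) < 0.2 && res$classification == "none") n_pass <- n_pass + 1
  }
  expect_gte(n_pass / n_seeds, 0.9)
})

test_that("zero-variance margins yield a flagged non-classification", {
  scens <- names(tear_scenarios())
  rows <- expand.grid(participant = sprintf("P%02d", 1:5),
                      scenario = scens, stringsAsFactors = FALSE)
  rows$activity <- "Flexion"; rows$bin_deg <- 20; rows$muscle <- "Tm"
  rows$stability <- 0.7 # identical everywhere: zero-variance delta margin
  set.seed(1); rows$force_N_per_kg <- rnorm(nrow(rows))
  rows$jrf_x <- rows$jrf_y <- rows$jrf_z <- 0
  rows$feasible <- TRUE; rows$n_trials_excluded <- 0
  res <- delta_correlation(rows, "Tm", "Flexion", 20)
  expect_equal(res$classification, "none")
  expect_match(res$note, "degenerate")
})

test_that("incomplete blocks are excluded from a cell with a count", {
  scens <- c("Intact", "S0")
  rows <- expand.grid(participant = sprintf("P%02d", 1:6),
                      scenario = scens, stringsAsFactors = FALSE)
  rows$activity <- "Flexion"; rows$bin_deg <- 20; rows$muscle <- "MD"
  set.seed(2)
  rows$force_N_per_kg <- rnorm(nrow(rows), 2)
  rows$stability <- rnorm(nrow(rows), 0.5, 0.05)
  rows$jrf_x <- rows$jrf_y <- rows$jrf_z <- 0
  rows$feasible <- TRUE; rows$n_trials_excluded <- 0
  rows$stability[1] <- NA; rows$force_N_per_kg[1] <- NA # P01 aborted
  cm <- glenosim:::cell_matrix(rows, "MD", "Flexion", 20, scens)
  expect_equal(nrow(cm), 5)
  expect_equal(attr(cm, "n_excluded"), 1)
})
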