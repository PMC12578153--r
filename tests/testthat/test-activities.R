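test_that("activity registry carries the analyzed elevation ranges", {
  reg <- activity_registry()
  expect_equal(reg$Flexion$analysis_range_deg, c(10, 120))
  expect_equal(reg$Abduction$analysis_range_deg, c(10, 120))
  expect_equal(reg$Shoulder$analysis_range_deg, c(10, 40))
  expect_equal(reg$Head$analysis_range_deg, c(10, 110))
  expect_equal(reg$UpL$analysis_range_deg, c(40, 60))
  expect_equal(reg$UpH$analysis_range_deg, c(80, 100))
  expect_equal(reg$UpL$external_load_kg, 1)
  expect_equal(reg$UpH$external_load_kg, 1)
  expect_equal(reg$Flexion$external_load_kg, 0)
})

test_that("trajectories are deterministic, cover the range, and carry the load", {
  p <- test_participant()
  t1 <- generate_trajectory("Flexion", p, seed = 1)
  t2 <- generate_trajectory("Flexion", p, seed = 1)
  expect_identical(t1, t2)
  t3 <- generate_trajectory("Flexion", p, seed = 2)
  expect_false(isTRUE(all.equal(t1$elevation_deg, t3$elevation_deg)))

  for (s in c(1, 5, 9)) {
    tr <- generate_trajectory("Flexion", p, seed = s)
    expect_lte(min(tr$elevation_deg), 10)
    expect_gte(max(tr$elevation_deg), 120)
  }
  up <- generate_trajectory("UpL", p, seed = 3)
  expect_true(all(up$load_kg == 1))

  # elevation completed in about 5 s for Flexion and Abduction
  for (a in c("Flexion", "Abduction")) {
    tr <- generate_trajectory(a, p, seed = 4)
    expect_equal(max(tr$time_s), 5, tolerance = 0.1)
    expect_equal(nrow(tr), 501) # 100 Hz sampling
  }
})

test_that("zero-phase Butterworth filter has unit DC gain and halves a cutoff sine", {
  expect_equal(lowpass_filter(rep(3.7, 200)), rep(3.7, 200), tolerance = 1e-7)

  t <- seq(0, 5, by = 0.01)
  x <- sin(2 * pi * 6 * t)
  y <- lowpass_filter(x, 6, 100)
  mid <- t > 1 & t < 4
  # amplitude via projection onto the quadrature pair, mid-section only
  amp <- sqrt(sum(y[mid] * sin(2 * pi * 6 * t[mid]))^2 +
                sum(y[mid] * cos(2 * pi * 6 * t[mid]))^2) /
    (sum(sin(2 * pi * 6 * t[mid])^2))
  expect_equal(amp, 0.5, tolerance = 0.05 * 0.5)

  noise <- with_seed_local(11, function() rnorm(1000))
  expect_lt(var(lowpass_filter(noise)), var(noise))

  expect_error(lowpass_filter(rep(0, 100), cutoff_hz = 60, fs_hz = 100),
               "Nyquist")
})

test_that("quasi-static net moments match closed-form gravity levers", {
  m <- load_model()
  p <- list(arm = list(mass_kg = 3.5, com_m = 0.3, hand_m = 0.6))

  drooped <- net_moments(m, make_posture(m, 0), p, 0)
  expect_equal(sqrt(sum(drooped^2)), 0, tolerance = 1e-9)

  ab90 <- net_moments(m, make_posture(m, 90, plane_deg = 0), p, 0)
  expect_equal(sqrt(sum(ab90^2)), 3.5 * 9.81 * 0.3, tolerance = 1e-9)

  loaded <- net_moments(m, make_posture(m, 90, plane_deg = 0), p, 1)
  expect_equal(sqrt(sum(loaded^2)) - sqrt(sum(ab90^2)), 1 * 9.81 * 0.6,
               tolerance = 1e-9)
})

test_that("lumped-arm moments agree with a two-segment rigid-body oracle", {
  m <- load_model()
  # segments: upper arm 2.0 kg at 0.15 m, forearm+hand 1.2 kg at 0.45 m
  m1 <- 2.0; d1 <- 0.15; m2 <- 1.2; d2 <- 0.45; dh <- 0.62; load <- 1
  lumped <- list(arm = list(mass_kg = m1 + m2,
                            com_m = (m1 * d1 + m2 * d2) / (m1 + m2),
                            hand_m = dh))
  for (th in c(20, 55, 90, 110)) {
    for (pl in c(0, 45, 90)) {
      po <- make_posture(m, th, plane_deg = pl)
      got <- net_moments(m, po, lumped, load)
      a <- glenosim:::arm_axis(po$elevation_gh_deg, pl)
      g_hat <- glenosim:::gravity_dir_scap(po)
      oracle <- -9.81 * glenosim:::cross3(
        (m1 * d1 + m2 * d2 + load * dh) * a, g_hat)
      expect_equal(got, oracle, tolerance = 1e-12)
    }
  }
  # linearity in the external load at fixed posture
  po <- make_posture(m, 70, plane_deg = 30)
  m0 <- net_moments(m, po, lumped, 0)
  m1v <- net_moments(m, po, lumped, 1)
  m2v <- net_moments(m, po, lumped, 2)
  expect_equal(m2v - m1v, m1v - m0, tolerance = 1e-12)
})

test_that("binning hits every 10-degree centre on the ascending phase", {
  p <- test_participant()
  fl <- generate_trajectory("Flexion", p, seed = 1)
  bins <- bin_by_elevation(fl, fl$elevation_deg, "Flexion")
  expect_equal(bins$bin_deg, seq(10, 120, by = 10)) # 12 bins
  uh <- generate_trajectory("UpH", p, seed = 1)
  bins_uh <- bin_by_elevation(uh, uh$elevation_deg, "UpH")
  expect_equal(bins_uh$bin_deg, c(80, 90, 100))

  # identity signal on a monotone ramp: binned value ~ centre within one step
  ramp <- data.frame(time_s = seq(0, 5, by = 0.01))
  ramp$elevation_deg <- seq(0, 130, length.out = nrow(ramp))
  step <- diff(ramp$elevation_deg[1:2])
  b <- bin_by_elevation(ramp, ramp$elevation_deg, "Flexion")
  expect_true(all(abs(b$value - b$bin_deg) <= step + 1e-12))

  # a trajectory that never reaches a bin names it in the error
  short <- data.frame(time_s = seq(0, 5, by = 0.01))
  short$elevation_deg <- seq(0, 90, length.out = nrow(short))
  expect_error(bin_by_elevation(short, short$elevation_deg, "Flexion"), "100")
})

test_that("binned crossing values converge as the sampling rate increases", {
  p <- test_participant(noise = 0)
  vals <- lapply(c(100, 400), function(fs) {
    tr <- generate_trajectory("Flexion", p, seed = 1, fs_hz = fs)
    bin_by_elevation(tr, tr$elevation_deg, "Flexion")$value
  })
  expect_equal(vals[[1]], vals[[2]], tolerance = 0.01)
})
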