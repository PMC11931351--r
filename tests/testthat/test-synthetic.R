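test_that("ground-truth draws are deterministic, ratio-bounded and scale-preserving", {
  panel <- default_nsd_panel()
  for (s in 1:10) {
    gt1 <- make_ground_truth(panel, seed = s)
    gt2 <- make_ground_truth(panel, seed = s)
    expect_identical(gt1, gt2)
    expect_true(all(gt1$ratio_ga_cp >= 2 & gt1$ratio_ga_cp <= 20))
    expect_true(all(gt1$pool_cp >= 0 & gt1$pool_ga >= 0))
    # the split preserves each analyte's whole-cell amount
    expect_equal(gt1$pool_cp + gt1$pool_ga, panel$total_amol_per_cell)
  }
  expect_false(identical(make_ground_truth(panel, seed = 1),
                         make_ground_truth(panel, seed = 2)))
  # panel spans the observed amount range
  tot <- gt1$pool_cp + gt1$pool_ga
  expect_equal(tot[gt1$analyte == "UDP-Glc/Gal"], 2923.58)
  expect_equal(tot[gt1$analyte == "GDP-Man"], 10.93)
})

test_that("degenerate ratio interval and invalid panels are handled", {
  gt <- make_ground_truth(ratio_range = c(1, 1), seed = 3)
  expect_equal(gt$pool_ga, gt$pool_cp)
  bad <- data.frame(analyte = c("ok", "broken"),
                    total_amol_per_cell = c(10, -5))
  expect_error(make_ground_truth(bad), "broken")
  expect_error(make_ground_truth(default_nsd_panel()[0, ]), "non-empty")
})

test_that("titration expectations follow the two-pool release model and conserve mass", {
  truth <- make_ground_truth(seed = 5)
  rel <- metabolite_release_params()
  cfg <- sim_config(seed = 5, noise_cv = 0,
                    digitonin_grid = c(0, 50, 100, 200, 400))
  ts <- simulate_titration(truth, rel, cfg)
  logistic <- function(x) rel$floor + rel$span /
    (1 + exp((rel$midpoint - x) / rel$steepness))
  leak <- function(x) rel$contamination_span /
    (1 + exp((rel$contamination_midpoint - x) / rel$steepness))
  for (i in seq_len(nrow(truth))) {
    sub <- ts[ts$analyte == truth$analyte[i] & ts$replicate == 1, ]
    cp <- sub$amount_amol_per_cell[sub$fraction == "CP"]
    org <- sub$amount_amol_per_cell[sub$fraction == "organelle"]
    x <- sub$digitonin_ug_per_ml[sub$fraction == "CP"]
    expect_equal(cp, truth$pool_cp[i] * logistic(x) +
                   truth$pool_ga[i] * leak(x), tolerance = 1e-12)
    # conservation before noise: CP + organelle = total pool exactly
    expect_equal(cp + org,
                 rep(truth$pool_cp[i] + truth$pool_ga[i], length(x)),
                 tolerance = 1e-12)
  }
  # x = 0: CP close to floor * pool_cp; saturating x: floor+span plus leak
  at0 <- ts[ts$digitonin_ug_per_ml == 0 & ts$fraction == "CP" &
              ts$replicate == 1, ]
  cp0 <- at0$amount_amol_per_cell[match(truth$analyte, at0$analyte)]
  # y(0) = floor + span/(1 + exp(midpoint/steepness)) ~= 1.15 * floor here
  expect_equal(cp0, truth$pool_cp * rel$floor, tolerance = 0.2)
  expect_error(simulate_titration(truth, rel,
                                  sim_config(digitonin_grid = c(100, 500))),
               "\\[0, 400\\]")
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
})

test_that("metabolites release earlier and steeper than proteins", {
  met <- metabolite_release_params()
  pro <- protein_release_params()
  expect_lt(met$midpoint, pro$midpoint)
  # empirical half-release on noise-free single-pool curves
  truth <- pure_cp_truth()
  cfg <- sim_config(noise_cv = 0, replicates = 1,
                    digitonin_grid = WIDE_GRID)
  half_release <- function(params) {
    ts <- normalize_series(simulate_titration(truth, params, cfg))
    cp <- ts[ts$fraction == "CP", ]
    stats::approx(cp$amount_amol_per_cell, cp$digitonin_ug_per_ml,
                  xout = (min(cp$amount_amol_per_cell) +
                            max(cp$amount_amol_per_cell)) / 2)$y
  }
  expect_lt(half_release(met), half_release(pro))
})

test_that("standard-addition generator produces the calibration line", {
  sa <- simulate_standard_addition(0.5, c(0, 1, 2), response_slope = 100,
                                   noise_cv = 0)
  expect_equal(sa$peak_area, c(50, 150, 250))
  sa0 <- simulate_standard_addition(0, c(0, 1, 2), response_slope = 100,
                                    noise_cv = 0)
  expect_equal(sa0$peak_area[sa0$spike_nM == 0], 0)
  expect_error(simulate_standard_addition(0.5, c(1, 1, 1)), "distinct")
  expect_error(simulate_standard_addition(0.5, c(1, 2)), "unspiked")
})

test_that("recovered native concentration is unbiased over many noisy sets", {
  # Monte-Carlo oracle: 500 seeds at CV 5%, truth 0.5 nM
  est <- vapply(1:500, function(s) {
    sa <- simulate_standard_addition(0.5, c(0, 1, 2), response_slope = 100,
                                     noise_cv = 0.05, seed = s)
    stdadd_fit(sa)$native_conc
  }, numeric(1))
  expect_lt(abs(mean(est) / 0.5 - 1), 0.02)
})

test_that("degradation conserves per-base totals and contrasts the methods", {
  panel <- default_nucleotide_panel()
  expect_equal(simulate_degradation(panel, "lyophilization", duration_h = 0),
               panel)
  # conservation to 1e-12 relative on random panels
  set.seed(11)
  for (i in 1:25) {
    p <- data.frame(base = "adenine", ntp = runif(1, 0, 5),
                    ndp = runif(1, 0, 5), nmp = runif(1, 0, 5))
    for (m in c("lyophilization", "evaporation")) {
      d <- simulate_degradation(p, m, duration_h = runif(1, 0, 72),
                                temperature_K = runif(1, 270, 310))
      expect_equal(d$ntp + d$ndp + d$nmp, p$ntp + p$ndp + p$nmp,
                   tolerance = 1e-12)
      expect_true(all(c(d$ntp, d$ndp, d$nmp) >= 0))
    }
  }
  # calibrated defaults: EC(evaporated)/EC(lyophilized) = 63%,
  # lyophilization conserves > 54% triphosphate
  lyo <- simulate_degradation(panel, "lyophilization")
  evap <- simulate_degradation(panel, "evaporation")
  expect_equal(energy_charge(evap)[1] / energy_charge(lyo)[1], 0.63,
               tolerance = 1e-9)
  expect_true(all(triphosphate_fraction(lyo) > 0.54))
  expect_error(simulate_degradation(panel, "microwave"))
})

test_that("pulse kernels peak as configured and respect causality", {
  k <- pulse_kernel("C", "GA", baseline = 800, peak_amplitude = 1350,
                    peak_time = 120, pulse_time = 80.5)
  # noise-free trace attains exactly baseline + amplitude at peak_time
  expect_equal(eval_pulse_kernel(k, 120), 2150)
  tt <- seq(80.5, 400, by = 0.05)
  expect_equal(max(eval_pulse_kernel(k, tt)), 2150, tolerance = 1e-6)
  expect_equal(tt[which.max(eval_pulse_kernel(k, tt))], 120,
               tolerance = 0.1)
  # causality: flat at baseline up to the pulse
  expect_equal(eval_pulse_kernel(k, c(0, 40, 80.5)), rep(800, 3))
  # return toward baseline at long times
  expect_lt(eval_pulse_kernel(k, 1500), 810)
  flat <- pulse_kernel("A", "CP", baseline = 100, peak_amplitude = 0,
                       peak_time = 100)
  expect_equal(eval_pulse_kernel(flat, c(0, 90, 120, 160)), rep(100, 4))
  expect_error(pulse_kernel("A", "CP", baseline = 1, peak_amplitude = 1,
                            peak_time = 100, decay_rate = 0), "decay_rate")
  expect_error(simulate_pulse_timecourse(k, sample_times = c(10, 5)),
               "increasing")
})

test_that("timecourse simulation is deterministic and kernel-faithful", {
  ks <- default_pulse_kernels()
  t1 <- simulate_pulse_timecourse(ks, noise_cv = 0.1, seed = 9)
  t2 <- simulate_pulse_timecourse(ks, noise_cv = 0.1, seed = 9)
  expect_identical(t1, t2)
  t0 <- simulate_pulse_timecourse(ks, noise_cv = 0)
  cGA <- t0[t0$condition == "C" & t0$compartment == "GA" &
              t0$replicate == 1, ]
  expect_equal(max(cGA$amount_amol_per_cell), 2150, tolerance = 1e-9)
  expect_equal(cGA$time_h[which.max(cGA$amount_amol_per_cell)], 120)
})

test_that("glycan profiles form a simplex monotone in donor exposure", {
  p0 <- simulate_glycan_profiles(0)
  expect_equal(p0$FA2, 1)
  expect_equal(p0$FA2G1 + p0$FA2G2, 0)
  psat <- simulate_glycan_profiles(1e9)
  expect_equal(psat$FA2G2, 1, tolerance = 1e-6)
  ex <- seq(0, 3000, by = 50)
  pr <- simulate_glycan_profiles(ex)
  expect_equal(pr$FA2 + pr$FA2G1 + pr$FA2G2, rep(1, length(ex)),
               tolerance = 1e-12)
  expect_true(all(diff(pr$FA2G2) >= 0))
  expect_true(all(as.matrix(pr[c("FA2", "FA2G1", "FA2G2")]) >= 0 &
                    as.matrix(pr[c("FA2", "FA2G1", "FA2G2")]) <= 1))
  expect_error(simulate_glycan_profiles(-1), ">= 0")
})
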