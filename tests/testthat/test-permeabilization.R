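test_that("normalization scales each analyte to its maximum cellular total", {
  s <- toy_series("m1", c(10, 50, 100), cp = c(1, 3, 7),
                  organelle = c(1, 1, 1))  # totals 2, 4, 8
  n <- normalize_series(s)
  tot <- tapply(n$amount_amol_per_cell, n$digitonin_ug_per_ml, sum)
  expect_equal(as.numeric(tot), c(0.25, 0.5, 1.0))
  # idempotence
  expect_equal(normalize_series(n), n)
  # two analytes at different scales normalize independently
  s2 <- rbind(s, toy_series("m2", c(10, 50, 100), cp = c(100, 300, 500),
                            organelle = c(300, 200, 100)))
  n2 <- normalize_series(s2)
  # m2 totals are 400, 500, 600 -> everything divides by 600
  expect_equal(
    n2$amount_amol_per_cell[n2$analyte == "m2" & n2$fraction == "CP"],
    c(100, 300, 500) / 600)
  tot2 <- tapply(n2$amount_amol_per_cell[n2$analyte == "m2"],
                 n2$digitonin_ug_per_ml[n2$analyte == "m2"], sum)
  expect_equal(max(tot2), 1)
  z <- toy_series("dead", c(10, 50, 100), cp = c(0, 0, 0),
                  organelle = c(0, 0, 0))
  expect_error(normalize_series(z), "dead")
})

test_that("per-fraction normalization rescales each fraction to its own maximum", {
  s <- toy_series("m1", c(10, 50, 100), cp = c(1, 3, 7),
                  organelle = c(4, 2, 1))
  n <- normalize_series(s, denominator = "per_fraction")
  expect_equal(n$amount_amol_per_cell[n$fraction == "CP"], c(1, 3, 7) / 7)
  expect_equal(n$amount_amol_per_cell[n$fraction == "organelle"],
               c(4, 2, 1) / 4)
})

test_that("sigmoid evaluation satisfies midpoint and asymptote identities", {
  expect_equal(eval_sigmoid(c(0, 1, 50, 10), 50), 0.5)
  cf <- REF_COEFS
  expect_equal(eval_sigmoid(cf, cf[["c"]]), cf[["a"]] + cf[["b"]] / 2)
  expect_equal(eval_sigmoid(cf, 1e6), cf[["a"]] + cf[["b"]])
  expect_equal(eval_sigmoid(cf, -1e6), cf[["a"]])
})

test_that("sigmoid inversion is the closed-form inverse", {
  expect_equal(invert_sigmoid(c(0, 1, 50, 10), 0.5), 50)
  cf <- REF_COEFS
  for (x in c(10, 50, 100, 200))
    expect_equal(invert_sigmoid(cf, eval_sigmoid(cf, x)), x,
                 tolerance = 1e-9)
  # reference coefficients at y = 0.38: closed form gives ~73.1 ug/mL
  expect_equal(invert_sigmoid(cf, 0.38), 73.06606, tolerance = 1e-6)
  expect_error(invert_sigmoid(cf, 0.05), "strictly inside")
  expect_error(invert_sigmoid(cf, 1.2), "strictly inside")
})

test_that("eval/invert are exact inverses over random valid fits", {
  set.seed(21)
  for (i in 1:50) {
    cf <- random_release_coefs()
    # sample where y is representably inside (a, a+b): beyond ~8
    # steepness units the curve saturates in double precision
    x <- cf[["c"]] + cf[["d"]] * runif(5, -8, 8)
    expect_equal(invert_sigmoid(cf, eval_sigmoid(cf, x)), x,
                 tolerance = 1e-9)
    y <- runif(5, cf[["a"]] + 1e-4, cf[["a"]] + cf[["b"]] - 1e-4)
    expect_equal(eval_sigmoid(cf, invert_sigmoid(cf, y)), y,
                 tolerance = 1e-9)
    # monotonicity for b > 0, d > 0
    grid <- seq(0, 400, length.out = 100)
    expect_true(all(diff(eval_sigmoid(cf, grid)) > 0))
  }
})

test_that("noise-free titrations recover the release parameters", {
  truth <- pure_cp_truth()
  cfg <- sim_config(noise_cv = 0, digitonin_grid = WIDE_GRID)
  ts <- normalize_series(simulate_titration(truth,
                                            metabolite_release_params(),
                                            cfg))
  fit <- release_fit(ts, fraction = "CP")
  expect_s3_class(fit, "release_fit")
  expect_equal(unname(coef(fit)), unname(REF_COEFS), tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  expect_equal(fit$n_points, length(WIDE_GRID))
  # direct x/y interface
  xy <- data.frame(x = WIDE_GRID, y = eval_sigmoid(REF_COEFS, WIDE_GRID))
  expect_equal(unname(coef(release_fit(xy))), unname(REF_COEFS),
               tolerance = 1e-6)
})

test_that("degenerate or underdetermined series are rejected", {
  xy <- data.frame(x = WIDE_GRID, y = rep(0.5, length(WIDE_GRID)))
  expect_error(release_fit(xy), "degenerate")
  xy3 <- data.frame(x = c(10, 50, 100),
                    y = eval_sigmoid(REF_COEFS, c(10, 50, 100)))
  expect_error(release_fit(xy3), "4 distinct")
})

test_that("fit methods are consistent with the fitted object", {
  xy <- data.frame(x = WIDE_GRID, y = eval_sigmoid(REF_COEFS, WIDE_GRID))
  fit <- release_fit(xy)
  expect_equal(predict(fit, 91.1277), eval_sigmoid(fit, 91.1277))
  expect_equal(length(residuals(fit)), fit$n_points)
  expect_equal(fitted(fit) + residuals(fit), xy$y, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_output(print(fit), "logistic")
  expect_output(print(summary(fit)), "Asymptotes")
  sims <- simulate(fit, nsim = 3, seed = 2, noise_cv = 0.1)
  expect_equal(dim(sims), c(length(WIDE_GRID), 3L))
  expect_true(all(sims > 0))
})

test_that("noisy triplicate fits recover the midpoint reliably", {
  truth <- pure_cp_truth()
  n_seeds <- 100
  c_hat <- numeric(n_seeds)
  r2 <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(seed = s, noise_cv = 0.10, replicates = 3,
                      digitonin_grid = WIDE_GRID)
    ts <- normalize_series(simulate_titration(truth,
                                              metabolite_release_params(),
                                              cfg))
    fit <- release_fit(ts, fraction = "CP")
    c_hat[s] <- coef(fit)[["c"]]
    r2[s] <- fit$r_squared
  }
  within <- mean(abs(c_hat / REF_COEFS[["c"]] - 1) <= 0.15)
  expect_gte(within, 0.90)
  expect_gte(stats::median(r2), 0.98)
})

test_that("compartment distribution reproduces the literature arithmetic", {
  d <- compartment_distribution(conc_ga = 40, vol_ga = 0.022,
                                conc_cp = 1, vol_cp = 0.55)
  expect_equal(unname(d$amounts), c(0.88, 0.55))
  expect_equal(d$total, 1.43)
  expect_equal(unname(round(d$shares_pct)), c(62, 38))
  expect_equal(sum(d$shares_pct), 100, tolerance = 1e-12)
  # symmetry and arithmetic-equality cases
  expect_equal(unname(compartment_distribution(1, 1, 1, 1)$shares_pct),
               c(50, 50))
  expect_equal(unname(compartment_distribution(10, 0.05, 1, 0.5)$shares_pct),
               c(50, 50))
  expect_error(compartment_distribution(conc_ga = 0), "> 0")
  set.seed(31)
  for (i in 1:20) {
    d <- compartment_distribution(runif(1, 1, 50), runif(1, 0.01, 0.1),
                                  runif(1, 0.5, 2), runif(1, 0.3, 0.7))
    expect_equal(sum(d$shares_pct), 100, tolerance = 1e-12)
  }
})

test_that("operating digitonin is rounded down on the available grid", {
  # exact solve of 58 ug/mL rounds down to the 50 ug/mL grid point
  sel <- select_operating_digitonin(58, grid = c(25, 50, 100, 200))
  expect_equal(sel$selected, 50)
  expect_false(sel$below_grid)
  # a solve equal to a grid point is kept
  expect_equal(select_operating_digitonin(100,
                                          grid = c(25, 50, 100, 200))$selected,
               100)
  # below every grid point: smallest value plus warning flag
  expect_warning(low <- select_operating_digitonin(10,
                                                   grid = c(25, 50, 100)))
  expect_equal(low$selected, 25)
  expect_true(low$below_grid)
  expect_error(select_operating_digitonin(58, grid = numeric(0)),
               "non-empty")
  # from a fit object: reference curve at 38% -> 73.1 -> 50
  xy <- data.frame(x = WIDE_GRID, y = eval_sigmoid(REF_COEFS, WIDE_GRID))
  fit <- release_fit(xy)
  sel2 <- select_operating_digitonin(fit, 0.38, c(25, 50, 100, 200))
  expect_equal(sel2$exact, 73.066, tolerance = 1e-3)
  expect_equal(sel2$selected, 50)
})
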