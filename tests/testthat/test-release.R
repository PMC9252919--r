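test_that("half-life conversions are exact and invert each other", {
  # the reported formation rate corresponds to a 2.94 h half-life
  expect_equal(round(half_life(6.55e-5), 2), 2.94)
  # unit definition: k = ln2 s^-1 gives a one-second half-life
  expect_equal(half_life(log(2)), 1 / 3600, tolerance = 1e-14)
  for (k in 10^seq(-8, 2)) {
    expect_equal(rate_from_half_life(half_life(k)), k, tolerance = 1e-12)
  }
  expect_error(half_life(0), "positive")
  expect_error(rate_from_half_life(-2), "positive")
})

test_that("sequential profile satisfies initial condition and mass balance", {
  tt <- seq(0, 30 * 3600, length.out = 200)
  prof <- sequential_profile(tt, a0 = 2.5, k1 = 1e-4, k2 = 3e-4)
  expect_equal(unlist(prof[1, c("A", "B", "C")]),
               c(A = 2.5, B = 0, C = 0))
  expect_true(all(abs(prof$A + prof$B + prof$C - 2.5) < 1e-12))
  expect_true(all(prof$A >= 0 & prof$B >= 0 & prof$C >= 0))
})

test_that("Bateman closed form agrees with a numerical ODE oracle", {
  skip_if_not_installed("deSolve")
  cases <- list(c(k1 = 1e-4, k2 = 1e-3), c(k1 = 5e-4, k2 = 5.1e-4),
                c(k1 = 2e-3, k2 = 1e-4))
  tt <- seq(0, 20 * 3600, length.out = 60)
  for (cs in cases) {
    ode <- deSolve::lsoda(
      y = c(A = 1, B = 0, C = 0), times = tt,
      func = function(t, y, p) {
        list(c(-p[1] * y["A"], p[1] * y["A"] - p[2] * y["B"],
               p[2] * y["B"]))
      }, parms = cs, rtol = 1e-12, atol = 1e-14)
    closed <- sequential_profile(tt, 1, cs[["k1"]], cs[["k2"]])
    expect_equal(closed$A, unname(ode[, "A"]), tolerance = 1e-8)
    expect_equal(closed$B, unname(ode[, "B"]), tolerance = 1e-8)
    expect_equal(closed$C, unname(ode[, "C"]), tolerance = 1e-8)
  }
})

test_that("equal-rate degenerate case uses the stable analytic limit", {
  tt <- seq(0, 10 * 3600, length.out = 50)
  k <- 2e-4
  exact <- 1 * k * tt * exp(-k * tt)
  near <- sequential_profile(tt, 1, k, k * (1 + 1e-12))
  equal <- sequential_profile(tt, 1, k, k)
  expect_equal(near$B, exact, tolerance = 1e-9)
  expect_equal(equal$B, exact, tolerance = 1e-12)
})

test_that("fast second step makes the intermediate invisible", {
  # oxygenated-solution regime: hydroquinone never accumulates
  tt <- seq(0, 20 * 3600, length.out = 100)
  k1 <- 1e-4
  prof <- sequential_profile(tt, 1, k1, k1 * 1e6)
  expect_lt(max(prof$B), 1e-5)
  expect_equal(prof$C, 1 * (1 - exp(-k1 * tt)), tolerance = 1e-5)
})

test_that("nmr_fraction normalizes integrals per proton", {
  expect_equal(nmr_fraction(1.0, 1, 12.0, 12), 1.0)
  expect_equal(nmr_fraction(0.5, 1, 12.0, 12), 0.5)
  # stoichiometric oracle: x = (I_p/n_p)/(I_t/n_t)
  set.seed(17)
  for (i in 1:10) {
    ip <- runif(1, 0.1, 2); np <- sample(1:3, 1)
    it <- runif(1, 5, 20); nt <- sample(10:14, 1)
    expect_equal(nmr_fraction(ip, np, it, nt), (ip / np) / (it / nt))
  }
  expect_error(nmr_fraction(1, 1, 0, 12), "positive")
})

test_that("exact first-order traces are recovered to high precision", {
  tt <- seq(0, 20 * 3600, length.out = 12)
  k <- 6.18e-5
  tc_decay <- time_course(tt, 0.8 * exp(-k * tt))
  fit_d <- fit_first_order(tc_decay, "decay")
  expect_true(fit_d$converged)
  expect_equal(fit_d$rate, k, tolerance = 1e-6)
  expect_equal(fit_d$half_life_h, half_life(k), tolerance = 1e-6)

  tc_form <- time_course(tt, 1.3 * (1 - exp(-k * tt)))
  fit_f <- fit_first_order(tc_form, "formation")
  expect_equal(fit_f$rate, k, tolerance = 1e-6)
  expect_equal(fit_f$amplitude, 1.3, tolerance = 1e-6)
})

test_that("free-baseline decay recovers an offset trace", {
  tt <- seq(0, 30 * 3600, length.out = 15)
  y <- 0.9 * exp(-5e-5 * tt) + 0.2
  fit <- fit_first_order(time_course(tt, y), "decay", baseline = "free")
  expect_equal(fit$rate, 5e-5, tolerance = 1e-5)
  expect_equal(fit$baseline, 0.2, tolerance = 1e-5)
})

test_that("rate estimates are invariant to the input time unit", {
  tt_h <- seq(0, 20, length.out = 10)
  y <- exp(-6e-5 * tt_h * 3600)
  fit_s <- fit_first_order(time_course(tt_h * 3600, y, time_unit = "s"),
                           "decay")
  fit_h <- fit_first_order(time_course(tt_h, y, time_unit = "h"), "decay")
  expect_equal(fit_s$rate, fit_h$rate, tolerance = 1e-10)
  expect_equal(fit_s$half_life_h, fit_h$half_life_h, tolerance = 1e-10)
})

test_that("paired decay/formation traces give consistent rate estimates", {
  # consumption of the ketol and formation of the quinone share one rate:
  # their 95% confidence intervals must overlap
  k <- 6.4e-5
  tt <- seq(0, 20 * 3600, length.out = 10)
  sim_d <- simulate_timecourse("first_order_decay", k, tt,
                               noise = noise_model(sd = 0.02), seed = 21)
  sim_f <- simulate_timecourse("first_order_formation", k, tt,
                               noise = noise_model(sd = 0.02), seed = 22)
  fd <- fit_first_order(sim_d$tc, "decay")
  ff <- fit_first_order(sim_f$tc, "formation")
  expect_true(fd$rate_ci[["lower"]] <= ff$rate_ci[["upper"]] &&
                ff$rate_ci[["lower"]] <= fd$rate_ci[["upper"]])
})

test_that("degenerate fitting inputs are rejected with diagnostics", {
  expect_error(fit_first_order(time_course(c(0, 1, 2) * 3600, c(1, 0.5, 0.2)),
                               "decay"),
               "insufficient points")
  tt <- seq(0, 10 * 3600, length.out = 6)
  expect_error(fit_first_order(time_course(tt, rep(1, 6)), "decay"),
               "constant")
  expect_error(time_course(c(0, 10, 5), c(1, 2, 3)), "strictly increasing")
  expect_error(sequential_profile(c(0, 10), 1, -1e-4, 1e-3), "positive")
})
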