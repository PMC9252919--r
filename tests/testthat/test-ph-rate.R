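test_that("predict_k_obs handles degenerate partitions exactly", {
  net <- single_reactive_network(rate = 1e-5)
  for (ph in c(0, 7, 14)) expect_equal(predict_k_obs(net, ph), 1e-5)

  # reactive anion at half-dissociation: half the intrinsic rate
  net2 <- two_species_network(log_beta_anion = -10, anion_rate = 1e4)
  expect_equal(predict_k_obs(net2, 10), 5e3, tolerance = 1e-12)
})

test_that("predict_k_obs equals the brute-force channel summation", {
  net <- build_default_network("PAB-PhQ")
  for (ph in c(3, 6, 9)) {
    expect_equal(predict_k_obs(net, ph), brute_force_k_obs(net, ph),
                 tolerance = 1e-12)
  }
})

test_that("predict_k_obs is bounded by the intrinsic rates", {
  for (mol in c("PAB-PhQ", "PAB-BL")) {
    net <- build_default_network(mol)
    k <- predict_k_obs(net, seq(-2, 16, by = 0.5))
    expect_true(all(k > 0))
    expect_true(all(k <= max(net$species$rate_s, na.rm = TRUE)))
  }
  no_channel <- two_species_network()
  expect_error(predict_k_obs(no_channel, 7), "no reactive species")
})

test_that("default parameterizations reproduce the qualitative pH-rate shapes", {
  # phenanthrenequinone ketol: acid-promoted elimination peaking at pH 5-6
  grid <- seq(1, 10, by = 0.01)
  k_phq <- predict_k_obs(build_default_network("PAB-PhQ"), grid)
  peak <- grid[which.max(k_phq)]
  expect_gte(peak, 5)
  expect_lte(peak, 6)

  # beta-lapachone ketol: >= 10x faster at pH 3 than at pH 6
  bl <- build_default_network("PAB-BL")
  expect_gte(predict_k_obs(bl, 3) / predict_k_obs(bl, 6), 10)
})

test_that("goodness_of_fit matches hand-computed values and flags degeneracy", {
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3)),
               list(chi_square = 0, r_square = 1))
  # chi2 = (3-4)^2 = 1; R2 = 1 - 1/2 = 0.5
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 4)),
               list(chi_square = 1, r_square = 0.5))
  # weights scale chi2 only
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 4), c(2, 2, 2))$chi_square, 2)
  expect_warning(g <- goodness_of_fit(c(2, 2, 2), c(1, 2, 3)), "undefined")
  expect_true(is.na(g$r_square))
  expect_error(goodness_of_fit(1:3, 1:2), "length mismatch")
})

test_that("noise-free profiles return the generating constants exactly", {
  net <- build_default_network("PAB-PhQ")
  free <- c("NH-", "OH+", "Zw1", "O-")
  sim <- simulate_ph_profile(net, seq(1, 10, length.out = 13),
                             noise_model(sd = 0), seed = 1)
  fit <- fit_ph_profile(sim$profile, net, free = free, n_starts = 8, seed = 3)
  truth <- sim$truth$log_beta[fit$free_parameters$label]
  expect_true(fit$converged)
  expect_equal(fit$free_parameters$estimate, unname(truth), tolerance = 1e-4)
  expect_lt(fit$chi_square, 1e-10)
  expect_equal(fit$r_square, 1, tolerance = 1e-8)
})

test_that("fitting is invariant to point order and weight rescaling", {
  net <- build_default_network("PAB-PhQ")
  free <- c("Zw1", "O-")
  sim <- simulate_ph_profile(net, seq(2, 9, length.out = 9),
                             noise_model(sd = 0.05, replicates = 3), seed = 5)
  p <- sim$profile
  fit1 <- fit_ph_profile(p, net, free, n_starts = 6, seed = 9)

  perm <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  p_perm <- ph_rate_profile(p$points$ph[perm], p$points$k_obs[perm],
                            p$points$ci95[perm], p$points$replicates[perm])
  fit2 <- fit_ph_profile(p_perm, net, free, n_starts = 6, seed = 9)
  expect_equal(fit1$free_parameters$estimate, fit2$free_parameters$estimate,
               tolerance = 1e-8)

  # scaling all CIs by a constant rescales weights uniformly: same optimum
  p_scaled <- ph_rate_profile(p$points$ph, p$points$k_obs,
                              p$points$ci95 * 7, p$points$replicates)
  fit3 <- fit_ph_profile(p_scaled, net, free, n_starts = 6, seed = 9)
  expect_equal(fit1$free_parameters$estimate, fit3$free_parameters$estimate,
               tolerance = 1e-6)
})

test_that("under-determined and malformed fits are rejected", {
  net <- build_default_network("PAB-PhQ")
  p2 <- ph_rate_profile(c(4, 7), c(1e-5, 1e-6))
  expect_error(fit_ph_profile(p2, net, free = c("NH-", "OH+", "Zw1", "O-")),
               "under-determined")
  p <- ph_rate_profile(c(3, 5, 7, 9), c(1e-5, 2e-5, 1e-5, 1e-6))
  expect_error(fit_ph_profile(p, net, free = "neutral"), "reference")
  expect_error(fit_ph_profile(p, net, free = "bogus"), "unknown free species")
  expect_error(ph_rate_profile(c(4, 7), c(1e-5, -1e-6)), "positive")
  expect_error(ph_rate_profile(c(4, 4), c(1e-5, 1e-6)), "distinct")
})
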