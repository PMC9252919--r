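test_that("redox-cycling increase is the relative change against control", {
  expect_equal(redox_cycling_increase(0.50, 0.25), 1.0)
  expect_equal(redox_cycling_increase(0.25, 0.25), 0.0)
  expect_equal(redox_cycling_increase(0.20, 0.25), -0.2)
  expect_error(redox_cycling_increase(0.5, 0), "positive")
})

test_that("methaemoglobin increase is a percent change against control", {
  expect_equal(methemoglobin_increase(0.2, 0.1), 100)
  expect_equal(methemoglobin_increase(0.1, 0.1), 0)
  expect_equal(methemoglobin_increase(0.15, 0.10), 50)
})

test_that("haemolysis percent anchors at the two controls and is affine-invariant", {
  neg <- 0.08; tot <- 0.95
  expect_equal(hemolysis_percent(neg, neg, tot), 0)
  expect_equal(hemolysis_percent(tot, neg, tot), 100)
  expect_equal(hemolysis_percent((neg + tot) / 2, neg, tot), 50)
  # adding a constant to all three absorbances changes nothing
  for (shift in c(-0.05, 0.3, 1)) {
    expect_equal(hemolysis_percent(0.4 + shift, neg + shift, tot + shift),
                 hemolysis_percent(0.4, neg, tot), tolerance = 1e-12)
  }
  expect_error(hemolysis_percent(0.5, 0.9, 0.9), "exceed")
})

test_that("tumour volume uses l*w^2/2 with longest axis first", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(10, 10), 500)
  expect_warning(v <- tumor_volume(5, 10), "swapped")
  expect_equal(v, 125)
  expect_error(tumor_volume(0, 5), "positive")
})

test_that("A280 scattering correction subtracts 1.929 x A330", {
  expect_equal(corrected_a280(1.0, 0.0), 1.0)
  expect_equal(corrected_a280(1.0, 0.1), 0.8071)
  expect_warning(v <- corrected_a280(0.5, 0.5), "negative")
  expect_equal(v, 0.5 - 1.929 * 0.5)
})

test_that("weighted calibration matches the closed-form normal equations", {
  # oracle: weighted least squares via the normal equations
  wls_oracle <- function(x, y, w) {
    sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
    sxx <- sum(w * x^2); sxy <- sum(w * x * y)
    slope <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
    c(intercept = (sy - slope * sx) / sw, slope = slope)
  }
  set.seed(31)
  conc <- c(0.25, 1, 5, 25, 100, 250)
  resp <- 0.11 * conc + 0.02 + rnorm(6, 0, 0.05 * (0.11 * conc))
  for (p in c(0, 1, 2)) {
    cal <- fit_weighted_calibration(conc, resp, weighting_exponent = p)
    ora <- wls_oracle(conc, resp, if (p == 0) rep(1, 6) else conc^(-p))
    expect_equal(cal$slope, ora[["slope"]], tolerance = 1e-12)
    expect_equal(cal$intercept, ora[["intercept"]], tolerance = 1e-12)
  }
})

test_that("exponent 0 equals ordinary least squares", {
  conc <- c(1, 2, 5, 10)
  resp <- c(0.9, 2.2, 4.8, 10.3)
  cal <- fit_weighted_calibration(conc, resp, weighting_exponent = 0)
  ols <- stats::lm(resp ~ conc)
  expect_equal(cal$intercept, unname(coef(ols)[1]), tolerance = 1e-12)
  expect_equal(cal$slope, unname(coef(ols)[2]), tolerance = 1e-12)
})

test_that("back-calculation inverts the line and flags below-limit values", {
  conc <- c(0.25, 1, 10, 100)
  resp <- 0.08 * conc + 0.01
  cal <- fit_weighted_calibration(conc, resp)
  # perfect line: back_calculate o predict is the identity
  expect_equal(as.numeric(back_calculate(cal, resp)), conc, tolerance = 1e-10)
  expect_warning(bc <- back_calculate(cal, 0.005), "limit of quantification")
  expect_true(attr(bc, "censored")[1])
})

test_that("1/x^2 weighting beats OLS at the low end of a proportional-noise curve", {
  set.seed(57)
  conc <- rep(c(0.25, 0.5, 2.5, 25, 100, 250), each = 3)
  n_rep <- 50
  err_w <- err_o <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    resp <- 0.1 * conc * (1 + rnorm(length(conc), 0, 0.08))
    cal_w <- fit_weighted_calibration(conc, resp, 2)
    cal_o <- fit_weighted_calibration(conc, resp, 0)
    true_low <- 0.25
    resp_low <- 0.1 * true_low
    err_w[i] <- abs(suppressWarnings(back_calculate(cal_w, resp_low)) - true_low)
    err_o[i] <- abs(suppressWarnings(back_calculate(cal_o, resp_low)) - true_low)
  }
  expect_lt(mean(err_w), mean(err_o))
})

test_that("calibration preconditions are enforced", {
  expect_error(fit_weighted_calibration(c(1, 2), c(1, 2)),
               "insufficient standards")
  expect_error(fit_weighted_calibration(c(0, 1, 2), c(0, 1, 2), 2),
               "positive")
  expect_error(fit_weighted_calibration(c(1, 1, 1), c(1, 2, 3)), "singular")
})
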