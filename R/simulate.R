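#' Noise model for synthetic kinetic data
#'
#' Describes the replicate noise applied by the generators. The default,
#' multiplicative Gaussian noise with sd 5% of the signal and 3 replicates,
#' emulates the triplicate assays whose error bars are reported as s.e.m.
#' of three independent reactions.
#'
#' @param kind `"multiplicative_gaussian"` (sd is a fraction of the signal)
#'   or `"additive_gaussian"` (sd is absolute).
#' @param sd Standard deviation (fraction or absolute; >= 0).
#' @param replicates Number of replicates (>= 1).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative_gaussian",
                                 "additive_gaussian"),
                        sd = 0.05, replicates = 3L) {
  kind <- match.arg(kind)
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(kind = kind, sd = sd, replicates = replicates),
            class = "noise_model")
}

# apply one replicate draw of noise to a noiseless signal vector
.perturb <- function(signal, noise) {
  if (noise$sd == 0) return(signal)
  if (noise$kind == "multiplicative_gaussian") {
    signal * (1 + stats::rnorm(length(signal), 0, noise$sd))
  } else {
    signal + stats::rnorm(length(signal), 0, noise$sd)
  }
}

#' Simulate a noisy triplicate pH-rate profile
#'
#' Draws `noise$replicates` noisy realizations of [predict_k_obs()] on a pH
#' grid, then summarizes each pH as the replicate mean with a 95% CI
#' half-width of 1.96 x s.e.m., mirroring how experimental profiles are
#' reported. Deterministic under `seed`; replicate rates are clamped to a
#' tiny positive floor so multiplicative noise cannot produce non-positive
#' rate constants.
#'
#' @param network A [microspecies_network()] with reactive rates; this is
#'   the generating truth.
#' @param ph_grid pH values (non-empty).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return A list with `profile` (a [ph_rate_profile()]), `replicates`
#'   (matrix of per-replicate rates) and `truth` (generating parameters,
#'   noise descriptor and seed).
#' @examples
#' net <- build_default_network("PAB-PhQ")
#' sim <- simulate_ph_profile(net, seq(1, 10, 0.75), noise_model(), seed = 7)
#' sim$profile
#' @export
simulate_ph_profile <- function(network, ph_grid, noise = noise_model(),
                                seed = 1) {
  stopifnot(inherits(network, "microspecies_network"),
            inherits(noise, "noise_model"))
  if (length(ph_grid) == 0) stop("ph_grid must be non-empty", call. = FALSE)
  k_true <- predict_k_obs(network, ph_grid)
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(noise$replicates),
                 function(i) pmax(.perturb(k_true, noise), 1e-300),
                 numeric(length(ph_grid)))
  reps <- matrix(reps, nrow = length(ph_grid))
  k_mean <- rowMeans(reps)
  ci95 <- if (noise$replicates > 1) {
    1.96 * apply(reps, 1L, stats::sd) / sqrt(noise$replicates)
  } else {
    rep(NA_real_, length(ph_grid))
  }
  profile <- ph_rate_profile(ph_grid, k_mean, ci95,
                             replicates = noise$replicates,
                             compound = network$molecule,
                             temperature = network$temperature)
  truth <- list(log_beta = stats::setNames(network$species$log_beta,
                                           network$species$label),
                rates = stats::setNames(
                  network$species$rate_s[network$species$reactive],
                  network$species$label[network$species$reactive]),
                k_true = k_true, noise = noise, seed = as.integer(seed))
  list(profile = profile, replicates = reps, truth = truth)
}

#' Simulate a noisy kinetic time course
#'
#' Generates replicate observable-vs-time records from the closed-form
#' first-order or sequential (Bateman) kinetics and perturbs them with the
#' noise model. For `model = "sequential"` the observable is the product
#' pool C (the released, re-oxidized quinone); the full A/B/C truth is
#' returned alongside.
#'
#' @param model `"first_order_decay"`, `"first_order_formation"` or
#'   `"sequential"`.
#' @param rates Rate constant (s\eqn{^{-1}}); length 1 for first-order
#'   models, `c(k1, k2)` for sequential.
#' @param schedule Sampling times in seconds, strictly increasing.
#' @param observable_kind Passed to [time_course()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param a0 Initial amount / amplitude (default 1; for formation this is
#'   the plateau).
#' @return A list with `tc` (a [time_course()]) and `truth`.
#' @export
simulate_timecourse <- function(model = c("first_order_decay",
                                          "first_order_formation",
                                          "sequential"),
                                rates, schedule,
                                observable_kind = "concentration",
                                noise = noise_model(), seed = 1, a0 = 1) {
  model <- match.arg(model)
  if (any(diff(schedule) <= 0)) {
    stop("schedule must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("rates must be positive (s^-1)", call. = FALSE)
  }
  curve <- switch(model,
    first_order_decay = a0 * exp(-rates[1] * schedule),
    first_order_formation = a0 * (1 - exp(-rates[1] * schedule)),
    sequential = {
      if (length(rates) < 2) stop("sequential model needs c(k1, k2)",
                                  call. = FALSE)
      sequential_profile(schedule, a0, rates[1], rates[2])$C
    })
  set.seed(as.integer(seed))
  recs <- do.call(rbind, lapply(seq_len(noise$replicates), function(r) {
    data.frame(time = schedule, value = .perturb(curve, noise), replicate = r)
  }))
  tc <- time_course(recs$time, recs$value, recs$replicate, time_unit = "s",
                    observable_kind = observable_kind)
  truth <- list(model = model, rates = rates, a0 = a0, curve = curve,
                noise = noise, seed = as.integer(seed))
  if (model == "sequential") {
    truth$pools <- sequential_profile(schedule, a0, rates[1], rates[2])
  }
  list(tc = tc, truth = truth)
}

#' Simulate plate readings with a known true effect
#'
#' Generates control and test wells whose assay metric (computed with the
#' matching `assay_*` function on replicate-averaged controls) recovers the
#' requested effect in expectation.
#'
#' @param metric `"methemoglobin"` (effect = percent increase),
#'   `"hemolysis"` (effect = percent haemolysis) or `"redox"` (effect =
#'   relative increase).
#' @param effect True effect size on the metric's own scale.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param baseline Control signal level (and for haemolysis the negative
#'   control; the total-lysis control is `baseline + 1`).
#' @return A list with `readings` (data frame: `well`, `role`,
#'   `wavelength_nm`, `signal`, `replicate`) and `truth`.
#' @seealso [plate_metric()]
#' @export
simulate_plate <- function(metric = c("methemoglobin", "hemolysis", "redox"),
                           effect, noise = noise_model(), seed = 1,
                           baseline = 0.1) {
  metric <- match.arg(metric)
  if (!is.finite(effect)) stop("effect must be finite", call. = FALSE)
  wavelength <- switch(metric, methemoglobin = 630, hemolysis = 540,
                       redox = 610)
  true_signal <- switch(metric,
    methemoglobin = baseline * (1 + effect / 100),
    redox = baseline * (1 + effect),
    hemolysis = baseline + (effect / 100) * 1)   # total control at baseline+1
  set.seed(as.integer(seed))
  one_role <- function(role, level) {
    data.frame(well = paste0(role, seq_len(noise$replicates)),
               role = role, wavelength_nm = wavelength,
               signal = .perturb(rep(level, noise$replicates), noise),
               replicate = seq_len(noise$replicates))
  }
  readings <- rbind(one_role("negative_control", baseline),
                    one_role("test", true_signal))
  if (metric == "hemolysis") {
    readings <- rbind(readings, one_role("positive_control", baseline + 1))
  }
  list(readings = readings,
       truth = list(metric = metric, effect = effect, baseline = baseline,
                    noise = noise, seed = as.integer(seed)))
}

#' Evaluate an assay metric on plate readings
#'
#' Averages control wells across replicates (plate-average controls), then
#' applies the matching closed-form metric to each test well.
#'
#' @param readings A readings data frame as produced by [simulate_plate()]
#'   or read from the plate CSV schema.
#' @param metric `"methemoglobin"`, `"hemolysis"` or `"redox"`.
#' @return Numeric metric value(s), one per test well.
#' @export
plate_metric <- function(readings,
                         metric = c("methemoglobin", "hemolysis", "redox")) {
  metric <- match.arg(metric)
  needed <- c("role", "signal")
  if (!all(needed %in% names(readings))) {
    stop("readings must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  neg <- mean(readings$signal[readings$role == "negative_control"])
  test <- readings$signal[readings$role == "test"]
  if (!is.finite(neg)) stop("no negative_control wells", call. = FALSE)
  switch(metric,
    methemoglobin = methemoglobin_increase(test, neg),
    redox = redox_cycling_increase(test, neg),
    hemolysis = {
      tot <- mean(readings$signal[readings$role == "positive_control"])
      if (!is.finite(tot)) stop("no positive_control wells", call. = FALSE)
      hemolysis_percent(test, neg, tot)
    })
}
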