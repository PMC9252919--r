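#' Construct a pH-rate profile
#'
#' A pH-rate profile holds observed first-order elimination rate constants
#' at a series of pH values, with optional 95% confidence-interval
#' half-widths and replicate counts, as produced by enzyme-triggered
#' release assays followed by HPLC.
#'
#' @param ph pH values (distinct, finite).
#' @param k_obs Observed rate constants, s\eqn{^{-1}} (positive).
#' @param ci95 Optional 95% CI half-widths on `k_obs`, s\eqn{^{-1}}.
#' @param replicates Replicate counts per point.
#' @param compound Compound label.
#' @param temperature Assay temperature, K.
#'
#' @return An object of class `ph_rate_profile` with a `points` data frame.
#' @export
ph_rate_profile <- function(ph, k_obs, ci95 = NA_real_, replicates = 1L,
                            compound = "", temperature = body_temperature) {
  if (!is.numeric(ph) || !is.numeric(k_obs) || length(ph) != length(k_obs)) {
    stop("ph and k_obs must be numeric vectors of equal length", call. = FALSE)
  }
  if (any(!is.finite(ph))) stop("non-finite pH values", call. = FALSE)
  if (anyDuplicated(ph)) stop("pH values must be distinct", call. = FALSE)
  if (any(!is.finite(k_obs)) || any(k_obs <= 0)) {
    stop("k_obs must be positive and finite", call. = FALSE)
  }
  ci95 <- rep_len(as.numeric(ci95), length(ph))
  if (any(ci95 < 0, na.rm = TRUE)) stop("ci95 must be >= 0", call. = FALSE)
  points <- data.frame(ph = ph, k_obs = k_obs, ci95 = ci95,
                       replicates = rep_len(as.integer(replicates), length(ph)))
  structure(list(compound = compound, temperature = temperature,
                 points = points),
            class = "ph_rate_profile")
}

#' @export
print.ph_rate_profile <- function(x, ...) {
  cat(sprintf("pH-rate profile: %s (%d points, T = %.2f K)\n",
              if (nzchar(x$compound)) x$compound else "<unnamed>",
              nrow(x$points), x$temperature))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Predicted observed rate constant as a function of pH
#'
#' Under rapid pre-equilibrium among the microspecies, the observed
#' elimination rate constant is the mole-fraction-weighted sum of the
#' intrinsic rates of the reactive channels:
#' \deqn{k_{\mathrm{obs}}(\mathrm{pH}) = \sum_{r \in \mathrm{reactive}}
#'   k_r \, x_r(\mathrm{pH}).}
#' The prediction is bounded by \eqn{0 < k_{\mathrm{obs}} \le \max_r k_r}.
#'
#' @param network A [microspecies_network()] with at least one reactive
#'   species carrying an intrinsic rate.
#' @param ph pH value(s).
#' @return Predicted rate constant(s), s\eqn{^{-1}}.
#' @examples
#' net <- build_default_network("PAB-PhQ")
#' predict_k_obs(net, c(3, 6, 9))
#' @export
predict_k_obs <- function(network, ph) {
  stopifnot(inherits(network, "microspecies_network"))
  sp <- network$species
  if (!any(sp$reactive)) {
    stop("network has no reactive species; cannot predict a rate", call. = FALSE)
  }
  frac <- mole_fractions(network, ph)
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = 1L,
                                         dimnames = list(NULL, names(frac)))
  k <- as.numeric(frac[, sp$label[sp$reactive], drop = FALSE] %*%
                    sp$rate_s[sp$reactive])
  k
}

#' Weighted chi-square and coefficient of determination
#'
#' \eqn{\chi^2 = \sum_i w_i (o_i - p_i)^2} (unreduced) and
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} computed on the same scale as the
#' inputs. If the observations have zero variance, \eqn{R^2} is undefined
#' and returned as `NA` with a warning.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @param weights Non-negative weights; default 1.
#' @return A list with `chi_square` and `r_square`.
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4))  # chi2 = 1, R2 = 0.5
#' @export
goodness_of_fit <- function(observed, predicted, weights = NULL) {
  n <- length(observed)
  if (length(predicted) != n) stop("length mismatch", call. = FALSE)
  if (n < 2) stop("need at least two points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("length mismatch for weights", call. = FALSE)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  chi_square <- sum(weights * (observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("observed values are constant; R^2 is undefined")
    r_square <- NA_real_
  } else {
    r_square <- 1 - sum((observed - predicted)^2) / ss_tot
  }
  list(chi_square = chi_square, r_square = r_square)
}

# replace the log_beta of the named free species in a network (no revalidation
# beyond finiteness; used inside the optimizer loop)
.set_log_betas <- function(network, labels, values) {
  idx <- match(labels, network$species$label)
  network$species$log_beta[idx] <- values
  network
}

#' Fit equilibrium constants to a pH-rate profile
#'
#' Fits the \eqn{\log_{10}\beta} values of a chosen set of species to an
#' observed pH-rate profile by weighted least squares, with the intrinsic
#' rate constants of the reactive channels held fixed (they come from
#' theory via the Eyring equation, not from the fit). Because observed
#' rates typically span several orders of magnitude across pH, the default
#' objective is on the \eqn{\log_{10} k_{\mathrm{obs}}} scale; a
#' linear-scale objective is available via `log_scale = FALSE`.
#'
#' The surface can be multimodal when reactive channels trade off, so the
#' optimizer is a bounded Levenberg-Marquardt least-squares run from
#' multiple starting points: the network's current values plus
#' `n_starts - 1` uniform draws over `[lower, upper]`, seeded for
#' reproducibility. The best solution (lowest objective; ties broken by
#' the smaller parameter-vector norm) is returned.
#'
#' Weighting: with `weighting = "inverse_variance"`, per-point standard
#' deviations are taken as `ci95 / 1.96`; points without an uncertainty get
#' the profile-median sigma. On the log scale sigmas are propagated as
#' \eqn{\sigma_{\log} = \sigma / (k_{\mathrm{obs}} \ln 10)}. Weights are
#' \eqn{w = 1/\sigma^2} on the fitted scale.
#'
#' @param profile A [ph_rate_profile()] with at least `length(free) + 1`
#'   points.
#' @param network A [microspecies_network()]; its current `log_beta` values
#'   seed the fit and its reactive rates are held fixed.
#' @param free Character vector of species labels whose `log_beta` is
#'   adjustable; must not include the neutral reference.
#' @param weighting `"inverse_variance"` (default) or `"uniform"`.
#' @param log_scale Fit on the log10(k_obs) scale (default `TRUE`).
#' @param n_starts Number of multi-start optimizations (default 16).
#' @param seed Integer seed for the start draws.
#' @param lower,upper Bounds on each free `log_beta`.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#'
#' @return An object of class `ph_rate_fit`: free-parameter estimates with
#'   standard errors, fixed intrinsic rates, unreduced and reduced
#'   chi-square, \eqn{R^2}, residuals (fitted scale), convergence flag,
#'   iteration count, the seed, and the updated network.
#' @examples
#' net <- build_default_network("PAB-PhQ")
#' sim <- simulate_ph_profile(net, seq(2, 9, length.out = 8),
#'                            noise_model(sd = 0), seed = 1)
#' fit <- fit_ph_profile(sim$profile, net, free = c("Zw1", "O-"),
#'                       n_starts = 4, seed = 1)
#' fit$free_parameters
#' @export
fit_ph_profile <- function(profile, network, free,
                           weighting = c("inverse_variance", "uniform"),
                           log_scale = TRUE, n_starts = 16, seed = 1,
                           lower = -30, upper = 5,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-12, ptol = 1e-12)) {
  stopifnot(inherits(profile, "ph_rate_profile"),
            inherits(network, "microspecies_network"))
  weighting <- match.arg(weighting)
  sp <- network$species
  if (!all(free %in% sp$label)) {
    stop("unknown free species label(s): ",
         paste(setdiff(free, sp$label), collapse = ", "), call. = FALSE)
  }
  if (network$reference %in% free) {
    stop("the neutral reference log_beta is fixed at 0 and cannot be freed",
         call. = FALSE)
  }
  pts <- profile$points
  if (nrow(pts) <= length(free)) {
    stop("under-determined fit: ", nrow(pts), " points for ", length(free),
         " free parameters", call. = FALSE)
  }

  # per-point sigma on the fitted scale
  if (weighting == "inverse_variance") {
    sigma <- pts$ci95 / 1.96
    sigma[!is.finite(sigma) | sigma <= 0] <- NA_real_
    med <- stats::median(sigma, na.rm = TRUE)
    if (!is.finite(med)) med <- 1
    sigma[is.na(sigma)] <- med
    if (log_scale) sigma <- sigma / (pts$k_obs * log(10))
    w <- 1 / sigma^2
  } else {
    w <- rep(1, nrow(pts))
  }
  sw <- sqrt(w)
  obs <- if (log_scale) log10(pts$k_obs) else pts$k_obs

  resid_fun <- function(par) {
    net2 <- .set_log_betas(network, free, par)
    pred <- predict_k_obs(net2, pts$ph)
    pred_s <- if (log_scale) log10(pmax(pred, 1e-300)) else pred
    sw * (obs - pred_s)
  }

  start0 <- sp$log_beta[match(free, sp$label)]
  start0 <- pmin(pmax(start0, lower), upper)
  set.seed(as.integer(seed))
  starts <- rbind(start0,
                  matrix(stats::runif((n_starts - 1) * length(free),
                                      lower, upper),
                         ncol = length(free)))

  best <- NULL
  best_obj <- Inf
  best_norm <- Inf
  n_converged <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = rep(lower, length(free)),
                         upper = rep(upper, length(free)),
                         fn = resid_fun, control = control),
      error = function(e) NULL)
    if (is.null(res)) next
    obj <- sum(res$fvec^2)
    if (res$info %in% 1:4) n_converged <- n_converged + 1L
    nrm <- sqrt(sum(res$par^2))
    if (obj < best_obj - 1e-12 * max(1, best_obj) ||
        (abs(obj - best_obj) <= 1e-12 * max(1, best_obj) && nrm < best_norm)) {
      best <- res; best_obj <- obj; best_norm <- nrm
    }
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  converged <- best$info %in% 1:4

  est <- as.numeric(best$par)
  se <- rep(NA_real_, length(free))
  dof <- nrow(pts) - length(free)
  cov <- tryCatch({
    s2 <- best_obj / dof
    s2 * solve(best$hessian)
  }, error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))

  net_fit <- .set_log_betas(network, free, est)
  pred <- predict_k_obs(net_fit, pts$ph)
  pred_s <- if (log_scale) log10(pred) else pred
  gof <- goodness_of_fit(obs, pred_s, w)

  structure(list(
    free_parameters = data.frame(label = free, estimate = est, se = se,
                                 stringsAsFactors = FALSE),
    fixed_rates = stats::setNames(sp$rate_s[sp$reactive],
                                  sp$label[sp$reactive]),
    chi_square = gof$chi_square,
    chi_square_reduced = gof$chi_square / dof,
    r_square = gof$r_square,
    residuals = obs - pred_s,
    fitted = pred,
    converged = converged,
    n_starts_converged = n_converged,
    iterations = best$niter,
    seed = as.integer(seed),
    weighting = weighting,
    log_scale = log_scale,
    network = net_fit,
    profile = profile
  ), class = "ph_rate_fit")
}

#' @export
print.ph_rate_fit <- function(x, ...) {
  cat(sprintf("pH-rate fit (%s scale, %s weights): chi2 = %.4g, R2 = %.4g%s\n",
              if (x$log_scale) "log10" else "linear", x$weighting,
              x$chi_square, x$r_square,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$free_parameters, row.names = FALSE)
  cat("fixed intrinsic rates (s^-1):\n")
  print(signif(x$fixed_rates, 3))
  invisible(x)
}
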