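#' Half-life of a first-order process
#'
#' \eqn{t_{1/2} = \ln 2 / k}, returned in hours.
#'
#' @param rate First-order rate constant(s), s\eqn{^{-1}} (positive).
#' @return Half-life in hours.
#' @examples
#' half_life(6.55e-5)  # ~2.94 h
#' @export
half_life <- function(rate) {
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop("rate must be positive and finite (s^-1)", call. = FALSE)
  }
  log(2) / rate / 3600
}

#' Rate constant from a half-life
#'
#' Inverse of [half_life()]: \eqn{k = \ln 2 / t_{1/2}}.
#'
#' @param t_half_h Half-life in hours (positive).
#' @return Rate constant in s\eqn{^{-1}}.
#' @export
rate_from_half_life <- function(t_half_h) {
  if (any(!is.finite(t_half_h)) || any(t_half_h <= 0)) {
    stop("half-life must be positive and finite (h)", call. = FALSE)
  }
  log(2) / (t_half_h * 3600)
}

#' Sequential two-step first-order kinetics (Bateman closed form)
#'
#' Amounts of the three pools of the release cascade
#' A (aminobenzyl-ketol intermediate) -> B (hydroquinone) -> C (quinone)
#' under consecutive first-order steps:
#' \deqn{A = a_0 e^{-k_1 t}, \quad
#'   B = a_0 \frac{k_1}{k_2 - k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right), \quad
#'   C = a_0 - A - B.}
#' When \eqn{k_1 \approx k_2} the two-exponential form is numerically
#' unstable and the analytic limit \eqn{B = a_0 k t e^{-k t}} is used
#' instead.
#'
#' @param times Time points in seconds (non-negative).
#' @param a0 Initial amount of A (positive).
#' @param k1,k2 Step rate constants, s\eqn{^{-1}} (positive).
#'
#' @return A data frame with columns `time`, `A`, `B`, `C`; rows satisfy
#'   `A + B + C == a0` to machine precision.
#' @examples
#' sequential_profile(c(0, 3600, 7200), a0 = 1, k1 = 1e-4, k2 = 1e-3)
#' @export
sequential_profile <- function(times, a0, k1, k2) {
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be non-negative and finite (s)", call. = FALSE)
  }
  if (!is.finite(a0) || a0 <= 0) stop("a0 must be positive", call. = FALSE)
  if (!is.finite(k1) || k1 <= 0 || !is.finite(k2) || k2 <= 0) {
    stop("k1 and k2 must be positive (s^-1)", call. = FALSE)
  }
  A <- a0 * exp(-k1 * times)
  if (abs(k2 - k1) <= 1e-9 * max(k1, k2)) {
    k <- (k1 + k2) / 2
    B <- a0 * k * times * exp(-k * times)
  } else {
    B <- a0 * k1 / (k2 - k1) * (exp(-k1 * times) - exp(-k2 * times))
  }
  B <- pmax(B, 0)
  C <- pmax(a0 - A - B, 0)
  data.frame(time = times, A = A, B = B, C = C)
}

#' Normalized NMR integral fraction
#'
#' Converts a peak integral into a mole fraction by normalizing to the
#' number of protons it represents and dividing by the per-proton integral
#' of the whole region:
#' \deqn{x = \frac{I_{\mathrm{peak}} / n_{\mathrm{peak}}}
#'   {I_{\mathrm{total}} / n_{\mathrm{total}}}.}
#'
#' @param peak_integral Integral of the monitored peak (> 0).
#' @param n_protons_peak Protons represented by that peak (integer > 0).
#' @param total_integral Integral of the whole reference region (> 0).
#' @param n_protons_total Protons represented by the whole region.
#' @return The mole fraction (in `[0, 1]` for consistent inputs).
#' @examples
#' nmr_fraction(1, 1, 12, 12)    # pure species: 1
#' nmr_fraction(0.5, 1, 12, 12)  # 50:50 mixture sharing the region: 0.5
#' @export
nmr_fraction <- function(peak_integral, n_protons_peak,
                         total_integral, n_protons_total) {
  vals <- c(peak_integral, n_protons_peak, total_integral, n_protons_total)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs must be positive and finite", call. = FALSE)
  }
  (peak_integral / n_protons_peak) / (total_integral / n_protons_total)
}

#' Construct a kinetic time course
#'
#' Replicate observable-vs-time records for a release experiment: an NMR
#' integral fraction, an HPLC peak-area/internal-standard ratio, or a
#' concentration. Times are normalized to seconds internally.
#'
#' @param time Time values (non-negative; strictly increasing within each
#'   replicate).
#' @param value Observable values (finite).
#' @param replicate Replicate ids (default all 1).
#' @param time_unit `"s"`, `"min"` or `"h"`; scalar or per-record.
#' @param observable_kind `"nmr_fraction"`, `"hplc_area_ratio"` or
#'   `"concentration"`.
#' @param compound Compound label.
#' @param temperature K.
#' @param medium Free-text medium descriptor.
#' @return An object of class `time_course` with a `records` data frame
#'   (`time` in seconds).
#' @export
time_course <- function(time, value, replicate = 1L, time_unit = "s",
                        observable_kind = c("concentration", "nmr_fraction",
                                            "hplc_area_ratio"),
                        compound = "", temperature = body_temperature,
                        medium = "") {
  observable_kind <- match.arg(observable_kind)
  if (length(time) != length(value)) {
    stop("time and value must have equal length", call. = FALSE)
  }
  unit_s <- c(s = 1, min = 60, h = 3600)
  tu <- rep_len(as.character(time_unit), length(time))
  if (!all(tu %in% names(unit_s))) {
    stop("time_unit must be one of 's', 'min', 'h'", call. = FALSE)
  }
  t_s <- time * unit_s[tu]
  if (any(!is.finite(t_s)) || any(t_s < 0)) {
    stop("times must be non-negative and finite", call. = FALSE)
  }
  if (any(!is.finite(value))) stop("observable values must be finite",
                                   call. = FALSE)
  replicate <- rep_len(replicate, length(time))
  for (r in unique(replicate)) {
    tr <- t_s[replicate == r]
    if (any(diff(tr) <= 0)) {
      stop("times must be strictly increasing within replicate ", r,
           call. = FALSE)
    }
  }
  structure(list(compound = compound, observable_kind = observable_kind,
                 temperature = temperature, medium = medium,
                 records = data.frame(time = as.numeric(t_s), value = value,
                                      replicate = replicate)),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course: %s [%s], %d records, %d replicate(s)\n",
              if (nzchar(x$compound)) x$compound else "<unnamed>",
              x$observable_kind, nrow(x$records),
              length(unique(x$records$replicate))))
  print(utils::head(x$records), row.names = FALSE)
  if (nrow(x$records) > 6) cat("...\n")
  invisible(x)
}

#' Fit a first-order decay or formation to a time course
#'
#' Pooled nonlinear least squares over all replicate points.
#' Decay: \eqn{y = y_0 e^{-kt} + b}; formation:
#' \eqn{y = y_\infty (1 - e^{-kt}) + b}. The decay baseline defaults to 0;
#' the formation plateau \eqn{y_\infty} is always free (HPLC response
#' factors differ between analyte and internal standard). Starting values
#' come from a log-linear regression and are refined with
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]).
#'
#' Error model: with `weighting = "none"` the fit assumes constant
#' (additive) noise. Spectroscopic and chromatographic traces usually have
#' noise roughly proportional to the signal; `weighting = "relative"`
#' fits with weights \eqn{1/\hat y^2} (iteratively reweighted, with the
#' weight floored at 1% of the largest fitted value to keep near-zero
#' points from dominating), which makes the standard error and confidence
#' interval of the rate consistent with multiplicative noise.
#'
#' @param tc A [time_course()] with at least 4 distinct time points.
#' @param mode `"decay"` or `"formation"`.
#' @param baseline `"fixed_zero"` (default) or `"free"`.
#' @param weighting `"relative"` (default; proportional-error model) or
#'   `"none"` (constant-error model).
#' @param conf_level Confidence level for the rate interval (default 0.95,
#'   t-distribution on the residual degrees of freedom).
#'
#' @return An object of class `kinetic_fit`: the rate estimate with
#'   standard error and confidence interval, the half-life in hours,
#'   amplitude/baseline estimates, residuals, and a convergence flag.
#' @examples
#' tt <- seq(0, 20 * 3600, length.out = 10)
#' tc <- time_course(tt, exp(-6.18e-5 * tt))
#' fit_first_order(tc, "decay")
#' @export
fit_first_order <- function(tc, mode = c("decay", "formation"),
                            baseline = c("fixed_zero", "free"),
                            weighting = c("relative", "none"),
                            conf_level = 0.95) {
  stopifnot(inherits(tc, "time_course"))
  mode <- match.arg(mode)
  baseline <- match.arg(baseline)
  weighting <- match.arg(weighting)
  d <- tc$records
  if (length(unique(d$time)) < 4) {
    stop("insufficient points: need >= 4 distinct time points", call. = FALSE)
  }

  rng <- diff(range(d$value))
  if (rng == 0) stop("observable is constant; nothing to fit", call. = FALSE)
  eps <- 1e-8 * max(abs(d$value), 1)
  # crude log-linear start for k
  if (mode == "decay") {
    b0 <- if (baseline == "free") min(d$value) * 0.9 else 0
    z <- pmax(d$value - b0, eps)
    k0 <- max(-stats::coef(stats::lm(log(z) ~ d$time))[[2]], 1e-12)
    y0 <- max(d$value) - b0
    form <- if (baseline == "free") value ~ y0 * exp(-k * time) + b else
      value ~ y0 * exp(-k * time)
    start <- if (baseline == "free") list(y0 = y0, k = k0, b = b0) else
      list(y0 = y0, k = k0)
  } else {
    yinf0 <- max(d$value)
    b0 <- if (baseline == "free") min(d$value) else 0
    z <- pmax(yinf0 + eps - d$value, eps)
    k0 <- max(-stats::coef(stats::lm(log(z) ~ d$time))[[2]], 1e-12)
    form <- if (baseline == "free") value ~ yinf * (1 - exp(-k * time)) + b else
      value ~ yinf * (1 - exp(-k * time))
    start <- if (baseline == "free") list(yinf = yinf0 - b0, k = k0, b = b0) else
      list(yinf = yinf0, k = k0)
  }

  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                     ptol = 1e-14)
  run_fit <- function(w) {
    d$.w <- w
    minpack.lm::nlsLM(form, data = d, start = start, weights = .w,
                      control = ctrl)
  }
  fit <- tryCatch({
    f <- run_fit(rep(1, nrow(d)))
    if (weighting == "relative") {
      # IRLS: two reweighting passes with 1/fitted^2, floored at 1% of max
      for (pass in 1:2) {
        yhat <- abs(stats::fitted(f))
        w <- 1 / pmax(yhat, 0.01 * max(yhat))^2
        start <- as.list(stats::coef(f))
        f <- run_fit(w)
      }
    }
    f
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    stop("first-order fit did not converge: ", conditionMessage(fit),
         call. = FALSE)
  }
  co <- summary(fit)$coefficients
  k_hat <- co["k", "Estimate"]
  k_se <- co["k", "Std. Error"]
  if (k_hat <= 0) {
    stop("fitted rate is non-positive (k = ", signif(k_hat, 3),
         " s^-1); the trace does not look ", mode, "-like", call. = FALSE)
  }
  dof <- nrow(d) - nrow(co)
  tq <- stats::qt(1 - (1 - conf_level) / 2, dof)
  amp_name <- if (mode == "decay") "y0" else "yinf"
  res <- stats::resid(fit)

  structure(list(
    model = paste0("first_order_", mode),
    rate = k_hat, rate_se = k_se,
    rate_ci = c(lower = k_hat - tq * k_se, upper = k_hat + tq * k_se),
    conf_level = conf_level,
    half_life_h = half_life(k_hat),
    amplitude = unname(co[amp_name, "Estimate"]),
    baseline = if (baseline == "free") unname(co["b", "Estimate"]) else 0,
    residuals = as.numeric(res),
    fitted = as.numeric(stats::fitted(fit)),
    sigma = summary(fit)$sigma,
    converged = fit$convInfo$isConv,
    n_points = nrow(d),
    observable_kind = tc$observable_kind
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit: k = %.4g +/- %.2g s^-1 (t1/2 = %.3g h)%s\n",
              x$model, x$rate, x$rate_se, x$half_life_h,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  %d%% CI for k: [%.4g, %.4g] s^-1; amplitude %.4g, baseline %.4g\n",
              round(100 * x$conf_level), x$rate_ci[["lower"]],
              x$rate_ci[["upper"]], x$amplitude, x$baseline))
  invisible(x)
}
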