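# Modified Gompertz growth model and OD-based biomass conversion factors.

#' Construct a set of Gompertz growth parameters
#'
#' Bundles the asymptote `A`, the maximum specific growth rate `mu_m` and the
#' lag time `lam` of the modified Gompertz growth model
#' \deqn{OD(t) = A \exp\{-\exp[k(\lambda - t) + 1]\}, \qquad k = \mu_m e / A,}
#' the standard three-phase description of a bacterial batch culture:
#' `mu_m` is the slope of the tangent at the inflection point, `lam` its
#' x-intercept, and `A` the saturation plateau.
#'
#' @param A asymptotic optical density (au); must be positive.
#' @param mu_m maximum specific growth rate (au/h); must be positive.
#' @param lam lag time (h); must be non-negative.
#' @return An object of class `gompertz_params`: a list with fields `A`,
#'   `mu_m`, `lam` and the derived rate constant `k = mu_m * e / A` (1/h).
#' @examples
#' p <- gompertz_params(A = 1.46, mu_m = 0.260, lam = 4.94)
#' gompertz_od(p, c(0, 5, 10, 30))
#' @export
gompertz_params <- function(A, mu_m, lam) {
  stopifnot(is.numeric(A), is.numeric(mu_m), is.numeric(lam),
            length(A) == 1L, length(mu_m) == 1L, length(lam) == 1L)
  if (!is.finite(A) || A <= 0) stop("'A' must be a positive finite number")
  if (!is.finite(mu_m) || mu_m <= 0) stop("'mu_m' must be a positive finite number")
  if (!is.finite(lam) || lam < 0) stop("'lam' must be a non-negative finite number")
  structure(list(A = A, mu_m = mu_m, lam = lam, k = mu_m * exp(1) / A),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf(
    "Gompertz parameters: A = %.4g au, mu_m = %.4g au/h, lambda = %.4g h (k = %.4g /h)\n",
    x$A, x$mu_m, x$lam, x$k))
  invisible(x)
}

#' Evaluate the modified Gompertz curve
#'
#' @param params a [gompertz_params()] object.
#' @param t time points (h); any finite numeric vector.
#' @return Optical density (au) at each time point.
#' @export
gompertz_od <- function(params, t) {
  if (!inherits(params, "gompertz_params")) {
    params <- do.call(gompertz_params, params[c("A", "mu_m", "lam")])
  }
  stopifnot(is.numeric(t), all(is.finite(t)))
  params$A * exp(-exp(params$k * (params$lam - t) + 1))
}

#' Inflection-point and tangent geometry of a Gompertz curve
#'
#' The curve's inflection point sits at `t = lambda + 1/k`, where the OD is
#' `A/e` and the slope equals `mu_m`; the tangent line drawn there crosses the
#' time axis exactly at the lag time `lambda`. These identities define how
#' `mu_m` and `lambda` are read off a fitted curve.
#'
#' @param params a [gompertz_params()] object.
#' @return A list with `t_inflection` (h), `od_inflection` (au), `slope`
#'   (au/h) and `tangent_x_intercept` (h).
#' @export
lag_time_geometry <- function(params) {
  stopifnot(inherits(params, "gompertz_params"))
  t_inf <- params$lam + 1 / params$k
  od_inf <- gompertz_od(params, t_inf)
  slope <- params$mu_m
  list(t_inflection = t_inf,
       od_inflection = od_inf,
       slope = slope,
       tangent_x_intercept = t_inf - od_inf / slope)
}

# Starting values for the Gompertz fit: plateau from the data maximum, rate
# from the steepest finite-difference slope, lag from the first time OD
# clears 5 % of the plateau.
gompertz_start <- function(times, od) {
  A0 <- max(od)
  dslope <- diff(od) / diff(times)
  mu0 <- max(dslope)
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- A0 / max(diff(range(times)), 1)
  above <- which(od > 0.05 * A0)
  lam0 <- if (length(above)) times[above[1]] else times[1]
  list(A = A0, mu_m = mu0, lam = max(lam0, 0))
}

#' Fit the modified Gompertz model to a growth curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nlsLM()]) in the
#' natural parameters `(A, mu_m, lam)`, with positivity enforced through box
#' constraints. Starting values are derived from the data (see Details in the
#' methods vignette). The derived rate constant `k` is recomputed from the
#' fitted values.
#'
#' @param times time points (h), strictly increasing, length >= 5.
#' @param od optical density readings (au), same length as `times`.
#' @return A list with `params` (a [gompertz_params()] object), `ssr` (sum of
#'   squared residuals), `residuals`, and the underlying `fit` object.
#' @examples
#' t <- seq(0, 30, by = 0.5)
#' truth <- gompertz_params(1.46, 0.260, 4.94)
#' fit <- fit_gompertz(t, gompertz_od(truth, t))
#' fit$params
#' @export
fit_gompertz <- function(times, od) {
  stopifnot(is.numeric(times), is.numeric(od), length(times) == length(od))
  if (length(times) < 5L) stop("need at least 5 points spanning lag and plateau")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(od < 0)) stop("'od' must be non-negative")
  if (diff(range(od)) < .Machine$double.eps^0.5 * max(od, 1)) {
    stop("degenerate flat curve: no growth signal to fit")
  }
  start <- gompertz_start(times, od)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      od ~ A * exp(-exp((mu_m * exp(1) / A) * (lam - times) + 1)),
      data = list(times = times, od = od),
      start = start,
      lower = c(A = 1e-9, mu_m = 1e-9, lam = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop("Gompertz fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  res <- stats::residuals(fit)
  list(params = gompertz_params(est[["A"]], est[["mu_m"]], est[["lam"]]),
       ssr = sum(res^2),
       residuals = as.numeric(res),
       fit = fit)
}

#' Fit a biomass conversion factor by linear regression
#'
#' Ordinary least squares of a growth proxy (DNA concentration, pellet mass,
#' cell count) against optical density, with a free intercept. The slope is
#' the conversion factor (proxy units per au); a large intercept relative to
#' the data is flagged because the proxies are expected to vanish at zero
#' biomass.
#'
#' @param od optical densities (au), length >= 3, non-constant.
#' @param measure paired proxy measurements.
#' @return A list with `slope`, `intercept`, `r_squared` and
#'   `intercept_flag` (TRUE when |intercept| exceeds 10 % of `max(measure)`).
#' @export
fit_conversion_factor <- function(od, measure) {
  stopifnot(is.numeric(od), is.numeric(measure), length(od) == length(measure))
  if (length(od) < 3L) stop("need at least 3 paired points")
  if (stats::var(od) == 0) stop("zero variance in od: slope undefined")
  fit <- stats::lm(measure ~ od)
  co <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # silence perfect-fit notice
  list(slope = unname(co[["od"]]),
       intercept = unname(co[["(Intercept)"]]),
       r_squared = r2,
       intercept_flag = abs(co[["(Intercept)"]]) > 0.1 * max(abs(measure)))
}
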