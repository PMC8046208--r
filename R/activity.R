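#' Logistic rate/location parameters
#'
#' Container for the two parameters of the logistic emission-activity curve
#' `f_l(y) = 1 / (1 + exp(rate * (y - location)))`. The rate parameter is in
#' inverse units of `y` (per %RH, per mm h^-1, ...), the location parameter in
#' the units of `y` itself.
#'
#' @param rate Finite, nonzero rate parameter.
#' @param location Finite location parameter (midpoint of the curve).
#' @return A `logistic_params` object.
#' @seealso [solve_logistic_params()] to obtain parameters from a two-point
#'   calibration, [logistic()] to evaluate the curve.
#' @export
#' @examples
#' logistic_params(rate = 0.196, location = 65)
logistic_params <- function(rate, location) {
  stopifnot(is.numeric(rate), length(rate) == 1L,
            is.numeric(location), length(location) == 1L)
  if (!is.finite(rate) || rate == 0) {
    stop("`rate` must be finite and nonzero", call. = FALSE)
  }
  if (!is.finite(location)) {
    stop("`location` must be finite", call. = FALSE)
  }
  structure(list(rate = rate, location = location), class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("<logistic_params> rate = %.6g, location = %.6g\n",
              x$rate, x$location))
  invisible(x)
}

#' Evaluate a logistic activity curve
#'
#' Evaluates `1 / (1 + exp(rate * (y - location)))`. With a positive rate the
#' curve decreases in `y`, which is the calibrated behaviour for both the
#' relative-humidity and precipitation activity factors (high moisture
#' suppresses emission).
#'
#' @param y Numeric vector (finite), in the units the parameters were
#'   calibrated for.
#' @param params A [logistic_params()] object.
#' @return Numeric vector of fractions strictly inside (0, 1).
#' @export
#' @examples
#' p <- solve_logistic_params(c(50, 0.95), c(80, 0.05))
#' logistic(65, p)  # midpoint: 0.5
logistic <- function(y, params) {
  stopifnot(inherits(params, "logistic_params"), is.numeric(y))
  if (any(!is.finite(y))) stop("`y` must be finite", call. = FALSE)
  1 / (1 + exp(params$rate * (y - params$location)))
}

#' Solve logistic parameters from a two-point calibration
#'
#' Closed-form inversion via log-odds: given `f_l(y1) = f1` and
#' `f_l(y2) = f2`, the rate is `(logit'(f2) - logit'(f1)) / (y2 - y1)` with
#' `logit'(f) = log((1 - f) / f)`, and the location follows from either
#' point. The solution is unique; re-evaluating the curve at the calibration
#' points reproduces the targets to machine precision.
#'
#' @param point1,point2 Length-2 numeric vectors `c(y, f)` with `0 < f < 1`.
#' @return A [logistic_params()] object.
#' @export
#' @examples
#' # relative-humidity calibration: 0.95 at 50 %RH, 0.05 at 80 %RH
#' solve_logistic_params(c(50, 0.95), c(80, 0.05))
#' # precipitation calibration: 0.95 at 0, 0.05 at 0.5 mm/h
#' solve_logistic_params(c(0, 0.95), c(0.5, 0.05))
solve_logistic_params <- function(point1, point2) {
  stopifnot(is.numeric(point1), length(point1) == 2L,
            is.numeric(point2), length(point2) == 2L)
  y1 <- point1[[1]]; f1 <- point1[[2]]
  y2 <- point2[[1]]; f2 <- point2[[2]]
  if (any(!is.finite(c(y1, f1, y2, f2)))) {
    stop("calibration points must be finite", call. = FALSE)
  }
  if (f1 <= 0 || f1 >= 1 || f2 <= 0 || f2 >= 1) {
    stop("calibration targets must lie strictly in (0, 1)", call. = FALSE)
  }
  if (y1 == y2 || f1 == f2) {
    stop("degenerate calibration: points must differ in both y and f",
         call. = FALSE)
  }
  # inverse log-odds of the printed form: rate*(y - c) = log((1-f)/f)
  g1 <- log((1 - f1) / f1)
  g2 <- log((1 - f2) / f2)
  rate <- (g2 - g1) / (y2 - y1)
  location <- y1 - g1 / rate
  logistic_params(rate = rate, location = location)
}

#' Emission-activity parameter set
#'
#' Bundles the baseline emitted fraction, the calibrated humidity and
#' precipitation logistics, and the saturation wind speed that together drive
#' the emission-activity factors `f_RH`, `f_PR` and `f_WS`.
#'
#' Defaults follow the ryegrass parameterisation: `f_baseline = 0.33` (the
#' fraction of pollen emitted at very low humidity), humidity logistic
#' calibrated to 0.95 at 50 %RH and 0.05 at 80 %RH, precipitation logistic to
#' 0.95 at 0 and 0.05 at 0.5 mm h^-1, and a saturation wind speed
#' `u_sat = 5` m s^-1.
#'
#' @param f_baseline Baseline emitted fraction, in `[0, 1)`.
#' @param rh_calibration,pr_calibration Two-point calibrations, each a list of
#'   two `c(y, f)` vectors passed to [solve_logistic_params()].
#' @param u_sat Saturation wind speed, m s^-1, positive.
#' @return An `activity_params` object with elements `f_baseline`,
#'   `rh_logistic`, `pr_logistic`, `u_sat`.
#' @export
#' @examples
#' act <- activity_params()
#' f_ws(5, act)  # 0.75 at the saturation wind speed
activity_params <- function(f_baseline = 0.33,
                            rh_calibration = list(c(50, 0.95), c(80, 0.05)),
                            pr_calibration = list(c(0, 0.95), c(0.5, 0.05)),
                            u_sat = 5) {
  stopifnot(is.numeric(f_baseline), length(f_baseline) == 1L,
            is.numeric(u_sat), length(u_sat) == 1L)
  if (!is.finite(f_baseline) || f_baseline < 0 || f_baseline >= 1) {
    stop("`f_baseline` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(u_sat) || u_sat <= 0) {
    stop("`u_sat` must be positive", call. = FALSE)
  }
  structure(
    list(
      f_baseline = f_baseline,
      rh_logistic = solve_logistic_params(rh_calibration[[1]], rh_calibration[[2]]),
      pr_logistic = solve_logistic_params(pr_calibration[[1]], pr_calibration[[2]]),
      u_sat = u_sat
    ),
    class = "activity_params"
  )
}

#' @export
print.activity_params <- function(x, ...) {
  cat("<activity_params>\n")
  cat(sprintf("  f_baseline: %.3g   u_sat: %.3g m/s\n", x$f_baseline, x$u_sat))
  cat(sprintf("  RH logistic:  rate %.5g, location %.5g %%RH\n",
              x$rh_logistic$rate, x$rh_logistic$location))
  cat(sprintf("  PR logistic:  rate %.5g, location %.5g mm/h\n",
              x$pr_logistic$rate, x$pr_logistic$location))
  invisible(x)
}

#' Humidity emission-activity factor
#'
#' `f_RH = f_baseline + (1 - f_baseline) * f_l(RH)`: close to 1 in dry air,
#' decreasing towards the `f_baseline` floor as humidity rises (anthers close
#' in humid conditions and retain pollen on the plant).
#'
#' @param rh Relative humidity, percent, in `[0, 100]`. Vectorised.
#' @param params An [activity_params()] object.
#' @return Fractions in `(f_baseline, 1)`.
#' @export
f_rh <- function(rh, params = activity_params()) {
  stopifnot(inherits(params, "activity_params"), is.numeric(rh))
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100)) {
    stop("`rh` must lie in [0, 100]", call. = FALSE)
  }
  params$f_baseline + (1 - params$f_baseline) * logistic(rh, params$rh_logistic)
}

#' Precipitation emission-activity factor
#'
#' `f_PR = f_baseline + (1 - f_baseline) * f_l(PR) / f_l(0)`. The division by
#' `f_l(0)` normalises the factor to exactly 1 under no rain; it decreases
#' towards the `f_baseline` floor as rain intensifies.
#'
#' @param pr Precipitation rate, mm h^-1, non-negative. Vectorised.
#' @inheritParams f_rh
#' @return Fractions in `(f_baseline, 1]`, with `f_pr(0) == 1` exactly.
#' @export
f_pr <- function(pr, params = activity_params()) {
  stopifnot(inherits(params, "activity_params"), is.numeric(pr))
  if (any(!is.finite(pr)) || any(pr < 0)) {
    stop("`pr` must be non-negative", call. = FALSE)
  }
  fl0 <- logistic(0, params$pr_logistic)
  params$f_baseline +
    (1 - params$f_baseline) * logistic(pr, params$pr_logistic) / fl0
}

#' Wind-speed emission-activity factor
#'
#' `f_WS = f_baseline + (1 - f_baseline) * (1 - exp(-WS / u_sat))`: 0.33 at
#' calm, 0.75 at the saturation wind speed (5 m s^-1 default), asymptoting to
#' 1 above ~15 m s^-1. Wind can only promote emission while pollen remains
#' available on the plant, hence the saturation.
#'
#' @param ws Wind speed, m s^-1, non-negative. Vectorised.
#' @inheritParams f_rh
#' @return Fractions in `[f_baseline, 1)`.
#' @export
f_ws <- function(ws, params = activity_params()) {
  stopifnot(inherits(params, "activity_params"), is.numeric(ws))
  if (any(!is.finite(ws)) || any(ws < 0)) {
    stop("`ws` must be non-negative", call. = FALSE)
  }
  params$f_baseline + (1 - params$f_baseline) * (1 - exp(-ws / params$u_sat))
}
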