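#' Physical constants used by the temperature models
#'
#' Gas constant `R` in J/(mol K), Boltzmann constant `kB` in J/K, Planck
#' constant `h` in J s, and seconds per day.
#' @keywords internal
.const <- list(R = 8.314, kB = 1.381e-23, h = 6.626e-34, day_s = 86400)

.check_rates <- function(k, temperature) {
  k <- as.numeric(k)
  temperature <- as.numeric(temperature)
  if (length(k) != length(temperature))
    stop("'k' and 'temperature' must have equal length", call. = FALSE)
  if (length(unique(temperature)) < 2L)
    stop("need rate constants at >= 2 distinct temperatures", call. = FALSE)
  if (any(k <= 0)) stop("all rate constants must be positive", call. = FALSE)
  if (any(temperature <= -273.15))
    stop("temperatures must exceed absolute zero", call. = FALSE)
  list(k = k, temp_c = temperature)
}

#' Fit the Arrhenius model to rate constants
#'
#' Centered Arrhenius regression
#' `ln(k) = ln(k_ref) - (Ea / R) * (1/T - 1/T_ref)` with temperatures in
#' Kelvin.  The reference temperature defaults to the arithmetic mean of the
#' input temperatures, so `k_ref` is the rate at the middle of the studied
#' range and the activation energy `Ea = -slope * R`.
#'
#' @param k Positive rate-constant magnitudes (any single reaction order).
#' @param temperature Storage temperatures in degrees Celsius.
#' @param t_ref Reference temperature in degrees Celsius (default: mean of
#'   `temperature`).
#' @return An object of class `arrhenius_fit`: list with `k_ref`, `Ea`
#'   (J/mol), `t_ref_c`, `t_ref_k`, `r2`.
#' @examples
#' fit_arrhenius(c(0.0694, 0.0815, 0.1279), c(5, 15, 25))
#' @export
fit_arrhenius <- function(k, temperature, t_ref = NULL) {
  r <- .check_rates(k, temperature)
  if (is.null(t_ref)) t_ref <- mean(r$temp_c)
  TK <- r$temp_c + 273.15
  Tref_K <- t_ref + 273.15
  x <- 1 / TK - 1 / Tref_K
  line <- .ols_line(x, log(r$k))
  structure(list(k_ref = exp(line$intercept), Ea = -line$slope * .const$R,
                 t_ref_c = t_ref, t_ref_k = Tref_K, r2 = line$r2),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Arrhenius fit: Ea = %.3f kJ/mol, k_ref = %.4g at %g degC (R2 = %.3f)\n",
    x$Ea / 1000, x$k_ref, x$t_ref_c, x$r2))
  invisible(x)
}

#' Predict a rate constant at a new temperature
#'
#' `k(T) = k_ref * exp(-(Ea / R) * (1/T - 1/T_ref))`, strictly increasing in
#' temperature when `Ea > 0`.
#'
#' @param fit An [fit_arrhenius()] result.
#' @param temperature Temperature(s) in degrees Celsius.
#' @return Predicted rate-constant magnitude(s).
#' @export
predict_k <- function(fit, temperature) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  temperature <- as.numeric(temperature)
  if (any(temperature <= -273.15))
    stop("temperature must exceed absolute zero", call. = FALSE)
  TK <- temperature + 273.15
  fit$k_ref * exp(-(fit$Ea / .const$R) * (1 / TK - 1 / fit$t_ref_k))
}

#' Fit the Eyring transition-state model to rate constants
#'
#' Regression of `ln(k/T)` on `1/T` (Kelvin):
#' `ln(k/T) = -(dH / R) * (1/T) + ln(kB/h) + dS / R`, giving the activation
#' enthalpy `dH = -slope * R` and entropy
#' `dS = R * (intercept - ln(kB/h))`.  Rate constants given per day are
#' converted to per second before the intercept decomposition (`dH` is
#' unit-invariant; `dS` is not, and the unit choice is recorded on the
#' fit).
#'
#' @param k Positive rate-constant magnitudes.
#' @param temperature Temperatures in degrees Celsius.
#' @param k_units `"per_day"` (converted to per second) or `"per_second"`.
#' @return An object of class `eyring_fit`: list with `delta_H` (J/mol),
#'   `delta_S` (J/(mol K)), `r2`, `k_units`.
#' @export
fit_eyring <- function(k, temperature, k_units = c("per_day", "per_second")) {
  k_units <- match.arg(k_units)
  r <- .check_rates(k, temperature)
  ks <- if (k_units == "per_day") r$k / .const$day_s else r$k
  TK <- r$temp_c + 273.15
  line <- .ols_line(1 / TK, log(ks / TK))
  dH <- -line$slope * .const$R
  dS <- .const$R * (line$intercept - log(.const$kB / .const$h))
  structure(list(delta_H = dH, delta_S = dS, r2 = line$r2,
                 k_units = k_units),
            class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf(
    "Eyring fit: dH = %.3f kJ/mol, dS = %.2f J/(mol K) (R2 = %.3f, k in %s)\n",
    x$delta_H / 1000, x$delta_S, x$r2, gsub("_", " ", x$k_units)))
  invisible(x)
}

#' Decimal-reduction time from a rate constant
#'
#' `D = ln(10) / k`: the storage time over which a first-order-style decade
#' change in the quality index would occur at rate `k`.
#'
#' @param k Positive rate-constant magnitude.
#' @return D-value in days (for `k` per day).
#' @export
d_value <- function(k) {
  if (any(k <= 0)) stop("'k' must be positive", call. = FALSE)
  log(10) / k
}

#' Fit the Ball model to rate constants
#'
#' D-values `D = ln(10)/k` are regressed as
#' `log10(D / D_ref) = -(T - T_ref) / Z` with temperatures in degrees
#' Celsius, giving `Z = -1 / slope` (the temperature shift producing a
#' tenfold change in D) and `D_ref = 10^intercept`.
#'
#' @param k Positive rate-constant magnitudes.
#' @param temperature Temperatures in degrees Celsius.
#' @param t_ref Reference temperature in degrees Celsius (default: mean of
#'   `temperature`).
#' @return An object of class `ball_fit`: list with `D_ref` (days), `Z`
#'   (degrees Celsius), `t_ref_c`, `r2`.  `Z` is `Inf` (with a message)
#'   when the rates do not vary with temperature.
#' @export
fit_ball <- function(k, temperature, t_ref = NULL) {
  r <- .check_rates(k, temperature)
  if (is.null(t_ref)) t_ref <- mean(r$temp_c)
  D <- d_value(r$k)
  line <- .ols_line(r$temp_c - t_ref, log10(D))
  Z <- if (line$slope == 0) {
    message("zero slope: Z is infinite (temperature-insensitive rates)")
    Inf
  } else -1 / line$slope
  structure(list(D_ref = 10^line$intercept, Z = Z, t_ref_c = t_ref,
                 r2 = line$r2),
            class = "ball_fit")
}

#' @export
print.ball_fit <- function(x, ...) {
  cat(sprintf("Ball fit: D_ref = %.2f days at %g degC, Z = %.2f degC (R2 = %.3f)\n",
              x$D_ref, x$t_ref_c, x$Z, x$r2))
  invisible(x)
}
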