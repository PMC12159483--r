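#' A storage time series for one quality index at one temperature
#'
#' @param index_name Name of the quality index (e.g. `"tba"`,
#'   `"total_plate_count"`).
#' @param temperature Storage temperature in degrees Celsius.
#' @param days Strictly increasing sampling days starting at 0.
#' @param values Mean index level per day, in `units`.
#' @param units Unit string (optional).
#' @param direction `"increasing"` or `"decreasing"`; inferred from the
#'   first and last value when omitted.
#' @return An object of class `storage_series`.
#' @examples
#' tba5 <- storage_series("tba", 5, c(0, 3, 6, 9, 12, 15),
#'                        c(0.022, 0.029, 0.037, 0.040, 0.043, 0.047))
#' fit_order(tba5, 0)
#' @export
storage_series <- function(index_name, temperature, days, values,
                           units = "", direction = NULL) {
  days <- as.numeric(days)
  values <- as.numeric(values)
  if (length(days) != length(values))
    stop("'days' and 'values' must have equal length", call. = FALSE)
  if (length(days) < 3L)
    stop("a storage series needs at least 3 time points", call. = FALSE)
  if (any(diff(days) <= 0) || days[1L] != 0)
    stop("'days' must be strictly increasing and start at 0", call. = FALSE)
  if (anyNA(values)) stop("'values' must not contain NA", call. = FALSE)
  if (is.null(direction))
    direction <- if (values[length(values)] >= values[1L])
      "increasing" else "decreasing"
  direction <- match.arg(direction, c("increasing", "decreasing"))
  structure(list(index_name = as.character(index_name),
                 temperature = as.numeric(temperature), days = days,
                 values = values, units = as.character(units),
                 direction = direction),
            class = "storage_series")
}

#' @export
print.storage_series <- function(x, ...) {
  cat("Storage series '", x$index_name, "' at ", x$temperature,
      " degC (", x$direction, ")\n", sep = "")
  print(data.frame(day = x$days, value = x$values))
  invisible(x)
}

## closed-form OLS slope/intercept with R^2 on the given scale
.ols_line <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  fitted <- intercept + slope * x
  sst <- sum((y - ym)^2)
  r2 <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else 1
  list(slope = slope, intercept = intercept, r2 = r2, fitted = fitted)
}

#' Fit an n-th order degradation model to a storage series
#'
#' Ordinary least squares on the linearizing transform of the chosen
#' reaction order: order 0 regresses `C` on `t`, order 1 regresses `ln(C)`
#' on `t`, order 2 regresses `1/C` on `t`.  The rate constant is stored as a
#' magnitude with a direction flag (quality indices that grow during
#' storage, such as acidity or microbial counts, have formally negative
#' zero-order slopes).  R-squared is computed on the transformed scale; the
#' reduced chi-square is computed on the original concentration scale.
#'
#' @param series A [storage_series()].
#' @param order Reaction order: 0, 1 or 2.
#' @return An object of class `kinetic_fit`: list with `order`, `k`
#'   (magnitude; units per day, 1/day or 1/(units*day) by order), `c0_fit`
#'   (back-transformed intercept), `r2`, `chi_square`, `direction`,
#'   `fitted` (original scale) and the input series.
#' @export
fit_order <- function(series, order) {
  stopifnot(inherits(series, "storage_series"))
  if (!order %in% c(0, 1, 2)) stop("order must be 0, 1 or 2", call. = FALSE)
  t <- series$days
  C <- series$values
  if (order %in% c(1, 2) && any(C <= 0))
    stop("first/second-order transforms need strictly positive values",
         call. = FALSE)
  y <- switch(as.character(order), "0" = C, "1" = log(C), "2" = 1 / C)
  line <- .ols_line(t, y)
  ## direction of change of C implied by the slope on the transform scale:
  ## C and ln(C) move with the slope, 1/C moves against it
  direction <- if (order == 2) {
    if (line$slope >= 0) "decreasing" else "increasing"
  } else {
    if (line$slope >= 0) "increasing" else "decreasing"
  }
  c0_fit <- switch(as.character(order),
                   "0" = line$intercept,
                   "1" = exp(line$intercept),
                   "2" = 1 / line$intercept)
  fitted_C <- switch(as.character(order),
                     "0" = line$fitted,
                     "1" = exp(line$fitted),
                     "2" = 1 / line$fitted)
  fit <- structure(list(order = order, k = abs(line$slope), c0_fit = c0_fit,
                        r2 = line$r2, direction = direction,
                        fitted = fitted_C, series = series),
                   class = "kinetic_fit")
  fit$chi_square <- chi_square(fit, series)
  fit
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "Order-%d kinetic fit for '%s' at %g degC: k = %.4g (%s), R2 = %.3f, chi2 = %.3g\n",
    x$order, x$series$index_name, x$series$temperature, x$k, x$direction,
    x$r2, x$chi_square))
  invisible(x)
}

#' Reduced chi-square of a kinetic fit
#'
#' `sum((observed - predicted)^2) / (n - p)` on the original concentration
#' scale, with `p = 2` fitted parameters (slope and intercept).
#'
#' @param fit A `kinetic_fit`.
#' @param series The series the fit was computed on (defaults to the one
#'   stored in the fit).
#' @return The reduced chi-square statistic.
#' @export
chi_square <- function(fit, series = fit$series) {
  stopifnot(inherits(fit, "kinetic_fit"))
  n <- length(series$values)
  p <- 2L
  if (n <= p) stop("chi-square undefined for n <= ", p, call. = FALSE)
  sum((series$values - fit$fitted)^2) / (n - p)
}

#' Select the best-fitting reaction order for a storage series
#'
#' Fits all three orders and returns the one with the highest transformed-
#' scale R-squared; ties break toward the lower order.  Orders whose
#' transform is inapplicable (non-positive values) are skipped.
#'
#' @param series A [storage_series()].
#' @return List with `best_order`, `best_fit`, and `fits` (named list of
#'   all applicable `kinetic_fit`s).
#' @export
select_order <- function(series) {
  stopifnot(inherits(series, "storage_series"))
  orders <- c(0, 1, 2)
  fits <- list()
  for (m in orders) {
    f <- tryCatch(fit_order(series, m), error = function(e) NULL)
    if (!is.null(f)) fits[[paste0("order", m)]] <- f
  }
  if (!length(fits)) stop("no reaction order could be fitted", call. = FALSE)
  r2s <- vapply(fits, `[[`, numeric(1L), "r2")
  best <- fits[[which.max(r2s)]]       # which.max keeps the lower order on ties
  list(best_order = best$order, best_fit = best, fits = fits)
}

#' Kinetic half-life of a quality index
#'
#' Time for the index to change by half its initial level: order 0
#' `c0 / (2k)`, order 1 `ln(2) / k`, order 2 `1 / (k * c0)`.  For indices
#' that increase during storage the same formulas give the time to gain
#' `c0 / 2`, matching the convention used for positive rate-constant
#' magnitudes.
#'
#' @param c0 Initial level (> 0); conventionally the observed day-0 value.
#' @param k Rate-constant magnitude (> 0, or 0 for an infinitely stable
#'   index).
#' @param order Reaction order: 0, 1 or 2.
#' @return Half-life in days; `Inf` (with a message) when `k == 0`.
#' @examples
#' half_life(8.29, 0.0694, 0)   # 59.73 days
#' @export
half_life <- function(c0, k, order) {
  if (!order %in% c(0, 1, 2)) stop("order must be 0, 1 or 2", call. = FALSE)
  if (c0 <= 0) stop("'c0' must be positive", call. = FALSE)
  if (k < 0) stop("'k' must be non-negative", call. = FALSE)
  if (k == 0) {
    message("k = 0: half-life is infinite")
    return(Inf)
  }
  switch(as.character(order),
         "0" = c0 / (2 * k),
         "1" = log(2) / k,
         "2" = 1 / (k * c0))
}
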