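#' Time for a quality index to reach a limit level
#'
#' Inverts the fitted reaction-order law for the time at which the index,
#' starting from `c0`, reaches `limit`: order 0 `|limit - c0| / k`, order 1
#' `|ln(limit / c0)| / k`, order 2 `|1/limit - 1/c0| / k`.
#'
#' @param c0 Initial level (> 0).
#' @param limit Failure threshold in index units, on the correct side of
#'   `c0` for the direction of change.
#' @param k Positive rate-constant magnitude.
#' @param order Reaction order: 0, 1 or 2.
#' @param direction `"increasing"` or `"decreasing"` change of the index
#'   during storage.
#' @return Time in days to reach the limit.
#' @examples
#' # log10 plate count from 3.07 to the 10^6 cfu/mL guideline at k = 0.1646
#' shelf_life_to_limit(3.07, 6, 0.1646, 0, "increasing")
#' @export
shelf_life_to_limit <- function(c0, limit, k, order,
                                direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!order %in% c(0, 1, 2)) stop("order must be 0, 1 or 2", call. = FALSE)
  if (c0 <= 0) stop("'c0' must be positive", call. = FALSE)
  if (k <= 0) stop("'k' must be positive", call. = FALSE)
  if (order %in% c(1, 2) && limit <= 0)
    stop("'limit' must be positive for first/second-order laws",
         call. = FALSE)
  if (direction == "increasing" && limit <= c0)
    stop("an increasing index never reaches a limit below c0", call. = FALSE)
  if (direction == "decreasing" && limit >= c0)
    stop("a decreasing index never reaches a limit above c0", call. = FALSE)
  switch(as.character(order),
         "0" = abs(limit - c0) / k,
         "1" = abs(log(limit / c0)) / k,
         "2" = abs(1 / limit - 1 / c0) / k)
}

#' Predict shelf life at an arbitrary storage temperature
#'
#' Combines a fitted Arrhenius model with a reaction-order law: the rate at
#' temperature `T` comes from [predict_k()], and the shelf life is either
#' the half-life (`criterion = "half_change"`) or the time to reach a limit
#' level (`criterion = "limit"`).
#'
#' @param arrhenius An [fit_arrhenius()] result for the index.
#' @param c0 Initial level of the index (observed day-0 value).
#' @param temperature Storage temperature in degrees Celsius.
#' @param criterion `"half_change"` or `"limit"`.
#' @param limit Failure threshold (required for `criterion = "limit"`).
#'   The microbial guideline of 10^6 cfu/mL corresponds to `limit = 6` on
#'   the log10 scale.
#' @param order Reaction order of the index (default 0).
#' @param direction Direction of change (`"increasing"` for spoilage
#'   indices such as microbial counts).
#' @param index_name Optional label carried into the result.
#' @return An object of class `shelf_life_estimate`: list with
#'   `index_name`, `temperature`, `criterion`, `limit_value`, `k`,
#'   `shelf_life_days`.
#' @export
shelf_life_at_temperature <- function(arrhenius, c0, temperature,
                                      criterion = c("half_change", "limit"),
                                      limit = NULL, order = 0,
                                      direction = c("increasing",
                                                    "decreasing"),
                                      index_name = "") {
  criterion <- match.arg(criterion)
  direction <- match.arg(direction)
  kT <- predict_k(arrhenius, temperature)
  days <- if (criterion == "half_change") {
    half_life(c0, kT, order)
  } else {
    if (is.null(limit))
      stop("criterion 'limit' needs a 'limit' value", call. = FALSE)
    shelf_life_to_limit(c0, limit, kT, order, direction)
  }
  structure(list(index_name = index_name, temperature = temperature,
                 criterion = criterion,
                 limit_value = if (criterion == "limit") limit else NA_real_,
                 k = kT, shelf_life_days = days),
            class = "shelf_life_estimate")
}

#' @export
print.shelf_life_estimate <- function(x, ...) {
  cat(sprintf(
    "Shelf life%s at %g degC (%s): %.2f days (k = %.4g)\n",
    if (nzchar(x$index_name)) paste0(" of '", x$index_name, "'") else "",
    x$temperature, x$criterion, x$shelf_life_days, x$k))
  invisible(x)
}

#' Kinetic stability report across indices and temperatures
#'
#' Fits all three reaction orders to every (index, temperature) series,
#' selects the best order, computes half-lives, and fits the Arrhenius,
#' Eyring and Ball models per index on the selected-order rate constants.
#'
#' @param series_list List of [storage_series()] objects covering one or
#'   more indices at two or more temperatures each.
#' @param c0 Optional named vector of initial levels per index used for
#'   half-lives; defaults to each series' observed day-0 value.
#' @return A data frame of class `stability_report` with one row per
#'   (index, temperature): rate constants and R-squared for all three
#'   orders (NA where a transform is inapplicable), `selected_order`,
#'   `k_selected`, `chi_square` and `t_half`.  Per-index temperature-model
#'   parameters are in `attr(report, "temperature_models")`; the row order
#'   is deterministic (index, then temperature).
#' @export
stability_report <- function(series_list, c0 = NULL) {
  if (!length(series_list)) stop("no series supplied", call. = FALSE)
  ok <- vapply(series_list, inherits, logical(1L), "storage_series")
  if (!all(ok)) stop("all elements must be storage_series", call. = FALSE)
  idx <- vapply(series_list, `[[`, character(1L), "index_name")
  tmp <- vapply(series_list, `[[`, numeric(1L), "temperature")
  ord <- order(idx, tmp)
  series_list <- series_list[ord]
  idx <- idx[ord]; tmp <- tmp[ord]

  rows <- lapply(series_list, function(s) {
    sel <- select_order(s)
    f <- sel$fits
    get <- function(m, field) {
      nm <- paste0("order", m)
      if (nm %in% names(f)) f[[nm]][[field]] else NA_real_
    }
    c0_i <- if (!is.null(c0) && s$index_name %in% names(c0))
      c0[[s$index_name]] else s$values[1L]
    data.frame(index = s$index_name, temperature_C = s$temperature,
               k0 = get(0, "k"), r2_0 = get(0, "r2"),
               k1 = get(1, "k"), r2_1 = get(1, "r2"),
               k2 = get(2, "k"), r2_2 = get(2, "r2"),
               selected_order = sel$best_order,
               k_selected = sel$best_fit$k,
               chi_square = sel$best_fit$chi_square,
               t_half = half_life(c0_i, sel$best_fit$k,
                                  sel$best_fit$order),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  ## temperature models need one shared order per index: rate constants of
  ## different orders are on different scales, so pick the order with the
  ## highest mean R-squared across temperatures (ties toward the lower order)
  tm_rows <- lapply(split(seq_len(nrow(report)), report$index), function(ii) {
    sub <- report[ii, , drop = FALSE]
    if (nrow(sub) < 2L) return(NULL)
    mean_r2 <- c(mean(sub$r2_0), mean(sub$r2_1), mean(sub$r2_2))
    common <- which.max(mean_r2) - 1L
    k <- sub[[paste0("k", common)]]
    tc <- sub$temperature_C
    if (anyNA(k) || any(k <= 0)) return(NULL)
    ar <- fit_arrhenius(k, tc)
    ey <- fit_eyring(k, tc)
    ba <- fit_ball(k, tc)
    data.frame(index = sub$index[1L], order = common, k_ref = ar$k_ref,
               Ea = ar$Ea, arrhenius_r2 = ar$r2, delta_H = ey$delta_H,
               delta_S = ey$delta_S, eyring_r2 = ey$r2, D_ref = ba$D_ref,
               Z = ba$Z, ball_r2 = ba$r2, stringsAsFactors = FALSE)
  })
  tm <- do.call(rbind, tm_rows[!vapply(tm_rows, is.null, logical(1L))])
  if (!is.null(tm)) {
    tm <- tm[order(tm$index), , drop = FALSE]
    rownames(tm) <- NULL
  }
  attr(report, "temperature_models") <- tm
  class(report) <- c("stability_report", "data.frame")
  report
}
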