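#' Define a constrained mixture design region
#'
#' A bounded mixture region for `q` components whose actual amounts (in
#' percent of the final product) are constrained to fixed lower and upper
#' bounds and must sum to a fixed `total`.  The region is the intersection of
#' the box `[lower, upper]` with the hyperplane `sum(x) == total`; it is
#' mapped onto the unit simplex by L-pseudo-component coding (see
#' [to_pseudo()]).
#'
#' @param components Character vector of component names, in model order
#'   (the first component is term `A`, the second `B`, ...).
#' @param lower,upper Numeric vectors of per-component bounds, in percent.
#' @param total Fixed sum of the component amounts in every run, in percent.
#'   Ingredients held constant across runs (e.g. sugar, stabilizer) are
#'   excluded from the mixture and from `total`.
#'
#' @return An object of class `mixture_design_spec`: a list with elements
#'   `components`, `lower`, `upper`, `total`.
#'
#' @details The region is feasible iff `sum(lower) < total < sum(upper)`.
#'
#' @examples
#' lassi_spec <- mixture_design_spec(
#'   components = c("juice", "dahi", "water"),
#'   lower = c(5, 60, 15), upper = c(9.5, 64.5, 19.5), total = 84.5)
#' lassi_spec
#' @export
mixture_design_spec <- function(components, lower, upper, total) {
  components <- as.character(components)
  q <- length(components)
  if (q < 2L) stop("a mixture needs at least two components", call. = FALSE)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != q || length(upper) != q)
    stop("'lower' and 'upper' must have one entry per component", call. = FALSE)
  if (anyDuplicated(components))
    stop("component names must be unique", call. = FALSE)
  if (any(lower < 0) || total <= 0)
    stop("bounds must be non-negative and 'total' positive", call. = FALSE)
  if (any(upper < lower))
    stop("each upper bound must be >= its lower bound", call. = FALSE)
  if (!(sum(lower) < total && total < sum(upper)))
    stop("infeasible region: need sum(lower) < total < sum(upper)",
         call. = FALSE)
  names(lower) <- names(upper) <- components
  structure(list(components = components, lower = lower, upper = upper,
                 total = total),
            class = "mixture_design_spec")
}

#' @export
print.mixture_design_spec <- function(x, ...) {
  cat("Mixture design region (", length(x$components),
      " components, total = ", x$total, "%)\n", sep = "")
  print(data.frame(component = x$components, lower = x$lower,
                   upper = x$upper, row.names = NULL))
  invisible(x)
}

## internal: coerce a point or matrix of points to a q-column matrix in
## spec component order, accepting named vectors/data frames
.as_amount_matrix <- function(x, spec) {
  q <- length(spec$components)
  if (is.data.frame(x)) x <- as.matrix(x[, spec$components, drop = FALSE])
  if (is.null(dim(x))) {
    if (length(x) != q)
      stop("expected ", q, " component amounts, got ", length(x),
           call. = FALSE)
    if (!is.null(names(x)) && all(spec$components %in% names(x)))
      x <- x[spec$components]
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != q)
    stop("expected ", q, " component columns, got ", ncol(x), call. = FALSE)
  colnames(x) <- spec$components
  x
}

#' Convert actual amounts to L-pseudo-component proportions
#'
#' L-pseudo-component coding maps the constrained mixture region onto the
#' unit simplex: `pseudo_i = (actual_i - lower_i) / (total - sum(lower))`.
#' Scheffe polynomial coefficients reported for constrained designs (as in
#' mixture-design software output) are in this coding.
#'
#' @param actual Numeric vector of amounts (percent) in spec component
#'   order, or a matrix/data frame with one row per point.
#' @param spec A [mixture_design_spec()].
#' @param tol Tolerance for the sum-to-total and bound checks.
#'
#' @return A numeric vector (or matrix) of proportions in `[0, 1]` summing
#'   to 1 per point.
#' @seealso [from_pseudo()] for the inverse map.
#' @examples
#' spec <- mixture_design_spec(c("juice", "dahi", "water"),
#'                             c(5, 60, 15), c(9.5, 64.5, 19.5), 84.5)
#' to_pseudo(c(9.189, 60, 15.311), spec)
#' @export
to_pseudo <- function(actual, spec, tol = 1e-6) {
  stopifnot(inherits(spec, "mixture_design_spec"))
  x <- .as_amount_matrix(actual, spec)
  bad_total <- abs(rowSums(x) - spec$total) > tol
  if (any(bad_total))
    stop("amounts must sum to ", spec$total, " (rows ",
         paste(which(bad_total), collapse = ", "), " do not)", call. = FALSE)
  for (j in seq_along(spec$components)) {
    if (any(x[, j] < spec$lower[j] - tol) || any(x[, j] > spec$upper[j] + tol))
      stop("component '", spec$components[j], "' outside its bounds [",
           spec$lower[j], ", ", spec$upper[j], "]", call. = FALSE)
  }
  denom <- spec$total - sum(spec$lower)
  p <- sweep(x, 2L, spec$lower, "-") / denom
  p[p < 0] <- 0                       # clip rounding slack within tol
  if (nrow(p) == 1L) p[1L, ] else p
}

#' Convert L-pseudo-component proportions back to actual amounts
#'
#' Exact inverse of [to_pseudo()]:
#' `actual_i = lower_i + pseudo_i * (total - sum(lower))`.
#'
#' @param pseudo Numeric vector of proportions summing to 1 (or a matrix of
#'   such rows).
#' @param spec A [mixture_design_spec()].
#' @param tol Tolerance for the sum-to-one check.
#' @return A numeric vector (or matrix) of actual amounts in percent.
#' @examples
#' spec <- mixture_design_spec(c("juice", "dahi", "water"),
#'                             c(5, 60, 15), c(9.5, 64.5, 19.5), 84.5)
#' from_pseudo(c(1, 0, 0), spec)
#' @export
from_pseudo <- function(pseudo, spec, tol = 1e-6) {
  stopifnot(inherits(spec, "mixture_design_spec"))
  p <- .as_amount_matrix(pseudo, spec)
  bad <- abs(rowSums(p) - 1) > tol | apply(p < -tol, 1L, any)
  if (any(bad))
    stop("pseudo proportions must lie in [0,1] and sum to 1 (rows ",
         paste(which(bad), collapse = ", "), " do not)", call. = FALSE)
  x <- sweep(p * (spec$total - sum(spec$lower)), 2L, spec$lower, "+")
  if (nrow(x) == 1L) x[1L, ] else x
}

#' Scheffe polynomial terms at a simplex point
#'
#' Expands a point on the unit simplex into the term vector of an
#' intercept-free Scheffe mixture polynomial.  For three components the
#' degrees give terms `(A, B, C)` (linear), plus `(AB, AC, BC)` (quadratic),
#' plus the three-way product `ABC` (special cubic).
#'
#' @param pseudo Numeric vector of proportions summing to 1, or a matrix
#'   with one row per point.
#' @param degree One of `"linear"`, `"quadratic"`, `"special_cubic"`.
#' @return A named numeric vector (or matrix with one row per point) of term
#'   values, ordered as in the fitted model.
#' @examples
#' scheffe_terms(c(1/3, 1/3, 1/3), "special_cubic")
#' @export
scheffe_terms <- function(pseudo, degree = c("special_cubic", "quadratic",
                                             "linear")) {
  degree <- match.arg(degree)
  p <- if (is.null(dim(pseudo))) matrix(pseudo, nrow = 1L) else as.matrix(pseudo)
  q <- ncol(p)
  labs <- if (is.null(colnames(p)) || q > length(LETTERS))
    LETTERS[seq_len(q)] else LETTERS[seq_len(q)]
  out <- p
  colnames(out) <- labs
  if (degree %in% c("quadratic", "special_cubic")) {
    pair_idx <- utils::combn(q, 2L)
    pairs <- apply(pair_idx, 2L, function(ij) p[, ij[1L]] * p[, ij[2L]])
    pairs <- matrix(pairs, nrow = nrow(p))
    colnames(pairs) <- apply(pair_idx, 2L, function(ij)
      paste0(labs[ij[1L]], labs[ij[2L]]))
    out <- cbind(out, pairs)
  }
  if (degree == "special_cubic") {
    trip_idx <- utils::combn(q, 3L)
    trips <- apply(trip_idx, 2L, function(ijk)
      p[, ijk[1L]] * p[, ijk[2L]] * p[, ijk[3L]])
    trips <- matrix(trips, nrow = nrow(p))
    colnames(trips) <- apply(trip_idx, 2L, function(ijk)
      paste0(labs[ijk[1L]], labs[ijk[2L]], labs[ijk[3L]]))
    out <- cbind(out, trips)
  }
  if (nrow(out) == 1L) out[1L, ] else out
}

## number of Scheffe terms for q components at a given degree
.n_scheffe_terms <- function(q, degree) {
  switch(degree,
         linear = q,
         quadratic = q + choose(q, 2L),
         special_cubic = q + choose(q, 2L) + choose(q, 3L),
         stop("unknown degree '", degree, "'", call. = FALSE))
}
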