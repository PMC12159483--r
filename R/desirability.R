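#' Define a desirability goal for one response
#'
#' Derringer-Suich desirability transforms map each predicted response onto
#' `[0, 1]` before geometric-mean combination.  Four goal kinds are
#' supported: `maximize` (ramp up from `low` to `high`), `minimize`
#' (mirrored ramp), `target` (two-sided ramp peaking at `target`) and
#' `in_range` (indicator of `[low, high]`).
#'
#' @param response Name of the response (or mixture component) the goal
#'   scores.
#' @param kind One of `"maximize"`, `"minimize"`, `"target"`, `"in_range"`.
#' @param low,high Ramp endpoints; `low < high`.
#' @param target Target value (required for `kind = "target"`,
#'   `low < target < high`).
#' @param weight Shape exponent of the ramp (> 0); 1 is linear.
#' @param importance Positive integer weight in the geometric-mean
#'   combination.
#' @return An object of class `desirability_goal`.
#' @examples
#' g <- desirability_goal("juice", "maximize", low = 5, high = 9.5)
#' desirability_score(9.189, g)
#' @export
desirability_goal <- function(response,
                              kind = c("maximize", "minimize", "target",
                                       "in_range"),
                              low, high, target = NULL, weight = 1,
                              importance = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(low) || !is.numeric(high) || low >= high)
    stop("need numeric low < high", call. = FALSE)
  if (weight <= 0) stop("'weight' must be > 0", call. = FALSE)
  if (importance < 1 || importance != round(importance))
    stop("'importance' must be a positive integer", call. = FALSE)
  if (kind == "target") {
    if (is.null(target) || target <= low || target >= high)
      stop("'target' goals need low < target < high", call. = FALSE)
  }
  structure(list(response = response, kind = kind, low = low, high = high,
                 target = target, weight = weight,
                 importance = as.integer(importance)),
            class = "desirability_goal")
}

#' @export
print.desirability_goal <- function(x, ...) {
  cat("Desirability goal: ", x$kind, " '", x$response, "' over [", x$low,
      ", ", x$high, "]",
      if (!is.null(x$target)) paste0(" target ", x$target) else "",
      " (weight ", x$weight, ", importance ", x$importance, ")\n", sep = "")
  invisible(x)
}

#' Score values against a desirability goal
#'
#' @param value Numeric vector of response values.
#' @param goal A [desirability_goal()].
#' @return Desirabilities in `[0, 1]`, vectorized over `value`.
#' @export
desirability_score <- function(value, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  v <- as.numeric(value)
  w <- goal$weight
  d <- switch(goal$kind,
    maximize = {
      r <- (v - goal$low) / (goal$high - goal$low)
      pmin(pmax(r, 0), 1)^w
    },
    minimize = {
      r <- (goal$high - v) / (goal$high - goal$low)
      pmin(pmax(r, 0), 1)^w
    },
    target = {
      up <- (v - goal$low) / (goal$target - goal$low)
      down <- (goal$high - v) / (goal$high - goal$target)
      pmin(pmax(pmin(up, down), 0), 1)^w
    },
    in_range = as.numeric(v >= goal$low & v <= goal$high))
  d
}

#' Combine per-goal desirabilities into an overall score
#'
#' Importance-weighted geometric mean
#' `D = (prod(d_i ^ r_i)) ^ (1 / sum(r_i))`; any zero desirability forces
#' `D = 0`.
#'
#' @param d Numeric vector of per-goal desirabilities in `[0, 1]`.
#' @param importance Positive integer importances, recycled to `length(d)`.
#' @return Overall desirability in `[0, 1]`.
#' @export
overall_desirability <- function(d, importance = 1L) {
  d <- as.numeric(d)
  if (!length(d)) stop("no desirabilities supplied", call. = FALSE)
  if (any(d < -1e-12 | d > 1 + 1e-12))
    stop("desirabilities must lie in [0, 1]", call. = FALSE)
  r <- rep_len(as.numeric(importance), length(d))
  if (any(d == 0)) return(0)
  exp(sum(r * log(d)) / sum(r))
}

#' Find the most desirable formulation over the mixture region
#'
#' Searches the constrained mixture simplex for the actual-amount point
#' maximizing overall desirability.  Each goal is scored either on a
#' component amount (when `goal$response` names a mixture component) or on a
#' model prediction.  The search is a coarse grid over the feasible region
#' followed by two local grid-refinement passes (step shrinks tenfold each
#' pass), which is robust to the flat zero regions of ramp desirabilities.
#'
#' @param models Named list of `scheffe_fit`/`scheffe_model` objects keyed
#'   by response name; every non-component goal must have a matching entry.
#' @param goals List of [desirability_goal()] objects.
#' @param spec A [mixture_design_spec()] with three components.
#' @param step Coarse grid step in actual percent units (default 0.5).
#' @param seed Optional seed (the search itself is deterministic; the seed
#'   is honored for interface stability).
#' @return An object of class `formulation_optimum`: list with `actual`,
#'   `pseudo`, `predicted` (per modeled response), `desirabilities` (per
#'   goal), and `overall_desirability`.
#' @export
optimize_formulation <- function(models, goals, spec, step = 0.5,
                                 seed = NULL) {
  stopifnot(inherits(spec, "mixture_design_spec"))
  if (!length(goals)) stop("no goals supplied", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  models <- lapply(models, function(m)
    if (inherits(m, "scheffe_fit")) m$model else m)
  for (g in goals) {
    if (!inherits(g, "desirability_goal"))
      stop("every goal must be a desirability_goal", call. = FALSE)
    if (!(g$response %in% spec$components) &&
        !(g$response %in% names(models)))
      stop("goal response '", g$response,
           "' matches neither a component nor a fitted model", call. = FALSE)
  }

  score_points <- function(pseudo) {
    actual <- attr(pseudo, "actual")
    npt <- nrow(pseudo)
    D <- numeric(npt)
    dmat <- matrix(NA_real_, npt, length(goals))
    preds <- lapply(models, function(m) predict_response(m, pseudo))
    for (gi in seq_along(goals)) {
      g <- goals[[gi]]
      v <- if (g$response %in% spec$components)
        actual[, g$response] else preds[[g$response]]
      dmat[, gi] <- desirability_score(v, g)
    }
    imp <- vapply(goals, `[[`, integer(1L), "importance")
    for (i in seq_len(npt)) D[i] <- overall_desirability(dmat[i, ], imp)
    list(D = D, d = dmat, preds = preds)
  }

  grid <- simplex_grid(spec, step)
  sc <- score_points(grid)
  if (all(sc$D == 0))
    warning("overall desirability is zero everywhere on the search grid",
            call. = FALSE)
  best_i <- which.max(sc$D)
  best_actual <- attr(grid, "actual")[best_i, ]
  cur_step <- step
  ## local refinement: re-grid a shrinking box around the incumbent
  for (pass in 1:2) {
    fine <- cur_step / 10
    a_rng <- pmax(spec$lower[1L], best_actual[1L] - cur_step)
    a_max <- pmin(spec$upper[1L], best_actual[1L] + cur_step)
    b_rng <- pmax(spec$lower[2L], best_actual[2L] - cur_step)
    b_max <- pmin(spec$upper[2L], best_actual[2L] + cur_step)
    g <- expand.grid(a = seq(a_rng, a_max, by = fine),
                     b = seq(b_rng, b_max, by = fine),
                     KEEP.OUT.ATTRS = FALSE)
    g$c <- spec$total - g$a - g$b
    keep <- g$c >= spec$lower[3L] - 1e-9 & g$c <= spec$upper[3L] + 1e-9
    g <- g[keep, , drop = FALSE]
    if (nrow(g)) {
      actual <- as.matrix(g)
      colnames(actual) <- spec$components
      pseudo <- to_pseudo(actual, spec)
      if (is.null(dim(pseudo))) pseudo <- matrix(pseudo, nrow = 1L)
      colnames(pseudo) <- spec$components
      attr(pseudo, "actual") <- actual
      sc2 <- score_points(pseudo)
      j <- which.max(sc2$D)
      if (sc2$D[j] >= max(sc$D)) {
        best_actual <- actual[j, ]
        sc <- sc2
        best_i <- j
      }
    }
    cur_step <- fine
  }

  best_pseudo <- to_pseudo(best_actual, spec)
  preds <- vapply(models, function(m)
    predict_response(m, best_pseudo), numeric(1L))
  dvals <- vapply(goals, function(g) {
    v <- if (g$response %in% spec$components)
      best_actual[g$response] else preds[[g$response]]
    desirability_score(v, g)
  }, numeric(1L))
  names(dvals) <- vapply(goals, `[[`, character(1L), "response")
  imp <- vapply(goals, `[[`, integer(1L), "importance")
  structure(list(actual = best_actual, pseudo = best_pseudo,
                 predicted = preds, desirabilities = dvals,
                 overall_desirability = overall_desirability(dvals, imp)),
            class = "formulation_optimum")
}

#' @export
print.formulation_optimum <- function(x, ...) {
  cat("Optimal formulation (overall desirability ",
      sprintf("%.3f", x$overall_desirability), ")\n", sep = "")
  print(round(x$actual, 3))
  if (length(x$predicted)) {
    cat("Predicted responses:\n")
    print(round(x$predicted, 3))
  }
  invisible(x)
}
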