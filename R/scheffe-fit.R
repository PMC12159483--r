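#' Construct a Scheffe mixture model from known coefficients
#'
#' Builds a model object directly from per-term coefficients (for example a
#' published regression equation), bypassing fitting.  Coefficients are in
#' L-pseudo-component coding.
#'
#' @param coefficients Named or unnamed numeric vector, one value per
#'   Scheffe term in standard order (e.g. `A, B, C, AB, AC, BC, ABC` for a
#'   special cubic in three components).
#' @param degree Polynomial degree; inferred from the coefficient count for
#'   three components when omitted.
#' @param response Name of the modeled response.
#' @param units Units of the response (optional).
#' @return An object of class `scheffe_model`.
#' @examples
#' tfc <- scheffe_model(c(23.43, 11.95, 11.97, -3.74, -2.32, -0.2499, 13.41),
#'                      response = "total_flavonoid_content")
#' predict_response(tfc, c(0.930889, 0, 0.069111))
#' @export
scheffe_model <- function(coefficients, degree = NULL, response = "response",
                          units = "") {
  coefficients <- as.numeric(unlist(coefficients))
  if (is.null(degree)) {
    degree <- switch(as.character(length(coefficients)),
                     "3" = "linear", "6" = "quadratic", "7" = "special_cubic",
                     stop("cannot infer degree from ", length(coefficients),
                          " coefficients; give 'degree'", call. = FALSE))
  }
  n_terms <- .n_scheffe_terms(3L, degree)
  if (length(coefficients) != n_terms)
    stop("degree '", degree, "' needs ", n_terms, " coefficients, got ",
         length(coefficients), call. = FALSE)
  term_labels <- names(scheffe_terms(c(1, 0, 0), degree))
  names(coefficients) <- term_labels
  structure(list(degree = degree, terms = term_labels,
                 coefficients = coefficients, response = response,
                 units = units),
            class = "scheffe_model")
}

#' @export
print.scheffe_model <- function(x, digits = 4, ...) {
  eq <- paste(sprintf("%.*g*%s", digits, x$coefficients, x$terms),
              collapse = " + ")
  cat("Scheffe ", gsub("_", " ", x$degree), " model for '", x$response,
      "'\n  ", gsub("\\+ -", "- ", eq), "\n", sep = "")
  invisible(x)
}

#' Predict a response from a Scheffe model
#'
#' Dot product of the model coefficients with the Scheffe term expansion of
#' one or more simplex points.
#'
#' @param model A [scheffe_model()] or a fitted `scheffe_fit`.
#' @param pseudo Pseudo-component proportions (vector, or matrix with one
#'   row per point).
#' @return Numeric vector of predicted response values.
#' @export
predict_response <- function(model, pseudo) {
  if (inherits(model, "scheffe_fit")) model <- model$model
  stopifnot(inherits(model, "scheffe_model"))
  tm <- scheffe_terms(pseudo, model$degree)
  if (is.null(dim(tm))) tm <- matrix(tm, nrow = 1L)
  if (ncol(tm) != length(model$coefficients))
    stop("term count mismatch: model has ", length(model$coefficients),
         " terms, point expands to ", ncol(tm), call. = FALSE)
  drop(tm %*% model$coefficients)
}

#' @export
predict.scheffe_fit <- function(object, pseudo = NULL, ...) {
  if (is.null(pseudo)) return(object$fitted)
  predict_response(object$model, pseudo)
}

## internal: pseudo-term design matrix + response from a design data frame
.scheffe_design_matrix <- function(design, response, spec, degree) {
  if (!response %in% names(design))
    stop("response '", response, "' not found in the design table",
         call. = FALSE)
  missing_cols <- setdiff(spec$components, names(design))
  if (length(missing_cols))
    stop("design table lacks component columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  pseudo <- to_pseudo(design[, spec$components], spec)
  if (is.null(dim(pseudo))) pseudo <- matrix(pseudo, nrow = 1L)
  X <- scheffe_terms(pseudo, degree)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L,
                                   dimnames = list(NULL, names(X)))
  list(X = X, y = as.numeric(design[[response]]), pseudo = pseudo)
}

#' Fit a Scheffe mixture polynomial by least squares
#'
#' Converts each run's actual amounts to L-pseudo-components, expands the
#' Scheffe terms for the requested degree, and fits an intercept-free
#' ordinary least squares model.  Fit statistics follow the standard
#' response-surface conventions (see [fit_statistics()]).
#'
#' @param design Data frame with one row per run, containing the component
#'   columns named in `spec$components` (actual percent) and the response
#'   column.
#' @param response Name of the response column to fit.
#' @param spec A [mixture_design_spec()].
#' @param degree Polynomial degree, default `"special_cubic"`.
#' @param units Response units recorded on the model (optional).
#' @return An object of class `scheffe_fit`: list with elements `model`
#'   (a `scheffe_model`), `stats` (a `fit_stats` list), `fitted`,
#'   `residuals`, `leverage`, and the inputs.
#' @examples
#' spec <- mixture_design_spec(c("juice", "dahi", "water"),
#'                             c(5, 60, 15), c(9.5, 64.5, 19.5), 84.5)
#' fx <- lassi_fixtures()
#' fit <- fit_scheffe(fx$design, "total_flavonoid_content", spec)
#' fit
#' @export
fit_scheffe <- function(design, response, spec,
                        degree = c("special_cubic", "quadratic", "linear"),
                        units = "") {
  degree <- match.arg(degree)
  dm <- .scheffe_design_matrix(design, response, spec, degree)
  X <- dm$X
  y <- dm$y
  n <- nrow(X)
  p <- ncol(X)
  if (n < p)
    stop("need at least ", p, " runs to fit a ", degree, " model; got ", n,
         call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design: terms ", paste(dropped, collapse = ", "),
         " are collinear with earlier terms", call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  hat <- rowSums(qr.Q(qrX)[, seq_len(p), drop = FALSE]^2)
  model <- scheffe_model(beta, degree = degree, response = response,
                         units = units)
  stats <- .compute_fit_stats(y, fitted, resid, hat, p,
                              groups = .replicate_groups(dm$pseudo))
  structure(list(model = model, stats = stats, fitted = fitted,
                 residuals = resid, leverage = hat, design = design,
                 response = response, spec = spec),
            class = "scheffe_fit")
}

#' @export
print.scheffe_fit <- function(x, ...) {
  print(x$model)
  s <- x$stats
  cat(sprintf("  n = %d   mean = %.4g (rmse %.4g, CV %.2f%%)\n",
              length(x$fitted), s$grand_mean, s$root_mse, s$cv_percent))
  cat(sprintf("  R2 = %.4f   adj R2 = %.4f   pred R2 = %.4f   adeq prec = %.2f\n",
              s$r2, s$adjusted_r2, s$predicted_r2, s$adequate_precision))
  invisible(x)
}

## identify replicated design points (identical pseudo rows within 1e-8)
.replicate_groups <- function(pseudo) {
  key <- apply(round(pseudo, 8L), 1L, paste, collapse = "|")
  match(key, unique(key))
}

## core response-surface fit statistics; hat values feed the PRESS identity
.compute_fit_stats <- function(y, fitted, resid, hat, p, groups = NULL) {
  n <- length(y)
  sse <- sum(resid^2)
  gm <- mean(y)
  sstot <- sum((y - gm)^2)
  dfe <- n - p
  mse <- if (dfe > 0) sse / dfe else NA_real_
  rmse <- if (dfe > 0) sqrt(mse) else NA_real_
  degenerate <- sstot < .Machine$double.eps * max(1, sum(y^2))
  if (degenerate) {
    warning("constant response: R-squared is undefined and reported as 0",
            call. = FALSE)
    r2 <- 0
    adj_r2 <- pred_r2 <- 0
    model_f <- NA_real_
  } else {
    r2 <- 1 - sse / sstot
    if (dfe > 0) {
      adj_r2 <- 1 - (sse / dfe) / (sstot / (n - 1L))
      press <- sum((resid / (1 - hat))^2)
      pred_r2 <- 1 - press / sstot
      model_f <- ((sstot - sse) / (p - 1L)) / mse
    } else {
      warning("saturated fit (n == p): adjusted and predicted R-squared ",
              "are undefined", call. = FALSE)
      adj_r2 <- pred_r2 <- NA_real_
      model_f <- NA_real_
    }
  }
  adeq <- if (dfe > 0 && mse > 0)
    (max(fitted) - min(fitted)) / sqrt(p * mse / n) else NA_real_
  out <- list(r2 = r2, adjusted_r2 = adj_r2, predicted_r2 = pred_r2,
              cv_percent = if (dfe > 0) 100 * rmse / gm else NA_real_,
              adequate_precision = adeq, model_f = model_f,
              grand_mean = gm, root_mse = rmse)
  ## pure-error / lack-of-fit decomposition when replicate runs exist
  if (!is.null(groups) && dfe > 0) {
    n_distinct <- length(unique(groups))
    df_pe <- n - n_distinct
    df_lof <- n_distinct - p
    if (df_pe > 0 && df_lof > 0) {
      ss_pe <- sum(tapply(y, groups, function(v) sum((v - mean(v))^2)))
      ss_lof <- max(sse - ss_pe, 0)
      out$lack_of_fit_f <- (ss_lof / df_lof) / (ss_pe / df_pe)
      out$lack_of_fit_df <- c(df_lof, df_pe)
    }
  }
  class(out) <- "fit_stats"
  out
}

#' @export
print.fit_stats <- function(x, ...) {
  flat <- unlist(x[!vapply(x, is.null, logical(1L))])
  print(round(flat, 4))
  invisible(x)
}

#' Response-surface fit statistics for a Scheffe model
#'
#' Recomputes the full set of adequacy statistics for a model evaluated on a
#' design: R-squared on the mean-corrected total sum of squares (the models
#' have no intercept, but the proportions sum to one, so the uncorrected
#' R-squared would be trivially near 1), adjusted R-squared, predicted
#' R-squared from leave-one-out PRESS via the hat-matrix identity,
#' `cv_percent = 100 * root_mse / grand_mean`, adequate precision
#' `(max(fitted) - min(fitted)) / sqrt(p * MSE / n)`, and the model F on
#' mean-corrected totals.  When the design contains replicated runs, a
#' pure-error/lack-of-fit F decomposition is added.
#'
#' @param model A `scheffe_model` or `scheffe_fit`.  PRESS uses the OLS
#'   leave-one-out identity, which is exact when `model` is the least-squares
#'   fit on this design.
#' @param design,response,spec As in [fit_scheffe()].
#' @return A `fit_stats` list.
#' @export
fit_statistics <- function(model, design, response, spec) {
  if (inherits(model, "scheffe_fit")) model <- model$model
  stopifnot(inherits(model, "scheffe_model"))
  dm <- .scheffe_design_matrix(design, response, spec, model$degree)
  n <- nrow(dm$X)
  p <- ncol(dm$X)
  if (n < p)
    stop("fewer runs (", n, ") than model terms (", p, ")", call. = FALSE)
  fitted <- drop(dm$X %*% model$coefficients)
  qrX <- qr(dm$X)
  hat <- rowSums(qr.Q(qrX)[, seq_len(min(p, qrX$rank)), drop = FALSE]^2)
  .compute_fit_stats(dm$y, fitted, dm$y - fitted, hat, p,
                     groups = .replicate_groups(dm$pseudo))
}
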