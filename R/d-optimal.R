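#' Candidate grid over a constrained mixture region
#'
#' Enumerates a regular grid of feasible actual-amount points (first two
#' components stepped, the third determined by the fixed total) and returns
#' them as pseudo-component rows.  Used both as a D-optimal candidate set
#' and as the search grid of [optimize_formulation()].
#'
#' @param spec A [mixture_design_spec()] with exactly three components.
#' @param step Grid step in actual percent units (default 0.5).
#' @return Matrix of pseudo-component rows (columns named after the
#'   components); the actual amounts are in attribute `"actual"`.
#' @export
simplex_grid <- function(spec, step = 0.5) {
  stopifnot(inherits(spec, "mixture_design_spec"),
            length(spec$components) == 3L, step > 0)
  a <- seq(spec$lower[1L], spec$upper[1L], by = step)
  b <- seq(spec$lower[2L], spec$upper[2L], by = step)
  g <- expand.grid(a = a, b = b, KEEP.OUT.ATTRS = FALSE)
  g$c <- spec$total - g$a - g$b
  keep <- g$c >= spec$lower[3L] - 1e-9 & g$c <= spec$upper[3L] + 1e-9
  g <- g[keep, , drop = FALSE]
  if (!nrow(g)) stop("no feasible grid points at step ", step, call. = FALSE)
  actual <- as.matrix(g)
  colnames(actual) <- spec$components
  pseudo <- to_pseudo(actual, spec)
  if (is.null(dim(pseudo))) pseudo <- matrix(pseudo, nrow = 1L,
                                             dimnames = list(NULL, spec$components))
  rownames(pseudo) <- rownames(actual) <- NULL
  attr(pseudo, "actual") <- actual
  pseudo
}

#' Select a D-optimal run subset by Fedorov exchange
#'
#' Chooses `n_runs` rows from a candidate set of simplex points to maximize
#' `det(X'X)` of the Scheffe term matrix.  The design is built greedily
#' (each added point maximizes the determinant of the regularized
#' information matrix) and then improved by Fedorov point exchanges until no
#' swap increases the determinant.  Candidates are shuffled under `seed`
#' before the build; ties break toward the first candidate index, so the
#' result is deterministic given the seed.
#'
#' @param candidates Matrix of pseudo-component rows (e.g. from
#'   [simplex_grid()]).
#' @param n_runs Number of runs to select; must be at least the number of
#'   model terms.
#' @param degree Scheffe polynomial degree defining the term matrix.
#' @param seed Optional integer seed controlling the candidate shuffle.
#' @param max_iter Maximum full exchange passes.
#' @return List with `indices` (into the original candidate order),
#'   `pseudo` (selected rows), `det` and `log_det` of `X'X`, and the
#'   exchange `history` of determinants (non-decreasing).
#' @export
d_optimal_select <- function(candidates, n_runs,
                             degree = c("special_cubic", "quadratic", "linear"),
                             seed = NULL, max_iter = 50L) {
  degree <- match.arg(degree)
  cand <- as.matrix(candidates)
  X <- scheffe_terms(cand, degree)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  p <- ncol(X)
  if (n_runs < p)
    stop("n_runs (", n_runs, ") must be >= number of model terms (", p, ")",
         call. = FALSE)
  if (n_runs > nrow(X))
    stop("n_runs exceeds the candidate count", call. = FALSE)
  ord <- seq_len(nrow(X))
  if (!is.null(seed)) {
    set.seed(seed)
    ord <- sample(ord)
  }
  Xo <- X[ord, , drop = FALSE]

  det_of <- function(idx) {
    M <- crossprod(Xo[idx, , drop = FALSE])
    det(M)
  }
  ## greedy build with a ridge to keep early (singular) steps ranked
  sel <- integer(0L)
  eps <- 1e-8
  for (step_i in seq_len(n_runs)) {
    pool <- setdiff(seq_len(nrow(Xo)), sel)
    gains <- vapply(pool, function(j) {
      M <- crossprod(Xo[c(sel, j), , drop = FALSE]) + eps * diag(p)
      det(M)
    }, numeric(1L))
    sel <- c(sel, pool[which.max(gains)])   # which.max: first index wins ties
  }
  cur <- det_of(sel)
  history <- cur
  for (iter in seq_len(max_iter)) {
    improved <- FALSE
    for (i in seq_along(sel)) {
      pool <- setdiff(seq_len(nrow(Xo)), sel)
      if (!length(pool)) break
      trial <- vapply(pool, function(j) {
        idx <- sel; idx[i] <- j; det_of(idx)
      }, numeric(1L))
      best <- which.max(trial)
      if (trial[best] > cur * (1 + 1e-12)) {
        sel[i] <- pool[best]
        cur <- trial[best]
        history <- c(history, cur)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  indices <- ord[sel]
  list(indices = indices, pseudo = cand[indices, , drop = FALSE],
       det = cur, log_det = log(cur), history = history)
}
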