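# shared fixtures and independent oracles for the test suite

lassi_spec <- lassikin::lassi_design_spec()

# uniform random feasible actual-amount points for the 3-component region
random_feasible <- function(n, spec = lassi_spec) {
  out <- matrix(NA_real_, n, 3L, dimnames = list(NULL, spec$components))
  i <- 0L
  while (i < n) {
    a <- stats::runif(1L, spec$lower[1L], spec$upper[1L])
    b <- stats::runif(1L, spec$lower[2L], spec$upper[2L])
    cc <- spec$total - a - b
    if (cc >= spec$lower[3L] && cc <= spec$upper[3L]) {
      i <- i + 1L
      out[i, ] <- c(a, b, cc)
    }
  }
  out
}

# brute-force normal-equations OLS oracle: solve(X'X) X'y
ols_oracle <- function(X, y) unname(drop(solve(crossprod(X), crossprod(X, y))))

# closed-form simple-regression slope oracle
slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
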