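## exact trajectory of the order-m law at rate k, signed by direction
.trajectory <- function(order, c0, k, t, direction) {
  s <- if (direction == "increasing") -1 else 1   # degradation is the + case
  switch(as.character(order),
         "0" = c0 - s * k * t,
         "1" = c0 * exp(-s * k * t),
         "2" = {
           denom <- 1 / c0 + s * k * t
           ifelse(denom > 0, 1 / denom, NA_real_)
         })
}

#' Simulate multi-temperature storage trajectories with known truth
#'
#' Generates storage series for one quality index: the rate constant at each
#' temperature follows the Arrhenius law
#' `k(T) = k_ref * exp(-(Ea/R) * (1/T - 1/T_ref))`, the mean trajectory is
#' the exact solution of the chosen reaction order, and i.i.d. Gaussian
#' noise is added per replicate on the concentration scale.  Defaults
#' mirror a chilled-beverage stability study: sampling every 3 days for 15
#' days at 5, 15 and 25 degrees Celsius with 3 replicates.
#'
#' @param order True reaction order: 0, 1 or 2.
#' @param c0 True initial level (> 0).
#' @param k_ref True rate magnitude at `t_ref` (units per day by order).
#' @param Ea Activation energy in J/mol (0 gives temperature-independent
#'   rates).
#' @param t_ref Reference temperature in degrees Celsius.
#' @param temperatures Storage temperatures in degrees Celsius.
#' @param days Sampling days (must start at 0).
#' @param replicates Number of replicates per day (>= 1).
#' @param noise_sd Gaussian noise SD in index units (>= 0).
#' @param direction Direction of change of the index.
#' @param index_name Label for the generated series.
#' @param seed Optional integer seed for reproducibility.
#' @return List of [storage_series()] (replicate means), one per
#'   temperature, named by temperature.  Raw replicate matrices are in
#'   attribute `"replicates"`; the true per-temperature rates in
#'   attribute `"k_true"`.
#' @export
simulate_storage <- function(order = 0, c0 = 1, k_ref = 0.1, Ea = 0,
                             t_ref = 15, temperatures = c(5, 15, 25),
                             days = seq(0, 15, by = 3), replicates = 3,
                             noise_sd = 0,
                             direction = c("decreasing", "increasing"),
                             index_name = "index", seed = NULL) {
  direction <- match.arg(direction)
  if (!order %in% c(0, 1, 2)) stop("order must be 0, 1 or 2", call. = FALSE)
  if (c0 <= 0 || k_ref <= 0) stop("'c0' and 'k_ref' must be positive",
                                  call. = FALSE)
  if (noise_sd < 0 || replicates < 1)
    stop("'noise_sd' must be >= 0 and 'replicates' >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Tref_K <- t_ref + 273.15
  out <- list()
  raw <- list()
  k_true <- numeric(length(temperatures))
  for (ti in seq_along(temperatures)) {
    TK <- temperatures[ti] + 273.15
    kT <- k_ref * exp(-(Ea / .const$R) * (1 / TK - 1 / Tref_K))
    k_true[ti] <- kT
    mu <- .trajectory(order, c0, kT, days, direction)
    if (anyNA(mu) || any(mu <= 0 & order %in% c(1, 2))) {
      warning("trajectory at ", temperatures[ti],
              " degC crosses zero; truncated to a small positive floor",
              call. = FALSE)
      floor_v <- 1e-9
      mu[is.na(mu) | mu <= 0] <- floor_v
    }
    reps <- matrix(rep(mu, each = replicates) +
                     stats::rnorm(replicates * length(days), 0, noise_sd),
                   nrow = replicates)
    if (order %in% c(1, 2)) reps[reps <= 0] <- 1e-9
    means <- colMeans(reps)
    if (order %in% c(1, 2)) means[means <= 0] <- 1e-9
    nm <- paste0("T", temperatures[ti])
    out[[nm]] <- storage_series(index_name, temperatures[ti], days, means,
                                direction = direction)
    raw[[nm]] <- reps
  }
  names(k_true) <- names(out)
  attr(out, "replicates") <- raw
  attr(out, "k_true") <- k_true
  out
}

#' Simulate a mixture study from a known Scheffe model
#'
#' Evaluates true Scheffe polynomials at each run's pseudo-component point
#' and adds i.i.d. Gaussian noise per response, yielding a design table
#' with known ground truth for coefficient-recovery experiments.  The
#' default run layout is the packaged 17-run D-optimal study design.
#'
#' @param spec A [mixture_design_spec()].
#' @param true_coefficients Named list: one coefficient vector (or
#'   [scheffe_model()]) per response.
#' @param design Data frame of runs with the component columns in actual
#'   percent; defaults to the packaged 17-run layout when `spec` matches
#'   the packaged study region.
#' @param noise_sd Noise SD, a single value or one per response.
#' @param seed Optional integer seed.
#' @return A design data frame with the component columns plus one column
#'   per simulated response.
#' @export
simulate_mixture_study <- function(spec, true_coefficients, design = NULL,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(inherits(spec, "mixture_design_spec"))
  if (is.null(design)) {
    design <- lassi_design_runs()
    if (!all(spec$components %in% names(design)))
      stop("default design lacks these component names; supply 'design'",
           call. = FALSE)
  }
  if (!all(spec$components %in% names(design)))
    stop("design lacks component columns ",
         paste(setdiff(spec$components, names(design)), collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  models <- lapply(true_coefficients, function(b)
    if (inherits(b, "scheffe_model")) b else scheffe_model(b))
  noise_sd <- rep_len(noise_sd, length(models))
  pseudo <- to_pseudo(design[, spec$components], spec)
  if (is.null(dim(pseudo))) pseudo <- matrix(pseudo, nrow = 1L)
  for (ri in seq_along(models)) {
    mu <- predict_response(models[[ri]], pseudo)
    design[[names(models)[ri]]] <-
      mu + stats::rnorm(length(mu), 0, noise_sd[ri])
  }
  design
}

#' Parameter-recovery experiment for the storage pipeline
#'
#' Repeats simulate-then-fit cycles: each replicate generates a storage
#' study via [simulate_storage()], fits all three reaction orders at every
#' temperature, records whether the true order is selected, and refits the
#' Arrhenius model on the true-order rate constants.
#'
#' @param n_replicates Number of simulation replicates.
#' @param seed Integer seed for the whole experiment.
#' @param noise_type `"additive"` Gaussian on the concentration scale, or
#'   `"lognormal_rate"`: multiplicative lognormal noise applied to the
#'   per-temperature rate constants themselves (the trajectory is then
#'   exact at the perturbed rate), isolating rate-level noise for Ea
#'   recovery studies.
#' @param rate_noise_cv Coefficient of variation of the lognormal rate
#'   noise (used only for `noise_type = "lognormal_rate"`).
#' @param ... Passed to [simulate_storage()] (true parameters, grid,
#'   `noise_sd`, ...).
#' @return List with `summary` (data frame of bias, RMSE and relative-error
#'   quantiles for `Ea` and per-temperature `k`), `order_accuracy`
#'   (fraction of series where the true order won), and the raw per-replicate
#'   estimates in `draws`.
#' @export
recovery_experiment <- function(n_replicates, seed = 1,
                                noise_type = c("additive", "lognormal_rate"),
                                rate_noise_cv = 0.05, ...) {
  noise_type <- match.arg(noise_type)
  args <- list(...)
  order_true <- if (is.null(args$order)) 0 else args$order
  Ea_true <- if (is.null(args$Ea)) 0 else args$Ea
  set.seed(seed)
  ea_hat <- numeric(n_replicates)
  k_hat <- NULL
  n_correct <- 0L
  n_series <- 0L
  for (r in seq_len(n_replicates)) {
    if (noise_type == "additive") {
      sim <- do.call(simulate_storage, c(args, list(seed = NULL)))
      k_true <- attr(sim, "k_true")
      k_est <- vapply(sim, function(s) fit_order(s, order_true)$k,
                      numeric(1L))
      sel <- vapply(sim, function(s) select_order(s)$best_order, numeric(1L))
      n_correct <- n_correct + sum(sel == order_true)
      n_series <- n_series + length(sel)
      temps <- vapply(sim, `[[`, numeric(1L), "temperature")
    } else {
      ## perturb the Arrhenius-true rates directly
      temps <- if (is.null(args$temperatures)) c(5, 15, 25)
               else args$temperatures
      t_ref <- if (is.null(args$t_ref)) 15 else args$t_ref
      k_ref <- if (is.null(args$k_ref)) 0.1 else args$k_ref
      TK <- temps + 273.15
      k_true <- k_ref * exp(-(Ea_true / .const$R) *
                              (1 / TK - 1 / (t_ref + 273.15)))
      sdlog <- sqrt(log(1 + rate_noise_cv^2))
      k_est <- k_true * stats::rlnorm(length(k_true), -sdlog^2 / 2, sdlog)
      names(k_est) <- paste0("T", temps)
    }
    ea_hat[r] <- fit_arrhenius(k_est, temps)$Ea
    if (is.null(k_hat)) k_hat <- matrix(NA_real_, n_replicates,
                                        length(k_est),
                                        dimnames = list(NULL, names(k_est)))
    k_hat[r, ] <- k_est
  }
  rel_err <- if (Ea_true != 0) abs(ea_hat - Ea_true) / abs(Ea_true)
             else abs(ea_hat)
  summ <- data.frame(
    parameter = "Ea", true = Ea_true, bias = mean(ea_hat) - Ea_true,
    rmse = sqrt(mean((ea_hat - Ea_true)^2)),
    rel_err_q05 = unname(stats::quantile(rel_err, 0.05)),
    rel_err_q50 = unname(stats::quantile(rel_err, 0.50)),
    rel_err_q95 = unname(stats::quantile(rel_err, 0.95)),
    stringsAsFactors = FALSE)
  list(summary = summ,
       order_accuracy = if (n_series > 0) n_correct / n_series else NA_real_,
       draws = list(Ea = ea_hat, k = k_hat))
}
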