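#' Evaluate heterogeneity priors on a simulation scenario
#'
#' For every replicate dataset of the scenario and every prior: fit the
#' binomial-normal hierarchical model, record the posterior median of
#' delta and tau, whether the equal-tailed 95% CrI covers the true
#' delta, and the convergence flag.  Per prior the replicates are
#' aggregated into the standard performance measures: average posterior
#' median of delta, 95% CrI coverage, mean squared error of the
#' posterior median of delta, and average posterior median of tau, each
#' with a Monte-Carlo standard error (binomial formula for coverage,
#' sample SD / sqrt(reps) for means).
#'
#' The empirical priors E/e recompute s0 from each replicate dataset.
#' Non-converged replicates are included in the aggregates (excluding
#' them would bias coverage) and tallied in \code{n_converged}; set
#' \code{drop_nonconverged = TRUE} for a sensitivity analysis.  A
#' replicate whose fit errors is dropped from that prior's aggregates
#' and counted in \code{n_failed}; the scenario run continues.
#'
#' @param scenario an \code{\link{ma_scenario}}.
#' @param priors character vector of prior ids.
#' @param chains,iter,burnin,thin MCMC settings per fit (defaults sized
#'   for simulation work).
#' @param drop_nonconverged exclude flagged replicates from aggregates?
#' @param ... further arguments passed to \code{\link{bnhm}}.
#' @return A data.frame of class \code{"bnhm_performance"}, one row per
#'   prior, carrying the scenario factors, the aggregates and their
#'   MC-SEs.
#' @examples
#' \donttest{
#' sc <- ma_scenario(k = 2, n_range = c(5, 10), pi_c = 0.1, tau = 0.5,
#'                   delta = 0, n_reps = 20, seed = 7)
#' eval_priors(sc, priors = c("AU", "dn"), iter = 6000, burnin = 1500)
#' }
#' @export
eval_priors <- function(scenario, priors, chains = 3, iter = 30000,
                        burnin = 4500, thin = 3,
                        drop_nonconverged = FALSE, ...) {
  stopifnot(inherits(scenario, "ma_scenario"), length(priors) >= 1)
  reps <- seq_len(scenario$n_reps)
  cells <- array(NA_real_, dim = c(length(reps), length(priors), 4),
                 dimnames = list(NULL, priors,
                                 c("med_delta", "covered", "med_tau",
                                   "converged")))
  for (r in reps) {
    dat <- simulate_meta(scenario, rep = r)
    for (p in seq_along(priors)) {
      fit <- tryCatch(
        suppressWarnings(
          bnhm(dat, priors[p], chains = chains, iter = iter,
               burnin = burnin, thin = thin,
               seed = replicate_seed(scenario$seed + 7919L * p, r), ...)),
        error = function(e) NULL)
      if (is.null(fit)) next
      delta <- posterior_draws(fit, "delta")
      qs <- stats::quantile(delta, c(0.025, 0.5, 0.975), names = FALSE)
      cells[r, p, "med_delta"] <- qs[2]
      cells[r, p, "covered"] <-
        as.numeric(qs[1] <= scenario$delta & scenario$delta <= qs[3])
      cells[r, p, "med_tau"] <- stats::median(posterior_draws(fit, "tau"))
      cells[r, p, "converged"] <- as.numeric(isTRUE(fit$diagnostics$converged))
    }
  }
  rows <- lapply(seq_along(priors), function(p) {
    med <- cells[, p, "med_delta"]
    cov <- cells[, p, "covered"]
    mtau <- cells[, p, "med_tau"]
    conv <- cells[, p, "converged"]
    ok <- !is.na(med)
    if (drop_nonconverged) ok <- ok & conv == 1
    n <- sum(ok)
    sqerr <- (med[ok] - scenario$delta)^2
    data.frame(
      k = scenario$k, n_low = scenario$n_low, n_high = scenario$n_high,
      pi_c = scenario$pi_c, tau = scenario$tau, delta = scenario$delta,
      prior = priors[p],
      avg_med_delta = mean(med[ok]),
      mcse_med_delta = stats::sd(med[ok]) / sqrt(n),
      coverage95 = mean(cov[ok]),
      mcse_coverage = sqrt(mean(cov[ok]) * (1 - mean(cov[ok])) / n),
      mse_delta = mean(sqerr),
      mcse_mse = stats::sd(sqerr) / sqrt(n),
      avg_med_tau = mean(mtau[ok]),
      mcse_med_tau = stats::sd(mtau[ok]) / sqrt(n),
      n_reps = n,
      n_converged = sum(conv[ok] == 1),
      n_failed = sum(is.na(med)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bnhm_performance", "data.frame")
  out
}

#' Long-format comparison table of performance results
#'
#' Reshapes one or more \code{\link{eval_priors}} results into tidy long
#' format: one row per scenario cell x prior x measure, with the value
#' and its MC-SE, ready for the scatter (average posterior median vs
#' coverage) and line (coverage or tau bias vs control event rate)
#' views.
#'
#' @param results a \code{"bnhm_performance"} data.frame or a list of
#'   them (rbind-ed first).
#' @return A data.frame with columns k, n_low, n_high, pi_c, tau, delta,
#'   prior, measure, value, mc_se; measures are avg_med_delta,
#'   coverage95, mse_delta, avg_med_tau.  Aggregates are carried over
#'   bit-exactly.
#' @export
comparison_table <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  measures <- c(avg_med_delta = "mcse_med_delta",
                coverage95 = "mcse_coverage",
                mse_delta = "mcse_mse",
                avg_med_tau = "mcse_med_tau")
  keys <- c("k", "n_low", "n_high", "pi_c", "tau", "delta", "prior")
  long <- lapply(names(measures), function(m) {
    cbind(results[keys],
          data.frame(measure = m, value = results[[m]],
                     mc_se = results[[measures[m]]],
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, long)
  out <- out[order(out$pi_c, out$prior, out$measure, out$k), ]
  rownames(out) <- NULL
  out
}
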