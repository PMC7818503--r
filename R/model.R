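#' Fit the binomial-normal hierarchical meta-analysis model
#'
#' Arm-level Bayesian random-effects model for two-arm trials with a
#' binary outcome.  Events in arm j of trial i follow
#' \eqn{r_{ij} \sim Binomial(\pi_{ij}, n_{ij})} with
#' \eqn{logit(\pi_{iT}) = \mu_i + 0.5\,\delta_i} and
#' \eqn{logit(\pi_{iC}) = \mu_i - 0.5\,\delta_i}; the trial-specific log
#' odds ratios are exchangeable, \eqn{\delta_i \sim N(\delta, \tau^2)}.
#' The overall effect has a weakly diffuse prior
#' \eqn{\delta \sim N(0, 100)}, the baselines
#' \eqn{\mu_i \sim N(\mu_0, 100)} with a vague \eqn{N(0, 10^6)}
#' hyperprior on \eqn{\mu_0}, and the between-study SD \eqn{\tau} gets
#' one of the \code{\link{tau_prior}} specifications.  Because the
#' likelihood is binomial, zero-event arms and double-zero trials enter
#' the model as-is, with no continuity correction.
#'
#' Sampling is adaptive Metropolis-within-Gibbs: \eqn{\delta} and
#' \eqn{\mu_0} have conjugate normal updates, each \eqn{\mu_i} and
#' \eqn{\delta_i} a random-walk Metropolis update, and \eqn{\tau} a
#' random-walk update on an unconstrained transform of the prior's
#' native scale (log precision, logit of a bounded uniform, log tau,
#' logit of the shrinkage ratio), with the reparameterization Jacobian
#' in the target.  Proposal scales adapt toward 44% acceptance during
#' burn-in only, preserving detailed balance afterwards.
#'
#' @param data a \code{\link{meta_dataset}}.
#' @param prior a \code{\link{tau_prior}}, or a prior id string
#'   understood by \code{tau_prior()} (for the empirical priors E/e the
#'   scale s0 is then computed from \code{data} with the default 0.5
#'   correction).
#' @param chains number of parallel chains (>= 2 for diagnostics).
#' @param iter iterations per chain, including burn-in.
#' @param burnin iterations discarded per chain (must be < iter).
#' @param thin thinning interval for retained draws.
#' @param seed integer seed; the fit is bit-reproducible given the seed.
#' @param delta_prior_var prior variance of the overall effect delta.
#' @param mu_prior_var prior variance of the baselines mu_i around mu_0.
#' @param mu0_prior_var hyperprior variance of mu_0.
#' @param include_likelihood if \code{FALSE} the binomial likelihood is
#'   switched off and the sampler targets the joint prior (a validation
#'   mode: posterior tau quantiles must then reproduce the prior's).
#'
#' @return An object of class \code{"bnhm_fit"}: list with \code{draws}
#'   (one matrix per chain; columns \code{delta}, \code{tau},
#'   \code{mu0}, \code{mu[label]}, \code{d[label]}), the inputs, and
#'   \code{diagnostics} (split-Rhat and bulk ESS for delta and tau, plus
#'   a \code{converged} flag: Rhat <= 1.05 and ESS >= 400 on both).  A
#'   warning is raised, and the flag set, when those thresholds fail;
#'   the result is still returned.
#' @examples
#' fit <- bnhm(mmn_trials(), "AU", iter = 4000, burnin = 1000, seed = 1)
#' summary(fit)
#' @seealso \code{\link{posterior_summary}}, \code{\link{prob_direction}}
#' @export
bnhm <- function(data, prior, chains = 3, iter = 30000, burnin = 4500,
                 thin = 3, seed = 1,
                 delta_prior_var = 100, mu_prior_var = 100,
                 mu0_prior_var = 1e6, include_likelihood = TRUE) {
  stopifnot(inherits(data, "meta_dataset"))
  if (is.character(prior)) {
    s0 <- if (prior %in% c("E", "e")) compute_s0(data) else NULL
    prior <- tau_prior(prior, s0 = s0)
  }
  stopifnot(inherits(prior, "tau_prior"))
  if (!(chains >= 1 && iter > burnin && burnin >= 0 && thin >= 1)) {
    stop("invalid MCMC configuration: need chains >= 1, burnin < iter, thin >= 1")
  }
  if (any(c(delta_prior_var, mu_prior_var, mu0_prior_var) <= 0)) {
    stop("prior variances must be positive")
  }
  k <- nrow(data)
  plan <- prior_plan(prior)

  # initialization: baselines at pooled corrected empirical logits,
  # effects at zero, tau at the prior median capped to [0.01, 5]
  mu_init <- stats::qlogis((data$r_t + data$r_c + 0.5) /
                             (data$n_t + data$n_c + 1))
  d_init <- rep(0, k)
  tau_init <- if (plan[1] == 99) plan[2] else {
    min(max(prior_quantile(prior, 0.5), 0.01), 5)
  }
  x_tau0 <- tau_to_x(plan, tau_init)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, chains)
  par_names <- c("delta", "tau", "mu0",
                 paste0("mu[", data$label, "]"),
                 paste0("d[", data$label, "]"))
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    res <- bnhm_chain(data$r_t, data$n_t, data$r_c, data$n_c,
                      as.integer(plan[1]), plan[2], plan[3],
                      delta_prior_var, mu_prior_var, mu0_prior_var,
                      as.integer(iter), as.integer(burnin), as.integer(thin),
                      0, mean(mu_init), x_tau0,
                      mu_init, d_init, include_likelihood)
    colnames(res$draws) <- par_names
    draws[[ch]] <- res$draws
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  fit <- structure(
    list(draws = draws, data = data, prior = prior,
         config = list(chains = chains, iter = iter, burnin = burnin,
                       thin = thin, seed = seed,
                       delta_prior_var = delta_prior_var,
                       mu_prior_var = mu_prior_var,
                       mu0_prior_var = mu0_prior_var,
                       include_likelihood = include_likelihood)),
    class = "bnhm_fit")
  fit$diagnostics <- fit_diagnostics(fit)
  fit
}

# map tau to the unconstrained sampling coordinate of a prior plan
tau_to_x <- function(plan, tau) {
  type <- plan[1]; p1 <- plan[2]; p2 <- plan[3]
  clamp01 <- function(u) min(max(u, 1e-6), 1 - 1e-6)
  switch(as.character(type),
    "1" = log(tau^-2),
    "2" = stats::qlogis(clamp01((log(tau^2) - p1) / (p2 - p1))),
    "3" = stats::qlogis(clamp01((tau^2 - p1) / (p2 - p1))),
    "4" = stats::qlogis(clamp01((tau - p1) / (p2 - p1))),
    "5" = log(tau),
    "6" = log(tau^2),
    "7" = stats::qlogis(clamp01(p1 / (p1 + tau))),
    "99" = 0,
    stop("unknown prior plan type"))
}

#' Extract posterior draws of one parameter
#'
#' @param fit a \code{\link{bnhm}} fit.
#' @param parameter column name, e.g. \code{"delta"} or \code{"tau"}.
#' @param by_chain if \code{TRUE}, a list of per-chain vectors; else the
#'   pooled vector across chains.
#' @return Numeric vector or list of vectors.
#' @export
posterior_draws <- function(fit, parameter = "delta", by_chain = FALSE) {
  stopifnot(inherits(fit, "bnhm_fit"))
  if (!parameter %in% colnames(fit$draws[[1]])) {
    stop("unknown parameter '", parameter, "'")
  }
  per <- lapply(fit$draws, function(m) m[, parameter])
  if (by_chain) per else unlist(per, use.names = FALSE)
}

#' Posterior summaries of a fitted model
#'
#' Posterior medians, equal-tailed 95% credible intervals (2.5% and
#' 97.5% quantiles) and Monte-Carlo standard errors for every monitored
#' parameter, plus the posterior tail probabilities P(delta > 0) and
#' P(delta < 0).
#'
#' The MC-SE of the posterior mean is sd/sqrt(ESS); for the median the
#' normal-approximation inflation sqrt(pi/2) is applied.
#'
#' @param fit a \code{\link{bnhm}} fit.
#' @return A list with \code{table} (data.frame: parameter, median,
#'   q025, q975, mean, sd, ess, mcse_median), \code{p_delta_gt0},
#'   \code{p_delta_lt0}, and \code{n_draws}.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "bnhm_fit"))
  pars <- colnames(fit$draws[[1]])
  rows <- lapply(pars, function(p) {
    per <- lapply(fit$draws, function(m) m[, p])
    x <- unlist(per, use.names = FALSE)
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    es <- tryCatch(ess_bulk(per), error = function(e) NA_real_)
    data.frame(parameter = p, median = q[2], q025 = q[1], q975 = q[3],
               mean = mean(x), sd = stats::sd(x), ess = es,
               mcse_median = sqrt(pi / 2) * stats::sd(x) / sqrt(max(es, 1)),
               stringsAsFactors = FALSE)
  })
  delta <- posterior_draws(fit, "delta")
  list(table = do.call(rbind, rows),
       p_delta_gt0 = mean(delta > 0),
       p_delta_lt0 = mean(delta < 0),
       n_draws = length(delta))
}

#' @export
summary.bnhm_fit <- function(object, ...) {
  s <- posterior_summary(object)
  structure(list(summary = s, prior = object$prior,
                 diagnostics = object$diagnostics),
            class = "summary.bnhm_fit")
}

#' @export
print.summary.bnhm_fit <- function(x, digits = 3, ...) {
  cat("Binomial-normal hierarchical model, heterogeneity prior '",
      x$prior$id, "'\n", sep = "")
  tab <- x$summary$table
  main <- tab[tab$parameter %in% c("delta", "tau"), , drop = FALSE]
  print(format(main, digits = digits), row.names = FALSE)
  cat(sprintf("P(delta > 0) = %.3f, P(delta < 0) = %.3f (%d draws)\n",
              x$summary$p_delta_gt0, x$summary$p_delta_lt0,
              x$summary$n_draws))
  d <- x$diagnostics
  cat(sprintf("split-Rhat: delta %.3f, tau %.3f; bulk ESS: delta %.0f, tau %.0f%s\n",
              d$rhat["delta"], d$rhat["tau"], d$ess["delta"], d$ess["tau"],
              if (d$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
print.bnhm_fit <- function(x, ...) {
  print(summary(x), ...)
  invisible(x)
}

#' Posterior probability of the beneficial direction
#'
#' The posterior mass of delta on the side of zero containing the
#' posterior median, i.e. the probability that the effect points in its
#' apparent direction.  For an outcome where events are harms (e.g.
#' treatment discontinuation) the beneficial side is delta < 0; the
#' convention used here needs no such knowledge because the median
#' carries the sign.
#'
#' @param fit a \code{\link{bnhm}} fit.
#' @return A scalar probability in \[0, 1\].
#' @export
prob_direction <- function(fit) {
  delta <- posterior_draws(fit, "delta")
  if (stats::median(delta) >= 0) mean(delta > 0) else mean(delta < 0)
}

#' Unnormalized log joint density of the model
#'
#' Evaluates the sum of the binomial log-likelihoods, the random-effects
#' normal terms, the priors on delta and mu_i, the mu_0 hyperprior, and
#' the heterogeneity prior's tau-scale log density (Jacobian included,
#' see \code{\link{prior_density}}).  Exposed mainly so the posterior
#' can be checked against brute-force quadrature on tiny problems.
#'
#' @inheritParams bnhm
#' @param state list with elements \code{delta}, \code{tau} (> 0),
#'   \code{mu0}, \code{mu} (length-k), \code{d} (length-k).
#' @return A scalar log density; \code{-Inf} for states outside the
#'   support, error for non-finite states.
#' @export
bnhm_log_joint <- function(data, prior, state,
                           delta_prior_var = 100, mu_prior_var = 100,
                           mu0_prior_var = 1e6, include_likelihood = TRUE) {
  stopifnot(inherits(data, "meta_dataset"), inherits(prior, "tau_prior"))
  need <- c("delta", "tau", "mu0", "mu", "d")
  if (!all(need %in% names(state))) {
    stop("state needs elements ", paste(need, collapse = ", "))
  }
  vals <- unlist(state[need], use.names = FALSE)
  if (any(!is.finite(vals))) stop("state contains non-finite values")
  if (state$tau <= 0) stop("tau must be positive")
  k <- nrow(data)
  stopifnot(length(state$mu) == k, length(state$d) == k)

  lp <- stats::dnorm(state$delta, 0, sqrt(delta_prior_var), log = TRUE) +
    stats::dnorm(state$mu0, 0, sqrt(mu0_prior_var), log = TRUE) +
    sum(stats::dnorm(state$mu, state$mu0, sqrt(mu_prior_var), log = TRUE)) +
    sum(stats::dnorm(state$d, state$delta, state$tau, log = TRUE)) +
    (if (prior$family == "fixed") 0 else prior_density(prior, state$tau, log = TRUE))
  if (include_likelihood) {
    eta_t <- state$mu + 0.5 * state$d
    eta_c <- state$mu - 0.5 * state$d
    lp <- lp +
      sum(stats::dbinom(data$r_t, data$n_t, stats::plogis(eta_t), log = TRUE)) +
      sum(stats::dbinom(data$r_c, data$n_c, stats::plogis(eta_c), log = TRUE))
  }
  lp
}

#' Per-prior sensitivity analysis of a dataset
#'
#' Fits the model once per heterogeneity prior and collects the
#' posterior median and equal-tailed 95% CrI of delta and tau, plus the
#' beneficial-direction probability: the forest-style table used to
#' display how inference moves with the prior.
#'
#' @inheritParams bnhm
#' @param priors character vector of prior ids (default: all twelve;
#'   E and e use s0 computed from \code{data}).
#' @param ... further arguments passed to \code{\link{bnhm}}.
#' @return A data.frame with one row per prior: id, delta_median,
#'   delta_q025, delta_q975, tau_median, tau_q025, tau_q975,
#'   p_direction, rhat_delta, ess_delta, converged.
#' @examples
#' \donttest{
#' prior_sensitivity(mmn_trials(), priors = c("AU", "dn"),
#'                   iter = 6000, burnin = 1500, seed = 1)
#' }
#' @export
prior_sensitivity <- function(data, priors = tau_prior_ids(), seed = 1, ...) {
  rows <- lapply(seq_along(priors), function(j) {
    fit <- bnhm(data, priors[j], seed = seed + j - 1, ...)
    s <- posterior_summary(fit)
    tab <- s$table
    dl <- tab[tab$parameter == "delta", ]
    ta <- tab[tab$parameter == "tau", ]
    data.frame(prior = priors[j],
               delta_median = dl$median, delta_q025 = dl$q025,
               delta_q975 = dl$q975,
               tau_median = ta$median, tau_q025 = ta$q025,
               tau_q975 = ta$q975,
               p_direction = prob_direction(fit),
               rhat_delta = fit$diagnostics$rhat["delta"],
               ess_delta = fit$diagnostics$ess["delta"],
               converged = fit$diagnostics$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
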