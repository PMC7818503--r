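#' MCMC convergence diagnostics
#'
#' Split-chain potential scale reduction factor (split-Rhat) and bulk
#' effective sample size for a set of parallel chains, following the
#' standard multi-chain variance-ratio and autocorrelation-sum
#' estimators.  Each chain is split in half, so a single long chain that
#' drifts is also detected.
#'
#' @param chains list of numeric vectors, one per chain, equal length.
#' @return \code{split_rhat}: the scalar Rhat (\code{NA} with a warning
#'   when the chains are degenerate, e.g. constant); values close to 1
#'   indicate convergence.
#' @name diagnostics
NULL

split_halves <- function(chains) {
  n <- min(lengths(chains))
  n <- n - n %% 2L
  if (n < 4L) stop("chains too short to split")
  out <- list()
  for (ch in chains) {
    out[[length(out) + 1L]] <- ch[seq_len(n / 2)]
    out[[length(out) + 1L]] <- ch[(n / 2 + 1L):n]
  }
  out
}

#' @rdname diagnostics
#' @export
split_rhat <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("diagnostics need at least 2 chains")
  }
  sp <- split_halves(chains)
  m <- length(sp)
  n <- length(sp[[1L]])
  means <- vapply(sp, mean, 0)
  vars <- vapply(sp, stats::var, 0)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (!is.finite(w) || w <= 0) {
    warning("within-chain variance is zero; Rhat undefined")
    return(NA_real_)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' @rdname diagnostics
#' @export
ess_bulk <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("diagnostics need at least 2 chains")
  }
  sp <- split_halves(chains)
  m <- length(sp)
  n <- length(sp[[1L]])
  vars <- vapply(sp, stats::var, 0)
  w <- mean(vars)
  b <- n * stats::var(vapply(sp, mean, 0))
  var_plus <- (n - 1) / n * w + b / n
  if (!is.finite(var_plus) || var_plus <= 0) {
    warning("zero variance; ESS undefined")
    return(NA_real_)
  }
  lag_max <- min(n - 2L, 1000L)
  # chain-averaged autocovariances (acf divisor n, matching var_plus scale)
  acov <- sapply(sp, function(x) {
    stats::acf(x, lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acov) * n / (n - 1)
  rho <- 1 - (w - mean_acov[-1L]) / var_plus
  # Geyer initial monotone positive sequence on paired sums
  n_pairs <- floor(length(rho) / 2)
  tau_int <- 1
  prev <- Inf
  for (p in seq_len(n_pairs)) {
    g <- rho[2 * p - 1] + rho[2 * p]
    if (!is.finite(g) || g <= 0) break
    g <- min(g, prev)
    prev <- g
    tau_int <- tau_int + 2 * g
  }
  min(m * n / tau_int, m * n)
}

#' Lag autocorrelation of pooled chains
#'
#' @param chains list of per-chain draw vectors.
#' @param lag.max maximum lag.
#' @return Numeric vector of chain-averaged autocorrelations at lags
#'   1..lag.max.
#' @export
chain_autocorrelation <- function(chains, lag.max = 50) {
  ac <- vapply(chains, function(x) {
    stats::acf(x, lag.max = lag.max, plot = FALSE)$acf[-1, 1, 1]
  }, numeric(lag.max))
  if (lag.max == 1L) mean(ac) else rowMeans(ac)
}

# diagnostics attached to a bnhm_fit: Rhat/ESS for delta and tau (and a
# convergence flag with the thresholds Rhat <= 1.05, ESS >= 400)
fit_diagnostics <- function(fit) {
  monitored <- c("delta", "tau")
  if (fit$config$chains < 2L) {
    return(list(rhat = stats::setNames(rep(NA_real_, 2), monitored),
                ess = stats::setNames(rep(NA_real_, 2), monitored),
                converged = NA))
  }
  rhat <- vapply(monitored, function(p) {
    tryCatch(suppressWarnings(split_rhat(posterior_draws(fit, p, by_chain = TRUE))),
             error = function(e) NA_real_)
  }, 0)
  ess <- vapply(monitored, function(p) {
    tryCatch(suppressWarnings(ess_bulk(posterior_draws(fit, p, by_chain = TRUE))),
             error = function(e) NA_real_)
  }, 0)
  # a fixed-tau run has zero tau variance by construction; judge delta only
  if (fit$prior$family == "fixed") {
    rhat["tau"] <- NA_real_
    ess["tau"] <- NA_real_
  }
  usable <- !is.na(rhat) & !is.na(ess)
  converged <- all(rhat[usable] <= 1.05) && all(ess[usable] >= 400) &&
    any(usable)
  if (!isTRUE(converged)) {
    warning("MCMC may not have converged (split-Rhat > 1.05 or bulk ESS < 400 ",
            "on delta/tau); result returned with converged = FALSE")
  }
  list(rhat = rhat, ess = ess, converged = converged)
}

#' Convergence diagnostics of a fitted model
#'
#' @param fit a \code{\link{bnhm}} fit with at least two chains.
#' @param parameters which parameters to diagnose (default: all).
#' @return A data.frame: parameter, split_rhat, ess_bulk.
#' @export
bnhm_diagnostics <- function(fit, parameters = colnames(fit$draws[[1]])) {
  stopifnot(inherits(fit, "bnhm_fit"))
  if (fit$config$chains < 2L) {
    stop("diagnostics need at least 2 chains")
  }
  rows <- lapply(parameters, function(p) {
    per <- posterior_draws(fit, p, by_chain = TRUE)
    data.frame(parameter = p,
               split_rhat = suppressWarnings(split_rhat(per)),
               ess_bulk = suppressWarnings(ess_bulk(per)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
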