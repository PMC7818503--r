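#' Between-study heterogeneity priors
#'
#' Constructs one of the twelve heterogeneity prior specifications used
#' throughout the package.  Each prior is stated for a transform g(tau)
#' of the between-study standard deviation tau (logOR units): the
#' precision 1/tau^2, log(tau^2), tau^2, tau itself, or the DuMouchel
#' shrinkage ratio s0/(s0 + tau).  Upper-case ids are the less
#' restrictive member of each pair, lower-case the more restrictive one.
#'
#' \describe{
#'   \item{AG, ag}{Gamma(0.001, 0.001) / Gamma(0.1, 0.1) on the precision
#'     1/tau^2 (shape/rate parameterization).}
#'   \item{AU, du}{Uniform(-10, 10) / Uniform(-10, 1.386) on log(tau^2).}
#'   \item{B, b}{Uniform(0, 1000) / Uniform(0, 4) on tau^2.}
#'   \item{C, c}{Uniform(0, 100) / Uniform(0, 2) on tau.}
#'   \item{DN, dn}{Half-normal(0, 100) / Half-normal(0, 1) on tau.  The
#'     second argument is the variance, so DN has SD 10 on the tau scale.}
#'   \item{E}{DuMouchel prior: the shrinkage ratio s0/(s0 + tau) is
#'     Uniform(0, 1), with s0 the square root of the harmonic mean of the
#'     within-study variances (\code{\link{compute_s0}}).}
#'   \item{e}{Half-normal on tau^2 with variance qnorm(0.75)/s0.}
#' }
#'
#' A thirteenth id, \code{"fixed"}, pins tau at a known value; it is not
#' part of the registry but supports exact quadrature checks of the
#' sampler.
#'
#' @param id prior identifier, one of \code{tau_prior_ids()} or
#'   \code{"fixed"}.
#' @param s0 positive scale (logOR units) required for the empirical
#'   priors \code{E} and \code{e}; typically \code{compute_s0(data)}.
#' @param tau0 fixed positive tau, required iff \code{id = "fixed"}.
#'
#' @return An object of class \code{"tau_prior"}: a list with elements
#'   \code{id}, \code{scale}, \code{family}, \code{params},
#'   \code{restrictive} and (for E/e) \code{s0}.
#' @examples
#' tau_prior("AU")
#' tau_prior("E", s0 = compute_s0(gbs_trials()))
#' @export
tau_prior <- function(id, s0 = NULL, tau0 = NULL) {
  registry <- list(
    AG = list(scale = "precision", family = "gamma",
              params = c(shape = 0.001, rate = 0.001), restrictive = "less"),
    ag = list(scale = "precision", family = "gamma",
              params = c(shape = 0.1, rate = 0.1), restrictive = "more"),
    AU = list(scale = "log_tau2", family = "uniform",
              params = c(lower = -10, upper = 10), restrictive = "less"),
    du = list(scale = "log_tau2", family = "uniform",
              params = c(lower = -10, upper = 1.386), restrictive = "more"),
    B  = list(scale = "tau2", family = "uniform",
              params = c(lower = 0, upper = 1000), restrictive = "less"),
    b  = list(scale = "tau2", family = "uniform",
              params = c(lower = 0, upper = 4), restrictive = "more"),
    C  = list(scale = "tau", family = "uniform",
              params = c(lower = 0, upper = 100), restrictive = "less"),
    c  = list(scale = "tau", family = "uniform",
              params = c(lower = 0, upper = 2), restrictive = "more"),
    DN = list(scale = "tau", family = "half_normal",
              params = c(variance = 100), restrictive = "less"),
    dn = list(scale = "tau", family = "half_normal",
              params = c(variance = 1), restrictive = "more"),
    E  = list(scale = "shrinkage", family = "dumouchel",
              params = numeric(0), restrictive = "empirical"),
    e  = list(scale = "tau2", family = "half_normal",
              params = numeric(0), restrictive = "empirical")
  )
  if (identical(id, "fixed")) {
    if (is.null(tau0) || !is.finite(tau0) || tau0 <= 0) {
      stop("prior 'fixed' requires a positive tau0")
    }
    p <- list(id = "fixed", scale = "tau", family = "fixed",
              params = c(tau0 = tau0), restrictive = "degenerate")
    class(p) <- "tau_prior"
    return(p)
  }
  if (!is.character(id) || length(id) != 1L || !id %in% names(registry)) {
    stop("unknown heterogeneity prior id '", paste(id, collapse = ","),
         "'; see tau_prior_ids()")
  }
  p <- registry[[id]]
  p$id <- id
  if (id %in% c("E", "e")) {
    if (is.null(s0) || !is.finite(s0) || s0 <= 0) {
      stop("empirical prior '", id,
           "' requires a positive s0 (see compute_s0())")
    }
    p$s0 <- s0
    if (id == "e") p$params <- c(variance = stats::qnorm(0.75) / s0)
    if (id == "E") p$params <- c(s0 = s0)
  }
  class(p) <- "tau_prior"
  p
}

#' @export
print.tau_prior <- function(x, ...) {
  cat("Heterogeneity prior '", x$id, "': ", x$family, " on ", x$scale,
      " (", paste(names(x$params), signif(unlist(x$params), 5),
                  sep = "=", collapse = ", "),
      "), ", x$restrictive, " restrictive\n", sep = "")
  invisible(x)
}

#' The twelve registry prior identifiers
#'
#' @return Character vector of ids in registry order.
#' @export
tau_prior_ids <- function() {
  c("AG", "ag", "AU", "du", "B", "b", "C", "c", "DN", "dn", "E", "e")
}

#' Empirical prior scale s0
#'
#' The square root of the harmonic mean of the within-study variances,
#' \eqn{s_0 = \sqrt{k / \sum s_i^{-2}}}, so that s0 shares units with tau
#' and the DuMouchel shrinkage ratio s0/(s0 + tau) is dimensionless.
#'
#' @inheritParams within_variances
#' @return A positive scalar (logOR units).
#' @examples
#' compute_s0(gbs_trials())
#' @export
compute_s0 <- function(data, correction = 0.5) {
  s2 <- within_variances(data, correction = correction)
  sqrt(length(s2) / sum(1 / s2))
}

# Half-normal with variance parameter v: density of |Z|, Z ~ N(0, v).
dhalfnorm <- function(x, v, log = FALSE) {
  out <- ifelse(x >= 0, log(2) + stats::dnorm(x, 0, sqrt(v), log = TRUE), -Inf)
  if (log) out else exp(out)
}
phalfnorm <- function(q, v) ifelse(q <= 0, 0, 2 * stats::pnorm(q / sqrt(v)) - 1)
qhalfnorm <- function(p, v) sqrt(v) * stats::qnorm((1 + p) / 2)

#' Prior density on the tau scale
#'
#' Pushes the stated distribution on g(tau) forward to the tau scale,
#' including the Jacobian of the transform, so densities of all priors
#' are directly comparable.
#'
#' @param prior a \code{\link{tau_prior}}.
#' @param tau positive numeric vector of evaluation points.
#' @param log return the log density?
#' @return Numeric vector of (log) density values; points outside the
#'   support get density 0 (log density \code{-Inf}).
#' @export
prior_density <- function(prior, tau, log = FALSE) {
  stopifnot(inherits(prior, "tau_prior"))
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("prior_density is defined for finite tau > 0")
  }
  p <- prior$params
  ld <- switch(
    paste(prior$family, prior$scale, sep = "."),
    gamma.precision =
      stats::dgamma(tau^-2, shape = p["shape"], rate = p["rate"], log = TRUE) +
        log(2) - 3 * log(tau),
    uniform.log_tau2 = ifelse(
      log(tau^2) > p["lower"] & log(tau^2) < p["upper"],
      -log(p["upper"] - p["lower"]) + log(2) - log(tau), -Inf),
    uniform.tau2 = ifelse(
      tau^2 < p["upper"] & tau^2 > p["lower"],
      -log(p["upper"] - p["lower"]) + log(2) + log(tau), -Inf),
    uniform.tau = ifelse(
      tau < p["upper"] & tau > p["lower"],
      -log(p["upper"] - p["lower"]), -Inf),
    half_normal.tau = dhalfnorm(tau, p["variance"], log = TRUE),
    half_normal.tau2 =
      dhalfnorm(tau^2, p["variance"], log = TRUE) + log(2) + log(tau),
    dumouchel.shrinkage = log(prior$s0) - 2 * log(prior$s0 + tau),
    stop("no density for prior family '", prior$family, "'")
  )
  ld <- unname(ld)
  if (log) ld else exp(ld)
}

#' Prior CDF on the tau scale
#'
#' @inheritParams prior_density
#' @param q positive numeric vector of tau values.
#' @return P(tau <= q) under the prior.
#' @export
prior_cdf <- function(prior, q) {
  stopifnot(inherits(prior, "tau_prior"))
  p <- prior$params
  out <- switch(
    paste(prior$family, prior$scale, sep = "."),
    gamma.precision =
      stats::pgamma(q^-2, shape = p["shape"], rate = p["rate"],
                    lower.tail = FALSE),
    uniform.log_tau2 =
      stats::punif(log(q^2), min = p["lower"], max = p["upper"]),
    uniform.tau2 = stats::punif(q^2, min = p["lower"], max = p["upper"]),
    uniform.tau = stats::punif(q, min = p["lower"], max = p["upper"]),
    half_normal.tau = phalfnorm(q, p["variance"]),
    half_normal.tau2 = phalfnorm(q^2, p["variance"]),
    dumouchel.shrinkage = q / (prior$s0 + q),
    stop("no CDF for prior family '", prior$family, "'")
  )
  unname(out)
}

#' Prior quantiles on the tau scale
#'
#' Closed-form inverse of \code{\link{prior_cdf}} for every family: the
#' uniform families invert the transform of the uniform quantile, the
#' half-normal priors use the folded-normal quantile, the gamma priors
#' the inverse incomplete gamma, and the DuMouchel prior
#' \eqn{\tau_p = s_0 p / (1 - p)}.
#'
#' @inheritParams prior_density
#' @param p probabilities in (0, 1).
#' @return Numeric vector of tau quantiles (>= 0; may be \code{Inf} for
#'   heavy-tailed priors at extreme p).
#' @examples
#' prior_quantile(tau_prior("dn"), c(0.025, 0.5, 0.975))
#' @export
prior_quantile <- function(prior, p) {
  stopifnot(inherits(prior, "tau_prior"))
  if (any(p <= 0) || any(p >= 1)) stop("probabilities must lie in (0, 1)")
  pp <- prior$params
  out <- switch(
    paste(prior$family, prior$scale, sep = "."),
    gamma.precision =
      stats::qgamma(1 - p, shape = pp["shape"], rate = pp["rate"])^-0.5,
    uniform.log_tau2 =
      exp(0.5 * stats::qunif(p, min = pp["lower"], max = pp["upper"])),
    uniform.tau2 =
      sqrt(stats::qunif(p, min = pp["lower"], max = pp["upper"])),
    uniform.tau = stats::qunif(p, min = pp["lower"], max = pp["upper"]),
    half_normal.tau = qhalfnorm(p, pp["variance"]),
    half_normal.tau2 = sqrt(qhalfnorm(p, pp["variance"])),
    dumouchel.shrinkage = prior$s0 * p / (1 - p),
    stop("no quantile function for prior family '", prior$family, "'")
  )
  unname(out)
}

#' Draw tau values from a heterogeneity prior
#'
#' Samples on the prior's native scale (the scale on which the
#' distribution is stated) and transforms to tau, so no clipping or
#' approximation enters.
#'
#' @inheritParams prior_density
#' @param n number of draws.
#' @return Numeric vector of n non-negative tau draws.
#' @export
prior_sample <- function(prior, n) {
  stopifnot(inherits(prior, "tau_prior"), n >= 1)
  p <- prior$params
  out <- switch(
    paste(prior$family, prior$scale, sep = "."),
    gamma.precision =
      stats::rgamma(n, shape = p["shape"], rate = p["rate"])^-0.5,
    uniform.log_tau2 =
      exp(0.5 * stats::runif(n, min = p["lower"], max = p["upper"])),
    uniform.tau2 = sqrt(stats::runif(n, min = p["lower"], max = p["upper"])),
    uniform.tau = stats::runif(n, min = p["lower"], max = p["upper"]),
    half_normal.tau = abs(stats::rnorm(n, 0, sqrt(p["variance"]))),
    half_normal.tau2 = sqrt(abs(stats::rnorm(n, 0, sqrt(p["variance"])))),
    dumouchel.shrinkage = {
      u <- stats::runif(n)
      prior$s0 * (1 - u) / u
    },
    stop("no sampler for prior family '", prior$family, "'")
  )
  unname(out)
}

#' Summary table of the heterogeneity prior registry
#'
#' Computes the tau-scale median and equal-tailed 95% range of every
#' registry prior; the empirical priors E and e are included only when
#' an s0 is supplied.
#'
#' @param s0 optional positive scale for the empirical priors.
#' @param ids subset of prior ids (default: the full registry).
#' @return A data frame with one row per prior: id, scale, family,
#'   restrictiveness, tau_median, tau_q025, tau_q975.
#' @examples
#' prior_table(s0 = compute_s0(mmn_trials()))
#' @export
prior_table <- function(s0 = NULL, ids = tau_prior_ids()) {
  if (is.null(s0)) ids <- setdiff(ids, c("E", "e"))
  rows <- lapply(ids, function(id) {
    pr <- tau_prior(id, s0 = s0)
    q <- prior_quantile(pr, c(0.025, 0.5, 0.975))
    data.frame(id = id, scale = pr$scale, family = pr$family,
               restrictive = pr$restrictive,
               tau_median = q[2], tau_q025 = q[1], tau_q975 = q[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Internal: encode a prior for the C++ sampler as (type, p1, p2).
# Types: 1 gamma on precision, 2/3/4 uniform on log tau^2 / tau^2 / tau,
# 5 half-normal on tau, 6 half-normal on tau^2, 7 DuMouchel, 99 fixed.
prior_plan <- function(prior) {
  key <- paste(prior$family, prior$scale, sep = ".")
  p <- prior$params
  switch(key,
    gamma.precision    = c(1, p[["shape"]], p[["rate"]]),
    uniform.log_tau2   = c(2, p[["lower"]], p[["upper"]]),
    uniform.tau2       = c(3, p[["lower"]], p[["upper"]]),
    uniform.tau        = c(4, p[["lower"]], p[["upper"]]),
    half_normal.tau    = c(5, p[["variance"]], 0),
    half_normal.tau2   = c(6, p[["variance"]], 0),
    dumouchel.shrinkage = c(7, prior$s0, 0),
    fixed.tau          = c(99, p[["tau0"]], 0),
    stop("prior family '", key, "' not supported by the sampler")
  )
}
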