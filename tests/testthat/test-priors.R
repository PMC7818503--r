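all_priors <- function(s0 = 1) {
  stats::setNames(lapply(tau_prior_ids(), tau_prior, s0 = s0),
                  tau_prior_ids())
}

test_that("the registry constructs the stated specifications", {
  p <- tau_prior("dn")
  expect_equal(p$family, "half_normal")
  expect_equal(p$scale, "tau")
  expect_equal(unname(p$params["variance"]), 1)

  p <- tau_prior("AU")
  expect_equal(p$family, "uniform")
  expect_equal(p$scale, "log_tau2")
  expect_equal(unname(p$params), c(-10, 10))

  expect_equal(tau_prior("AG")$params, c(shape = 0.001, rate = 0.001))
  expect_equal(tau_prior("du")$params[["upper"]], 1.386)

  expect_error(tau_prior("E"), "s0")
  expect_error(tau_prior("e"), "s0")
  expect_error(tau_prior("XX"), "unknown")
  expect_error(tau_prior("fixed"), "tau0")
})

test_that("tau-scale densities integrate to their CDF mass", {
  # integral between far quantiles must match the CDF increment; for the
  # short-tailed priors that increment is itself 1 to near machine accuracy
  for (pr in all_priors()) {
    lo <- max(prior_quantile(pr, 1e-9), 1e-12)
    hi <- min(prior_quantile(pr, 1 - 1e-9), 1e100)
    expected <- prior_cdf(pr, hi) - prior_cdf(pr, lo)
    # integrate in log-tau space: the gamma-precision priors spread mass
    # over hundreds of orders of magnitude of tau
    got <- stats::integrate(function(y) prior_density(pr, exp(y)) * exp(y),
                            log(lo), log(hi), rel.tol = 1e-10,
                            subdivisions = 1000L)$value
    expect_equal(got, expected, tolerance = 1e-6,
                 label = paste0("integral[", pr$id, "]"))
    if (!pr$id %in% c("AG", "ag")) {
      expect_equal(expected, 1, tolerance = 1e-6,
                   label = paste0("mass[", pr$id, "]"))
    }
  }
})

test_that("densities vanish off-support and reject tau <= 0", {
  pc <- tau_prior("c")  # Uniform(0, 2) on tau
  expect_equal(prior_density(pc, 1), 0.5)
  expect_equal(prior_density(pc, 3), 0)
  expect_equal(prior_density(pc, 3, log = TRUE), -Inf)
  expect_error(prior_density(pc, 0), "tau > 0")
  expect_error(prior_density(pc, -1), "tau > 0")

  # push-forward of a flat density on log tau^2 is proportional to 1/tau
  pau <- tau_prior("AU")
  expect_equal(prior_density(pau, 2, log = TRUE) -
                 prior_density(pau, 1, log = TRUE),
               -log(2), tolerance = 1e-12)
})

test_that("quantile and CDF are mutually inverse on all priors", {
  ps <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  for (pr in all_priors()) {
    q <- prior_quantile(pr, ps)
    ok <- is.finite(q)  # AG's upper quantiles overflow double range
    expect_true(all(ok) || pr$id == "AG")
    expect_equal(prior_cdf(pr, q[ok]), ps[ok], tolerance = 1e-8,
                 label = paste0("roundtrip[", pr$id, "]"))
    expect_true(all(diff(q[ok]) >= 0))
  }
  expect_error(prior_quantile(tau_prior("dn"), 0), "in \\(0, 1\\)")
  expect_error(prior_quantile(tau_prior("dn"), 1), "in \\(0, 1\\)")
})

test_that("samplers agree with the quantile functions", {
  set.seed(1234)
  n <- 1e5
  for (pr in all_priors()) {
    x <- prior_sample(pr, n)
    for (p in c(0.25, 0.5, 0.75)) {
      q <- prior_quantile(pr, p)
      if (!is.finite(q)) next  # AG's upper quantiles exceed double range
      tol <- 3 * sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(x <= q) - p), tol,
                label = paste0("ecdf[", pr$id, ", p=", p, "]"))
    }
  }
  # bounded supports are respected
  expect_true(all(prior_sample(tau_prior("c"), 1e4) < 2))
  # DuMouchel median equals s0
  set.seed(99)
  expect_equal(median(prior_sample(tau_prior("E", s0 = 1), 1e6)), 1,
               tolerance = 2e-2)
})

test_that("s0 is the root harmonic mean of within-study variances", {
  d_eq <- meta_dataset(c("a", "b"), r_t = c(2, 2), n_t = c(4, 4),
                       r_c = c(2, 2), n_c = c(4, 4))
  # both trials have four cells of 2, so s_i^2 = 4 * (1/2) = 2 and the
  # harmonic mean equals the common value
  expect_equal(unname(within_variances(d_eq)), c(2, 2))
  expect_equal(compute_s0(d_eq), sqrt(2), tolerance = 1e-12)

  # hand example: variances {1, 4} -> sqrt(2 / 1.25)
  expect_equal(sqrt(2 / (1 / 1 + 1 / 4)), 1.2649111, tolerance = 1e-6)

  s0 <- compute_s0(gbs_trials())
  expect_true(is.finite(s0) && s0 > 0)
  expect_identical(s0, compute_s0(gbs_trials()))  # deterministic
})

test_that("empirical prior e uses the qnorm(0.75)/s0 variance", {
  pe <- tau_prior("e", s0 = 2)
  expect_equal(unname(pe$params["variance"]), qnorm(0.75) / 2)
})

test_that("the prior table reports the registry on the tau scale", {
  tab <- prior_table()
  expect_equal(nrow(tab), 10L)     # E/e need s0
  tab2 <- prior_table(s0 = 1.5)
  expect_equal(tab2$id, tau_prior_ids())
  expect_true(all(tab2$tau_q025 <= tab2$tau_median &
                    tab2$tau_median <= tab2$tau_q975))
})
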