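test_that("log joint is symmetric under arm relabelling", {
  d <- toy_two_trials()
  pr <- tau_prior("dn")
  state <- list(delta = 0.7, tau = 0.4, mu0 = -0.5,
                mu = c(-1, -0.2), d = c(0.5, 1.1))
  neg <- state
  neg$delta <- -state$delta
  neg$d <- -state$d
  expect_equal(bnhm_log_joint(swap_arms(d), pr, neg),
               bnhm_log_joint(d, pr, state), tolerance = 1e-12)
})

test_that("log joint matches an independent term-by-term evaluation", {
  d <- meta_dataset("z", r_t = 0, n_t = 5, r_c = 0, n_c = 5)
  pr <- tau_prior("fixed", tau0 = 0.5)
  st <- list(delta = 0, tau = 0.5, mu0 = 0, mu = -10, d = 0)
  # double-zero trial at mu = -10: likelihood ~ 10 * log(expit(10))
  lik <- 10 * log(plogis(10))
  manual <- lik + dnorm(0, 0, 10, log = TRUE) +
    dnorm(0, 0, 1000, log = TRUE) + dnorm(-10, 0, 10, log = TRUE) +
    dnorm(0, 0, 0.5, log = TRUE)
  expect_equal(bnhm_log_joint(d, pr, st), manual, tolerance = 1e-10)
  expect_gt(lik, -5e-4)  # near-certain non-events contribute almost nothing

  expect_error(bnhm_log_joint(d, pr, within(st, delta <- NaN)), "non-finite")
  expect_error(bnhm_log_joint(d, pr, within(st, tau <- -1)), "positive")
})

test_that("posterior of delta matches brute-force quadrature at k = 1, tau fixed", {
  d <- meta_dataset("t1", r_t = 3, n_t = 10, r_c = 1, n_c = 10)
  tau0 <- 0.5
  # integrate delta and mu0 analytically: d1 ~ N(0, 100 + tau^2) marginally,
  # mu1 ~ N(0, 100 + 1e6); then delta | d1 ~ N(c * d1, c * tau^2) with
  # c = 100 / (100 + tau^2)
  grid_d <- seq(-12, 12, length.out = 501)
  grid_m <- seq(-12, 12, length.out = 501)
  lp <- outer(grid_d, grid_m, function(d1, m1) {
    dbinom(3, 10, plogis(m1 + 0.5 * d1), log = TRUE) +
      dbinom(1, 10, plogis(m1 - 0.5 * d1), log = TRUE) +
      dnorm(d1, 0, sqrt(100 + tau0^2), log = TRUE) +
      dnorm(m1, 0, sqrt(100 + 1e6), log = TRUE)
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  e_d1 <- sum(w * grid_d)
  v_d1 <- sum(w * outer(grid_d, grid_m, function(a, b) a)^2) - e_d1^2
  cc <- 100 / (100 + tau0^2)
  oracle_mean <- cc * e_d1
  oracle_sd <- sqrt(cc^2 * v_d1 + cc * tau0^2)

  fit <- suppressWarnings(
    bnhm(d, tau_prior("fixed", tau0 = tau0), chains = 3,
         iter = 60000, burnin = 6000, thin = 3, seed = 31))
  delta <- posterior_draws(fit, "delta")
  ess <- fit$diagnostics$ess["delta"]
  mcse_mean <- sd(delta) / sqrt(ess)
  expect_lt(abs(mean(delta) - oracle_mean), 3 * mcse_mean)
  mcse_sd <- sd(delta) / sqrt(2 * ess)
  expect_lt(abs(sd(delta) - oracle_sd), 3 * mcse_sd)
})

test_that("with the likelihood switched off the sampler recovers each prior", {
  d <- toy_two_trials()
  for (id in c("AU", "dn", "b", "C", "E")) {
    pr <- tau_prior(id, s0 = 1.5)
    fit <- suppressWarnings(
      bnhm(d, pr, chains = 3, iter = 40000, burnin = 5000, thin = 2,
           seed = 17, include_likelihood = FALSE))
    tau <- posterior_draws(fit, "tau")
    ess <- max(suppressWarnings(
      ess_bulk(posterior_draws(fit, "tau", by_chain = TRUE))), 100)
    for (p in c(0.25, 0.5, 0.75)) {
      tol <- 3 * sqrt(p * (1 - p) / ess)
      expect_lt(abs(mean(tau <= prior_quantile(pr, p)) - p), tol,
                label = paste0("prior recovery [", id, ", p=", p, "]"))
    }
  }
})

test_that("swapping arms negates the posterior of delta", {
  d <- gbs_trials()
  f1 <- suppressWarnings(bnhm(d, "dn", chains = 3, iter = 30000,
                              burnin = 4500, thin = 3, seed = 5))
  f2 <- suppressWarnings(bnhm(swap_arms(d), "dn", chains = 3, iter = 30000,
                              burnin = 4500, thin = 3, seed = 6))
  s1 <- posterior_summary(f1)$table
  s2 <- posterior_summary(f2)$table
  m1 <- s1[s1$parameter == "delta", ]
  m2 <- s2[s2$parameter == "delta", ]
  tol <- 3 * (m1$mcse_median + m2$mcse_median)
  expect_lt(abs(m1$median + m2$median), tol)
})

test_that("fits are bit-reproducible given the seed", {
  d <- toy_two_trials()
  f1 <- fast_fit(d, "AU", seed = 123)
  f2 <- fast_fit(d, "AU", seed = 123)
  expect_identical(f1$draws, f2$draws)
  f3 <- fast_fit(d, "AU", seed = 124)
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("summaries expose medians, equal-tailed CrIs and tail probabilities", {
  x <- (1:1000) / 100
  fake <- structure(
    list(draws = list(matrix(x[1:500], ncol = 1,
                             dimnames = list(NULL, "delta")),
                      matrix(x[501:1000], ncol = 1,
                             dimnames = list(NULL, "delta"))),
         config = list(chains = 2)),
    class = "bnhm_fit")
  s <- posterior_summary(fake)
  tab <- s$table
  expect_equal(tab$median, 5.005)
  expect_equal(tab$q025, 0.26, tolerance = 0.015)
  expect_equal(tab$q975, 9.76, tolerance = 0.015)
  expect_true(tab$q025 <= tab$median && tab$median <= tab$q975)
  expect_equal(s$p_delta_gt0, 1)
  expect_equal(s$p_delta_lt0, 0)
  expect_lte(s$p_delta_gt0 + s$p_delta_lt0, 1)
})

test_that("fit validates its configuration", {
  d <- toy_two_trials()
  expect_error(bnhm(d, "AU", iter = 100, burnin = 200), "burnin < iter")
  expect_error(bnhm(d, "AU", thin = 0), "thin >= 1")
  expect_error(bnhm(d, "AU", delta_prior_var = -1), "positive")
  expect_error(bnhm(d, "nope"), "unknown")
})

test_that("the sampler agrees with JAGS on a case study", {
  model <- "model {
    for (i in 1:k) {
      rT[i] ~ dbin(pT[i], nT[i]); rC[i] ~ dbin(pC[i], nC[i])
      logit(pT[i]) <- mu[i] + 0.5 * d[i]
      logit(pC[i]) <- mu[i] - 0.5 * d[i]
      d[i] ~ dnorm(delta, prec.tau)
      mu[i] ~ dnorm(mu0, 0.01)
    }
    delta ~ dnorm(0, 0.01)
    mu0 ~ dnorm(0, 1.0E-6)
    tau ~ dnorm(0, 1) T(0,)
    prec.tau <- 1 / (tau * tau)
  }"
  d <- mmn_trials()
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(rT = d$r_t, nT = d$n_t, rC = d$r_c, nC = d$n_c,
                k = nrow(d)),
    n.chains = 2, n.adapt = 2000, quiet = TRUE)
  update(jm, 5000)
  draws <- rjags::coda.samples(jm, "delta", n.iter = 60000, thin = 3)
  jags_med <- median(as.matrix(draws)[, "delta"])

  fit <- suppressWarnings(bnhm(d, "dn", chains = 3, iter = 60000,
                               burnin = 6000, thin = 3, seed = 8))
  s <- posterior_summary(fit)$table
  ours <- s[s$parameter == "delta", ]
  expect_lt(abs(ours$median - jags_med), 0.05 + 3 * ours$mcse_median)
})
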