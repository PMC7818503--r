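# small in-code fixtures and shared tolerances

toy_two_trials <- function() {
  meta_dataset(c("t1", "t2"), r_t = c(2, 3), n_t = c(10, 12),
               r_c = c(1, 4), n_c = c(10, 11))
}

swap_arms <- function(data) {
  meta_dataset(data$label, r_t = data$r_c, n_t = data$n_c,
               r_c = data$r_t, n_c = data$n_t)
}

# fast MCMC settings for structural tests (not for numerical accuracy)
fast_fit <- function(data, prior, seed = 1, ...) {
  suppressWarnings(bnhm(data, prior, chains = 2, iter = 3000,
                        burnin = 1000, thin = 2, seed = seed, ...))
}
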