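# Movement HMM: likelihood, fitting, decoding, labeling

two_state_params <- function() {
  hmm_params(step_mean = c(0.2, 3), step_sd = c(0.1, 1),
             step_zero_mass = c(0.2, 0),
             angle_shape = c(1, 2.5), angle_scale = c(1.5, 0.4),
             beta = matrix(c(-1.5, -2, 0.3, -0.1, 0.1, 0.2), nrow = 2),
             delta = c(0.6, 0.4))
}

test_that("forward log-likelihood at T = 1 equals the hand formula", {
  p <- two_state_params()
  obs <- data.frame(sqrt_step = 1.2, turn_angle = 0.5, solar_hour = 3)
  f <- oracle_emissions(obs, p)
  expect_equal(hmm_forward_loglik(obs, p), log(sum(p$delta * f[1, ])),
               tolerance = 1e-12)
})

test_that("forward log-likelihood equals exhaustive path enumeration", {
  p2 <- two_state_params()
  sim <- simulate_hmm_steps(p2, 5, seed = 8)
  ll <- hmm_forward_loglik(sim$obs, p2)
  expect_equal(ll, oracle_forward_loglik(sim$obs, p2), tolerance = 1e-10)
  # 4 states, T = 6, with a missing observation
  p4 <- default_hmm_params()
  sim4 <- simulate_hmm_steps(p4, 6, seed = 3)
  obs <- sim4$obs
  obs$sqrt_step[3] <- NA; obs$turn_angle[3] <- NA
  expect_equal(hmm_forward_loglik(obs, p4), oracle_forward_loglik(obs, p4),
               tolerance = 1e-10)
})

test_that("a missing observation is exact marginalisation (density 1)", {
  p <- two_state_params()
  sim <- simulate_hmm_steps(p, 6, seed = 12)
  obs <- sim$obs
  obs$sqrt_step[4] <- NA
  obs$turn_angle[4] <- NA
  # oracle computes the same likelihood with that emission term set to 1
  expect_equal(hmm_forward_loglik(obs, p), oracle_forward_loglik(obs, p),
               tolerance = 1e-10)
  # and the missing-term likelihood differs from the fully observed one
  expect_false(isTRUE(all.equal(hmm_forward_loglik(obs, p),
                                hmm_forward_loglik(sim$obs, p))))
})

test_that("non-finite parameters are rejected", {
  p <- two_state_params()
  p$step_mean[1] <- Inf
  obs <- data.frame(sqrt_step = 1, turn_angle = 0.1, solar_hour = 0)
  expect_error(hmm_forward_loglik(obs, p), "non-finite")
})

test_that("transition matrix rows sum to one across the day", {
  p <- default_hmm_params()
  withr::with_seed(9, {
    for (h in runif(100, 0, 24)) {
      G <- hmm_transition_matrix(p, h)
      expect_equal(rowSums(G), rep(1, 4), tolerance = 1e-12)
      expect_true(all(G >= 0))
    }
  })
})

test_that("likelihood is invariant under state relabeling", {
  p <- default_hmm_params()
  sim <- simulate_hmm_steps(p, 200, seed = 5)
  ll <- hmm_forward_loglik(sim$obs, p)
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    expect_equal(hmm_forward_loglik(sim$obs, relabel_hmm_params(p, perm)), ll,
                 tolerance = 1e-10)
  }
})

test_that("Viterbi equals exhaustive argmax and respects the tie rule", {
  p4 <- default_hmm_params()
  sim <- simulate_hmm_steps(p4, 8, seed = 14)
  expect_identical(viterbi_decode(sim$obs, p4), oracle_viterbi(sim$obs, p4))
  # with a missing observation in the stream
  obs <- sim$obs
  obs$sqrt_step[5] <- NA; obs$turn_angle[5] <- NA
  expect_identical(viterbi_decode(obs, p4), oracle_viterbi(obs, p4))
  # all-uniform model: everything ties, path collapses to state 1
  pu <- hmm_params(step_mean = rep(1, 4), step_sd = rep(0.5, 4),
                   step_zero_mass = rep(0, 4),
                   angle_shape = rep(1.2, 4), angle_scale = rep(1, 4),
                   beta = matrix(0, 12, 1), delta = rep(0.25, 4))
  expect_identical(viterbi_decode(sim$obs, pu), rep(1L, 8))
})

test_that("Viterbi path likelihood never exceeds the total likelihood", {
  p <- default_hmm_params()
  sim <- simulate_hmm_steps(p, 50, seed = 31)
  path <- viterbi_decode(sim$obs, p)
  emis <- oracle_emissions(sim$obs, p)
  G <- lapply(sim$obs$solar_hour, function(h) hmm_transition_matrix(p, h))
  lp <- log(p$delta[path[1]]) + log(emis[1, path[1]])
  for (t in 2:50) lp <- lp + log(G[[t]][path[t - 1], path[t]]) +
    log(emis[t, path[t]])
  expect_lt(lp, hmm_forward_loglik(sim$obs, p))
})

test_that("well-separated states give near-perfect decoding", {
  # near-deterministic emissions: step distributions barely overlap
  p <- hmm_params(step_mean = c(0.1, 10), step_sd = c(0.02, 0.5),
                  step_zero_mass = c(0, 0),
                  angle_shape = c(1, 2), angle_scale = c(1.5, 0.3),
                  beta = matrix(-2, 2, 1), delta = c(0.5, 0.5))
  sim <- simulate_hmm_steps(p, 500, seed = 2)
  expect_identical(viterbi_decode(sim$obs, p), sim$states)
})

test_that("degenerate 1-state fit equals the direct gamma MLE", {
  p1 <- hmm_params(step_mean = 2, step_sd = 0.8, step_zero_mass = 0,
                   angle_shape = 1.3, angle_scale = 0.9,
                   beta = matrix(0, 0, 1), delta = 1)
  sim <- simulate_hmm_steps(p1, 800, seed = 6)
  fit <- fit_hmm(sim$obs, n_states = 1, cosinor = FALSE, seeds = 1,
                 init = p1, maxit = 500)
  ora <- oracle_gamma_mle(sim$obs$sqrt_step)
  expect_equal(fit$params$step_mean, ora$mean, tolerance = 1e-5)
  expect_equal(fit$params$step_sd, ora$sd, tolerance = 1e-5)
})

test_that("fitting is deterministic under identical seed lists", {
  p <- default_hmm_params()
  sim <- simulate_hmm_steps(p, 1500, seed = 77)
  f1 <- fit_hmm(sim$obs, seeds = c(3, 4), init = p, maxit = 40)
  f2 <- fit_hmm(sim$obs, seeds = c(3, 4), init = p, maxit = 40)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-12)
  expect_identical(f1$params, f2$params)
})

test_that("label_states orders by step mean and relabeling inverts permutations", {
  p <- default_hmm_params()
  expect_identical(label_states(p), 1:4)  # already ordered
  perm <- c(3, 1, 4, 2)
  ps <- relabel_hmm_params(p, perm)
  expect_equal(ps$step_mean, p$step_mean[perm])
  # labeling the shuffled params recovers the increasing order
  lab <- label_states(ps)
  expect_equal(ps$step_mean[lab], sort(p$step_mean))
  expect_identical(relabel_hmm_params(ps, lab)$step_mean, p$step_mean)
})

test_that("HMM parameter JSON round-trips", {
  p <- default_hmm_params()
  f <- withr::local_tempfile(fileext = ".json")
  write_hmm_params_json(p, f)
  q <- read_hmm_params_json(f)
  expect_equal(q$step_mean, p$step_mean)
  expect_equal(q$beta, p$beta)
  expect_equal(q$delta, p$delta)
})
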