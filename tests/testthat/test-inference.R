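test_that("a flat target recovers the prior's moments", {
  pri <- default_priors(ddm_model("reduced"))
  set.seed(31)
  run <- de_mcmc(function(th) rep(0, ncol(th)), pri, n_chains = 12,
                 n_iter = 1500, burn_in = 300)
  dm <- dustddm:::draw_matrix_from_array(run$draws)
  for (i in seq_len(nrow(pri))) {
    mo <- truncnorm_moments(pri$mean[i], pri$sd[i], pri$lower[i],
                            pri$upper[i])
    expect_lt(abs(mean(dm[, i]) - mo["mean"]), 0.15 * mo["sd"])
    expect_lt(abs(sd(dm[, i]) - mo["sd"]), 0.15 * mo["sd"])
  }
})

test_that("fits are deterministic given data and seed", {
  dat <- toy_trials(n = 60)
  f1 <- rlang::exec(fit_ddm, dat, "reduced", seed = 5, !!!quick_fit,
                    on_nonconvergence = "ignore")
  f2 <- rlang::exec(fit_ddm, dat, "reduced", seed = 5, !!!quick_fit,
                    on_nonconvergence = "ignore")
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pointwise, f2$pointwise)
})

test_that("posterior recovers known generating parameters (reduced, 500 trials)", {
  m <- ddm_model("reduced")
  truth <- c(a = 1.2, w_base = 0.5, v_mag = 0.706, t0 = 0.3, sv = 0.4)
  sched <- generate_schedule(n_trials = 498,
                             norm_counts = c(none = 166, same = 166,
                                             only = 166),
                             social_props = c(valid = 0, invalid = 0,
                                              incongruent = 1),
                             seed = 32)
  dat <- dplyr::filter(simulate_from_model(m, truth, sched, seed = 33),
                       !no_response)
  fit <- fit_ddm(dat, m, seed = 34, on_nonconvergence = "warn")
  sm <- tidy(fit)
  for (i in seq_len(nrow(sm))) {
    expect_lt(abs(sm$estimate[i] - truth[sm$parameter[i]]),
              3 * sm$std.error[i] + 1e-8)
  }
})

test_that("stored pointwise log-likelihoods match fresh evaluations", {
  dat <- toy_trials(n = 45)
  fit <- rlang::exec(fit_ddm, dat, "reduced", seed = 6, !!!quick_fit,
                     on_nonconvergence = "ignore")
  expect_equal(rowSums(fit$pointwise), fit$log_lik, tolerance = 1e-8)
  dm <- draw_matrix(fit)
  for (s in c(1, 101, nrow(dm))) {
    fresh <- ddm_loglik(dat, fit$model, dm[s, ])
    expect_equal(fit$pointwise[s, ], fresh$pointwise, tolerance = 1e-8)
  }
})

test_that("posterior SDs shrink as trial counts double", {
  m <- ddm_model("reduced")
  truth <- c(a = 1.2, w_base = 0.5, v_mag = 0.706, t0 = 0.3, sv = 0)
  mean_sd <- function(n_trials, seed) {
    sched <- generate_schedule(
      n_trials = n_trials,
      norm_counts = setNames(rep(n_trials / 3, 3), c("none", "same", "only")),
      seed = seed)
    dat <- dplyr::filter(simulate_from_model(m, truth, sched,
                                             seed = seed + 1),
                         !no_response)
    fit <- rlang::exec(fit_ddm, dat, m, seed = seed + 2, !!!quick_fit,
                       on_nonconvergence = "ignore")
    mean(tidy(fit)$std.error[1:4])  # a, w, v, t0 (sv boundary-limited)
  }
  seeds <- c(41, 47, 53, 59, 61)
  sd250 <- vapply(seeds, function(s) mean_sd(240, s), numeric(1))
  sd500 <- vapply(seeds, function(s) mean_sd(480, s * 100), numeric(1))
  expect_lt(mean(sd500), mean(sd250))
})

test_that("split-chain R-hat behaves across regimes", {
  # well-mixed iid chains
  set.seed(35)
  good <- array(rnorm(4000), c(1000, 4, 1))
  expect_lt(gelman_rubin(good)[1], 1.05)
  # separated chains
  apart <- array(c(rnorm(500, 0, 0.01), rnorm(500, 10, 0.01)), c(500, 2, 1))
  expect_gt(gelman_rubin(apart)[1], 1.1)
  # degenerate constant chains
  flat <- array(1, c(100, 3, 1))
  expect_warning(r <- gelman_rubin(flat), "zero within-chain")
  expect_identical(unname(r[1]), Inf)
  # input contract
  expect_error(gelman_rubin(array(rnorm(100), c(100, 1, 1))), "2 chains")
  expect_error(gelman_rubin(array(rnorm(8), c(4, 2, 1))), "10 retained")
})

test_that("a degenerate sampler run fails loudly naming parameters", {
  pri <- default_priors(ddm_model("reduced"))
  set.seed(36)
  expect_error(
    de_mcmc(function(th) rep(-Inf, ncol(th)), pri, n_chains = 12,
            n_iter = 100, burn_in = 100),
    "finite posterior|degenerate")
})
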