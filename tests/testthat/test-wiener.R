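test_that("density vanishes at and below zero decision time", {
  p <- base_params()
  expect_equal(fpt_density(c(-1, 0), p, "upper"), c(0, 0))
  expect_lt(fpt_density(1e-6, p, "upper"), 1e-10)
})

test_that("unbiased zero-drift walk has symmetric boundary densities", {
  p <- base_params(v = 0, w = 0.5)
  t <- c(0.05, 0.2, 0.5, 1, 2)
  expect_equal(fpt_density(t, p, "upper"), fpt_density(t, p, "lower"))
})

test_that("density integrates to the closed-form absorption probability", {
  p <- base_params(t0 = 0)
  int_up <- integrate(function(t) fpt_density(t, p, "upper"), 0, 60)$value
  expect_equal(int_up, 0.70, tolerance = 0.005)
  expect_equal(int_up, choice_probability(p, "upper"), tolerance = 1e-4)
})

test_that("boundary densities normalise to 1, with and without sv", {
  for (p in list(base_params(t0 = 0),
                 ddm_params(a = 0.8, w = 0.3, v = -1.5, sv = 0),
                 ddm_params(a = 1.5, w = 0.4, v = 1, sv = 0.8),
                 ddm_params(a = 2.2, w = 0.65, v = 0.3, sv = 1.2))) {
    total <- integrate(function(t) fpt_density(t, p, "upper"), 0, 200,
                       rel.tol = 1e-9)$value +
      integrate(function(t) fpt_density(t, p, "lower"), 0, 200,
                rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-4)
  }
})

test_that("small- and large-time series agree around the crossover", {
  p <- ddm_params(a = 1.3, w = 0.45, v = 0.9, sv = 0.4)
  t <- seq(0.05, 2, by = 0.05)
  expect_lt(max(abs(fpt_density(t, p, method = "small") -
                      fpt_density(t, p, method = "large"))), 1e-6)
})

test_that("mirror symmetry: upper(a, w, v) equals lower(a, 1-w, -v)", {
  set.seed(4)
  for (i in 1:10) {
    a <- runif(1, 0.5, 3); w <- runif(1, 0.1, 0.9); v <- runif(1, -3, 3)
    sv <- runif(1, 0, 1.5); t <- runif(5, 0.02, 3)
    expect_equal(fpt_density(t, ddm_params(a, w, v, sv = sv), "upper"),
                 fpt_density(t, ddm_params(a, 1 - w, -v, sv = sv), "lower"))
  }
})

test_that("choice probability closed form and its symmetries", {
  expect_equal(choice_probability(base_params(v = 0)), 0.5)
  expect_equal(choice_probability(base_params()),
               1 / (1 + exp(-0.706 * 1.2)), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, 0.5, 3); w <- runif(1, 0.1, 0.9); v <- runif(1, -3, 3)
    expect_equal(choice_probability(ddm_params(a, w, v), "upper"),
                 choice_probability(ddm_params(a, 1 - w, -v), "lower"))
  }
})

test_that("invalid parameters are rejected", {
  expect_error(ddm_params(a = -1, w = 0.5, v = 0), "threshold")
  expect_error(ddm_params(a = 1, w = 1.2, v = 0), "starting point")
  expect_error(ddm_params(a = 1, w = 0.5, v = 0, t0 = -0.1), "t0")
  expect_error(ddm_params(a = 1, w = 0.5, v = 0, sv = -1), "sv")
})

test_that("simulator matches the analytic choice probability", {
  set.seed(21)
  n <- 4e4
  for (p in list(base_params(), ddm_params(a = 1.6, w = 0.35, v = -0.5,
                                           t0 = 0.2, sv = 0.6))) {
    s <- simulate_trials(n, p, deadline = 20)
    p_up <- choice_probability(p, "upper")
    mc_se <- sqrt(p_up * (1 - p_up) / n)
    expect_lt(abs(mean(s$boundary == "upper") - p_up), 4 * mc_se)
  }
})

test_that("simulated RT distribution matches the density (binned chi-square)", {
  set.seed(22)
  p <- base_params(t0 = 0.3)
  n <- 1e5
  s <- simulate_trials(n, p, deadline = 20)
  up <- s$rt[s$boundary == "upper"] - p$t0
  breaks <- c(seq(0, 3, by = 0.1), Inf)
  obs <- table(cut(up, breaks)) # counts among ALL n trials land in upper bins
  probs <- vapply(seq_len(length(breaks) - 1), function(i) {
    integrate(function(t) fpt_density(t, p, "upper"), breaks[i],
              min(breaks[i + 1], 60), rel.tol = 1e-8)$value
  }, numeric(1))
  expected <- n * probs
  keep <- expected > 10
  chi2 <- sum((as.numeric(obs[keep]) - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE), 1e-4)
})

test_that("simulator determinism and degenerate limits", {
  set.seed(7); s1 <- simulate_trials(50, base_params())
  set.seed(7); s2 <- simulate_trials(50, base_params())
  expect_identical(s1, s2)
  set.seed(8)
  s <- simulate_trials(200, ddm_params(a = 1.2, w = 0.5, v = 50, t0 = 0.1))
  expect_true(all(s$boundary == "upper"))
  expect_error(simulate_trials(10, base_params(t0 = 0.5), deadline = 0.4),
               "deadline")
})

test_that("tight deadlines yield no-response trials", {
  set.seed(9)
  s <- simulate_trials(500, ddm_params(a = 3, w = 0.5, v = 0.1, t0 = 0.3),
                       deadline = 0.6)
  expect_gt(mean(is.na(s$boundary)), 0)
  expect_true(all(is.na(s$rt[is.na(s$boundary)])))
  expect_true(all(s$rt[!is.na(s$rt)] <= 0.6))
})
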