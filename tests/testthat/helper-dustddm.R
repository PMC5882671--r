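# shared fixtures: everything is generated in code at test time

base_params <- function(...) {
  args <- modifyList(list(a = 1.2, w = 0.5, v = 0.706, t0 = 0.3, sv = 0),
                     list(...))
  do.call(ddm_params, args)
}

# a small responded-trial tibble simulated from a zero-effect subject;
# n is rounded up to a multiple of 60 so the design cells stay integral
toy_trials <- function(n = 60, seed = 11) {
  n <- 60 * ceiling(n / 60)
  truth <- preset_truth("bo")
  truth$dw_none <- truth$dw_same <- truth$dw_only <- truth$dv_only <- 0
  sched <- generate_schedule(n_trials = n,
                             norm_counts = c(none = n / 3, same = n / 3,
                                             only = n / 3),
                             seed = seed)
  dplyr::filter(simulate_subject(truth, sched, seed = seed + 1),
                !no_response)
}

# flat theta at the prior means, for context-resolution checks
theta_at_prior_means <- function(m) {
  pri <- default_priors(m)
  setNames(pri$mean, pri$name)
}

# Six minimal ddm_fit-shaped objects whose posterior means are exactly the
# supplied values (constant draws), for averaging arithmetic tests.
mock_six_fits <- function(w_base = 0.5, w_cong_left = 0.45,
                          w_cong_right = 0.55, v = 0.7) {
  out <- lapply(model_names(), function(nm) {
    m <- ddm_model(nm)
    th <- vapply(m$params$name, function(p) {
      if (p == "a") 1.2
      else if (p == "t0") 0.3
      else if (p == "sv") 0.2
      else if (p == "w_base") w_base
      else if (startsWith(p, "w_cong_left")) w_cong_left
      else if (startsWith(p, "w_cong_right")) w_cong_right
      else v
    }, numeric(1))
    draws <- array(rep(th, each = 4), c(2, 2, length(th)),
                   dimnames = list(NULL, NULL, m$params$name))
    structure(list(draws = draws,
                   pointwise = matrix(log(0.5), 4, 3),
                   model = m),
              class = "ddm_fit")
  })
  setNames(out, model_names())
}

# sampler settings small enough for unit tests
quick_fit <- list(n_iter = 400, burn_in = 300)

# mean/sd of a truncated Normal (closed form), used as the prior oracle
truncnorm_moments <- function(mu, s, lo, hi) {
  a <- (lo - mu) / s; b <- (hi - mu) / s
  Z <- pnorm(b) - pnorm(a)
  m <- mu + s * (dnorm(a) - dnorm(b)) / Z
  v <- s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = m, sd = sqrt(v))
}
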