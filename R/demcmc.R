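#' Differential-evolution MCMC sampler
#'
#' Population MCMC in which each chain's proposal is the scaled difference
#' of two other chains' states plus a small uniform jitter. Chains are split
#' into two fixed halves; each half is updated in one batched
#' Metropolis sweep using difference vectors drawn from the other half (a
#' valid composition of two conditional updates), so one iteration costs two
#' vectorised target evaluations. The scale is `gamma = 2.38 / sqrt(2 p)`
#' with a 5% chance of `gamma = 1` (mode jumping). During burn-in, every
#' 20th iteration migrates states by a random cyclic swap among a random
#' chain subset.
#'
#' @param log_target Function taking a `p x m` matrix of parameter vectors
#'   (columns) and returning `m` log target densities.
#' @param priors Prior tibble (see [default_priors()]); used to initialise
#'   chains and bound the support.
#' @param n_chains Number of chains (>= 4; default `3 p`).
#' @param n_iter Retained iterations per chain after burn-in.
#' @param burn_in Discarded initial iterations.
#' @param jitter Half-width of the uniform proposal jitter.
#' @param migrate Enable burn-in migration.
#'
#' @return List with `draws` (`n_iter x n_chains x p` array),
#'   `log_post` (`n_iter x n_chains`), and `acceptance` (per-chain rate).
#' @export
de_mcmc <- function(log_target, priors, n_chains = 3 * nrow(priors),
                    n_iter = 1000, burn_in = 500, jitter = 1e-3,
                    migrate = TRUE) {
  p <- nrow(priors)
  if (n_chains < 4) stop("`n_chains` must be >= 4", call. = FALSE)
  if (n_chains < 2 * p) {
    warning("n_chains < 2 x parameters; DE proposals may span the ",
            "posterior poorly", call. = FALSE)
  }

  # initialise from the prior, retrying chains stuck at -Inf
  x <- rprior(priors, n_chains)
  lp <- log_target(x) + dprior_log(priors, x)
  for (tries in 1:50) {
    bad <- !is.finite(lp)
    if (!any(bad)) break
    x[, bad] <- rprior(priors, sum(bad))
    lp[bad] <- log_target(x[, bad, drop = FALSE]) +
      dprior_log(priors, x[, bad, drop = FALSE])
  }
  if (any(!is.finite(lp))) {
    stop("could not initialise all chains at finite posterior density",
         call. = FALSE)
  }

  half_a <- seq_len(floor(n_chains / 2))
  half_b <- setdiff(seq_len(n_chains), half_a)
  gamma0 <- 2.38 / sqrt(2 * p)

  draws <- array(NA_real_, c(n_iter, n_chains, p),
                 dimnames = list(NULL, NULL, priors$name))
  lp_out <- matrix(NA_real_, n_iter, n_chains)
  n_acc <- numeric(n_chains)
  epoch_acc <- 0L

  update_half <- function(idx, other) {
    m <- length(idx)
    r1 <- other[sample.int(length(other), m, replace = TRUE)]
    repeat {
      r2 <- other[sample.int(length(other), m, replace = TRUE)]
      if (all(r2 != r1)) break
    }
    gam <- ifelse(runif(m) < 0.05, 1, gamma0)
    prop <- x[, idx, drop = FALSE] +
      sweep(x[, r1, drop = FALSE] - x[, r2, drop = FALSE], 2, gam, `*`) +
      matrix(runif(p * m, -jitter, jitter), p, m)
    lp_prior <- dprior_log(priors, prop)
    lp_prop <- rep(-Inf, m)
    ok <- is.finite(lp_prior)
    if (any(ok)) {
      lp_prop[ok] <- log_target(prop[, ok, drop = FALSE]) + lp_prior[ok]
    }
    acc <- log(runif(m)) < lp_prop - lp[idx]
    x[, idx[acc]] <<- prop[, acc, drop = FALSE]
    lp[idx[acc]] <<- lp_prop[acc]
    n_acc[idx[acc]] <<- n_acc[idx[acc]] + 1
    epoch_acc <<- epoch_acc + sum(acc)
  }

  total_iter <- burn_in + n_iter
  for (it in seq_len(total_iter)) {
    update_half(half_a, half_b)
    update_half(half_b, half_a)
    if (migrate && it <= burn_in && it %% 20 == 0) {
      # ring migration: each selected chain proposes adopting its
      # predecessor's state (Metropolis-accepted), which lets high-density
      # states displace stuck outlier chains; burn-in only
      k <- sample(2:max(2, ceiling(n_chains / 4)), 1)
      sel <- sample.int(n_chains, k)
      prev <- c(sel[k], sel[-k])
      x_new <- x[, prev, drop = FALSE]
      lp_new <- lp[prev]
      acc <- log(runif(k)) < lp_new - lp[sel]
      x[, sel[acc]] <- x_new[, acc, drop = FALSE]
      lp[sel[acc]] <- lp_new[acc]
    }
    if (it %% 50 == 0) {
      if (epoch_acc == 0L) {
        stuck <- priors$name[apply(x, 1, var) < .Machine$double.eps]
        stop("sampler degenerate: no acceptances across all chains in a ",
             "50-iteration epoch; stuck parameter(s): ",
             paste(if (length(stuck)) stuck else priors$name, collapse = ", "),
             call. = FALSE)
      }
      epoch_acc <- 0L
    }
    if (it > burn_in) {
      draws[it - burn_in, , ] <- t(x)
      lp_out[it - burn_in, ] <- lp
    }
  }

  list(draws = draws, log_post = lp_out,
       acceptance = n_acc / total_iter)
}

#' Fit a diffusion model to one subject's trials
#'
#' Samples the joint posterior of a model's parameters given responded
#' trials, using [de_mcmc()] with the joint choice/RT likelihood
#' ([ddm_loglik()]) and truncated-Normal priors. Retained draws carry
#' per-trial pointwise log-likelihoods (for WAIC) and split-chain
#' convergence diagnostics. If any parameter's R-hat exceeds 1.1 the fit is
#' rerun once with doubled iterations; if it still fails the fit errors
#' unless `on_nonconvergence = "warn"`.
#'
#' @param data Trial tibble (see [ddm_loglik()]); no-response trials are
#'   dropped automatically when a `no_response` column is present.
#' @param model A [ddm_model()] or model name.
#' @param priors Prior tibble; defaults to [default_priors()].
#' @param n_chains,n_iter,burn_in Sampler size (defaults: `3 p` chains,
#'   1000 retained, 500 burn-in).
#' @param seed Integer seed; fixed seed + data => identical draws.
#' @param on_nonconvergence `"error"`, `"warn"`, or `"ignore"` after the one
#'   automatic refit.
#' @param ... Passed to [de_mcmc()].
#'
#' @return A `ddm_fit` object: `draws` (iterations x chains x parameters),
#'   `pointwise` (draws x trials log-likelihood matrix), `log_lik` (total
#'   per draw), `rhat`, `meta`, plus the `model` and fitted `data`.
#'   [tidy()][generics::tidy()] and [glance()][generics::glance()] methods
#'   summarise it.
#' @export
fit_ddm <- function(data, model, priors = NULL,
                    n_chains = NULL, n_iter = 1000, burn_in = 500,
                    seed = NULL,
                    on_nonconvergence = c("error", "warn", "ignore"), ...) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (is.character(model)) model <- ddm_model(model)
  if ("no_response" %in% names(data)) {
    data <- dplyr::filter(data, !.data$no_response)
  }
  check_trial_data(data)
  priors <- if (is.null(priors)) default_priors(model) else
    check_priors(model, priors)
  if (is.null(n_chains)) n_chains <- 3 * n_params(model)
  if (!is.null(seed)) set.seed(seed)

  ll_fn <- make_loglik_batch(data, model)

  run <- de_mcmc(ll_fn, priors, n_chains = n_chains, n_iter = n_iter,
                 burn_in = burn_in, ...)
  rhat <- gelman_rubin(run$draws)
  if (any(rhat > 1.1)) {
    run <- de_mcmc(ll_fn, priors, n_chains = n_chains, n_iter = 2 * n_iter,
                   burn_in = 2 * burn_in, ...)
    rhat <- gelman_rubin(run$draws)
    if (any(rhat > 1.1)) {
      msg <- paste0("fit of '", model$name, "' did not converge after refit",
                    " (max R-hat ", round(max(rhat), 3), ")")
      if (on_nonconvergence == "error") stop(msg, call. = FALSE)
      if (on_nonconvergence == "warn") warning(msg, call. = FALSE)
    }
  }

  th <- draw_matrix_from_array(run$draws)      # S x p
  pw <- pointwise_loglik(data, model, th)      # S x n
  structure(list(
    draws = run$draws,
    pointwise = pw,
    log_lik = rowSums(pw),
    rhat = rhat,
    acceptance = run$acceptance,
    model = model,
    data = data,
    priors = priors,
    meta = list(model = model$name, seed = seed, n_chains = dim(run$draws)[2],
                n_iter = dim(run$draws)[1], burn_in = burn_in,
                acceptance = mean(run$acceptance),
                converged = all(rhat <= 1.1))
  ), class = "ddm_fit")
}

# stack an [iter, chain, p] array into an S x p matrix (chains concatenated)
draw_matrix_from_array <- function(a) {
  d <- dim(a)
  m <- matrix(aperm(a, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(m) <- dimnames(a)[[3]]
  m
}

#' Retained posterior draws as a matrix
#' @param fit A `ddm_fit`.
#' @return `S x p` matrix, chains stacked.
#' @export
draw_matrix <- function(fit) draw_matrix_from_array(fit$draws)

# per-trial log-likelihood for each draw (rows of theta matrix), chunked
pointwise_loglik <- function(data, model, theta, chunk = 2000L) {
  map <- dplyr::left_join(
    dplyr::select(data, "norm", "social", "stimulus"),
    model$context_map, by = c("norm", "social", "stimulus"))
  pn <- model$params$name
  w_idx <- match(map$w_par, pn); v_idx <- match(map$v_par, pn)
  n <- nrow(data); S <- nrow(theta)
  out <- matrix(NA_real_, S, n)
  upper <- data$response == "right"
  for (start in seq(1, S, by = chunk)) {
    sel <- start:min(start + chunk - 1L, S)
    th <- t(theta[sel, , drop = FALSE])       # p x m
    m <- length(sel)
    a <- rep(th["a", ], each = n)
    t0 <- rep(th["t0", ], each = n)
    sv <- rep(th["sv", ], each = n)
    w <- th[w_idx, , drop = FALSE]
    v <- th[v_idx, , drop = FALSE] * map$v_sign
    td <- rep(data$rt_s, m) - t0
    dens <- .dwiener_cpp(td, a, as.vector(w), as.vector(v), sv,
                         rep(upper, m), 1e-7, 0L)
    pw <- ifelse(td > 0 & dens > 0, log(pmax(dens, .Machine$double.xmin)), -Inf)
    out[sel, ] <- matrix(pw, m, n, byrow = TRUE)
  }
  out
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat with each chain split in half. Values near 1 indicate
#' mixed chains; > 1.1 flags non-convergence. Chains with zero pooled
#' within-chain variance (all-constant series) yield `Inf` with a warning.
#'
#' @param draws `iterations x chains x parameters` array (or
#'   `iterations x chains` matrix for a single parameter).
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(draws) {
  if (is.matrix(draws)) draws <- array(draws, c(dim(draws), 1))
  d <- dim(draws)
  if (d[2] < 2) stop("R-hat needs at least 2 chains", call. = FALSE)
  if (d[1] < 10) stop("R-hat needs at least 10 retained iterations",
                      call. = FALSE)
  half <- floor(d[1] / 2)
  out <- numeric(d[3])
  for (j in seq_len(d[3])) {
    chains <- cbind(draws[seq_len(half), , j, drop = TRUE],
                    draws[(d[1] - half + 1):d[1], , j, drop = TRUE])
    n <- nrow(chains)
    W <- mean(apply(chains, 2, var))
    B <- n * var(colMeans(chains))
    if (W <= .Machine$double.eps) {
      warning("zero within-chain variance; R-hat undefined (Inf)",
              call. = FALSE)
      out[j] <- Inf
    } else {
      out[j] <- sqrt(((n - 1) / n * W + B / n) / W)
    }
  }
  names(out) <- dimnames(draws)[[3]]
  out
}
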