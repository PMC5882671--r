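#' Joint choice/RT log-likelihood of a model on one subject's trials
#'
#' Each responded trial contributes the log of the defective first-passage
#' density of its RT (net of non-decision time) at the boundary of the
#' observed response, with parameters resolved from the trial context. Any
#' trial whose density underflows — including `rt <= t0` — makes the total
#' `-Inf` rather than raising an error, so a sampler can reject the draw.
#' No-response trials must be excluded upstream.
#'
#' @param data Trial tibble with columns `norm`, `social`, `stimulus`,
#'   `response` (`"left"`/`"right"`) and `rt_s` (seconds).
#' @param model A [ddm_model()].
#' @param theta Flat parameter vector (see [resolve_params()]).
#'
#' @return List with `total` (scalar) and `pointwise` (per-trial vector of
#'   log-densities; `total == sum(pointwise)`).
#' @export
ddm_loglik <- function(data, model, theta) {
  check_trial_data(data)
  if (nrow(data) == 0) return(list(total = 0, pointwise = numeric(0)))
  theta <- check_theta(model, theta)
  pars <- resolve_params(model, theta, data$norm, data$social, data$stimulus)
  td <- data$rt_s - pars$t0
  dens <- .dwiener_cpp(td, pars$a, pars$w, pars$v, pars$sv,
                       data$response == "right", 1e-7, 0L)
  pw <- ifelse(td > 0 & dens > 0, log(pmax(dens, .Machine$double.xmin)), -Inf)
  list(total = sum(pw), pointwise = pw)
}

# Precompiles a batched likelihood over the trial set: returns
# function(theta_matrix p x m) -> length-m vector of total log-likelihoods.
# Index lookups are resolved once so MCMC iterations are one C++ call.
make_loglik_batch <- function(data, model) {
  check_trial_data(data)
  map <- dplyr::left_join(
    dplyr::select(data, "norm", "social", "stimulus"),
    model$context_map, by = c("norm", "social", "stimulus"))
  pn <- model$params$name
  w_idx <- match(map$w_par, pn)
  v_idx <- match(map$v_par, pn)
  a_idx <- match("a", pn); t0_idx <- match("t0", pn); sv_idx <- match("sv", pn)
  v_sign <- map$v_sign
  rt <- data$rt_s
  upper <- data$response == "right"
  n <- nrow(data)

  function(theta) {
    theta <- as.matrix(theta)  # p x m
    .wiener_loglik_batch_cpp(
      rt, upper,
      a = theta[rep(a_idx, n), , drop = FALSE],
      w = theta[w_idx, , drop = FALSE],
      v = theta[v_idx, , drop = FALSE] * v_sign,
      t0 = theta[rep(t0_idx, n), , drop = FALSE],
      sv = theta[rep(sv_idx, n), , drop = FALSE],
      n_trials = n)
  }
}

check_trial_data <- function(data, need_response = TRUE) {
  req <- c("norm", "social", "stimulus", if (need_response) c("response", "rt_s"))
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("trial data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (need_response && any(is.na(data$response) | is.na(data$rt_s))) {
    stop("trial data passed to the likelihood contains no-response trials; ",
         "drop them first (e.g. dplyr::filter(!no_response))", call. = FALSE)
  }
  check_context(data)
}
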