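#' Widely applicable information criterion from pointwise log-likelihoods
#'
#' `lppd` is the summed log pointwise predictive density,
#' `sum_i log mean_s exp(ll[s, i])`, computed with log-sum-exp
#' stabilisation; the effective parameter count `p_waic` is the summed
#' per-trial variance of the log-likelihood over draws (denominator-n
#' variance, so duplicating every draw changes nothing); and
#' `waic = -2 (lppd - p_waic)` on the deviance scale (smaller is better).
#'
#' @param pointwise `draws x trials` matrix of log-likelihoods (e.g.
#'   `fit$pointwise` from [fit_ddm()]), or a `ddm_fit`.
#' @return A list of class `ddm_waic` with `lppd`, `p_waic`, `waic`,
#'   `n_draws`, `n_trials`.
#' @examples
#' ll <- matrix(log(c(0.2, 0.4)), nrow = 2)  # 2 draws, 1 trial
#' waic(ll)
#' @export
waic <- function(pointwise) {
  if (inherits(pointwise, "ddm_fit")) pointwise <- pointwise$pointwise
  pointwise <- as.matrix(pointwise)
  if (nrow(pointwise) < 1 || ncol(pointwise) < 1) {
    stop("`pointwise` needs at least 1 draw and 1 trial", call. = FALSE)
  }
  bad <- apply(pointwise, 2, function(x) all(x == -Inf))
  if (any(bad)) {
    stop("trial(s) ", paste(head(which(bad), 5), collapse = ", "),
         " impossible (log-likelihood -Inf) under every draw", call. = FALSE)
  }
  if (any(!is.finite(pointwise))) {
    stop("`pointwise` contains non-finite log-likelihoods", call. = FALSE)
  }
  S <- nrow(pointwise)
  lppd <- sum(apply(pointwise, 2, function(x) {
    m <- max(x)
    m + log(mean(exp(x - m)))
  }))
  p_waic <- sum(apply(pointwise, 2, function(x) mean((x - mean(x))^2)))
  structure(list(lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic),
                 n_draws = S, n_trials = ncol(pointwise)),
            class = "ddm_waic")
}

#' @export
print.ddm_waic <- function(x, ...) {
  cat(sprintf("<ddm_waic> waic = %.2f  (lppd = %.2f, p_waic = %.2f; %d draws, %d trials)\n",
              x$waic, x$lppd, x$p_waic, x$n_draws, x$n_trials))
  invisible(x)
}

#' Akaike-style weights over a set of WAIC values
#'
#' `w_m = exp(-Delta_m / 2) / sum_k exp(-Delta_k / 2)` with
#' `Delta_m = waic_m - min(waic)`; invariant to adding a constant to all
#' values.
#'
#' @param waics Numeric vector of WAIC values (deviance scale), or a list
#'   of `ddm_waic` objects.
#' @return Numeric weights summing to 1, names preserved.
#' @examples
#' waic_weights(c(m1 = 100, m2 = 102))
#' @export
waic_weights <- function(waics) {
  if (is.list(waics)) {
    waics <- vapply(waics, function(x) if (inherits(x, "ddm_waic")) x$waic
                    else as.numeric(x), numeric(1))
  }
  if (any(!is.finite(waics))) stop("WAIC values must be finite", call. = FALSE)
  d <- waics - min(waics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Per-subject model-comparison table
#'
#' WAIC, its components, Akaike-style weights and the worst R-hat for one
#' subject's set of fitted models.
#'
#' @param fits Named list of `ddm_fit` objects (names default to each fit's
#'   model name).
#' @param subject Optional subject identifier column value.
#' @return A tibble: `subject` (if given), `model`, `waic`, `lppd`,
#'   `p_waic`, `weight`, `rhat_max`; weights sum to 1.
#' @export
compare_models <- function(fits, subject = NULL) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$model$name, character(1))
  }
  ws <- lapply(fits, waic)
  tab <- tibble::tibble(
    model = names(fits),
    waic = vapply(ws, `[[`, numeric(1), "waic"),
    lppd = vapply(ws, `[[`, numeric(1), "lppd"),
    p_waic = vapply(ws, `[[`, numeric(1), "p_waic"),
    weight = waic_weights(vapply(ws, `[[`, numeric(1), "waic")),
    rhat_max = vapply(fits, function(f) max(f$rhat), numeric(1))
  )
  if (!is.null(subject)) tab <- dplyr::bind_cols(tibble::tibble(subject = subject), tab)
  tab
}

#' WAIC-weighted condition-level parameter averages
#'
#' Folds each model's posterior-mean parameters into two condition-level
#' summaries and averages them across models with the WAIC weights:
#'
#' * `sp_bias` — the congruent-cue starting-point shift toward the cued
#'   side, corrected for any incongruent-trial bias and averaged over the
#'   two cue sides: `mean(w_congR - w_incong, w_incong - w_congL)`. Models
#'   without congruent starting points contribute 0.
#' * `drift_delta` — congruent-trial drift magnitude minus the
#'   incongruent (dots-only) drift. Models with a single drift contribute 0.
#'
#' A positive `sp_bias` always means "start shifted toward the cued side".
#'
#' @param fits Named list of the six `ddm_fit`s (all must be present).
#' @param weights Optional weights named by model; defaults to
#'   [waic_weights()] of the fits.
#' @return A tibble: `condition` (`none`/`same`/`only`), `sp_bias`,
#'   `drift_delta`.
#' @export
average_parameters <- function(fits, weights = NULL) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$model$name, character(1))
  }
  missing_m <- setdiff(model_names(), names(fits))
  if (length(missing_m)) {
    stop("averaging needs all six fitted models; missing: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- waic_weights(vapply(fits, function(f) waic(f)$waic, numeric(1)))
  }
  weights <- weights[names(fits)]

  per_model <- purrr::imap_dfr(fits, function(f, nm) {
    th <- colMeans(draw_matrix(f))
    purrr::map_dfr(.norms, function(cond) {
      tibble::tibble(model = nm, condition = cond,
                     sp_bias = model_sp_bias(nm, th, cond),
                     drift_delta = model_drift_delta(nm, th, cond))
    })
  })

  per_model |>
    dplyr::mutate(weight = weights[.data$model]) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(sp_bias = sum(.data$weight * .data$sp_bias),
                     drift_delta = sum(.data$weight * .data$drift_delta),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$condition, .norms))
}

model_sp_bias <- function(model_name, theta, cond) {
  switch(model_name,
    reduced = ,
    drift_reduced = ,
    drift = 0,
    sp_reduced = mean(c(theta[["w_cong_right"]] - theta[["w_base"]],
                        theta[["w_base"]] - theta[["w_cong_left"]])),
    sp = ,
    spdr = mean(c(theta[[paste0("w_cong_right_", cond)]] - theta[["w_base"]],
                  theta[["w_base"]] - theta[[paste0("w_cong_left_", cond)]]))
  )
}

model_drift_delta <- function(model_name, theta, cond) {
  switch(model_name,
    reduced = ,
    sp_reduced = ,
    sp = 0,
    drift_reduced = theta[["v_cong"]] - theta[["v_incong"]],
    drift = ,
    spdr = theta[[paste0("v_cong_", cond)]] - theta[["v_incong"]]
  )
}
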