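#' Diffusion parameter set
#'
#' Bundles one concrete parameter vector of the Wiener diffusion model with
#' two absorbing boundaries. The diffusion coefficient is fixed at `s = 1`;
#' all parameter values reported by this package are on that scale.
#'
#' @param a Threshold separation (> 0), evidence units.
#' @param w Relative starting point in (0, 1), measured from the lower
#'   (left-response) boundary; the absolute start is `z = w * a`.
#' @param v Mean drift rate, evidence units per second. Positive drifts
#'   toward the upper (right-response) boundary.
#' @param t0 Non-decision time in seconds (>= 0).
#' @param sv Across-trial standard deviation of the drift rate (>= 0).
#'
#' @return A list of class `ddm_params`.
#' @examples
#' ddm_params(a = 1.2, w = 0.5, v = 0.706, t0 = 0.3)
#' @export
ddm_params <- function(a, w, v, t0 = 0, sv = 0) {
  p <- list(a = a, w = w, v = v, t0 = t0, sv = sv)
  validate_ddm_params(p)
  structure(p, class = "ddm_params")
}

validate_ddm_params <- function(p) {
  stopifnot(is.numeric(p$a), is.numeric(p$w), is.numeric(p$v),
            is.numeric(p$t0), is.numeric(p$sv))
  if (any(!is.finite(c(p$a, p$w, p$v, p$t0, p$sv)))) {
    stop("diffusion parameters must be finite", call. = FALSE)
  }
  if (any(p$a <= 0)) stop("threshold separation `a` must be > 0", call. = FALSE)
  if (any(p$w <= 0 | p$w >= 1)) {
    stop("relative starting point `w` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(p$t0 < 0)) stop("non-decision time `t0` must be >= 0", call. = FALSE)
  if (any(p$sv < 0)) stop("drift variability `sv` must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("<ddm_params>  a =", x$a, " w =", x$w, " v =", x$v,
      " t0 =", x$t0, " sv =", x$sv, " (s = 1)\n")
  invisible(x)
}

#' First-passage-time density of the Wiener diffusion
#'
#' Defective density of absorption at a boundary at decision time `t`
#' (already net of non-decision time). Computed from the small-time or
#' large-time series expansion, whichever needs fewer terms for the target
#' accuracy; across-trial drift variability (`sv > 0`) is integrated out in
#' closed form. Integrating the density for one boundary over all `t` gives
#' that boundary's absorption probability, and the two boundaries together
#' integrate to 1.
#'
#' @param t Decision time(s) in seconds. Values `<= 0` return density 0.
#' @param params A [ddm_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @param eps Target absolute truncation error of the series (on the scaled
#'   density).
#' @param method `"auto"` picks the cheaper series; `"small"` / `"large"`
#'   force one expansion (exposed for numerical verification).
#'
#' @return Numeric vector of non-negative densities, same length as `t`.
#' @examples
#' p <- ddm_params(a = 1.2, w = 0.5, v = 0.706, t0 = 0.3)
#' fpt_density(c(0.2, 0.5, 1), p, "upper")
#' @export
fpt_density <- function(t, params, boundary = c("upper", "lower"),
                        eps = 1e-7, method = c("auto", "small", "large")) {
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  validate_ddm_params(params)
  .dwiener_cpp(as.numeric(t), params$a, params$w, params$v, params$sv,
               boundary == "upper", eps,
               match(method, c("auto", "small", "large")) - 1L)
}

#' Closed-form choice probability of the Wiener diffusion
#'
#' Probability that the process is absorbed at the given boundary. For
#' `sv = 0` this is the classical closed form
#' `P(upper) = (1 - exp(-2 v w a)) / (1 - exp(-2 v a))` (with `s = 1`),
#' reducing to `w` at zero drift; for `sv > 0` the closed form is averaged
#' numerically over the across-trial drift distribution.
#'
#' @inheritParams fpt_density
#' @return A probability.
#' @examples
#' choice_probability(ddm_params(a = 1.2, w = 0.5, v = 0.706)) # ~0.70
#' @export
choice_probability <- function(params, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  validate_ddm_params(params)
  p_upper_v <- function(v) {
    ifelse(abs(v) < 1e-10,
           params$w,
           (1 - exp(-2 * v * params$w * params$a)) / (1 - exp(-2 * v * params$a)))
  }
  if (params$sv == 0) {
    p <- p_upper_v(params$v)
  } else {
    p <- integrate(function(v) p_upper_v(v) * dnorm(v, params$v, params$sv),
                   params$v - 8 * params$sv, params$v + 8 * params$sv,
                   rel.tol = 1e-10)$value
  }
  if (boundary == "upper") p else 1 - p
}

#' Simulate diffusion trials
#'
#' Draws trial outcomes (absorbed boundary and RT) from the Wiener process
#' by exact Gaussian increments on a fine grid with Brownian-bridge
#' absorption between grid points, so hit probabilities are exact in law and
#' RTs are discretised at `dt`. When `sv > 0` each trial's drift is first
#' drawn from `N(v, sv)`. Trials still unabsorbed when `t0 +` decision time
#' reaches `deadline` are returned as no-response.
#'
#' @param n Number of trials.
#' @param params A [ddm_params()] object.
#' @param deadline Response deadline in seconds; must exceed `t0`.
#' @param dt Simulation step in seconds.
#'
#' @return A tibble with columns `boundary` (`"upper"`/`"lower"`/`NA`) and
#'   `rt` (seconds, `NA` for no-response trials). Reproducible under
#'   [set.seed()].
#' @examples
#' set.seed(1)
#' simulate_trials(5, ddm_params(a = 1.2, w = 0.5, v = 0.706, t0 = 0.3))
#' @export
simulate_trials <- function(n, params, deadline = 2.5, dt = 1e-3) {
  validate_ddm_params(params)
  if (deadline <= params$t0) {
    stop("`deadline` must exceed the non-decision time `t0`", call. = FALSE)
  }
  v_trial <- if (params$sv > 0) rnorm(n, params$v, params$sv) else rep(params$v, n)
  sim <- .sim_wiener_cpp(v_trial, rep(params$w, n), params$a, params$t0,
                         dt, deadline)
  tibble::tibble(
    boundary = dplyr::case_when(sim$boundary == 1L ~ "upper",
                                sim$boundary == 0L ~ "lower"),
    rt = sim$rt
  )
}
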