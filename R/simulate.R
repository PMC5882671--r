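#' Ground-truth presets for the two norm-strength experiments
#'
#' Subject-level generating parameters for the synthetic cohorts. The base
#' diffusion parameters are calibrated so dots-only accuracy is ~70%
#' (closed-form absorption probability `1/(1 + exp(-v a)) = 0.6998` at
#' `a = 1.2`, `v = 0.706`). Condition effects encode the qualitative
#' pattern of the two experiments: starting-point shifts toward the cued
#' side ordered `same > none > only`, with the `only` shift and the
#' congruent-drift change more negative in the harm-others (`ho`) variant
#' than in the benefit-others (`bo`) variant. These are the generator's
#' design values, not estimates from any human data set.
#'
#' @param experiment `"bo"` (benefit others) or `"ho"` (harm others).
#' @return A one-row tibble: `experiment`, `a`, `v_base`, `t0`, `sv`,
#'   `dw_none`, `dw_same`, `dw_only`, `dv_only`.
#' @examples
#' preset_truth("ho")
#' @export
preset_truth <- function(experiment = c("bo", "ho")) {
  experiment <- match.arg(tolower(experiment), c("bo", "ho"))
  tibble::tibble(
    experiment = experiment,
    a = 1.2, v_base = 0.706, t0 = 0.3, sv = 0,
    dw_none = 0.06, dw_same = 0.12,
    dw_only = if (experiment == "bo") 0.02 else -0.04,
    dv_only = if (experiment == "bo") -0.15 else -0.35
  )
}

#' Simulate one subject's trials from ground-truth effects
#'
#' Runs each scheduled trial through the diffusion simulator with
#' context-resolved parameters: on congruent-cue trials the starting point
#' is shifted toward the cued side by the norm condition's `dw` effect
#' (`w = 0.5 + dw` for rightward cues, `0.5 - dw` for leftward; 0.5 on
#' incongruent trials), and on `only`-norm congruent trials the drift
#' magnitude becomes `v_base + dv_only`. Drift sign follows the stimulus.
#' Trials exceeding the deadline are recorded as no-response.
#'
#' @param truth One-row tibble/list of generating parameters (see
#'   [preset_truth()]); may include `subject`.
#' @param schedule Trial schedule from [generate_schedule()].
#' @param seed Optional integer seed.
#' @param dt Simulation step in seconds.
#'
#' @return The schedule joined with `response`, `rt_s`, `accuracy`,
#'   `no_response`, plus `subject`/`experiment` identifiers.
#' @examples
#' tr <- preset_truth("ho")
#' dat <- simulate_subject(tr, generate_schedule(seed = 1), seed = 2)
#' mean(dat$accuracy, na.rm = TRUE)
#' @export
simulate_subject <- function(truth, schedule, seed = NULL, dt = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  truth <- as.list(tibble::as_tibble(truth)[1, ])
  dw <- c(none = truth$dw_none, same = truth$dw_same, only = truth$dw_only)

  w <- dplyr::case_when(
    schedule$social == "congruent_right" ~ 0.5 + dw[schedule$norm],
    schedule$social == "congruent_left" ~ 0.5 - dw[schedule$norm],
    TRUE ~ 0.5
  )
  w <- pmin(pmax(w, 0.02), 0.98)
  v_mag <- truth$v_base +
    ifelse(schedule$norm == "only" & schedule$social != "incongruent",
           truth$dv_only, 0)
  v_mag <- pmax(v_mag, 0.01)
  v_mean <- v_mag * ifelse(schedule$stimulus == "right", 1, -1)
  v_trial <- if (truth$sv > 0) rnorm(length(v_mean), v_mean, truth$sv) else v_mean

  sim <- .sim_wiener_cpp(v_trial, w, truth$a, truth$t0, dt,
                         schedule$deadline_s[1])
  schedule |>
    dplyr::mutate(
      subject = if (!is.null(truth$subject)) truth$subject else 1L,
      experiment = if (!is.null(truth$experiment)) truth$experiment else NA_character_,
      response = dplyr::case_when(sim$boundary == 1L ~ "right",
                                  sim$boundary == 0L ~ "left"),
      rt_s = sim$rt,
      no_response = is.na(.data$response),
      accuracy = .data$response == .data$stimulus
    ) |>
    dplyr::relocate("subject", "experiment")
}

#' Simulate trials from an explicit model parametrization
#'
#' Like [simulate_subject()], but the per-trial diffusion parameters come
#' from a [ddm_model()] and a flat `theta` via [resolve_params()]. Used by
#' the parameter-recovery and posterior-predictive machinery.
#'
#' @inheritParams simulate_subject
#' @param model A [ddm_model()] or model name.
#' @param theta Flat parameter vector for `model`.
#' @return Trial tibble as in [simulate_subject()].
#' @export
simulate_from_model <- function(model, theta, schedule, seed = NULL,
                                dt = 1e-3) {
  if (is.character(model)) model <- ddm_model(model)
  if (!is.null(seed)) set.seed(seed)
  pars <- resolve_params(model, theta, schedule$norm, schedule$social,
                         schedule$stimulus)
  v_trial <- if (pars$sv[1] > 0) rnorm(nrow(pars), pars$v, pars$sv) else pars$v
  sim <- .sim_wiener_cpp(v_trial, pars$w, pars$a[1], pars$t0[1], dt,
                         schedule$deadline_s[1])
  schedule |>
    dplyr::mutate(
      response = dplyr::case_when(sim$boundary == 1L ~ "right",
                                  sim$boundary == 0L ~ "left"),
      rt_s = sim$rt,
      no_response = is.na(.data$response),
      accuracy = .data$response == .data$stimulus
    )
}

#' Generate a synthetic cohort with a ground-truth sidecar
#'
#' Draws per-subject generating parameters around an experiment preset
#' (truncated-Normal jitter, SD = 25% of each preset magnitude, zero-effect
#' parameters left exact), builds every subject an independent schedule and
#' simulates their trials. Every random stream derives from `master_seed`.
#'
#' @param n_subjects Number of subjects.
#' @param experiment `"bo"` or `"ho"` (ignored when `truths` is supplied).
#' @param truths Optional explicit tibble of per-subject generating
#'   parameters (columns as [preset_truth()], one row per subject).
#' @param master_seed Integer master seed.
#' @param jitter_sd Relative jitter SD around preset values.
#' @param ... Passed to [generate_schedule()].
#'
#' @return List with `data` (all subjects' trials, one row per trial) and
#'   `truth` (the per-subject generating parameters).
#' @examples
#' coh <- generate_cohort(2, "ho", master_seed = 1)
#' dplyr::count(coh$data, subject)
#' @export
generate_cohort <- function(n_subjects, experiment = c("bo", "ho"),
                            truths = NULL, master_seed = 1,
                            jitter_sd = 0.25, ...) {
  set.seed(master_seed)
  if (is.null(truths)) {
    experiment <- match.arg(tolower(experiment), c("bo", "ho"))
    base <- preset_truth(experiment)
    truths <- purrr::map_dfr(seq_len(n_subjects), function(i) {
      tr <- base
      tr$subject <- i
      for (par in c("a", "v_base", "t0", "dw_none", "dw_same", "dw_only",
                    "dv_only")) {
        tr[[par]] <- jitter_truncnorm(base[[par]], jitter_sd, par)
      }
      tr
    })
  } else {
    truths <- tibble::as_tibble(truths)
    if (is.null(truths$subject)) truths$subject <- seq_len(nrow(truths))
    n_subjects <- nrow(truths)
  }
  seeds <- sample.int(.Machine$integer.max - 1L, 2 * n_subjects)
  data <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    sched <- generate_schedule(seed = seeds[2 * i - 1], ...)
    simulate_subject(truths[i, ], sched, seed = seeds[2 * i])
  })
  list(data = data, truth = truths)
}

# truncated-Normal jitter around a preset value; SD relative to magnitude,
# zero-valued presets stay exact; hard floors keep parameters in-domain
jitter_truncnorm <- function(x, rel_sd, par) {
  if (x == 0) return(x)
  s <- rel_sd * abs(x)
  lims <- switch(par,
    a = c(0.3, 5), v_base = c(0.1, 7), t0 = c(0.05, 1),
    dw_none = , dw_same = , dw_only = c(-0.3, 0.3),
    dv_only = c(-2, 2), c(-Inf, Inf))
  u <- runif(1, pnorm(lims[1], x, s), pnorm(lims[2], x, s))
  qnorm(u, x, s)
}
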