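#' Accuracy by subject, norm condition and cue validity
#'
#' Mean proportion of correct responses per subject x norm x validity cell,
#' excluding no-response trials. Empty cells are kept as `NA`.
#'
#' @param data Trial tibble with `subject`, `norm`, `social`, `stimulus`,
#'   `accuracy`, and (optionally) `no_response`.
#' @return A tibble: `subject`, `norm`, `validity`, `n_trials`, `accuracy`.
#' @export
accuracy_table <- function(data) {
  check_trial_data(data, need_response = FALSE)
  scored <- data |>
    dplyr::mutate(validity = cue_validity(.data$social, .data$stimulus)) |>
    dplyr::filter(if ("no_response" %in% names(data)) !.data$no_response else
      !is.na(.data$accuracy)) |>
    dplyr::group_by(.data$subject, .data$norm, .data$validity) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     accuracy = mean(.data$accuracy), .groups = "drop")
  grid <- tidyr::expand_grid(subject = unique(data$subject), norm = .norms,
                             validity = c("valid", "invalid", "incongruent"))
  grid |>
    dplyr::left_join(scored, by = c("subject", "norm", "validity")) |>
    dplyr::mutate(n_trials = dplyr::coalesce(.data$n_trials, 0L)) |>
    dplyr::arrange(.data$subject, match(.data$norm, .norms), .data$validity)
}

#' Norm-induced change in choices toward the social cue
#'
#' On congruent-cue trials, the per-subject probability of responding in
#' the cued direction under the named norm minus the same probability in
#' the no-norm condition. Positive values mean the norm increased
#' cue-following (conformity); range [-1, 1].
#'
#' @param data Trial tibble (as [accuracy_table()], plus `response`).
#' @param norm `"same"` or `"only"`.
#' @return A tibble: `subject`, `norm`, `p_follow`, `p_follow_none`,
#'   `delta`.
#' @export
conformity_delta <- function(data, norm = c("same", "only")) {
  target <- match.arg(norm)
  check_trial_data(data, need_response = FALSE)
  per <- data |>
    dplyr::filter(.data$social != "incongruent", !is.na(.data$response),
                  .data$norm %in% c(target, "none")) |>
    dplyr::mutate(follow = .data$response == cued_side(.data$social)) |>
    dplyr::group_by(.data$subject, .data$norm) |>
    dplyr::summarise(p = mean(.data$follow), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "norm", values_from = "p")
  if (!all(c(target, "none") %in% names(per)) || anyNA(per[[target]]) ||
      anyNA(per$none)) {
    stop("conformity_delta needs congruent-cue trials under both '", target,
         "' and 'none' for every subject", call. = FALSE)
  }
  tibble::tibble(subject = per$subject, norm = target,
                 p_follow = per[[target]], p_follow_none = per$none,
                 delta = per[[target]] - per$none)
}

#' Per-trial payoff under the two norm-strength experiments
#'
#' Scores each phase-two trial by the task's payoff matrix: the player
#' earns 1 cent per correct response; consequences for the other players
#' depend on experiment, norm, cue validity and correctness. In the
#' benefit-others experiment (`bo`) the others gain 1 cent when the player
#' complies with the norm *and* is correct (same-norm: valid cue + correct;
#' only-norm: invalid cue + correct). In the harm-others experiment (`ho`)
#' the others lose 1 cent when the player breaks the norm *and* is wrong
#' (same-norm: valid cue + wrong; only-norm: invalid cue + wrong).
#' No-norm and incongruent-cue trials never affect the others; no-response
#' trials score (0, 0).
#'
#' @param data Trial tibble with `norm`, `social`, `stimulus`, `response`,
#'   `accuracy` (and optionally `experiment`).
#' @param experiment `"bo"` or `"ho"`; defaults to the data's `experiment`
#'   column.
#' @return `data` with added integer columns `points_self` and
#'   `points_others` (cents).
#' @export
payoff <- function(data, experiment = NULL) {
  check_trial_data(data, need_response = FALSE)
  exp_vec <- if (!is.null(experiment)) {
    rep(match.arg(tolower(experiment), c("bo", "ho")), nrow(data))
  } else if ("experiment" %in% names(data)) {
    tolower(data$experiment)
  } else {
    stop("supply `experiment` or an `experiment` column", call. = FALSE)
  }
  validity <- cue_validity(data$social, data$stimulus)
  answered <- !is.na(data$response)
  correct <- answered & data$response == data$stimulus

  others <- dplyr::case_when(
    !answered | validity == "incongruent" | data$norm == "none" ~ 0L,
    exp_vec == "bo" & data$norm == "same" & validity == "valid" & correct ~ 1L,
    exp_vec == "bo" & data$norm == "only" & validity == "invalid" & correct ~ 1L,
    exp_vec == "ho" & data$norm == "same" & validity == "valid" & !correct ~ -1L,
    exp_vec == "ho" & data$norm == "only" & validity == "invalid" & !correct ~ -1L,
    TRUE ~ 0L
  )
  dplyr::mutate(data, points_self = as.integer(correct),
                points_others = others)
}

#' Minimum sample size for a paired t-test
#'
#' Smallest `n` at which the paired (dependent) t-test reaches the target
#' power, via the noncentral t distribution with `df = n - 1` and
#' noncentrality `d * sqrt(n)`. The task's design calculation (5% accuracy
#' change, SD 0.1, so d = 0.5, alpha = 0.05, power = 0.8, one-tailed)
#' returns 27.
#'
#' @param effect_size_d Cohen's d of the paired differences (> 0).
#' @param alpha Type-I error rate.
#' @param power Target power (1 - beta).
#' @param tails 1 or 2.
#' @return Integer minimum `n` (>= 2).
#' @examples
#' required_sample_size(0.5, 0.05, 0.8, tails = 1)  # 27
#' @export
required_sample_size <- function(effect_size_d, alpha = 0.05, power = 0.8,
                                 tails = 1) {
  stopifnot(effect_size_d > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            tails %in% c(1, 2))
  for (n in 2:1e6) {
    if (paired_t_power(n, effect_size_d, alpha, tails) >= power) {
      return(as.integer(n))
    }
  }
  stop("target power unattainable at n <= 1e6", call. = FALSE)
}

paired_t_power <- function(n, d, alpha, tails) {
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 1) {
    pt(qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  } else {
    crit <- qt(1 - alpha / 2, df)
    pt(-crit, df, ncp) + pt(crit, df, ncp, lower.tail = FALSE)
  }
}
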