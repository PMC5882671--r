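#' Accuracy by cue validity and norm condition
#'
#' Cohort means with standard-error bars, the model-free summary of how
#' valid/invalid social cues and norm prompts move accuracy.
#'
#' @param data Trial tibble (one or more subjects).
#' @return A ggplot.
#' @export
plot_accuracy <- function(data) {
  tab <- accuracy_table(data) |>
    dplyr::filter(!is.na(.data$accuracy)) |>
    dplyr::group_by(.data$norm, .data$validity) |>
    dplyr::summarise(mean_acc = mean(.data$accuracy),
                     sem = sd(.data$accuracy) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(norm = factor(.data$norm, .norms),
                  validity = factor(.data$validity,
                                    c("valid", "incongruent", "invalid")))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$validity, y = .data$mean_acc,
                                    colour = .data$norm,
                                    group = .data$norm)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_acc - .data$sem,
                                        ymax = .data$mean_acc + .data$sem),
                           width = 0.15,
                           position = ggplot2::position_dodge(0.3)) +
    ggplot2::labs(x = "social information", y = "accuracy",
                  colour = "norm prompt")
}

#' Norm-induced conformity change
#'
#' Per-subject change in the probability of choosing the cued side under
#' each norm prompt relative to no norm, split by experiment when an
#' `experiment` column is present.
#'
#' @param data Trial tibble.
#' @return A ggplot.
#' @export
plot_conformity <- function(data) {
  deltas <- dplyr::bind_rows(conformity_delta(data, "same"),
                             conformity_delta(data, "only"))
  if ("experiment" %in% names(data)) {
    deltas <- dplyr::left_join(
      deltas, dplyr::distinct(data, .data$subject, .data$experiment),
      by = "subject")
  } else {
    deltas$experiment <- "all"
  }
  summ <- deltas |>
    dplyr::group_by(.data$norm, .data$experiment) |>
    dplyr::summarise(m = mean(.data$delta),
                     sem = sd(.data$delta) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$norm, y = .data$m,
                                     fill = .data$experiment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$sem,
                                        ymax = .data$m + .data$sem),
                           width = 0.2,
                           position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "norm prompt",
                  y = "Δ P(choice toward cue) vs no norm",
                  fill = "experiment")
}

#' Model-averaged condition parameters across subjects
#'
#' Cohort means (with SEM bars) of the WAIC-weighted starting-point bias
#' and drift delta per norm condition.
#'
#' @param averaged Tibble binding each subject's [average_parameters()]
#'   output with a `subject` column (and optionally `experiment`).
#' @return A ggplot, panelled by parameter.
#' @export
plot_averaged_params <- function(averaged) {
  long <- tidyr::pivot_longer(averaged, c("sp_bias", "drift_delta"),
                              names_to = "parameter", values_to = "value")
  grp <- c("condition", "parameter",
           intersect("experiment", names(averaged)))
  summ <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(m = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(condition = factor(.data$condition, .norms))
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$condition, y = .data$m))
  if ("experiment" %in% names(summ)) {
    p <- p + ggplot2::aes(colour = .data$experiment)
  }
  p +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$sem,
                                        ymax = .data$m + .data$sem),
                           width = 0.15,
                           position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "norm condition", y = "weighted estimate")
}
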