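#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy posterior summary of a fitted diffusion model
#'
#' @param x A `ddm_fit`.
#' @param conf_level Central credible-interval mass.
#' @param ... Unused.
#' @return A tibble: `parameter`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`, `conf.high`, `rhat`.
#' @export
tidy.ddm_fit <- function(x, conf_level = 0.95, ...) {
  dm <- draw_matrix(x)
  al <- (1 - conf_level) / 2
  q <- apply(dm, 2, quantile, c(al, 1 - al))
  tibble::tibble(
    parameter = colnames(dm),
    estimate = unname(colMeans(dm)),
    std.error = unname(apply(dm, 2, sd)),
    conf.low = unname(q[1, ]), conf.high = unname(q[2, ]),
    rhat = unname(x$rhat[colnames(dm)])
  )
}

#' One-row summary of a fitted diffusion model
#'
#' @param x A `ddm_fit`.
#' @param ... Unused.
#' @return A tibble: model name, trial and draw counts, mean total
#'   log-likelihood, WAIC, worst R-hat, mean acceptance rate, convergence
#'   flag.
#' @export
glance.ddm_fit <- function(x, ...) {
  w <- waic(x)
  tibble::tibble(
    model = x$model$name,
    n_trials = nrow(x$data),
    n_draws = nrow(x$pointwise),
    n_chains = x$meta$n_chains,
    log_lik = mean(x$log_lik),
    waic = w$waic,
    p_waic = w$p_waic,
    rhat_max = max(x$rhat),
    acceptance = x$meta$acceptance,
    converged = x$meta$converged
  )
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("<ddm_fit> model '", x$model$name, "': ", nrow(x$data), " trials, ",
      x$meta$n_chains, " chains x ", x$meta$n_iter, " retained draws\n",
      sep = "")
  cat("  max R-hat ", round(max(x$rhat), 3),
      if (x$meta$converged) " (converged)" else " (NOT converged)",
      ", mean acceptance ", round(x$meta$acceptance, 2), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Posterior-density panels of a fitted diffusion model
#'
#' @param object A `ddm_fit`.
#' @param ... Unused.
#' @return A ggplot: one density panel per parameter with the posterior
#'   mean marked.
#' @export
autoplot.ddm_fit <- function(object, ...) {
  dm <- draw_matrix(object)
  long <- tibble::as_tibble(dm) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter",
                        values_to = "value")
  means <- dplyr::summarise(dplyr::group_by(long, .data$parameter),
                            m = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$m),
                        linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "posterior density",
                  title = paste0("Posterior, model '", object$model$name, "'"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' True-versus-estimated panels of a recovery study
#'
#' @param object A `ddm_recovery` from [run_recovery()].
#' @param ... Unused.
#' @return A ggplot with identity line, one panel per parameter.
#' @export
autoplot.ddm_recovery <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$converged),
                  ggplot2::aes(x = .data$true, y = .data$estimate)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "true value", y = "posterior mean (95% CrI)",
                  title = "Parameter recovery")
}

#' Observed statistics against posterior predictive intervals
#'
#' @param object A `ddm_ppc` from [run_ppc()].
#' @param ... Unused.
#' @return A ggplot: predictive 95% intervals with observed values
#'   overlaid, panelled by statistic.
#' @export
autoplot.ddm_ppc <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = interaction(.data$norm, .data$validity,
                                               sep = "\n"))) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$pred_lower,
                                         ymax = .data$pred_upper),
                            linewidth = 2, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$inside), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "red"),
                                 name = "inside 95% PI") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Posterior predictive check")
}
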