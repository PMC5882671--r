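#' Parameter-recovery study
#'
#' Simulates subjects from known parameter vectors of a chosen model, fits
#' the same model to each simulated data set and scores how well the truths
#' are recovered: per-parameter posterior mean/SD, central 95% coverage,
#' and the cross-subject correlation between true and estimated values.
#' Non-converged fits are excluded from scoring and counted.
#'
#' @param model A [ddm_model()] or name.
#' @param n_subjects Number of simulated subjects.
#' @param n_trials Trials per subject (schedule scaled from the default
#'   design; must be >= 100 and divisible into the design cells).
#' @param truth `"preset"` (model parameters implied by the experiment
#'   presets, jittered 25% per subject), `"prior"` (truths drawn from the
#'   fitting priors, under which 95% intervals have exactly nominal
#'   coverage), or an explicit `n_subjects x p` matrix/tibble of truths.
#' @param experiment Preset used when `truth = "preset"`.
#' @param seed Master seed.
#' @param fit_args List of arguments passed on to [fit_ddm()] (e.g. smaller
#'   `n_iter` for quick studies).
#'
#' @return A `ddm_recovery` tibble: `subject`, `parameter`, `true`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high`, `covered`,
#'   `converged`; attribute `correlations` holds the per-parameter
#'   cross-subject correlation (`NA` for zero-variance truths), attribute
#'   `n_nonconverged` the exclusion count.
#' @export
run_recovery <- function(model, n_subjects = 10, n_trials = 360,
                         truth = "preset", experiment = "ho", seed = 1,
                         fit_args = list()) {
  if (is.character(model)) model <- ddm_model(model)
  stopifnot(n_trials >= 100)
  set.seed(seed)
  priors <- default_priors(model)

  truths <- if (is.character(truth) && truth[1] == "preset") {
    t(replicate(n_subjects,
                preset_theta(model, experiment = experiment, jitter = TRUE)))
  } else if (is.character(truth) && truth[1] == "prior") {
    t(rprior(priors, n_subjects))
  } else {
    m <- as.matrix(truth)
    colnames(m) <- model$params$name
    m
  }
  colnames(truths) <- model$params$name
  seeds <- sample.int(.Machine$integer.max - 1L, 3 * n_subjects)

  rows <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    sched <- generate_schedule(
      n_trials = n_trials,
      norm_counts = setNames(rep(n_trials / 3, 3), .norms),
      seed = seeds[3 * i - 2])
    dat <- simulate_from_model(model, truths[i, ], sched,
                               seed = seeds[3 * i - 1]) |>
      dplyr::filter(!.data$no_response)
    fit <- rlang::exec(fit_ddm, dat, model, seed = seeds[3 * i],
                       on_nonconvergence = "ignore", !!!fit_args)
    dm <- draw_matrix(fit)
    q <- apply(dm, 2, quantile, c(0.025, 0.975))
    tibble::tibble(
      subject = i, parameter = colnames(dm), true = unname(truths[i, ]),
      estimate = unname(colMeans(dm)), std.error = unname(apply(dm, 2, sd)),
      conf.low = unname(q[1, ]), conf.high = unname(q[2, ]),
      covered = .data$true >= .data$conf.low & .data$true <= .data$conf.high,
      converged = fit$meta$converged)
  })

  scored <- dplyr::filter(rows, .data$converged)
  cors <- scored |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(correlation = if (sd(.data$true) < 1e-12) NA_real_ else
      cor(.data$true, .data$estimate), .groups = "drop")
  structure(rows, class = c("ddm_recovery", class(rows)),
            correlations = cors,
            n_nonconverged = sum(!rows$converged) / n_params(model))
}

# flat theta implied by an experiment preset for a given model (the
# data-generating truth of simulate_subject() expressed in model space)
preset_theta <- function(model, experiment = "ho", jitter = FALSE) {
  if (is.character(model)) model <- ddm_model(model)
  tr <- as.list(preset_truth(experiment))
  if (jitter) {
    for (par in c("a", "v_base", "t0", "dw_none", "dw_same", "dw_only",
                  "dv_only")) {
      tr[[par]] <- jitter_truncnorm(tr[[par]], 0.25, par)
    }
  }
  dw <- c(none = tr$dw_none, same = tr$dw_same, only = tr$dw_only)
  dw_shared <- mean(dw)  # collapsed effect for norm-blind models
  val <- function(nm) {
    if (nm %in% c("a", "t0", "sv")) return(tr[[nm]])
    if (nm %in% c("v_mag", "v_incong")) return(tr$v_base)
    if (nm == "v_cong") return(tr$v_base + tr$dv_only / 3)
    if (startsWith(nm, "v_cong_")) {
      cond <- sub("v_cong_", "", nm)
      return(tr$v_base + if (cond == "only") tr$dv_only else 0)
    }
    if (nm == "w_base") return(0.5)
    if (nm == "w_cong_left") return(0.5 - dw_shared)
    if (nm == "w_cong_right") return(0.5 + dw_shared)
    if (startsWith(nm, "w_cong_left_")) {
      return(0.5 - dw[sub("w_cong_left_", "", nm)])
    }
    if (startsWith(nm, "w_cong_right_")) {
      return(0.5 + dw[sub("w_cong_right_", "", nm)])
    }
    stop("unmapped parameter ", nm)
  }
  setNames(vapply(model$params$name, val, numeric(1)), model$params$name)
}

#' Posterior predictive check of a fitted model
#'
#' Draws `n_reps` parameter vectors from the posterior, simulates the trial
#' schedule under each, and compares observed condition-level statistics
#' (accuracy and RT quantiles 0.1/0.5/0.9 per norm x cue-validity cell)
#' with their central 95% predictive intervals.
#'
#' @param fit A `ddm_fit` from [fit_ddm()].
#' @param schedule Trial schedule to simulate; defaults to the fitted
#'   trials' own schedule columns.
#' @param n_reps Number of posterior replicates (>= 20).
#' @param seed Integer seed (PPC is reproducible given a fixed fit).
#'
#' @return A `ddm_ppc` tibble: `norm`, `validity`, `statistic`, `observed`,
#'   `pred_mean`, `pred_lower`, `pred_upper`, `inside`.
#' @export
run_ppc <- function(fit, schedule = NULL, n_reps = 100, seed = 1) {
  if (n_reps < 20) {
    stop("`n_reps` must be >= 20 for meaningful predictive intervals",
         call. = FALSE)
  }
  set.seed(seed)
  if (is.null(schedule)) {
    schedule <- fit$data
    if (is.null(schedule$deadline_s)) schedule$deadline_s <- 2.5
  }
  dm <- draw_matrix(fit)
  idx <- sample.int(nrow(dm), n_reps, replace = n_reps > nrow(dm))

  observed <- ppc_stats(fit$data)
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    sim <- simulate_from_model(fit$model, dm[idx[r], ], schedule) |>
      dplyr::filter(!.data$no_response)
    dplyr::mutate(dplyr::rename(ppc_stats(sim), value = "observed"), rep = r)
  })
  reps |>
    dplyr::group_by(.data$norm, .data$validity, .data$statistic) |>
    dplyr::summarise(pred_mean = mean(.data$value),
                     pred_lower = quantile(.data$value, 0.025, na.rm = TRUE),
                     pred_upper = quantile(.data$value, 0.975, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::left_join(x = observed, by = c("norm", "validity", "statistic")) |>
    dplyr::mutate(inside = .data$observed >= .data$pred_lower &
                    .data$observed <= .data$pred_upper) |>
    structure(class = c("ddm_ppc", class(observed)))
}

ppc_stats <- function(data) {
  data |>
    dplyr::mutate(validity = cue_validity(.data$social, .data$stimulus)) |>
    dplyr::group_by(.data$norm, .data$validity) |>
    dplyr::summarise(
      accuracy = mean(.data$accuracy),
      rt_q10 = quantile(.data$rt_s, 0.1), rt_q50 = quantile(.data$rt_s, 0.5),
      rt_q90 = quantile(.data$rt_s, 0.9), .groups = "drop") |>
    tidyr::pivot_longer(c("accuracy", "rt_q10", "rt_q50", "rt_q90"),
                        names_to = "statistic", values_to = "observed")
}
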