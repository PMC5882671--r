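#' Run configuration for the end-to-end pipeline
#'
#' A validated list of settings from which every pipeline stage derives its
#' behaviour and random streams; one config fully determines all outputs.
#' Unknown keys are rejected by name.
#'
#' @param ... Overrides of the defaults: `seed` (master seed),
#'   `experiment` (`"bo"`/`"ho"`), `n_subjects`, `models` (character subset
#'   of [model_names()]), `n_trials`, `deadline`, `sampler` (list with
#'   `n_iter`, `burn_in`, `chains_per_param`), `out_dir`.
#' @param file Optional YAML file of overrides (applied before `...`).
#' @return A list of class `dust_config`.
#' @examples
#' cfg <- dust_config(seed = 7, n_subjects = 2, experiment = "ho")
#' @export
dust_config <- function(..., file = NULL) {
  defaults <- list(
    seed = 1L,
    experiment = "ho",
    n_subjects = 6L,
    models = model_names(),
    n_trials = 360L,
    deadline = 2.5,
    sampler = list(n_iter = 1000L, burn_in = 500L, chains_per_param = 3L),
    out_dir = "dust_run"
  )
  overrides <- list(...)
  if (!is.null(file)) {
    overrides <- modifyList(yaml::read_yaml(file), overrides)
  }
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(overrides$sampler)) {
    bad_s <- setdiff(names(overrides$sampler), names(defaults$sampler))
    if (length(bad_s)) {
      stop("unknown sampler config key(s): ", paste(bad_s, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg <- modifyList(defaults, overrides)
  cfg$experiment <- match.arg(tolower(cfg$experiment), c("bo", "ho"))
  unknown_models <- setdiff(tolower(cfg$models), model_names())
  if (length(unknown_models)) {
    stop("unknown model(s) in config: ",
         paste(unknown_models, collapse = ", "), call. = FALSE)
  }
  cfg$models <- tolower(cfg$models)
  structure(cfg, class = "dust_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(config, stage, dir) {
  meta <- list(stage = stage, config = unclass(config),
               config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("dustddm")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

subject_file <- function(dir, i) {
  file.path(dir, sprintf("subject_%03d.csv", i))
}

#' Simulate a synthetic cohort to disk
#'
#' Writes one trial CSV per subject (RTs to 6 decimal places) plus a
#' ground-truth sidecar (`truth.csv`) and a provenance record. Re-running
#' with an unchanged config reproduces the files byte-for-byte.
#'
#' @param config A [dust_config()].
#' @return Invisibly, the output directory.
#' @export
dust_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  coh <- generate_cohort(config$n_subjects, config$experiment,
                         master_seed = config$seed,
                         n_trials = config$n_trials,
                         norm_counts = setNames(rep(config$n_trials / 3, 3),
                                                .norms),
                         deadline = config$deadline)
  for (i in unique(coh$data$subject)) {
    coh$data |>
      dplyr::filter(.data$subject == i) |>
      dplyr::mutate(rt_s = round(.data$rt_s, 6),
                    prompt_s = round(.data$prompt_s, 6)) |>
      readr::write_csv(subject_file(config$out_dir, i), na = "")
  }
  readr::write_csv(coh$truth, file.path(config$out_dir, "truth.csv"))
  write_provenance(config, "simulate", config$out_dir)
  invisible(config$out_dir)
}

#' Read a cohort written by [dust_simulate()] (or conforming CSVs)
#'
#' @param dir Directory of `subject_*.csv` files.
#' @return One tibble of all subjects' trials.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, "^subject_\\d+\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no subject_*.csv files in ", dir, call. = FALSE)
  purrr::map_dfr(files, read_trials)
}

read_trials <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject", "norm", "social", "stimulus", "response", "rt_s",
           "no_response")
  miss <- setdiff(req, names(dat))
  if (length(miss)) {
    stop("malformed trial file ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!dat$norm %in% .norms | !dat$social %in% .socials |
                 !dat$stimulus %in% .stimuli)
  if (length(bad)) {
    stop("malformed trial file ", basename(path), ": invalid norm/social/",
         "stimulus at row(s) ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  dat
}

#' Fit the configured models to every subject
#'
#' Fits each model in `config$models` to each subject's responded trials,
#' writing one `.rds` fit container per subject x model (posterior draws,
#' pointwise log-likelihoods, diagnostics, seed) and a `fits_index.csv` of
#' glance summaries.
#'
#' @param config A [dust_config()].
#' @param data_dir Directory of trial CSVs; defaults to `config$out_dir`.
#' @return Invisibly, the fit index tibble.
#' @export
dust_fit <- function(config, data_dir = config$out_dir) {
  data <- read_cohort(data_dir)
  fit_dir <- file.path(config$out_dir, "fits")
  dir.create(fit_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  subjects <- sort(unique(data$subject))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(subjects) * length(config$models)),
                  nrow = length(subjects))
  index <- purrr::map_dfr(seq_along(subjects), function(si) {
    sdat <- dplyr::filter(data, .data$subject == subjects[si],
                          !.data$no_response)
    purrr::map_dfr(seq_along(config$models), function(mi) {
      m <- ddm_model(config$models[mi])
      fit <- fit_ddm(sdat, m,
                     n_chains = config$sampler$chains_per_param * n_params(m),
                     n_iter = config$sampler$n_iter,
                     burn_in = config$sampler$burn_in,
                     seed = seeds[si, mi], on_nonconvergence = "warn")
      saveRDS(fit, file.path(fit_dir, sprintf("fit_s%03d_%s.rds",
                                              subjects[si], m$name)))
      dplyr::bind_cols(tibble::tibble(subject = subjects[si]), glance(fit))
    })
  })
  readr::write_csv(index, file.path(config$out_dir, "fits_index.csv"))
  write_provenance(config, "fit", config$out_dir)
  invisible(index)
}

#' WAIC comparison and model-averaged parameters for a fitted cohort
#'
#' Writes `comparison.csv` (per subject x model: WAIC, components, weight,
#' worst R-hat) and `averaged_params.csv` (per subject x condition:
#' WAIC-weighted starting-point bias and drift delta; requires all six
#' models in the config).
#'
#' @param config A [dust_config()].
#' @return Invisibly, a list of the two tibbles.
#' @export
dust_compare <- function(config) {
  fit_dir <- file.path(config$out_dir, "fits")
  files <- list.files(fit_dir, "^fit_s\\d+_.*\\.rds$", full.names = TRUE)
  if (!length(files)) stop("no fit files under ", fit_dir, call. = FALSE)
  subjects <- sort(unique(as.integer(sub("^fit_s(\\d+)_.*", "\\1",
                                         basename(files)))))
  comparison <- NULL
  averaged <- NULL
  for (s in subjects) {
    fits <- purrr::map(config$models, function(m) {
      readRDS(file.path(fit_dir, sprintf("fit_s%03d_%s.rds", s, m)))
    })
    names(fits) <- config$models
    comparison <- dplyr::bind_rows(comparison, compare_models(fits, subject = s))
    if (setequal(config$models, model_names())) {
      averaged <- dplyr::bind_rows(
        averaged,
        dplyr::bind_cols(tibble::tibble(subject = s),
                         average_parameters(fits)))
    }
  }
  readr::write_csv(comparison, file.path(config$out_dir, "comparison.csv"))
  if (!is.null(averaged)) {
    readr::write_csv(averaged, file.path(config$out_dir,
                                         "averaged_params.csv"))
  }
  write_provenance(config, "compare", config$out_dir)
  invisible(list(comparison = comparison, averaged = averaged))
}

#' Parameter-recovery stage of the pipeline
#'
#' @param config A [dust_config()].
#' @param model Model to recover (default `"reduced"`).
#' @param n_subjects Simulated subjects (defaults to the config's cohort
#'   size).
#' @return Invisibly, the `ddm_recovery` tibble (also written to
#'   `recovery.csv` with its correlations in `recovery_correlations.csv`).
#' @export
dust_recover <- function(config, model = "reduced",
                         n_subjects = config$n_subjects) {
  rec <- run_recovery(model, n_subjects = n_subjects,
                      n_trials = config$n_trials, seed = config$seed + 2L,
                      experiment = config$experiment,
                      fit_args = list(
                        n_iter = config$sampler$n_iter,
                        burn_in = config$sampler$burn_in))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(rec, file.path(config$out_dir, "recovery.csv"))
  readr::write_csv(attr(rec, "correlations"),
                   file.path(config$out_dir, "recovery_correlations.csv"))
  write_provenance(config, "recover", config$out_dir)
  invisible(rec)
}

#' Posterior-predictive-check stage of the pipeline
#'
#' Runs [run_ppc()] on every stored subject x model fit for the configured
#' models and writes `ppc.csv`.
#'
#' @param config A [dust_config()].
#' @param n_reps Posterior replicates per fit.
#' @return Invisibly, the combined PPC tibble.
#' @export
dust_ppc <- function(config, n_reps = 100) {
  fit_dir <- file.path(config$out_dir, "fits")
  files <- list.files(fit_dir, "^fit_s\\d+_.*\\.rds$", full.names = TRUE)
  files <- files[sub("^fit_s\\d+_(.*)\\.rds$", "\\1", basename(files)) %in%
                   config$models]
  if (!length(files)) stop("no fit files under ", fit_dir, call. = FALSE)
  out <- purrr::map_dfr(files, function(f) {
    fit <- readRDS(f)
    ppc <- run_ppc(fit, n_reps = n_reps, seed = config$seed + 3L)
    dplyr::mutate(ppc,
                  subject = as.integer(sub("^fit_s(\\d+)_.*", "\\1",
                                           basename(f))),
                  model = fit$model$name)
  })
  readr::write_csv(out, file.path(config$out_dir, "ppc.csv"))
  write_provenance(config, "ppc", config$out_dir)
  invisible(out)
}

#' Plain-text summary report of a pipeline run
#'
#' Summarises the cohort's accuracy by condition, conformity deltas, mean
#' WAIC weights, and cohort-mean model-averaged parameters into
#' `report.txt`.
#'
#' @param config A [dust_config()].
#' @return Invisibly, the report path.
#' @export
dust_report <- function(config) {
  data <- read_cohort(config$out_dir)
  lines <- c("Synthetic social-norm diffusion pipeline report",
             paste0("config hash: ", config_hash(config)),
             paste0("experiment: ", config$experiment, ", subjects: ",
                    length(unique(data$subject))), "")

  acc <- accuracy_table(data) |>
    dplyr::group_by(.data$norm, .data$validity) |>
    dplyr::summarise(accuracy = mean(.data$accuracy, na.rm = TRUE),
                     .groups = "drop")
  lines <- c(lines, "Mean accuracy by norm x validity:",
             utils::capture.output(as.data.frame(acc)), "")

  for (nm in c("same", "only")) {
    cd <- conformity_delta(data, nm)
    lines <- c(lines, sprintf("Mean conformity delta (%s vs none): %+.3f",
                              nm, mean(cd$delta)))
  }

  cmp_file <- file.path(config$out_dir, "comparison.csv")
  if (file.exists(cmp_file)) {
    cmp <- readr::read_csv(cmp_file, show_col_types = FALSE)
    wts <- cmp |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(mean_weight = mean(.data$weight), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$mean_weight))
    lines <- c(lines, "", "Mean WAIC weights:",
               utils::capture.output(as.data.frame(wts)))
  }
  avg_file <- file.path(config$out_dir, "averaged_params.csv")
  if (file.exists(avg_file)) {
    avg <- readr::read_csv(avg_file, show_col_types = FALSE) |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(sp_bias = mean(.data$sp_bias),
                       drift_delta = mean(.data$drift_delta),
                       .groups = "drop") |>
      dplyr::arrange(match(.data$condition, .norms))
    lines <- c(lines, "", "Cohort-mean model-averaged parameters:",
               utils::capture.output(as.data.frame(avg)))
  }
  path <- file.path(config$out_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
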