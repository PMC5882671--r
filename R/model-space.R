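#' The six competing model parametrizations
#'
#' Each model maps a trial context — norm prompt (`none`/`same`/`only`),
#' social-cue configuration (`incongruent`/`congruent_left`/
#' `congruent_right`) and true stimulus direction — to a concrete diffusion
#' parameter set. Threshold separation `a`, non-decision time `t0` and drift
#' variability `sv` are always shared across contexts; models differ in how
#' many starting-point and drift-magnitude parameters they carry:
#'
#' * `reduced` (5): one starting point, one drift magnitude — social cues
#'   have no effect.
#' * `sp_reduced` (7): adds starting points for congruent-left and
#'   congruent-right cues, shared across norm conditions.
#' * `sp` (11): the two congruent starting points vary by norm condition.
#' * `drift_reduced` (6): separate drift magnitudes for incongruent vs
#'   congruent cue trials.
#' * `drift` (8): the congruent drift magnitude varies by norm condition.
#' * `spdr` (14): union of `sp`'s starting points and `drift`'s drifts.
#'
#' Drift magnitudes are signed at resolution time by the stimulus: positive
#' toward the upper/right boundary for rightward motion, negative for
#' leftward. In starting-point models the congruent-cue drift is the shared
#' magnitude; congruent cues act only on `w` there.
#'
#' @param name Model name, one of
#'   `r paste0('\x60', c("reduced","sp_reduced","sp","drift_reduced","drift","spdr"), '\x60', collapse = ", ")`.
#'
#' @return An object of class `ddm_model`: parameter table (`$params`, with
#'   a prior `type` per parameter), the 18-row context map (`$context_map`)
#'   and the model `$name`.
#' @examples
#' m <- ddm_model("sp_reduced")
#' m$params
#' @export
ddm_model <- function(name) {
  name <- tolower(name)
  if (!name %in% model_names()) {
    stop("unknown model '", name, "'; valid names: ",
         paste(model_names(), collapse = ", "), call. = FALSE)
  }

  grid <- tidyr::expand_grid(norm = .norms, social = .socials,
                             stimulus = .stimuli)

  w_par <- switch(name,
    reduced = ,
    drift_reduced = ,
    drift = rep("w_base", nrow(grid)),
    sp_reduced = dplyr::case_when(
      grid$social == "congruent_left" ~ "w_cong_left",
      grid$social == "congruent_right" ~ "w_cong_right",
      TRUE ~ "w_base"),
    sp = ,
    spdr = dplyr::case_when(
      grid$social == "congruent_left" ~ paste0("w_cong_left_", grid$norm),
      grid$social == "congruent_right" ~ paste0("w_cong_right_", grid$norm),
      TRUE ~ "w_base")
  )
  v_par <- switch(name,
    reduced = ,
    sp_reduced = ,
    sp = rep("v_mag", nrow(grid)),
    drift_reduced = ifelse(grid$social == "incongruent", "v_incong", "v_cong"),
    drift = ,
    spdr = ifelse(grid$social == "incongruent", "v_incong",
                  paste0("v_cong_", grid$norm))
  )

  map <- dplyr::mutate(grid, w_par = w_par, v_par = v_par,
                       v_sign = ifelse(.data$stimulus == "right", 1, -1))

  par_names <- c("a", sort(unique(w_par)), sort(unique(v_par)), "t0", "sv")
  params <- tibble::tibble(
    name = par_names,
    type = dplyr::case_when(
      par_names == "a" ~ "a",
      par_names == "t0" ~ "t0",
      par_names == "sv" ~ "sv",
      startsWith(par_names, "w") ~ "w",
      TRUE ~ "v")
  )

  structure(list(name = name, params = params, context_map = map),
            class = "ddm_model")
}

#' @rdname ddm_model
#' @export
model_names <- function() {
  c("reduced", "sp_reduced", "sp", "drift_reduced", "drift", "spdr")
}

#' @export
print.ddm_model <- function(x, ...) {
  cat("<ddm_model> ", x$name, " (", nrow(x$params), " parameters)\n", sep = "")
  cat(" ", paste(x$params$name, collapse = ", "), "\n")
  invisible(x)
}

#' Number of free parameters of a model
#' @param model A [ddm_model()].
#' @return Integer count.
#' @export
n_params <- function(model) nrow(model$params)

#' Resolve a flat parameter vector for trial contexts
#'
#' Maps each trial context to the concrete diffusion parameters implied by
#' `model` and `theta`. Vectorised over contexts.
#'
#' @param model A [ddm_model()].
#' @param theta Numeric vector of length [n_params()]; if named, names must
#'   match the model's parameter names (any order), otherwise positional in
#'   the order of `model$params$name`.
#' @param norm,social,stimulus Context vectors (recycled to a common
#'   length).
#'
#' @return A tibble with one row per context and columns
#'   `a, w, v, t0, sv` (drift already signed by the stimulus direction).
#' @examples
#' m <- ddm_model("reduced")
#' resolve_params(m, c(1.2, 0.5, 0.7, 0.3, 0), "none", "incongruent",
#'                c("left", "right"))
#' @export
resolve_params <- function(model, theta, norm, social, stimulus) {
  theta <- check_theta(model, theta)
  ctx <- vctrs_recycle(norm = norm, social = social, stimulus = stimulus)
  check_context(ctx)
  map <- dplyr::left_join(ctx, model$context_map,
                          by = c("norm", "social", "stimulus"))
  tibble::tibble(
    a = theta[["a"]],
    w = unname(theta[map$w_par]),
    v = unname(theta[map$v_par]) * map$v_sign,
    t0 = theta[["t0"]],
    sv = theta[["sv"]]
  )
}

check_theta <- function(model, theta) {
  if (length(theta) != n_params(model)) {
    stop("`theta` has length ", length(theta), " but model '", model$name,
         "' has ", n_params(model), " parameters", call. = FALSE)
  }
  if (is.null(names(theta))) {
    names(theta) <- model$params$name
  } else if (!setequal(names(theta), model$params$name)) {
    stop("`theta` names do not match model parameters", call. = FALSE)
  }
  theta
}

check_context <- function(ctx) {
  bad <- !ctx$norm %in% .norms | !ctx$social %in% .socials |
    !ctx$stimulus %in% .stimuli
  if (any(bad)) {
    stop("invalid trial context in row(s) ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  invisible(ctx)
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  tibble::as_tibble(lapply(args, rep_len, length.out = n))
}

#' Cue validity of a trial context
#'
#' Congruent arrows are `valid` when they point in the true motion
#' direction, `invalid` otherwise; incongruent arrows (the dots-only
#' condition) are `incongruent`.
#'
#' @param social,stimulus Context vectors.
#' @return Character vector in `valid`/`invalid`/`incongruent`.
#' @export
cue_validity <- function(social, stimulus) {
  dplyr::case_when(
    social == "incongruent" ~ "incongruent",
    social == paste0("congruent_", stimulus) ~ "valid",
    TRUE ~ "invalid"
  )
}

#' Side a congruent cue points toward
#' @param social Social-cue configuration vector.
#' @return `"left"`, `"right"`, or `NA` for incongruent cues.
#' @export
cued_side <- function(social) {
  dplyr::case_when(
    social == "congruent_left" ~ "left",
    social == "congruent_right" ~ "right"
  )
}
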