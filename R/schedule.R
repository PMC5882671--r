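#' Generate a task trial schedule
#'
#' Builds the phase-two trial plan of the social motion-discrimination
#' task: by default 360 trials, 120 per norm condition (`none`/`same`/
#' `only`) with no more than `max_run` consecutive trials sharing a norm,
#' and social cues stratified within each norm condition at 40% valid /
#' 30% invalid / 30% incongruent with stimulus direction balanced
#' left/right within every norm-by-validity cell. All counts are exact,
#' not expected. `phase = 1` instead yields a familiarisation block
#' (default 150 trials, all `none`, all incongruent cues, balanced
#' stimulus).
#'
#' @param n_trials Total number of trials.
#' @param norm_counts Named integer vector of trials per norm condition;
#'   must sum to `n_trials`.
#' @param social_props Named proportions (`valid`, `invalid`,
#'   `incongruent`); each norm condition's `count x proportion` must be a
#'   whole number divisible by 2 (left/right balance).
#' @param max_run Maximum run length of identical norm conditions.
#' @param phase 1 or 2.
#' @param seed Optional integer seed (schedules are reproducible per seed).
#' @param deadline,iti_s Response deadline and inter-trial interval,
#'   seconds.
#' @param prompt_range Range the norm-prompt duration is drawn from
#'   (uniform), seconds.
#' @param coherence Motion-strength proxy carried through to the output
#'   (arbitrary units; difficulty itself is encoded in the drift rate).
#'
#' @return A tibble with one row per trial: `trial`, `phase`, `norm`,
#'   `social`, `stimulus`, `validity`, `coherence`, `prompt_s`,
#'   `deadline_s`, `iti_s`.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' table(sched$norm)
#' @export
generate_schedule <- function(n_trials = 360,
                              norm_counts = c(none = 120, same = 120, only = 120),
                              social_props = c(valid = 0.4, invalid = 0.3,
                                               incongruent = 0.3),
                              max_run = 3, phase = 2, seed = NULL,
                              deadline = 2.5, iti_s = 3,
                              prompt_range = c(0.5, 1), coherence = NA_real_) {
  if (!is.null(seed)) set.seed(seed)
  if (phase == 1) {
    # familiarisation block: no norm alternation to constrain
    norm_counts <- c(none = n_trials)
    social_props <- c(valid = 0, invalid = 0, incongruent = 1)
    max_run <- n_trials
  }
  norm_counts <- norm_counts[norm_counts > 0]
  if (sum(norm_counts) != n_trials) {
    stop("`norm_counts` must sum to `n_trials`", call. = FALSE)
  }
  if (abs(sum(social_props) - 1) > 1e-9) {
    stop("`social_props` must sum to 1", call. = FALSE)
  }

  # per-norm (social, stimulus) cell sizes; all must be whole
  cells <- purrr::imap(norm_counts, function(cnt, nm) {
    sizes <- social_props * cnt
    if (any(abs(sizes - round(sizes)) > 1e-9)) {
      stop("social proportions x norm count must be integral (norm '",
           nm, "')", call. = FALSE)
    }
    sizes <- round(sizes)
    halves <- sizes / 2
    if (any(abs(halves - round(halves)) > 1e-9)) {
      stop("cells must split evenly over left/right stimuli (norm '",
           nm, "')", call. = FALSE)
    }
    pool <- tibble::tibble(
      social = rep(c("congruent_left", "congruent_right",   # valid
                     "congruent_right", "congruent_left",   # invalid
                     "incongruent", "incongruent"),
                   times = rep(halves[c("valid", "valid", "invalid",
                                        "invalid", "incongruent",
                                        "incongruent")], 1)),
      stimulus = rep(c("left", "right", "left", "right", "left", "right"),
                     times = halves[c("valid", "valid", "invalid", "invalid",
                                      "incongruent", "incongruent")])
    )
    pool[sample.int(nrow(pool)), ]
  })

  norm_seq <- sample_norm_sequence(norm_counts, max_run)

  out <- tibble::tibble(
    trial = seq_len(n_trials), phase = phase, norm = norm_seq,
    social = NA_character_, stimulus = NA_character_
  )
  for (nm in names(norm_counts)) {
    idx <- which(out$norm == nm)
    out$social[idx] <- cells[[nm]]$social
    out$stimulus[idx] <- cells[[nm]]$stimulus
  }
  out |>
    dplyr::mutate(
      validity = cue_validity(.data$social, .data$stimulus),
      coherence = coherence,
      prompt_s = runif(n_trials, prompt_range[1], prompt_range[2]),
      deadline_s = deadline, iti_s = iti_s)
}

# constrained sequential sampling of the norm order (max-run restriction),
# probability proportional to remaining counts, with bounded restarts
sample_norm_sequence <- function(norm_counts, max_run, max_attempts = 200) {
  norms <- names(norm_counts)
  n <- sum(norm_counts)
  if (length(norms) == 1) {
    if (n > max_run) {
      stop("norm schedule infeasible: a single condition cannot satisfy ",
           "max_run = ", max_run, call. = FALSE)
    }
    return(rep(norms, n))
  }
  for (attempt in seq_len(max_attempts)) {
    remaining <- norm_counts
    seq_out <- character(n)
    run_len <- 0L
    ok <- TRUE
    for (i in seq_len(n)) {
      avail <- remaining > 0
      if (i > 1 && run_len >= max_run) avail[seq_out[i - 1]] <- FALSE
      if (!any(avail)) { ok <- FALSE; break }
      pick <- sample(norms, 1, prob = remaining * avail)
      run_len <- if (i > 1 && pick == seq_out[i - 1]) run_len + 1L else 1L
      seq_out[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
    }
    if (ok) return(seq_out)
  }
  stop("norm schedule infeasible: no valid sequence found in ",
       max_attempts, " attempts (counts ",
       paste(norm_counts, collapse = "/"), ", max_run ", max_run, ")",
       call. = FALSE)
}
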