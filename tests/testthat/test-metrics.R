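test_that("accuracy table: all-correct toy data scores 1 everywhere", {
  dat <- generate_schedule(seed = 70) |>
    dplyr::mutate(subject = 1, response = stimulus, rt_s = 0.5,
                  accuracy = TRUE, no_response = FALSE)
  tab <- accuracy_table(dat)
  expect_true(all(tab$accuracy == 1))
  expect_equal(nrow(tab), 9)
})

test_that("accuracy table marks empty cells as missing, not errors", {
  dat <- generate_schedule(seed = 71) |>
    dplyr::mutate(subject = 1, response = stimulus, rt_s = 0.5,
                  accuracy = TRUE, no_response = FALSE) |>
    dplyr::filter(!(norm == "only" & validity == "valid"))
  tab <- accuracy_table(dat)
  gap <- dplyr::filter(tab, norm == "only", validity == "valid")
  expect_true(is.na(gap$accuracy))
  expect_equal(gap$n_trials, 0L)
})

test_that("no-effect synthetic subjects sit near 70% in every cell", {
  truth <- preset_truth("bo")
  truth$dw_none <- truth$dw_same <- truth$dw_only <- truth$dv_only <- 0
  dat <- purrr::map_dfr(1:8, function(i) {
    dplyr::mutate(
      simulate_subject(truth, generate_schedule(seed = 700 + i),
                       seed = 800 + i),
      subject = i)
  })
  tab <- accuracy_table(dat) |>
    dplyr::group_by(norm, validity) |>
    dplyr::summarise(acc = mean(accuracy), n = sum(n_trials),
                     .groups = "drop")
  # each of the 9 cells within 4 binomial SEs of the calibrated value
  expect_true(all(abs(tab$acc - 0.6998) <
                    4 * sqrt(0.6998 * 0.3002 / tab$n)))
})

test_that("conformity deltas: identical behaviour gives 0, extremes give 1", {
  sched <- generate_schedule(seed = 72)
  flat <- sched |>
    dplyr::mutate(subject = 1, response = stimulus, rt_s = 0.5,
                  accuracy = TRUE, no_response = FALSE)
  expect_equal(conformity_delta(flat, "same")$delta, 0)
  expect_equal(conformity_delta(flat, "only")$delta, 0)

  extreme <- sched |>
    dplyr::mutate(
      subject = 1,
      response = dplyr::case_when(
        norm == "same" & social != "incongruent" ~ cued_side(social),
        social == "congruent_left" ~ "right",
        social == "congruent_right" ~ "left",
        TRUE ~ stimulus),
      rt_s = 0.5, no_response = FALSE,
      accuracy = response == stimulus)
  expect_equal(conformity_delta(extreme, "same")$delta, 1)
})

test_that("conformity identity: follow rate is accuracy on valid cues", {
  set.seed(73)
  dat <- generate_schedule(seed = 74) |>
    dplyr::mutate(subject = 1,
                  response = sample(c("left", "right"), 360, replace = TRUE),
                  rt_s = 0.6, no_response = FALSE,
                  accuracy = response == stimulus,
                  validity = cue_validity(social, stimulus))
  cong <- dplyr::filter(dat, validity != "incongruent")
  follow <- cong$response == cued_side(cong$social)
  expect_equal(mean(follow[cong$validity == "valid"]),
               mean(cong$accuracy[cong$validity == "valid"]))
  expect_equal(mean(follow[cong$validity == "invalid"]),
               1 - mean(cong$accuracy[cong$validity == "invalid"]))
})

test_that("conformity requires congruent trials in both conditions", {
  dat <- generate_schedule(seed = 75) |>
    dplyr::mutate(subject = 1, response = stimulus, rt_s = 0.5,
                  accuracy = TRUE, no_response = FALSE) |>
    dplyr::filter(!(norm == "none" & social != "incongruent"))
  expect_error(conformity_delta(dat, "same"), "congruent")
})

test_that("payoff reproduces the full payoff matrix by enumeration", {
  grid <- tidyr::expand_grid(
    experiment = c("bo", "ho"),
    norm = c("none", "same", "only"),
    validity = c("valid", "invalid", "incongruent"),
    correct = c(TRUE, FALSE)) |>
    dplyr::mutate(
      stimulus = "right",
      social = dplyr::case_when(validity == "valid" ~ "congruent_right",
                                validity == "invalid" ~ "congruent_left",
                                TRUE ~ "incongruent"),
      response = ifelse(correct, "right", "left"),
      subject = 1, rt_s = 0.5, accuracy = correct, no_response = FALSE)
  out <- payoff(grid)
  expect_equal(out$points_self, as.integer(grid$correct))

  expected_others <- function(experiment, norm, validity, correct) {
    if (norm == "none" || validity == "incongruent") return(0L)
    if (experiment == "bo") {
      if (norm == "same" && validity == "valid" && correct) return(1L)
      if (norm == "only" && validity == "invalid" && correct) return(1L)
      return(0L)
    }
    if (norm == "same" && validity == "valid" && !correct) return(-1L)
    if (norm == "only" && validity == "invalid" && !correct) return(-1L)
    0L
  }
  want <- purrr::pmap_int(grid[c("experiment", "norm", "validity",
                                 "correct")], expected_others)
  expect_equal(out$points_others, want)
  # the three worked examples of the matrix
  g <- function(e, n, v, c) out$points_others[grid$experiment == e &
    grid$norm == n & grid$validity == v & grid$correct == c]
  expect_equal(g("bo", "same", "valid", TRUE), 1L)
  expect_equal(g("ho", "same", "valid", FALSE), -1L)
  expect_equal(g("ho", "only", "invalid", FALSE), -1L)
})

test_that("self points sum to the number of correct responses", {
  dat <- simulate_subject(preset_truth("ho"), generate_schedule(seed = 76),
                          seed = 77)
  out <- payoff(dat)
  expect_equal(sum(out$points_self),
               sum(dat$accuracy & !dat$no_response, na.rm = TRUE))
  nr <- dplyr::filter(out, no_response)
  expect_true(all(nr$points_self == 0L & nr$points_others == 0L))
})

test_that("paired t-test sample size reproduces the design value 27", {
  expect_identical(required_sample_size(0.5, 0.05, 0.8, tails = 1), 27L)
})

test_that("sample size saturates for huge effects and scans two-tailed", {
  expect_lte(required_sample_size(3, 0.05, 0.8, tails = 1), 3L)
  # two-tailed scan lands at 34; cross-check the noncentral-t power with a
  # simulated one-sample t-test on the paired differences
  n2 <- required_sample_size(0.5, 0.05, 0.8, tails = 2)
  expect_identical(n2, 34L)
  sim_power <- function(n, reps = 4000) {
    set.seed(78)
    mean(replicate(reps, t.test(rnorm(n, 0.5, 1))$p.value < 0.05))
  }
  mc_se <- sqrt(0.8 * 0.2 / 4000)
  expect_gte(sim_power(n2), 0.8 - 3 * mc_se)     # at n2, power >= 0.8
  expect_lte(sim_power(n2 - 1), 0.8 + 3 * mc_se) # just below at n2 - 1
})

test_that("sample size is monotone in effect, alpha, and power", {
  expect_gte(required_sample_size(0.4), required_sample_size(0.5))
  expect_gte(required_sample_size(0.5, alpha = 0.01),
             required_sample_size(0.5, alpha = 0.05))
  expect_gte(required_sample_size(0.5, power = 0.9),
             required_sample_size(0.5, power = 0.8))
})
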