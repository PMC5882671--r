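test_that("the six models carry the documented parameter counts", {
  counts <- c(reduced = 5, sp_reduced = 7, sp = 11, drift_reduced = 6,
              drift = 8, spdr = 14)
  for (nm in names(counts)) {
    expect_equal(n_params(ddm_model(nm)), unname(counts[nm]), info = nm)
  }
  expect_error(ddm_model("fancy"), "reduced, sp_reduced")
})

test_that("reduced maps every context to one starting point and one drift", {
  m <- ddm_model("reduced")
  expect_equal(nrow(m$context_map), 18)
  expect_equal(unique(m$context_map$w_par), "w_base")
  expect_equal(unique(m$context_map$v_par), "v_mag")
})

test_that("sp_reduced shares congruent starting points across norms", {
  m <- ddm_model("sp_reduced")
  cl <- dplyr::filter(m$context_map, social == "congruent_left")
  cr <- dplyr::filter(m$context_map, social == "congruent_right")
  ic <- dplyr::filter(m$context_map, social == "incongruent")
  expect_equal(unique(cl$w_par), "w_cong_left")
  expect_equal(unique(cr$w_par), "w_cong_right")
  expect_equal(unique(ic$w_par), "w_base")
})

test_that("drift model separates congruent drifts by norm condition", {
  m <- ddm_model("drift")
  cong <- dplyr::filter(m$context_map, social != "incongruent")
  expect_setequal(unique(cong$v_par),
                  c("v_cong_none", "v_cong_same", "v_cong_only"))
  expect_equal(
    unique(dplyr::filter(m$context_map, social == "incongruent")$v_par),
    "v_incong")
})

test_that("every context resolves for every model without fallback", {
  grid <- tidyr::expand_grid(norm = c("none", "same", "only"),
                             social = c("incongruent", "congruent_left",
                                        "congruent_right"),
                             stimulus = c("left", "right"))
  for (nm in model_names()) {
    m <- ddm_model(nm)
    th <- theta_at_prior_means(m)
    pars <- resolve_params(m, th, grid$norm, grid$social, grid$stimulus)
    expect_false(anyNA(pars), info = nm)
    expect_true(all(pars$w > 0 & pars$w < 1), info = nm)
  }
})

test_that("stimulus coding flips the drift sign, not the starting point", {
  m <- ddm_model("reduced")
  th <- c(a = 1.2, w_base = 0.45, v_mag = 0.7, t0 = 0.3, sv = 0.2)
  pr <- resolve_params(m, th, "none", "incongruent", "right")
  pl <- resolve_params(m, th, "none", "incongruent", "left")
  expect_equal(pr$v, 0.7)
  expect_equal(pl$v, -0.7)
  expect_equal(pr$w, pl$w)
})

test_that("left/right congruent parameters mirror around 0.5 when set so", {
  m <- ddm_model("sp")
  th <- setNames(rep(0, n_params(m)), m$params$name)
  th[c("a", "v_mag", "t0", "sv", "w_base")] <- c(1.2, 0.7, 0.3, 0, 0.5)
  th[paste0("w_cong_left_", c("none", "same", "only"))] <- 0.4
  th[paste0("w_cong_right_", c("none", "same", "only"))] <- 0.6
  pr <- resolve_params(m, th, "same", "congruent_right", "right")
  pl <- resolve_params(m, th, "same", "congruent_left", "left")
  expect_equal(pr$w, 1 - pl$w)
})

test_that("theta validation catches length and name mismatches", {
  m <- ddm_model("reduced")
  expect_error(resolve_params(m, 1:3, "none", "incongruent", "left"),
               "length")
  bad <- setNames(rep(1, 5), c("a", "b", "c", "d", "e"))
  expect_error(resolve_params(m, bad, "none", "incongruent", "left"),
               "names")
  expect_error(
    resolve_params(m, c(a = 1.2, w_base = .5, v_mag = .7, t0 = .3, sv = 0),
                   "weird", "incongruent", "left"), "context")
})

test_that("cue validity is derivable from cue and stimulus", {
  expect_equal(cue_validity(c("incongruent", "congruent_left",
                              "congruent_left", "congruent_right"),
                            c("left", "left", "right", "right")),
               c("incongruent", "valid", "invalid", "valid"))
})

test_that("nested models reproduce each other's likelihoods exactly", {
  dat <- toy_trials(n = 60)

  # sp with norm-equal congruent starting points == sp_reduced
  sp <- ddm_model("sp"); spr <- ddm_model("sp_reduced")
  th_spr <- c(a = 1.2, v_mag = 0.7, t0 = 0.25, sv = 0.3, w_base = 0.5,
              w_cong_left = 0.42, w_cong_right = 0.61)
  th_sp <- c(a = 1.2, v_mag = 0.7, t0 = 0.25, sv = 0.3, w_base = 0.5,
             setNames(rep(0.42, 3), paste0("w_cong_left_", c("none", "same", "only"))),
             setNames(rep(0.61, 3), paste0("w_cong_right_", c("none", "same", "only"))))
  expect_equal(ddm_loglik(dat, sp, th_sp)$total,
               ddm_loglik(dat, spr, th_spr)$total)

  # drift with norm-equal congruent drifts == drift_reduced
  dr <- ddm_model("drift"); drr <- ddm_model("drift_reduced")
  th_drr <- c(a = 1.2, w_base = 0.48, v_incong = 0.7, v_cong = 0.9,
              t0 = 0.25, sv = 0.3)
  th_dr <- c(a = 1.2, w_base = 0.48, v_incong = 0.7,
             setNames(rep(0.9, 3), paste0("v_cong_", c("none", "same", "only"))),
             t0 = 0.25, sv = 0.3)
  expect_equal(ddm_loglik(dat, dr, th_dr)$total,
               ddm_loglik(dat, drr, th_drr)$total)

  # spdr with sp-style drifts fixed equal == sp; with flat w == drift
  spdr <- ddm_model("spdr")
  th_sp_full <- c(a = 1.2, v_mag = 0.8, t0 = 0.25, sv = 0.3, w_base = 0.5,
                  setNames(c(0.4, 0.45, 0.42), paste0("w_cong_left_", c("none", "same", "only"))),
                  setNames(c(0.6, 0.63, 0.58), paste0("w_cong_right_", c("none", "same", "only"))))
  th_spdr <- c(th_sp_full[setdiff(names(th_sp_full), "v_mag")],
               v_incong = 0.8,
               setNames(rep(0.8, 3), paste0("v_cong_", c("none", "same", "only"))))
  expect_equal(ddm_loglik(dat, spdr, th_spdr)$total,
               ddm_loglik(dat, sp, th_sp_full)$total)
})
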