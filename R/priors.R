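#' Default priors for a model's parameters
#'
#' Weakly informative truncated-Normal priors spanning the range of typical
#' two-alternative forced-choice fits, assigned by parameter type:
#' threshold separation `a ~ N(1.5, 1)` on (0.1, 5); starting points
#' `~ N(0.5, 0.25)` on (0.02, 0.98); drift magnitudes `~ N(1, 2)` on (0, 7);
#' non-decision time `t0 ~ N(0.3, 0.2)` on (0.05, 1); drift variability
#' `sv ~ N(0.5, 0.5)` on (0, 3). Override any row (or supply your own
#' tibble) to change them.
#'
#' @param model A [ddm_model()].
#' @return A tibble with columns `name`, `mean`, `sd`, `lower`, `upper`.
#' @examples
#' default_priors(ddm_model("reduced"))
#' @export
default_priors <- function(model) {
  by_type <- tibble::tribble(
    ~type, ~mean, ~sd, ~lower, ~upper,
    "a",   1.5,   1,   0.1,    5,
    "w",   0.5,   0.25, 0.02,  0.98,
    "v",   1,     2,   0,      7,
    "t0",  0.3,   0.2, 0.05,   1,
    "sv",  0.5,   0.5, 0,      3
  )
  dplyr::select(
    dplyr::left_join(model$params, by_type, by = "type"),
    "name", "mean", "sd", "lower", "upper")
}

check_priors <- function(model, priors) {
  req <- c("name", "mean", "sd", "lower", "upper")
  if (!all(req %in% names(priors)) ||
      !setequal(priors$name, model$params$name)) {
    stop("`priors` must be a tibble with columns name/mean/sd/lower/upper ",
         "covering exactly the model's parameters", call. = FALSE)
  }
  priors[match(model$params$name, priors$name), ]
}

# log prior density of theta matrix (p x m), summed over parameters
dprior_log <- function(priors, theta) {
  theta <- as.matrix(theta)
  lp <- numeric(ncol(theta))
  for (i in seq_len(nrow(priors))) {
    x <- theta[i, ]
    mu <- priors$mean[i]; s <- priors$sd[i]
    lo <- priors$lower[i]; hi <- priors$upper[i]
    norm <- pnorm(hi, mu, s) - pnorm(lo, mu, s)
    d <- ifelse(x > lo & x < hi, dnorm(x, mu, s, log = TRUE) - log(norm), -Inf)
    lp <- lp + d
  }
  lp
}

# m draws from the prior, as a p x m matrix
rprior <- function(priors, m) {
  p <- nrow(priors)
  out <- matrix(NA_real_, p, m, dimnames = list(priors$name, NULL))
  for (i in seq_len(p)) {
    mu <- priors$mean[i]; s <- priors$sd[i]
    u <- runif(m, pnorm(priors$lower[i], mu, s), pnorm(priors$upper[i], mu, s))
    out[i, ] <- qnorm(u, mu, s)
  }
  out
}
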