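#' Prior specification for the linked shrinkage model and its variants
#'
#' The core model places, given residual variance sigma^2 and local scales
#' tau_j ~ half-Cauchy(0, 1):
#' \itemize{
#'   \item main effects: beta_j ~ N(0, sigma^2 tau_j^2),
#'   \item interactions: beta_jk ~ N(0, sigma^2 tau_j tau_k tau_int),
#'   \item tau_int ~ Uniform(0.01, 1), alpha ~ N(0, alpha_sd^2),
#'   \item sigma^2 ~ Inverse-Gamma(shape, scale) with density proportional to
#'     (sigma^2)^-(shape+1) exp(-scale / sigma^2).
#' }
#' The product tau_j tau_k links the shrinkage of an interaction to that of
#' its two parent main effects; tau_int is a global factor letting
#' interactions be weaker on average, bounded below at 0.01 so they are never
#' shrunk away entirely.
#'
#' Variants:
#' \describe{
#'   \item{`"bayint"`}{the model above.}
#'   \item{`"bayint_star"`}{pins tau_int = 1 (more power for strong
#'     interactions, usually worse prediction).}
#'   \item{`"bay0int"`}{main effects get a wide fixed N(0, 10^2) prior
#'     (no shrinkage); tau_j remain and act only through the interactions.}
#'   \item{`"bayintadd"`}{replaces the factor tau_j tau_k by
#'     (tau_j^2 + tau_k^2) / 2, so the stronger parent dominates.}
#' }
#'
#' @param variant One of `"bayint"`, `"bayint_star"`, `"bay0int"`,
#'   `"bayintadd"`.
#' @param alpha_sd Prior s.d. of the intercept (default 10).
#' @param sigma2_shape,sigma2_scale Inverse-gamma hyperparameters for
#'   sigma^2 (defaults 1 and 0.001).
#' @param tau_int_bounds Support of the uniform prior on tau_int
#'   (default c(0.01, 1); ignored for `"bayint_star"`).
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(variant = c("bayint", "bayint_star", "bay0int", "bayintadd"),
                       alpha_sd = 10,
                       sigma2_shape = 1, sigma2_scale = 0.001,
                       tau_int_bounds = c(0.01, 1)) {
  variant <- match.arg(variant)
  stopifnot(length(tau_int_bounds) == 2, tau_int_bounds[1] > 0,
            tau_int_bounds[1] < tau_int_bounds[2], alpha_sd > 0,
            sigma2_shape > 0, sigma2_scale > 0)
  structure(
    list(variant = variant, alpha_sd = alpha_sd,
         sigma2_shape = sigma2_shape, sigma2_scale = sigma2_scale,
         tau_int_bounds = tau_int_bounds,
         # fixed prior s.d. for main effects when they are not shrunk
         main_fixed_sd = 10),
    class = "prior_spec"
  )
}

# Does this variant shrink the main effects (i.e. scale them by sigma^2 tau^2)?
shrinks_mains <- function(prior) prior$variant != "bay0int"

# tau_int value / support handling: bayint_star pins tau_int = 1.
tau_int_fixed <- function(prior) prior$variant == "bayint_star"

# Pairwise local variance factor f_jk (excluding sigma^2 and tau_int):
# tau_j tau_k for the multiplicative variants, (tau_j^2 + tau_k^2)/2 for the
# additive one. Vectorized over pairs.
pair_var_factor <- function(tau, pairs, variant) {
  tj <- tau[pairs[, 1]]
  tk <- tau[pairs[, 2]]
  if (variant == "bayintadd") (tj^2 + tk^2) / 2 else tj * tk
}

# Per-coefficient prior variances given the hyperparameters.
# Returns list(main = p-vector, int = q-vector), both on the response scale
# (sigma^2 included where applicable).
coef_prior_variances <- function(tau, tau_int, sigma2, pairs, prior) {
  main <- if (shrinks_mains(prior)) sigma2 * tau^2 else
    rep(prior$main_fixed_sd^2, length(tau))
  int <- sigma2 * tau_int * pair_var_factor(tau, pairs, prior$variant)
  list(main = main, int = int)
}

half_cauchy_logpdf <- function(x) {
  ifelse(x > 0, log(2 / pi) - log1p(x^2), -Inf)
}

inv_gamma_logpdf <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Unnormalized log posterior density of the linked shrinkage model
#'
#' Evaluates the sum of the Gaussian log likelihood and all prior log
#' densities at a parameter point. Parameters outside the support (any
#' tau <= 0, sigma^2 <= 0, tau_int outside its uniform bounds, or tau_int
#' != 1 for the `"bayint_star"` variant) return `-Inf` rather than raising an
#' error, so the function is directly usable as an MCMC target.
#'
#' @param params A named list with elements `alpha` (scalar), `beta_main`
#'   (length p_enc), `beta_int` (length q), `tau` (length p_enc), `tau_int`
#'   (scalar) and `sigma2` (scalar).
#' @param y Numeric response vector.
#' @param design An `encoded_design` with interactions built.
#' @param prior A [prior_spec()].
#' @return A single numeric value (possibly `-Inf`).
#' @export
log_joint_density <- function(params, y, design, prior = prior_spec()) {
  stopifnot(inherits(design, "encoded_design"))
  if (is.null(design$X_int)) design <- build_interactions(design)
  p <- ncol(design$X_main)
  q <- nrow(design$pairs)
  stopifnot(length(params$beta_main) == p, length(params$beta_int) == q,
            length(params$tau) == p)
  tau <- params$tau
  tau_int <- params$tau_int
  sigma2 <- params$sigma2

  # support checks
  if (any(tau <= 0) || sigma2 <= 0) return(-Inf)
  if (tau_int_fixed(prior)) {
    if (tau_int != 1) return(-Inf)
  } else {
    b <- prior$tau_int_bounds
    if (tau_int < b[1] || tau_int > b[2]) return(-Inf)
  }

  mu <- as.vector(params$alpha + design$X_main %*% params$beta_main +
                    design$X_int %*% params$beta_int)
  ll <- sum(stats::dnorm(y, mu, sqrt(sigma2), log = TRUE))

  v <- coef_prior_variances(tau, tau_int, sigma2, design$pairs, prior)
  lp <- stats::dnorm(params$alpha, 0, prior$alpha_sd, log = TRUE) +
    sum(stats::dnorm(params$beta_main, 0, sqrt(v$main), log = TRUE)) +
    sum(stats::dnorm(params$beta_int, 0, sqrt(v$int), log = TRUE)) +
    sum(half_cauchy_logpdf(tau)) +
    inv_gamma_logpdf(sigma2, prior$sigma2_shape, prior$sigma2_scale)
  if (!tau_int_fixed(prior)) {
    lp <- lp - log(diff(prior$tau_int_bounds)) # uniform density
  }
  ll + lp
}

#' Draw hyperparameters and coefficients from the priors alone
#'
#' Useful for prior-predictive checks: tau_j are half-Cauchy(0,1), tau_int is
#' uniform on its bounds (or exactly 1 for `"bayint_star"`), sigma^2 is
#' inverse-gamma, and coefficients are drawn from their conditional Gaussian
#' priors.
#'
#' @param prior A [prior_spec()].
#' @param p_enc Number of encoded main columns.
#' @param pairs Interaction pair index matrix (q x 2); defaults to all pairs.
#' @param ndraw Number of prior draws.
#' @return A tibble with one row per draw: `sigma2`, `tau_int`, list-columns
#'   `tau`, `beta_main`, `beta_int`, and `alpha`.
#' @export
prior_predictive <- function(prior, p_enc, pairs = NULL, ndraw = 1000) {
  if (is.null(pairs)) {
    pairs <- if (p_enc >= 2) t(utils::combn(p_enc, 2)) else
      matrix(integer(0), 0, 2)
  }
  draws <- purrr::map(seq_len(ndraw), function(i) {
    tau <- abs(stats::rcauchy(p_enc))
    tau_int <- if (tau_int_fixed(prior)) 1 else
      stats::runif(1, prior$tau_int_bounds[1], prior$tau_int_bounds[2])
    sigma2 <- 1 / stats::rgamma(1, prior$sigma2_shape, rate = prior$sigma2_scale)
    v <- coef_prior_variances(tau, tau_int, sigma2, pairs, prior)
    tibble::tibble(
      alpha = stats::rnorm(1, 0, prior$alpha_sd),
      sigma2 = sigma2, tau_int = tau_int,
      tau = list(tau),
      beta_main = list(stats::rnorm(p_enc, 0, sqrt(v$main))),
      beta_int = list(stats::rnorm(nrow(pairs), 0, sqrt(v$int)))
    )
  })
  dplyr::bind_rows(draws)
}
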