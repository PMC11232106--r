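#' Fit the linked shrinkage interaction model
#'
#' `bayint()` is the data-frame-first interface: it encodes the covariates,
#' builds all admissible two-way interactions, and runs the blocked Gibbs
#' sampler. `fit_linked_shrinkage()` is the lower-level entry point taking a
#' response vector and a prepared `encoded_design`.
#'
#' Each chain runs `warmup + iter` sweeps with its own seed derived from
#' `seed`; only post-warmup draws are kept. A warning (never silence) is
#' issued when the maximum split R-hat over coefficients exceeds
#' `rhat_warn`.
#'
#' @param data A data frame with the response column and raw covariates.
#' @param response Name of the numeric response column.
#' @param schema A [covariate_schema()] for the covariate columns; inferred
#'   from `data` (excluding `response`) when `NULL`.
#' @param variant Prior variant, see [prior_spec()].
#' @param chains Number of MCMC chains (default 4).
#' @param warmup Burn-in sweeps per chain (default 1000).
#' @param iter Kept sweeps per chain (default 5250, i.e. ~25,000 total draws
#'   with 4 chains).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param prior A [prior_spec()]; overrides `variant` if supplied.
#' @param rhat_warn Split R-hat threshold for the convergence warning.
#' @return An object of class `bayint_fit` containing the draw matrices
#'   (`alpha`, `beta_main`, `beta_int`, `tau`, `tau_int`, `sigma2`, with a
#'   `chain` index vector), the `design`, the `prior`, and a `diagnostics`
#'   tibble (split R-hat, effective sample size per parameter).
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config("sim1"), seed = 1)
#' fit <- bayint(sim$data, response = "y", chains = 2,
#'               warmup = 200, iter = 300, seed = 1)
#' tidy(fit)
#' }
#' @export
bayint <- function(data, response = "y", schema = NULL,
                   variant = c("bayint", "bayint_star", "bay0int", "bayintadd"),
                   chains = 4, warmup = 1000, iter = 5250, seed = 1,
                   prior = NULL, rhat_warn = 1.1) {
  stopifnot(response %in% names(data))
  y <- data[[response]]
  stopifnot(is.numeric(y), all(is.finite(y)))
  covs <- data[setdiff(names(data), response)]
  if (is.null(schema)) schema <- infer_schema(covs)
  design <- prepare_design(covs, schema)
  if (is.null(prior)) prior <- prior_spec(match.arg(variant))
  fit_linked_shrinkage(y, design, prior, chains = chains, warmup = warmup,
                       iter = iter, seed = seed, rhat_warn = rhat_warn)
}

#' @rdname bayint
#' @param y Numeric response vector.
#' @param design An `encoded_design` (interactions are built if absent).
#' @export
fit_linked_shrinkage <- function(y, design, prior = prior_spec(),
                                 chains = 4, warmup = 1000, iter = 5250,
                                 seed = 1, rhat_warn = 1.1) {
  stopifnot(inherits(design, "encoded_design"), inherits(prior, "prior_spec"),
            length(y) == design$n, length(y) > 0, all(is.finite(y)),
            chains >= 1, iter >= 1, warmup >= 0)
  if (is.null(design$X_int)) design <- build_interactions(design)

  chains_out <- lapply(seq_len(chains), function(c) {
    gibbs_chain(y, design, prior, warmup = warmup, iter = iter,
                seed = seed + c - 1L)
  })
  param_names <- list(main = colnames(design$X_main),
                      int = colnames(design$X_int))
  diagnostics <- compute_diagnostics(chains_out, param_names)

  bind <- function(field) do.call(rbind, lapply(chains_out, `[[`, field))
  bindv <- function(field) do.call(c, lapply(chains_out, `[[`, field))
  fit <- structure(
    list(
      alpha = bindv("alpha"),
      beta_main = `colnames<-`(bind("beta_main"), param_names$main),
      beta_int = `colnames<-`(bind("beta_int"), param_names$int),
      tau = `colnames<-`(bind("tau"), param_names$main),
      tau_int = bindv("tau_int"),
      sigma2 = bindv("sigma2"),
      chain = rep(seq_len(chains), each = iter),
      design = design, prior = prior,
      mcmc = list(chains = chains, warmup = warmup, iter = iter, seed = seed),
      diagnostics = diagnostics
    ),
    class = "bayint_fit"
  )
  coef_diag <- diagnostics[diagnostics$parameter %in%
                             c(param_names$main, param_names$int), ]
  max_rhat <- suppressWarnings(max(coef_diag$rhat, na.rm = TRUE))
  if (is.finite(max_rhat) && max_rhat > rhat_warn) {
    worst <- coef_diag$parameter[which.max(coef_diag$rhat)]
    warning(sprintf(
      "MCMC convergence: max split R-hat %.3f (parameter %s) exceeds %.2f; consider more iterations",
      max_rhat, worst, rhat_warn))
  }
  fit
}

#' @export
print.bayint_fit <- function(x, ...) {
  cat("<bayint_fit> variant =", x$prior$variant,
      "| n =", x$design$n,
      "| p_enc =", ncol(x$design$X_main),
      "| q =", nrow(x$design$pairs), "\n")
  cat(" draws =", length(x$alpha), "(", x$mcmc$chains, "chains x",
      x$mcmc$iter, "kept )\n")
  cat(" max coefficient R-hat:",
      round(suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)), 3), "\n")
  invisible(x)
}

# draws x ncoef matrix of all regression coefficients (mains then
# interactions), named.
coef_draws <- function(fit) {
  cbind(fit$beta_main, fit$beta_int)
}

coef_types <- function(fit) {
  c(rep("main", ncol(fit$beta_main)), rep("interaction", ncol(fit$beta_int)))
}

# Empirical two-sided "exclusion score": the largest credible level at which
# the equal-tailed interval excludes zero, 1 - 2*min(P(b<0), P(b>0)).
exclusion_score <- function(draws_mat) {
  pr_neg <- colMeans(draws_mat < 0) + 0.5 * colMeans(draws_mat == 0)
  1 - 2 * pmin(pr_neg, 1 - pr_neg)
}

#' Tidy posterior summaries of a fitted linked shrinkage model
#'
#' One row per regression coefficient (mains and interactions): the posterior
#' mean (the point estimate), posterior s.d., equal-tailed credible interval
#' at `level`, whether the interval excludes zero, and the exclusion score
#' (the largest level at which the interval still excludes zero), which
#' enables threshold sweeps for selection.
#'
#' @param x A `bayint_fit`.
#' @param level Credible level in (0, 1), default 0.95.
#' @param ... Unused.
#' @return A tibble with columns `term`, `type`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `excludes_zero`, `score`.
#' @export
tidy.bayint_fit <- function(x, level = 0.95, ...) {
  stopifnot(level > 0, level < 1)
  draws <- coef_draws(x)
  probs <- c((1 - level) / 2, (1 + level) / 2)
  qs <- t(apply(draws, 2, stats::quantile, probs = probs, names = FALSE))
  tibble::tibble(
    term = colnames(draws),
    type = coef_types(x),
    estimate = unname(colMeans(draws)),
    std.error = unname(apply(draws, 2, stats::sd)),
    conf.low = unname(qs[, 1]),
    conf.high = unname(qs[, 2]),
    excludes_zero = unname(qs[, 1] > 0 | qs[, 2] < 0),
    score = unname(exclusion_score(draws))
  )
}

#' @rdname tidy.bayint_fit
#' @export
glance.bayint_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$prior$variant,
    n = x$design$n,
    p_enc = ncol(x$design$X_main),
    q = nrow(x$design$pairs),
    draws = length(x$alpha),
    chains = x$mcmc$chains,
    sigma2 = mean(x$sigma2),
    tau_int = mean(x$tau_int),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE))
  )
}

#' Select coefficients whose credible interval excludes zero
#'
#' A coefficient is selected at level `level` when its equal-tailed posterior
#' credible interval excludes zero. The returned `score` column (largest
#' level at which the interval still excludes zero) supports sweeping the
#' selection threshold, e.g. for sensitivity-at-FDR curves.
#'
#' @param fit A `bayint_fit`.
#' @param level Credible level, default 0.95.
#' @return A tibble like [tidy.bayint_fit()] with a logical `selected`
#'   column.
#' @export
select_coefficients <- function(fit, level = 0.95) {
  out <- tidy(fit, level = level)
  out$selected <- out$excludes_zero
  out
}

#' Posterior summary of arbitrary draw matrices
#'
#' Equal-tailed interval summaries for a draws x parameters matrix; interval
#' endpoints are the empirical quantiles of the draws.
#'
#' @param draws A numeric matrix (draws in rows) or vector.
#' @param level Credible level.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `excludes_zero`.
#' @export
summarize_draws <- function(draws, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  if (is.null(colnames(draws))) {
    colnames(draws) <- paste0("par", seq_len(ncol(draws)))
  }
  probs <- c((1 - level) / 2, (1 + level) / 2)
  qs <- t(apply(draws, 2, stats::quantile, probs = probs, names = FALSE))
  tibble::tibble(
    term = colnames(draws),
    estimate = unname(colMeans(draws)),
    std.error = unname(apply(draws, 2, stats::sd)),
    conf.low = unname(qs[, 1]),
    conf.high = unname(qs[, 2]),
    excludes_zero = unname(qs[, 1] > 0 | qs[, 2] < 0)
  )
}

#' Predict from a fitted linked shrinkage model
#'
#' @param object A `bayint_fit`.
#' @param new_data Raw covariate data frame (encoded with the training
#'   transform statistics).
#' @param summary If `TRUE` (default) return posterior-mean predictions;
#'   otherwise a draws x n matrix.
#' @param ... Unused.
#' @return Numeric vector or matrix of linear predictor values.
#' @export
predict.bayint_fit <- function(object, new_data, summary = TRUE, ...) {
  nd <- prepare_design(new_data, object$design$schema,
                       stats = object$design$stats)
  eta <- tcrossprod(object$beta_main, nd$X_main) +
    tcrossprod(object$beta_int, nd$X_int)
  eta <- sweep(eta, 1, object$alpha, `+`)
  if (summary) colMeans(eta) else eta
}
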