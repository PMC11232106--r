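#' Personalized unit-change effects
#'
#' In a model with interactions, the effect of a one-unit change in encoded
#' covariate j depends on where the individual sits:
#' `E_ij = beta_j + sum_{k != j} beta_jk x_ik`. The coefficient `beta_j`
#' alone is only the *conditional* main effect at the covariate center; the
#' personalized effect accounts for all interactions. Computed per posterior
#' draw, so each effect comes with a credible interval.
#'
#' Effects are defined per encoded column (for a categorical covariate, per
#' contrast column).
#'
#' @param fit A `bayint_fit`.
#' @param new_data Raw covariate data frame of individuals.
#' @param level Credible level for the summary.
#' @param thin Keep every `thin`-th draw.
#' @return An object of class `unit_change_effect`: array `E`
#'   (draws x individuals x encoded columns) plus a tidy summary accessor
#'   via [tidy.unit_change_effect()].
#' @export
unit_change_effect <- function(fit, new_data, level = 0.95, thin = 1L) {
  stopifnot(inherits(fit, "bayint_fit"))
  design <- fit$design
  nd <- prepare_design(new_data[intersect(names(new_data),
                                          design$schema$name)],
                       design$schema, stats = design$stats)
  keep <- seq(1, length(fit$alpha), by = thin)
  Xs <- nd$X_main
  p <- ncol(Xs)
  pairs <- design$pairs
  E <- array(0, c(length(keep), nrow(Xs), p),
             dimnames = list(NULL, NULL, colnames(Xs)))
  for (d in seq_along(keep)) {
    b <- fit$beta_main[keep[d], ]
    B <- matrix(0, p, p)
    if (nrow(pairs)) {
      B[pairs] <- fit$beta_int[keep[d], ]
      B[pairs[, c(2, 1), drop = FALSE]] <- fit$beta_int[keep[d], ]
    }
    # E_i = beta + B x_i, for all individuals at once
    E[d, , ] <- sweep(Xs %*% B, 2, b, `+`)
  }
  structure(list(E = E, terms = colnames(Xs), level = level),
            class = "unit_change_effect")
}

#' @export
print.unit_change_effect <- function(x, ...) {
  d <- dim(x$E)
  cat("<unit_change_effect>", d[1], "draws x", d[2], "individuals x", d[3],
      "encoded covariates\n")
  invisible(x)
}

#' Summarize personalized unit-change effects
#'
#' @param x A `unit_change_effect`.
#' @param level Credible level (defaults to the stored level).
#' @param ... Unused.
#' @return A tibble with `individual`, `term`, `estimate`, `conf.low`,
#'   `conf.high`, `excludes_zero`.
#' @export
tidy.unit_change_effect <- function(x, level = NULL, ...) {
  if (is.null(level)) level <- x$level
  probs <- c((1 - level) / 2, (1 + level) / 2)
  est <- apply(x$E, c(2, 3), mean)
  lo <- apply(x$E, c(2, 3), stats::quantile, probs = probs[1], names = FALSE)
  hi <- apply(x$E, c(2, 3), stats::quantile, probs = probs[2], names = FALSE)
  tibble::tibble(
    individual = rep(seq_len(nrow(est)), times = ncol(est)),
    term = rep(x$terms, each = nrow(est)),
    estimate = as.vector(est),
    conf.low = as.vector(lo),
    conf.high = as.vector(hi),
    excludes_zero = as.vector(lo > 0 | hi < 0)
  )
}

#' Range of significance of a covariate across an interacting covariate
#'
#' Posterior credible intervals for `beta_j + beta_jk x_k` — the effect of a
#' unit change in encoded covariate j when only its interaction with
#' covariate k varies — evaluated on a grid of x_k values. The "range of
#' significance" is the set of grid points where the interval excludes zero.
#'
#' @param fit A `bayint_fit`.
#' @param j,k Encoded column names or indices (j != k); the pair must be an
#'   admissible interaction in the design.
#' @param grid Numeric grid of x_k values. Default: 41 equally spaced points
#'   over the observed training range of column k.
#' @param level Credible level.
#' @return A tibble with `x_k`, `estimate`, `conf.low`, `conf.high`,
#'   `excludes_zero`.
#' @export
range_of_significance <- function(fit, j, k, grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "bayint_fit"))
  design <- fit$design
  nm <- colnames(design$X_main)
  if (is.character(j)) j <- match(j, nm)
  if (is.character(k)) k <- match(k, nm)
  stopifnot(!is.na(j), !is.na(k), j != k)
  pr <- which((design$pairs[, 1] == min(j, k)) & (design$pairs[, 2] == max(j, k)))
  if (!length(pr)) stop("columns ", nm[j], " and ", nm[k],
                        " do not form an admissible interaction pair")
  if (is.null(grid)) {
    rng <- range(design$X_main[, k])
    grid <- seq(rng[1], rng[2], length.out = 41)
  }
  bj <- fit$beta_main[, j]
  bjk <- fit$beta_int[, pr]
  probs <- c((1 - level) / 2, (1 + level) / 2)
  draws <- outer(bjk, grid) + bj # draws x grid
  qs <- apply(draws, 2, stats::quantile, probs = probs, names = FALSE)
  tibble::tibble(
    x_k = grid,
    estimate = colMeans(draws),
    conf.low = qs[1, ],
    conf.high = qs[2, ],
    excludes_zero = qs[1, ] > 0 | qs[2, ] < 0
  )
}
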