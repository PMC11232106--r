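#' Per-coefficient root mean squared error over replicates
#'
#' `rMSE = sqrt(1/B sum_b (bhat^(b) - b)^2)` for each coefficient, over B
#' replicate training sets.
#'
#' @param estimates A B x K matrix (or data frame) of estimated coefficient
#'   vectors, one row per replicate, columns named by term.
#' @param beta_true Length-K true coefficient vector (recycled names checked
#'   if both are named).
#' @return A tibble with `term` and `rmse`.
#' @export
coef_rmse <- function(estimates, beta_true) {
  estimates <- as.matrix(estimates)
  stopifnot(nrow(estimates) >= 1, ncol(estimates) == length(beta_true))
  if (!is.null(colnames(estimates)) && !is.null(names(beta_true))) {
    stopifnot(identical(colnames(estimates), names(beta_true)))
  }
  dev2 <- sweep(estimates, 2, beta_true)^2
  tibble::tibble(
    term = colnames(estimates) %||% paste0("b", seq_along(beta_true)),
    rmse = unname(sqrt(colMeans(dev2)))
  )
}

#' Prediction error against the true linear predictor
#'
#' `MSEp = 1/B sum_b || X_test bhat^(b) - X_test b ||_2^2`: the squared
#' distance between the fitted and the true linear predictor on a test
#' design that includes all two-way interaction columns. Reported per
#' replicate together with the average.
#'
#' @param estimates B x K matrix of estimated coefficients (including the
#'   intercept if `X_test` has an intercept column).
#' @param beta_true Length-K true coefficient vector.
#' @param X_test Test design matrix (n_test x K) with all interaction
#'   columns.
#' @return A tibble with `replicate` and `msep`; the mean over replicates is
#'   attached as attribute `"mean"`.
#' @export
msep <- function(estimates, beta_true, X_test) {
  estimates <- as.matrix(estimates)
  if (ncol(estimates) != ncol(X_test) || length(beta_true) != ncol(X_test)) {
    stop("dimension mismatch: estimates and beta_true must match ncol(X_test)")
  }
  eta_true <- as.vector(X_test %*% beta_true)
  per_rep <- unname(apply(estimates, 1, function(bh) {
    sum((as.vector(X_test %*% bh) - eta_true)^2)
  }))
  out <- tibble::tibble(replicate = seq_along(per_rep), msep = per_rep)
  attr(out, "mean") <- mean(per_rep)
  out
}

#' Sensitivity at fixed empirical FDR levels
#'
#' Sweeps the selection-score threshold from strictest to loosest; at each
#' selection computes the realized false discovery proportion
#' `FDR = FP / (FP + TP)` and `sensitivity = TP / #positives`, counting only
#' coefficients labelled `"positive"` or `"negative"` (label
#' `"indeterminate"` excludes a coefficient from both numerator and
#' denominator). For each requested FDR level the sensitivity of the largest
#' selection whose FDR does not exceed the level is reported. Ties in scores
#' are broken by coefficient index.
#'
#' @param scores Numeric vector; larger means stronger evidence for
#'   selection (e.g. the credible-interval exclusion score).
#' @param labels Character vector of truth labels: `"positive"`,
#'   `"negative"`, or `"indeterminate"`.
#' @param fdr_levels Numeric vector of target FDR levels (default 0.1, 0.2).
#' @return A tibble with `fdr_level`, `sensitivity`, `n_selected`, and the
#'   realized `fdr` of the reported selection.
#' @export
sensitivity_at_fdr <- function(scores, labels, fdr_levels = c(0.1, 0.2)) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("positive", "negative", "indeterminate")))
  n_pos <- sum(labels == "positive")
  if (n_pos == 0) stop("no positive coefficients in truth labels")
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  tp <- cumsum(lab == "positive")
  fp <- cumsum(lab == "negative")
  labelled <- tp + fp
  fdp <- ifelse(labelled > 0, fp / labelled, 0)
  sens <- tp / n_pos
  out <- purrr::map_dfr(fdr_levels, function(f) {
    ok <- which(fdp <= f)
    if (!length(ok)) {
      return(tibble::tibble(fdr_level = f, sensitivity = 0,
                            n_selected = 0L, fdr = 0))
    }
    i <- max(ok)
    tibble::tibble(fdr_level = f, sensitivity = sens[i],
                   n_selected = i, fdr = fdp[i])
  })
  out
}

#' Label coefficients by the simulation truth
#'
#' @param beta_true Named numeric vector of true coefficients.
#' @return Character vector: `"positive"` where nonzero, `"negative"` where
#'   zero.
#' @export
truth_labels <- function(beta_true) {
  ifelse(beta_true != 0, "positive", "negative")
}

#' Ordinary least squares on the full interaction design
#'
#' The no-shrinkage reference estimator: OLS on the intercept + main +
#' interaction design. Errors on rank deficiency rather than dropping
#' columns silently.
#'
#' @param y Numeric response.
#' @param design An `encoded_design` (interactions built if needed).
#' @return A tibble with `term`, `type` and `estimate` (intercept first).
#' @export
ols_baseline <- function(y, design) {
  stopifnot(inherits(design, "encoded_design"), length(y) == design$n)
  X <- full_design_matrix(design)
  if (length(y) <= ncol(X)) {
    stop("n must exceed the number of coefficients (", ncol(X), ") for OLS")
  }
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    stop("rank-deficient interaction design: OLS estimates undefined")
  }
  est <- qr.coef(qr_X, y)
  tibble::tibble(
    term = colnames(X),
    type = c("intercept", rep("main", ncol(design$X_main)),
             rep("interaction", nrow(design$pairs))),
    estimate = unname(est)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
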