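# Convergence diagnostics: split R-hat (Gelman et al.) and effective sample
# size via coda. Both operate on an iterations x chains matrix.

split_rhat <- function(draws) {
  niter <- nrow(draws)
  if (niter < 4) return(NA_real_)
  half <- niter %/% 2
  # split each chain in two halves
  mat <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(niter - half + 1):niter, , drop = FALSE])
  if (stats::var(as.vector(mat)) < .Machine$double.eps) return(1)
  m <- ncol(mat)
  n <- nrow(mat)
  chain_means <- colMeans(mat)
  chain_vars <- apply(mat, 2, stats::var)
  B <- n * stats::var(chain_means)
  W <- mean(chain_vars)
  if (W < .Machine$double.eps) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_total <- function(draws) {
  v <- stats::var(as.vector(draws))
  if (!is.finite(v) || v < .Machine$double.eps) return(NA_real_)
  sum(apply(draws, 2, function(x) unname(coda::effectiveSize(x))))
}

# Per-parameter diagnostics table for a list of per-chain draw lists.
compute_diagnostics <- function(chains_out, param_names) {
  # chains_out: list over chains of lists (alpha, beta_main, ...)
  nchains <- length(chains_out)
  stack <- function(getcol) {
    vapply(chains_out, getcol, numeric(length(getcol(chains_out[[1]]))))
  }
  diag_one <- function(name, getcol) {
    m <- stack(getcol)
    tibble::tibble(parameter = name, rhat = split_rhat(m), ess = ess_total(m),
                   mean = mean(m))
  }
  rows <- list(diag_one("alpha", function(ch) ch$alpha))
  p <- ncol(chains_out[[1]]$beta_main)
  q <- ncol(chains_out[[1]]$beta_int)
  for (j in seq_len(p)) {
    rows[[length(rows) + 1]] <-
      diag_one(param_names$main[j], function(ch) ch$beta_main[, j])
  }
  for (k in seq_len(q)) {
    rows[[length(rows) + 1]] <-
      diag_one(param_names$int[k], function(ch) ch$beta_int[, k])
  }
  for (j in seq_len(p)) {
    rows[[length(rows) + 1]] <-
      diag_one(paste0("tau[", param_names$main[j], "]"),
               function(ch) ch$tau[, j])
  }
  rows[[length(rows) + 1]] <- diag_one("tau_int", function(ch) ch$tau_int)
  rows[[length(rows) + 1]] <- diag_one("sigma2", function(ch) ch$sigma2)
  dplyr::bind_rows(rows)
}
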