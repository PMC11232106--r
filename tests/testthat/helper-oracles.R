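# Independent oracles and small fixture builders, written from textbook
# formulas and kept independent of the package internals they check.

# Textbook sum of log densities for the linked shrinkage joint: Gaussian
# likelihood + N(0, sigma^2 tau_j^2) mains + N(0, sigma^2 f_jk tau_int)
# interactions + half-Cauchy taus + uniform tau_int + inverse-gamma sigma^2.
oracle_log_joint <- function(params, y, X_main, X_int, pairs,
                             variant = "bayint") {
  alpha <- params$alpha
  bm <- params$beta_main
  bi <- params$beta_int
  tau <- params$tau
  ti <- params$tau_int
  s2 <- params$sigma2
  mu <- as.vector(alpha + X_main %*% bm + X_int %*% bi)
  ll <- sum(dnorm(y, mu, sqrt(s2), log = TRUE))
  lp <- dnorm(alpha, 0, 10, log = TRUE)
  main_sd <- if (variant == "bay0int") rep(10, length(tau)) else sqrt(s2) * tau
  lp <- lp + sum(dnorm(bm, 0, main_sd, log = TRUE))
  f <- if (variant == "bayintadd") {
    (tau[pairs[, 1]]^2 + tau[pairs[, 2]]^2) / 2
  } else {
    tau[pairs[, 1]] * tau[pairs[, 2]]
  }
  lp <- lp + sum(dnorm(bi, 0, sqrt(s2 * f * ti), log = TRUE))
  lp <- lp + sum(log(2 * dcauchy(tau))) # half-Cauchy(0,1)
  if (variant != "bayint_star") lp <- lp + dunif(ti, 0.01, 1, log = TRUE)
  a <- 1; b <- 0.001 # inverse-gamma on sigma^2
  lp <- lp + a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2
  ll + lp
}

# all-continuous toy design with given columns
toy_design <- function(X) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  prepare_design(as.data.frame(X))
}

# random parameter point inside the support
random_params <- function(p, q, star = FALSE) {
  list(alpha = rnorm(1), beta_main = rnorm(p), beta_int = rnorm(q, 0, 0.5),
       tau = abs(rcauchy(p)) + 0.01,
       tau_int = if (star) 1 else runif(1, 0.01, 1),
       sigma2 = rexp(1) + 0.1)
}

# random Shapley instance: coefficients, point, moments (means/cross from an
# arbitrary consistent construction)
random_shapley_instance <- function(p, centered = TRUE) {
  pairs <- t(combn(p, 2))
  n_mom <- 400
  Xm <- matrix(rnorm(n_mom * p), n_mom, p)
  if (!centered) Xm <- sweep(Xm, 2, runif(p, -1, 1), `+`)
  means <- if (centered) rep(0, p) else colMeans(Xm)
  cross <- colMeans(Xm[, pairs[, 1], drop = FALSE] * Xm[, pairs[, 2], drop = FALSE])
  list(
    beta = list(alpha = rnorm(1), beta_main = rnorm(p),
                beta_int = rnorm(nrow(pairs), 0, 0.7)),
    x_star = rnorm(p), pairs = pairs, means = means, cross = cross
  )
}
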