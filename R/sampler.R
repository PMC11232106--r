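# Blocked Gibbs sampler for the linked shrinkage model.
#
# The Gaussian likelihood makes the model conditionally conjugate in two
# blocks: (alpha, beta) | tau, sigma2 is multivariate normal (drawn exactly
# via a Cholesky solve of the posterior precision), and sigma2 | beta, tau is
# inverse-gamma. The non-conjugate local scales tau_j (half-Cauchy) are
# updated one at a time by slice sampling on the log scale; the global
# interaction factor tau_int (uniform on a bounded interval) by slice
# sampling within its bounds.

# Univariate slice sampler (Neal 2003): stepping-out + shrinkage.
slice_sample1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started outside the support")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > z) {
    L <- L - w; j <- j - 1
  }
  while (k > 0 && R < upper && logf(R) > z) {
    R <- R + w; k <- k - 1
  }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# One MCMC chain. Returns a list of draw matrices (kept iterations only).
gibbs_chain <- function(y, design, prior, warmup, iter, seed,
                        thin = 1L) {
  set.seed(seed)
  X <- full_design_matrix(design)
  n <- length(y)
  p <- ncol(design$X_main)
  q <- nrow(design$pairs)
  K <- 1L + p + q
  idx_main <- 1L + seq_len(p)
  idx_int <- 1L + p + seq_len(q)
  pairs <- design$pairs
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1]
  yty <- sum(y^2)
  variant <- prior$variant
  a0 <- prior$sigma2_shape
  b0 <- prior$sigma2_scale
  tib <- prior$tau_int_bounds
  mains_scaled <- shrinks_mains(prior)
  # count of sigma2-scaled coefficients in the sigma2 conditional
  m_scaled <- q + if (mains_scaled) p else 0L

  # pair bookkeeping: for each column j, which pairs contain it and who is
  # the partner
  pairs_of <- lapply(seq_len(p), function(j) which(pairs[, 1] == j | pairs[, 2] == j))
  partner_of <- lapply(seq_len(p), function(j) {
    pr <- pairs_of[[j]]
    ifelse(pairs[pr, 1] == j, pairs[pr, 2], pairs[pr, 1])
  })

  # initial state
  tau <- rep(0.5, p)
  tau_int <- if (tau_int_fixed(prior)) 1 else mean(tib)
  sigma2 <- max(stats::var(y), 1e-6)
  theta <- numeric(K)

  n_keep <- iter %/% thin
  out <- list(
    alpha = numeric(n_keep),
    beta_main = matrix(0, n_keep, p),
    beta_int = matrix(0, n_keep, q),
    tau = matrix(0, n_keep, p),
    tau_int = numeric(n_keep),
    sigma2 = numeric(n_keep)
  )

  total <- warmup + iter
  for (it in seq_len(total)) {
    ## --- (alpha, beta) block: exact MVN draw -------------------------------
    v <- coef_prior_variances(tau, tau_int, sigma2, pairs, prior)
    prior_prec <- c(1 / prior$alpha_sd^2, 1 / v$main, 1 / v$int)
    A <- XtX / sigma2
    diag(A) <- diag(A) + prior_prec
    R <- chol(A)
    b <- Xty / sigma2
    mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
    theta <- mu + backsolve(R, stats::rnorm(K))
    beta_main <- theta[idx_main]
    beta_int <- theta[idx_int]

    ## --- sigma2: conjugate inverse-gamma -----------------------------------
    rss <- yty - 2 * sum(theta * Xty) + sum(theta * (XtX %*% theta))
    rss <- max(rss, 0)
    f_pair <- pair_var_factor(tau, pairs, variant) * tau_int
    rate <- b0 + rss / 2 + sum(beta_int^2 / f_pair) / 2
    if (mains_scaled) rate <- rate + sum(beta_main^2 / tau^2) / 2
    sigma2 <- 1 / stats::rgamma(1, a0 + n / 2 + m_scaled / 2, rate = rate)

    ## --- tau_j: slice sampling on the log scale ----------------------------
    for (j in seq_len(p)) {
      pr <- pairs_of[[j]]
      ks <- partner_of[[j]]
      bj2 <- beta_main[j]^2
      bint2 <- beta_int[pr]^2
      tk <- tau[ks]
      logf <- function(lt) {
        t1 <- exp(lt)
        lp <- -log1p(t1^2) + lt # half-Cauchy kernel + log-scale Jacobian
        if (mains_scaled) lp <- lp - lt - bj2 / (2 * sigma2 * t1^2)
        if (length(pr)) {
          f <- if (variant == "bayintadd") (t1^2 + tk^2) / 2 else t1 * tk
          f <- f * tau_int
          lp <- lp - 0.5 * sum(log(f)) - sum(bint2 / f) / (2 * sigma2)
        }
        lp
      }
      tau[j] <- exp(slice_sample1(log(tau[j]), logf, w = 1))
    }

    ## --- tau_int: slice sampling on its bounded support --------------------
    if (!tau_int_fixed(prior) && q > 0) {
      f0 <- pair_var_factor(tau, pairs, variant)
      S <- sum(beta_int^2 / f0) / (2 * sigma2)
      logf <- function(u) -q / 2 * log(u) - S / u
      tau_int <- slice_sample1(tau_int, logf, w = diff(tib) / 4,
                               lower = tib[1], upper = tib[2])
    }

    ## --- store -------------------------------------------------------------
    if (it > warmup && (it - warmup) %% thin == 0) {
      s <- (it - warmup) %/% thin
      out$alpha[s] <- theta[1]
      out$beta_main[s, ] <- beta_main
      out$beta_int[s, ] <- beta_int
      out$tau[s, ] <- tau
      out$tau_int[s] <- tau_int
      out$sigma2[s] <- sigma2
    }
  }
  out
}
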