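test_that("log joint density matches the independent textbook oracle", {
  set.seed(11)
  n <- 25; p <- 4
  des <- toy_design(matrix(rnorm(n * p), n, p))
  y <- rnorm(n)
  q <- nrow(des$pairs)
  for (variant in c("bayint", "bayint_star", "bay0int", "bayintadd")) {
    pr <- prior_spec(variant)
    for (i in 1:15) {
      params <- random_params(p, q, star = variant == "bayint_star")
      expect_equal(
        log_joint_density(params, y, des, pr),
        oracle_log_joint(params, y, des$X_main, des$X_int, des$pairs, variant),
        tolerance = 1e-8
      )
    }
  }
})

test_that("out-of-support parameters give -Inf, not an error", {
  set.seed(12)
  des <- toy_design(matrix(rnorm(60), 20, 3))
  y <- rnorm(20)
  pr <- prior_spec("bayint")
  ok <- random_params(3, 3)
  expect_true(is.finite(log_joint_density(ok, y, des, pr)))
  low <- ok; low$tau_int <- 0.005 # below the uniform lower bound
  expect_identical(log_joint_density(low, y, des, pr), -Inf)
  neg <- ok; neg$tau[2] <- -0.1
  expect_identical(log_joint_density(neg, y, des, pr), -Inf)
  s2 <- ok; s2$sigma2 <- 0
  expect_identical(log_joint_density(s2, y, des, pr), -Inf)
  # bayint_star: tau_int must be pinned at 1
  star <- ok; star$tau_int <- 0.7
  expect_identical(log_joint_density(star, y, des, prior_spec("bayint_star")), -Inf)
})

test_that("single-observation likelihood reduces to the closed form", {
  # identity transform stats let a single all-zero row through the encoder
  st <- structure(list(x1 = list(kind = "continuous", center = 0, scale = 1),
                       x2 = list(kind = "continuous", center = 0, scale = 1)),
                  class = "transform_stats")
  df1 <- data.frame(x1 = 0, x2 = 0)
  des <- prepare_design(df1, covariate_schema(c("x1", "x2"), "continuous"),
                        stats = st)
  # all-zero parameters: likelihood term is log N(0 | 0, 1)
  params <- list(alpha = 0, beta_main = c(0, 0), beta_int = 0,
                 tau = c(1, 1), tau_int = 1, sigma2 = 1)
  lik_plus_priors <- log_joint_density(params, 0, des, prior_spec("bayint"))
  priors_only <- oracle_log_joint(params, numeric(0),
                                  des$X_main[0, , drop = FALSE],
                                  des$X_int[0, , drop = FALSE], des$pairs)
  expect_equal(lik_plus_priors - priors_only, dnorm(0, 0, 1, log = TRUE),
               tolerance = 1e-10)
})

test_that("prior predictive draws respect the hyperprior laws", {
  set.seed(13)
  pp <- prior_predictive(prior_spec("bayint"), p_enc = 5, ndraw = 2000)
  # tau_int uniform on [0.01, 1]
  ks <- ks.test(pp$tau_int, "punif", 0.01, 1)
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pp$tau_int >= 0.01 & pp$tau_int <= 1))
  # tau_j half-Cauchy: positive, heavy tailed (quantile check)
  taus <- unlist(pp$tau)
  expect_true(all(taus > 0))
  expect_equal(median(taus), 1, tolerance = 0.15) # C+(0,1) median = 1
  expect_gt(mean(taus > 10), 0.03) # P(tau > 10) ~ 0.063 for C+(0,1)
  # bayint_star pins tau_int at 1
  pps <- prior_predictive(prior_spec("bayint_star"), p_enc = 3, ndraw = 50)
  expect_true(all(pps$tau_int == 1))
})

test_that("interaction prior variance is maximal at tau_int = 1", {
  set.seed(14)
  pairs <- t(combn(4, 2))
  tau <- abs(rcauchy(4)) + 0.01
  pr <- prior_spec("bayint")
  v1 <- linkshrink:::coef_prior_variances(tau, 1, 1.3, pairs, pr)$int
  for (u in runif(10, 0.01, 0.999)) {
    vu <- linkshrink:::coef_prior_variances(tau, u, 1.3, pairs, pr)$int
    expect_true(all(v1 >= vu))
  }
})

test_that("posterior summaries use empirical quantiles and handle degenerate draws", {
  set.seed(15)
  draws <- cbind(a = rnorm(500, 2, 1), b = rnorm(500, 0, 1))
  sm <- summarize_draws(draws, level = 0.9)
  expect_equal(sm$conf.low, unname(apply(draws, 2, quantile, 0.05)),
               tolerance = 1e-12)
  expect_equal(sm$conf.high, unname(apply(draws, 2, quantile, 0.95)),
               tolerance = 1e-12)
  expect_false(sm$excludes_zero[2]) # symmetric around 0
  degen <- summarize_draws(rep(3.5, 100))
  expect_equal(degen$estimate, 3.5)
  expect_equal(degen$conf.high - degen$conf.low, 0)
})

test_that("gibbs sampler agrees with JAGS on a small instance", {
  set.seed(42)
  n <- 100; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  df <- as.data.frame(X); names(df) <- paste0("x", 1:p)
  y <- 0.8 * X[, 1] + 0.4 * X[, 2] + 0.3 * X[, 1] * X[, 2] + rnorm(n)
  des <- prepare_design(df)
  fit <- fit_linked_shrinkage(y, des, prior_spec("bayint"),
                              chains = 2, warmup = 500, iter = 2500, seed = 7)
  q <- nrow(des$pairs)
  model_str <- "model {
    for (i in 1:n) { y[i] ~ dnorm(alpha + inprod(X[i,], beta), 1/sigma2) }
    alpha ~ dnorm(0, 1/100)
    for (j in 1:p) {
      tau[j] ~ dt(0, 1, 1) T(0,)
      beta[j] ~ dnorm(0, 1/(sigma2 * tau[j]^2))
    }
    for (m in 1:q) {
      beta[p+m] ~ dnorm(0, 1/(sigma2 * tau[pj[m]] * tau[pk[m]] * tauint))
    }
    tauint ~ dunif(0.01, 1)
    prec ~ dgamma(1, 0.001)
    sigma2 <- 1/prec
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = y, X = cbind(des$X_main, des$X_int), n = n, p = p, q = q,
                pj = des$pairs[, 1], pk = des$pairs[, 2]),
    n.chains = 2, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 11)
  )
  update(jm, 1000, progress.bar = "none")
  s <- rjags::coda.samples(jm, c("alpha", "beta", "sigma2"),
                           n.iter = 5000, progress.bar = "none")
  sm <- summary(s)$statistics
  jn <- rownames(sm)
  jags_coef <- sm[grep("^beta", jn), "Mean"]
  mine_coef <- colMeans(cbind(fit$beta_main, fit$beta_int))
  expect_lt(max(abs(unname(jags_coef) - unname(mine_coef))), 0.05)
  expect_equal(mean(fit$sigma2), unname(sm["sigma2", "Mean"]), tolerance = 0.1)
})

test_that("zero-signal data yields credible intervals covering zero", {
  set.seed(16)
  n <- 400; p <- 6
  df <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(df) <- paste0("x", 1:p)
  df$y <- rnorm(n)
  fit <- suppressWarnings(
    bayint(df, response = "y", chains = 2, warmup = 250, iter = 400, seed = 3)
  )
  td <- tidy(fit, level = 0.95)
  ints <- td[td$type == "interaction", ]
  expect_gte(mean(!ints$excludes_zero), 0.9)
})

test_that("linked shrinkage learns larger local scales for active covariates", {
  set.seed(17)
  n <- 300; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  df <- as.data.frame(X); names(df) <- paste0("x", 1:p)
  df$y <- 2 * X[, 1] + rnorm(n) # covariate 1 strong, covariate 2 null
  fit <- suppressWarnings(
    bayint(df, response = "y", chains = 2, warmup = 250, iter = 400, seed = 5)
  )
  expect_gt(mean(fit$tau[, "x1"]), mean(fit$tau[, "x2"]))
})

test_that("bayint_star pins every tau_int draw at one and fits reproduce under a seed", {
  set.seed(18)
  n <- 80; p <- 3
  df <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(df) <- paste0("x", 1:p)
  df$y <- rnorm(n) + df$x1
  fit1 <- bayint(df, response = "y", variant = "bayint_star",
                 chains = 2, warmup = 100, iter = 150, seed = 9)
  expect_true(all(fit1$tau_int == 1))
  fit2 <- bayint(df, response = "y", variant = "bayint_star",
                 chains = 2, warmup = 100, iter = 150, seed = 9)
  expect_identical(fit1$beta_int, fit2$beta_int)
  expect_identical(tidy(fit1), tidy(fit2))
})

test_that("credible-interval selection and its score sweep are consistent", {
  set.seed(19)
  draws <- cbind(pos = rnorm(800, 3, 0.5), null = rnorm(800, 0, 1),
                 weak = rnorm(800, 0.8, 0.5))
  sc <- linkshrink:::exclusion_score(draws)
  sm <- summarize_draws(draws, level = 0.95)
  # all-positive draws are selected at any reasonable level
  expect_true(sm$excludes_zero[1])
  expect_gt(sc[1], 0.999)
  # symmetric-about-zero draws are not selected at 0.95
  expect_false(sm$excludes_zero[2])
  # score-threshold sweep reproduces the 0.95-level selection
  expect_identical(unname(sc >= 0.95), unname(sm$excludes_zero))
})
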