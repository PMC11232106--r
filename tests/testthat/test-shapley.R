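test_that("closed form equals coalition enumeration on random instances", {
  set.seed(21)
  for (rep in 1:100) {
    p <- sample(2:8, 1)
    inst <- random_shapley_instance(p, centered = rep %% 2 == 0)
    cf <- shapley_closed_form(inst$beta$beta_main, inst$beta$beta_int,
                              matrix(inst$x_star, 1), inst$pairs,
                              means = inst$means, cross = inst$cross)
    bf <- shapley_bruteforce(inst$beta, inst$x_star, inst$pairs,
                             means = inst$means, cross = inst$cross)
    expect_lt(max(abs(cf$phi[1, ] - bf)), 1e-9)
  }
})

test_that("grouped categorical players match the enumeration oracle", {
  set.seed(22)
  n <- 120
  df <- data.frame(a = rnorm(n), b = rnorm(n),
                   g = sample(c("u", "v", "w", "z"), n, TRUE))
  sch <- covariate_schema(c("a", "b", "g"),
                          c("continuous", "continuous", "categorical"),
                          list(NULL, NULL, c("u", "v", "w", "z")))
  des <- prepare_design(df, sch)
  q <- nrow(des$pairs)
  beta <- list(alpha = 0.3, beta_main = rnorm(ncol(des$X_main)),
               beta_int = rnorm(q, 0, 0.5))
  x_star <- des$X_main[5, ]
  cf <- shapley_closed_form(beta$beta_main, beta$beta_int,
                            matrix(x_star, 1), des$pairs,
                            means = des$moments$means,
                            cross = des$moments$cross, groups = des$groups)
  bf <- shapley_bruteforce(beta, x_star, des$pairs,
                           means = des$moments$means,
                           cross = des$moments$cross, groups = des$groups)
  expect_lt(max(abs(cf$phi[1, ] - bf)), 1e-9)
  expect_identical(colnames(cf$phi), c("a", "b", "g"))
})

test_that("two-player single-interaction model matches the hand enumeration", {
  # f(x) = b12 x1 x2, centered: phi_1 = b12 (x1 x2 - E[x1 x2]) / 2
  pairs <- matrix(c(1L, 2L), 1)
  beta <- list(alpha = 0, beta_main = c(0, 0), beta_int = 0.7)
  x <- c(1.4, -0.6)
  cross <- 0.25
  bf <- shapley_bruteforce(beta, x, pairs, means = c(0, 0), cross = cross)
  expect_equal(unname(bf[1]), 0.5 * 0.7 * x[1] * x[2] - 0.5 * 0.7 * cross,
               tolerance = 1e-12)
  expect_equal(unname(bf[1]), unname(bf[2]), tolerance = 1e-12)
})

test_that("pure main-effects model gives phi_j = beta_j x_j and dummies get zero", {
  set.seed(23)
  p <- 5
  pairs <- t(combn(p, 2))
  beta <- list(alpha = 1.2, beta_main = rnorm(p), beta_int = rep(0, nrow(pairs)))
  x <- rnorm(p)
  bf <- shapley_bruteforce(beta, x, pairs)
  expect_equal(unname(bf), beta$beta_main * x, tolerance = 1e-10)
  # dummy axiom: a covariate with all-zero coefficients gets exactly 0
  inst <- random_shapley_instance(5)
  inst$beta$beta_main[3] <- 0
  inst$beta$beta_int[inst$pairs[, 1] == 3 | inst$pairs[, 2] == 3] <- 0
  bf2 <- shapley_bruteforce(inst$beta, inst$x_star, inst$pairs,
                            means = inst$means, cross = inst$cross)
  expect_equal(unname(bf2[3]), 0, tolerance = 1e-12)
})

test_that("coalition values hit the no-marginalization and all-marginal limits", {
  set.seed(24)
  inst <- random_shapley_instance(4, centered = TRUE)
  b <- inst$beta
  full <- coalition_value(b, inst$x_star, 1:4, inst$pairs,
                          means = inst$means, cross = inst$cross)
  pred <- b$alpha + sum(b$beta_main * inst$x_star) +
    sum(b$beta_int * inst$x_star[inst$pairs[, 1]] * inst$x_star[inst$pairs[, 2]])
  expect_equal(full, pred, tolerance = 1e-12)
  empty <- coalition_value(b, inst$x_star, integer(0), inst$pairs,
                           means = inst$means, cross = inst$cross)
  expect_equal(empty, b$alpha + sum(b$beta_int * inst$cross), tolerance = 1e-12)
})

test_that("coalition value matches Monte-Carlo interventional marginalization", {
  set.seed(25)
  p <- 4
  mu <- c(0.3, -0.2, 0.5, 0)
  A <- matrix(rnorm(16, 0, 0.4), 4)
  Sigma <- crossprod(A) + diag(0.5, 4)
  pairs <- t(combn(p, 2))
  means <- mu
  cross <- Sigma[pairs] + mu[pairs[, 1]] * mu[pairs[, 2]] # exact E[x_j x_k]
  beta <- list(alpha = 0.4, beta_main = rnorm(p), beta_int = rnorm(nrow(pairs)))
  x_star <- rnorm(p)
  predict_f <- function(X) {
    beta$alpha + X %*% beta$beta_main +
      (X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]) %*% beta$beta_int
  }
  for (S in list(c(1L), c(2L, 4L), c(1L, 3L))) {
    v <- coalition_value(beta, x_star, S, pairs, means = means, cross = cross)
    # draw non-players from their joint law, ignoring dependence on players
    notS <- setdiff(1:p, S)
    draws <- mvtnorm::rmvnorm(2e5, mu[notS], Sigma[notS, notS, drop = FALSE])
    X <- matrix(x_star, 2e5, p, byrow = TRUE)
    X[, notS] <- draws
    mc <- mean(predict_f(X))
    expect_equal(v, mc, tolerance = 0.03)
  }
})

test_that("per-draw Shapley values satisfy efficiency, additivity and linearity", {
  set.seed(26)
  n <- 150; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  df <- as.data.frame(X); names(df) <- paste0("x", 1:p)
  df$y <- X[, 1] + 0.5 * X[, 1] * X[, 2] + rnorm(n)
  fit <- suppressWarnings(
    bayint(df, response = "y", chains = 2, warmup = 150, iter = 200, seed = 2)
  )
  nd <- df[1:7, ]
  sh <- shapley(fit, nd, thin = 5)
  # phi = phi_main + phi_int exactly
  expect_equal(sh$phi, sh$phi_main + sh$phi_int, tolerance = 1e-12)
  # efficiency per draw and individual: sum_j phi_ij = v(full) - v(empty)
  des <- fit$design
  ndes <- prepare_design(nd[paste0("x", 1:p)], des$schema, stats = des$stats)
  for (d in seq(1, dim(sh$phi)[1], by = 7)) {
    draw_id <- sh$draw_index[d]
    bm <- fit$beta_main[draw_id, ]
    bi <- fit$beta_int[draw_id, ]
    for (i in c(1, 4)) {
      xs <- ndes$X_main[i, ]
      pred <- sum(bm * xs) + sum(bi * xs[des$pairs[, 1]] * xs[des$pairs[, 2]])
      base <- sum(bi * des$moments$cross) +
        sum(bm * des$moments$means)
      expect_equal(sum(sh$phi[d, i, ]), pred - base, tolerance = 1e-8)
    }
  }
  # linearity in beta: doubling all coefficients doubles phi
  inst <- random_shapley_instance(4)
  cf1 <- shapley_closed_form(inst$beta$beta_main, inst$beta$beta_int,
                             matrix(inst$x_star, 1), inst$pairs,
                             means = inst$means, cross = inst$cross)
  cf2 <- shapley_closed_form(2 * inst$beta$beta_main, 2 * inst$beta$beta_int,
                             matrix(inst$x_star, 1), inst$pairs,
                             means = inst$means, cross = inst$cross)
  expect_equal(cf2$phi, 2 * cf1$phi, tolerance = 1e-12)
})

test_that("exchangeable covariates receive symmetric attributions", {
  # x1 and x2 play identical roles (same coefficients, same moments) and are
  # fixed at the same value: their Shapley values must coincide
  pairs <- t(combn(3, 2))
  beta <- list(alpha = 0, beta_main = c(0.6, 0.6, -0.2),
               beta_int = c(0, 0.3, 0.3)) # pairs (1,2),(1,3),(2,3)
  x <- c(0.8, 0.8, -0.5)
  bf <- shapley_bruteforce(beta, x, pairs, means = rep(0, 3),
                           cross = c(0.1, 0.05, 0.05))
  expect_equal(unname(bf[1]), unname(bf[2]), tolerance = 1e-12)
})

test_that("Shapley values center near zero over the training distribution", {
  set.seed(27)
  p <- 4
  n <- 4000
  X <- matrix(rnorm(n * p), n, p)
  des <- toy_design(X)
  beta <- list(alpha = 0.5, beta_main = rnorm(p),
               beta_int = rnorm(nrow(des$pairs), 0, 0.5))
  cf <- shapley_closed_form(beta$beta_main, beta$beta_int, des$X_main,
                            des$pairs, means = des$moments$means,
                            cross = des$moments$cross)
  expect_lt(max(abs(colMeans(cf$phi))), 0.05)
})

test_that("global importance summarises mean absolute Shapley values", {
  set.seed(28)
  # all-zero phi -> all-zero importance; single individual -> |phi_1j|
  arr0 <- array(0, c(3, 2, 2), dimnames = list(NULL, NULL, c("a", "b")))
  res0 <- structure(list(phi = arr0, phi_main = arr0, phi_int = arr0,
                         players = c("a", "b"), level = 0.95),
                    class = "shapley_result")
  gi0 <- global_importance(res0)
  expect_true(all(gi0$importance == 0))
  one <- array(rnorm(3 * 1 * 2), c(3, 1, 2), dimnames = list(NULL, NULL, c("a", "b")))
  res1 <- structure(list(phi = one, phi_main = one, phi_int = 0 * one,
                         players = c("a", "b"), level = 0.95),
                    class = "shapley_result")
  gi1 <- global_importance(res1)
  expect_equal(gi1$importance, unname(abs(apply(one, 3, mean))), tolerance = 1e-12)
  # sign cancellation: I_j != I_j^main + I_j^int in general
  pm <- array(1, c(1, 2, 1), dimnames = list(NULL, NULL, "a"))
  pi_ <- array(-1, c(1, 2, 1), dimnames = list(NULL, NULL, "a"))
  res2 <- structure(list(phi = pm + pi_, phi_main = pm, phi_int = pi_,
                         players = "a", level = 0.95),
                    class = "shapley_result")
  gi2 <- global_importance(res2)
  expect_equal(gi2$importance, 0)
  expect_equal(gi2$importance_main + gi2$importance_int, 2)
})
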