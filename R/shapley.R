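#' Interventional Shapley values for the interaction model
#'
#' For a linear model with all two-way interactions the interventional
#' Shapley value of covariate j for individual i has an exact closed form.
#' With centered covariates it is
#' `phi_ij = beta_j x*_ij + 1/2 sum_k beta_jk (x*_ij x*_ik - E[x_ij x_ik])`;
#' the general (non-centered, grouped-player) form implemented here reduces
#' to that expression and is validated against coalition enumeration
#' ([shapley_bruteforce()]). "Interventional" means non-player covariates are
#' marginalized ignoring their dependence on the players, so only the frozen
#' training moments E\[x_j\] and E\[x_j x_k\] enter.
#'
#' Players are source covariates, not encoded columns: all contrast columns
#' of a categorical covariate enter or leave a coalition together.
#'
#' Applied per posterior draw, the Shapley values inherit full posterior
#' uncertainty; `phi = phi_main + phi_int` splits each value into the
#' main-effect part `beta_j (x*_ij - E[x_ij])` and the interaction remainder.
#'
#' @param fit A `bayint_fit`.
#' @param new_data Raw covariate data frame of test individuals (encoded with
#'   the training transform statistics).
#' @param level Credible level for the summary intervals.
#' @param thin Keep every `thin`-th posterior draw (1 = all).
#' @return An object of class `shapley_result`: arrays `phi`, `phi_main`,
#'   `phi_int` of dimension draws x individuals x players, the `players`
#'   names, and the `level`. Use [tidy.shapley_result()] for a long summary
#'   table and [global_importance()] for I_j scores.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config("sim1"), seed = 1)
#' fit <- bayint(sim$data, chains = 2, warmup = 200, iter = 300, seed = 1)
#' sh <- shapley(fit, sim$data[1:5, ], thin = 10)
#' tidy(sh)
#' }
#' @export
shapley <- function(fit, new_data, level = 0.95, thin = 1L) {
  stopifnot(inherits(fit, "bayint_fit"))
  design <- fit$design
  nd <- prepare_design(new_data[intersect(names(new_data),
                                          design$schema$name)],
                       design$schema, stats = design$stats)
  if (!identical(colnames(nd$X_main), colnames(design$X_main))) {
    stop("encoding mismatch between training design and new data")
  }
  keep <- seq(1, length(fit$alpha), by = thin)
  D <- length(keep)
  Xs <- nd$X_main
  n_t <- nrow(Xs)
  p <- ncol(Xs)
  players <- names(design$groups)
  P <- length(players)
  G <- matrix(0, p, P, dimnames = list(NULL, players))
  for (g in seq_len(P)) G[design$groups[[g]], g] <- 1

  means <- design$moments$means
  pairs <- design$pairs
  cross <- design$moments$cross

  phi <- array(0, c(D, n_t, P), dimnames = list(NULL, NULL, players))
  phi_main <- phi
  phi_int <- phi
  Xc <- sweep(Xs, 2, means) # x* - m
  for (d in seq_len(D)) {
    b <- fit$beta_main[keep[d], ]
    bi <- fit$beta_int[keep[d], ]
    parts <- shapley_columns(b, bi, Xs, Xc, means, pairs, cross)
    phi_main[d, , ] <- parts$main %*% G
    phi_int[d, , ] <- parts$int %*% G
  }
  phi <- phi_main + phi_int
  structure(
    list(phi = phi, phi_main = phi_main, phi_int = phi_int,
         players = players, level = level,
         new_data = new_data, draw_index = keep),
    class = "shapley_result"
  )
}

# Per-encoded-column closed-form contributions for one coefficient draw.
# Returns list(main, int): n_t x p matrices; summing columns within a player
# group gives the player's Shapley value.
shapley_columns <- function(beta_main, beta_int, Xs, Xc, means, pairs, cross) {
  p <- ncol(Xs)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  if (nrow(pairs)) {
    B[pairs] <- beta_int
    B[pairs[, c(2, 1), drop = FALSE]] <- beta_int
    M[pairs] <- cross
    M[pairs[, c(2, 1), drop = FALSE]] <- cross
  }
  s <- rowSums(B * M) # s_j = sum_k beta_jk E[x_j x_k]
  XB <- Xs %*% B          # (B x_i)_j
  Bm <- as.vector(B %*% means)
  main <- sweep(Xc, 2, beta_main, `*`)
  int <- 0.5 * (Xc * XB + sweep(Xs, 2, Bm, `*`) - matrix(s, nrow(Xs), p, byrow = TRUE))
  list(main = main, int = int)
}

#' Closed-form Shapley values for a single coefficient point
#'
#' Low-level interface used for validation: computes per-player Shapley
#' values, and their main/interaction split, for one coefficient vector and a
#' batch of encoded covariate rows.
#'
#' @param beta_main Length-p vector of main-effect coefficients.
#' @param beta_int Length-q vector of interaction coefficients (in pair
#'   order).
#' @param X_star Encoded covariate matrix (individuals x p).
#' @param pairs q x 2 integer matrix of interaction pairs.
#' @param means Length-p vector of training column means E\[x_j\].
#' @param cross Length-q vector of training moments E\[x_j x_k\] per pair.
#' @param groups Optional named list mapping players to encoded column
#'   indices (default: one player per column).
#' @return A list with matrices `phi`, `phi_main`, `phi_int`
#'   (individuals x players).
#' @export
shapley_closed_form <- function(beta_main, beta_int, X_star, pairs,
                                means = rep(0, ncol(X_star)),
                                cross = rep(0, nrow(pairs)),
                                groups = NULL) {
  X_star <- rbind(X_star)
  p <- ncol(X_star)
  if (is.null(groups)) groups <- as.list(seq_len(p))
  if (is.null(names(groups))) names(groups) <- paste0("x", seq_along(groups))
  P <- length(groups)
  G <- matrix(0, p, P, dimnames = list(NULL, names(groups)))
  for (g in seq_len(P)) G[groups[[g]], g] <- 1
  Xc <- sweep(X_star, 2, means)
  parts <- shapley_columns(beta_main, beta_int, X_star, Xc, means, pairs, cross)
  phi_main <- parts$main %*% G
  phi_int <- parts$int %*% G
  list(phi = phi_main + phi_int, phi_main = phi_main, phi_int = phi_int)
}

#' Value of a player coalition under interventional marginalization
#'
#' The coalition value v(S) fixes the covariates of the players in `S` at the
#' individual's values and marginalizes the rest using the frozen training
#' moments: non-player mains contribute beta_j E[x_j], mixed interaction
#' pairs beta_jk x*_j E[x_k], and fully marginalized pairs
#' beta_jk E[x_j x_k]. v(all players) is the point prediction; v(empty set)
#' is the model-implied mean prediction.
#'
#' @param beta_point List with `alpha`, `beta_main` (p), `beta_int` (q).
#' @param x_star Encoded covariate vector (length p).
#' @param S Integer vector of player indices in the coalition (may be empty).
#' @param pairs q x 2 pair matrix.
#' @param means,cross Training moments as in [shapley_closed_form()].
#' @param groups Player-to-column map (default singletons).
#' @return Scalar coalition value.
#' @export
coalition_value <- function(beta_point, x_star, S, pairs,
                            means = rep(0, length(x_star)),
                            cross = rep(0, nrow(pairs)),
                            groups = NULL) {
  p <- length(x_star)
  if (is.null(groups)) groups <- as.list(seq_len(p))
  stopifnot(all(S %in% seq_along(groups)))
  in_S <- rep(FALSE, p)
  if (length(S)) in_S[unlist(groups[S])] <- TRUE
  b <- beta_point$beta_main
  bi <- beta_point$beta_int
  v <- beta_point$alpha +
    sum(b[in_S] * x_star[in_S]) + sum(b[!in_S] * means[!in_S])
  if (nrow(pairs)) {
    j <- pairs[, 1]; k <- pairs[, 2]
    both <- in_S[j] & in_S[k]
    jonly <- in_S[j] & !in_S[k]
    konly <- !in_S[j] & in_S[k]
    none <- !in_S[j] & !in_S[k]
    v <- v + sum(bi[both] * x_star[j[both]] * x_star[k[both]]) +
      sum(bi[jonly] * x_star[j[jonly]] * means[k[jonly]]) +
      sum(bi[konly] * means[j[konly]] * x_star[k[konly]]) +
      sum(bi[none] * cross[none])
  }
  v
}

#' Shapley values by exhaustive coalition enumeration
#'
#' The defining weighted average of marginal contributions,
#' `phi_g = sum_S |S|! (P-|S|-1)! / P! (v(S + g) - v(S))` over all subsets S
#' of the other players. Exponential in the number of players; used as the
#' independent oracle for [shapley_closed_form()].
#'
#' @inheritParams coalition_value
#' @return Named numeric vector of per-player Shapley values.
#' @export
shapley_bruteforce <- function(beta_point, x_star, pairs,
                               means = rep(0, length(x_star)),
                               cross = rep(0, nrow(pairs)),
                               groups = NULL) {
  p <- length(x_star)
  if (is.null(groups)) groups <- as.list(seq_len(p))
  if (is.null(names(groups))) names(groups) <- paste0("x", seq_along(groups))
  P <- length(groups)
  if (P > 15) {
    stop("more than 15 players: enumeration infeasible, use shapley_closed_form()")
  }
  lw <- function(s) lfactorial(s) + lfactorial(P - s - 1) - lfactorial(P)
  phi <- stats::setNames(numeric(P), names(groups))
  others <- function(g) setdiff(seq_len(P), g)
  for (g in seq_len(P)) {
    oth <- others(g)
    nS <- length(oth)
    for (mask in 0:(2^nS - 1)) {
      S <- oth[bitwAnd(mask, bitwShiftL(1, seq_len(nS) - 1)) != 0]
      w <- exp(lw(length(S)))
      phi[g] <- phi[g] + w *
        (coalition_value(beta_point, x_star, c(S, g), pairs, means, cross, groups) -
           coalition_value(beta_point, x_star, S, pairs, means, cross, groups))
    }
  }
  phi
}

#' @export
print.shapley_result <- function(x, ...) {
  d <- dim(x$phi)
  cat("<shapley_result>", d[1], "draws x", d[2], "individuals x", d[3],
      "players\n players:", paste(x$players, collapse = ", "), "\n")
  invisible(x)
}

#' Long-format posterior summary of Shapley values
#'
#' @param x A `shapley_result`.
#' @param level Credible level (defaults to the level stored in `x`).
#' @param ... Unused.
#' @return A tibble with columns `individual`, `covariate`, `component`
#'   (`"total"`, `"main"`, `"interaction"`), `estimate`, `conf.low`,
#'   `conf.high`, `excludes_zero`.
#' @export
tidy.shapley_result <- function(x, level = NULL, ...) {
  if (is.null(level)) level <- x$level
  probs <- c((1 - level) / 2, (1 + level) / 2)
  one <- function(arr, comp) {
    est <- apply(arr, c(2, 3), mean)
    lo <- apply(arr, c(2, 3), stats::quantile, probs = probs[1], names = FALSE)
    hi <- apply(arr, c(2, 3), stats::quantile, probs = probs[2], names = FALSE)
    tibble::tibble(
      individual = rep(seq_len(nrow(est)), times = ncol(est)),
      covariate = rep(x$players, each = nrow(est)),
      component = comp,
      estimate = as.vector(est),
      conf.low = as.vector(lo),
      conf.high = as.vector(hi),
      excludes_zero = as.vector(lo > 0 | hi < 0)
    )
  }
  dplyr::bind_rows(one(x$phi, "total"), one(x$phi_main, "main"),
                   one(x$phi_int, "interaction"))
}

#' Global variable importance from Shapley values
#'
#' The conventional Shapley importance `I_j = 1/n sum_i |phi_ij|` computed on
#' posterior-mean Shapley values, with analogous `I_j^main` and `I_j^int` for
#' the main-effect and interaction components. Note `I_j` is generally not
#' the sum of the two component scores, since the components can cancel in
#' sign within an individual.
#'
#' @param x A `shapley_result`.
#' @return A tibble with `covariate`, `importance`, `importance_main`,
#'   `importance_int`.
#' @export
global_importance <- function(x) {
  stopifnot(inherits(x, "shapley_result"))
  imp <- function(arr) colMeans(abs(apply(arr, c(2, 3), mean)))
  tibble::tibble(
    covariate = x$players,
    importance = unname(imp(x$phi)),
    importance_main = unname(imp(x$phi_main)),
    importance_int = unname(imp(x$phi_int))
  )
}
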