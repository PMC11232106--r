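#' Configuration of the built-in simulation designs
#'
#' Three seeded generators with known truth:
#' \describe{
#'   \item{`"sim1"`}{n = 200 samples of p = 10 moderately collinear
#'     (exchangeable correlation `rho`) standard-normal covariates, giving
#'     q = 45 two-way interactions. Five main effects are nonzero, plus 13
#'     nonzero interactions of three types: 6 between two nonzero mains, 4
#'     between a nonzero and an absent main, and 3 "surprising" ones between
#'     two absent mains (two of which share a covariate) — 18 nonzero
#'     coefficients in total.}
#'   \item{`"sim2"`}{n = 500; the same effect structure, plus four
#'     independent standard-normal noise covariates (p = 14, q = 91). Being
#'     sparser, the signal of one main effect and one interaction of each
#'     type is increased by half.}
#'   \item{`"helius_like"`}{a mixed-type epidemiological covariate set:
#'     three continuous, three binary, one 5-level categorical and four
#'     standard-normal noise columns (14 source covariates; 14 encoded
#'     columns, q = 85 after excluding within-categorical pairs).}
#' }
#' Gaussian noise is calibrated so the population R-squared of the response
#' is `r2` (default 0.5). Main effect sizes default to
#' 1.0, 0.75, 0.5, 0.3, 0.15 and interaction sizes span 0.1-0.3; both are
#' package conventions, configurable here.
#'
#' @param setting `"sim1"`, `"sim2"`, or `"helius_like"`.
#' @param n Sample size (defaults: 200 / 500 / 1000 by setting).
#' @param rho Exchangeable correlation of the non-noise continuous
#'   covariates (default 0.3).
#' @param r2 Target population coefficient of determination (default 0.5).
#' @param main_effects Sizes of the five nonzero main effects (sim1/sim2).
#' @param boost Multiplier applied in `"sim2"` to one main effect and one
#'   interaction of each type (default 1.5).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(setting = c("sim1", "sim2", "helius_like"),
                       n = NULL, rho = 0.3, r2 = 0.5,
                       main_effects = c(1.0, 0.75, 0.5, 0.3, 0.15),
                       boost = 1.5) {
  setting <- match.arg(setting)
  if (is.null(n)) n <- switch(setting, sim1 = 200L, sim2 = 500L,
                              helius_like = 1000L)
  p_base <- 10L
  if (rho <= -1 / (p_base - 1) || rho >= 1) {
    stop("rho = ", rho, " makes the exchangeable correlation matrix non-PSD")
  }
  stopifnot(r2 > 0, r2 < 1, length(main_effects) == 5, n >= 1)
  structure(
    list(setting = setting, n = as.integer(n), rho = rho, r2 = r2,
         main_effects = main_effects, boost = boost,
         p = switch(setting, sim1 = 10L, sim2 = 14L, helius_like = 14L),
         n_noise = switch(setting, sim1 = 0L, sim2 = 4L, helius_like = 4L)),
    class = "sim_config"
  )
}

# Interaction truth structure shared by sim1/sim2: pairs (j < k), type and
# base effect size. Exactly 6 both-main, 4 one-main, 3 surprising; the
# surprising pairs (6,7) and (7,8) share covariate 7.
interaction_structure <- function() {
  tibble::tibble(
    j = c(1L, 1L, 2L, 2L, 3L, 4L, 1L, 2L, 3L, 5L, 6L, 7L, 9L),
    k = c(2L, 3L, 3L, 4L, 4L, 5L, 6L, 7L, 6L, 8L, 7L, 8L, 10L),
    type = rep(c("both-main", "one-main", "surprising"), c(6, 4, 3)),
    value = c(0.3, 0.25, 0.2, 0.15, 0.125, 0.1,
              0.3, 0.25, 0.15, 0.1,
              0.3, 0.2, 0.15)
  )
}

#' True coefficients of the simulation designs
#'
#' The deterministic truth vector of `"sim1"` and `"sim2"`: all main and
#' interaction coefficients of the design, with 18 nonzero entries (5 mains
#' and interactions of the three types in counts 6 / 4 / 3). In `"sim2"` the
#' first main effect and the first interaction of each type are boosted, and
#' the four noise covariates carry only zero coefficients.
#'
#' @param config A [sim_config()] with setting `"sim1"` or `"sim2"`.
#' @return A tibble with `term`, `type` (`"main"`/`"interaction"`),
#'   `int_type` (`"both-main"`, `"one-main"`, `"surprising"`, or `NA`),
#'   `j`, `k` (encoded column indices; `k` is `NA` for mains) and `value`.
#' @export
true_coefficients <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$setting %in% c("sim1", "sim2")) {
    stop("true_coefficients is defined for settings 'sim1' and 'sim2' only")
  }
  p <- config$p
  mains <- tibble::tibble(
    term = paste0("x", seq_len(p)), type = "main",
    int_type = NA_character_, j = seq_len(p), k = NA_integer_,
    value = c(config$main_effects, rep(0, p - 5))
  )
  ints <- interaction_structure()
  if (config$setting == "sim2") {
    # boost one main effect and the first interaction of each type
    mains$value[1] <- mains$value[1] * config$boost
    first_of_type <- !duplicated(ints$type)
    ints$value[first_of_type] <- ints$value[first_of_type] * config$boost
  }
  all_pairs <- t(utils::combn(p, 2))
  full <- tibble::tibble(
    j = all_pairs[, 1], k = all_pairs[, 2], type = "interaction"
  )
  full <- dplyr::left_join(full, ints, by = c("j", "k"))
  full$value[is.na(full$value)] <- 0
  full$int_type <- full$type.y
  full$term <- paste0("x", full$j, ":x", full$k)
  ints_full <- full[, c("term", "j", "k", "int_type", "value")]
  ints_full$type <- "interaction"
  dplyr::bind_rows(mains, ints_full[, names(mains)])
}

# noise column names follow the source covariates
sim_colnames <- function(config) {
  base <- paste0("x", seq_len(10L))
  if (config$n_noise > 0) c(base, paste0("noise", seq_len(config$n_noise)))
  else base
}

#' Draw the covariate table of a simulation design
#'
#' `"sim1"`/`"sim2"`: multivariate normal with exchangeable correlation
#' `rho` among the 10 base covariates; `"sim2"` appends four independent
#' standard-normal noise columns. `"helius_like"`: three continuous columns
#' on realistic raw scales, three 0/1 binaries, one 5-level categorical and
#' four standard-normal noise columns.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble with `config$n` rows.
#' @export
simulate_covariates <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n
  if (config$setting %in% c("sim1", "sim2")) {
    p0 <- 10L
    R <- matrix(config$rho, p0, p0)
    diag(R) <- 1
    L <- chol(R)
    X <- matrix(stats::rnorm(n * p0), n, p0) %*% L
    if (config$n_noise > 0) {
      X <- cbind(X, matrix(stats::rnorm(n * config$n_noise), n))
    }
    colnames(X) <- sim_colnames(config)
    return(tibble::as_tibble(X))
  }
  # helius_like: independent mixed-type columns on raw scales
  tibble::tibble(
    age = stats::rnorm(n, 50, 12),
    packyears = stats::rnorm(n, 10, 8),
    bmi = stats::rnorm(n, 26, 4),
    gender = stats::rbinom(n, 1, 0.5),
    smoking = stats::rbinom(n, 1, 0.3),
    coffee = stats::rbinom(n, 1, 0.6),
    ethnicity = sample(LETTERS[1:5], n, replace = TRUE),
    noise1 = stats::rnorm(n), noise2 = stats::rnorm(n),
    noise3 = stats::rnorm(n), noise4 = stats::rnorm(n)
  )
}

#' Covariate schema of a simulation design
#'
#' @param config A [sim_config()].
#' @return A [covariate_schema()].
#' @export
sim_schema <- function(config) {
  if (config$setting %in% c("sim1", "sim2")) {
    nms <- sim_colnames(config)
    return(covariate_schema(nms, "continuous"))
  }
  covariate_schema(
    name = c("age", "packyears", "bmi", "gender", "smoking", "coffee",
             "ethnicity", paste0("noise", 1:4)),
    kind = c(rep("continuous", 3), rep("binary", 3), "categorical",
             rep("continuous", 4)),
    levels = c(rep(list(NULL), 6), list(LETTERS[1:5]), rep(list(NULL), 4))
  )
}

# default truth for the helius_like setting, on the encoded scale
# (a package convention: a few plausible mains and interactions, zero for
# the noise columns)
helius_truth <- function() {
  tibble::tibble(
    term = c("age", "gender", "bmi", "smoking",
             "age:gender", "age:bmi", "gender:smoking"),
    value = c(0.5, 0.3, 0.4, 0.2, 0.2, 0.15, 0.1)
  )
}

# linear predictor from a term-value truth table on a prepared design
linear_predictor <- function(truth, design) {
  X <- cbind(design$X_main, design$X_int)
  miss <- setdiff(truth$term, colnames(X))
  if (length(miss)) stop("truth terms not in design: ", paste(miss, collapse = ", "))
  beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  beta[truth$term] <- truth$value
  list(eta = as.vector(X %*% beta), beta = beta)
}

#' Calibrate the noise standard deviation for a target R-squared
#'
#' Estimates the variance of the true linear predictor (mains plus
#' interactions) by Monte Carlo over `mc_n` covariate draws and returns the
#' residual s.d. `sigma_eps` such that the population R-squared
#' `Var(X beta) / (Var(X beta) + sigma_eps^2)` equals `config$r2`.
#'
#' @param config A [sim_config()].
#' @param mc_n Monte Carlo sample size (default 1e5).
#' @param seed Seed for the Monte Carlo draw.
#' @return A list with `sigma_eps`, `signal_var` (the Monte Carlo estimate
#'   of Var(X beta)) and the target `r2`.
#' @export
calibrate_noise <- function(config, mc_n = 1e5, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  big <- config
  big$n <- as.integer(mc_n)
  covs <- simulate_covariates(big, seed = seed)
  eta <- sim_linear_predictor(config, covs)
  signal_var <- stats::var(eta)
  if (signal_var <= 0) stop("zero signal variance: cannot calibrate noise")
  sigma_eps <- sqrt(signal_var * (1 - config$r2) / config$r2)
  list(sigma_eps = sigma_eps, signal_var = signal_var, r2 = config$r2)
}

# true linear predictor for a covariate table, by setting
sim_linear_predictor <- function(config, covs) {
  if (config$setting %in% c("sim1", "sim2")) {
    truth <- true_coefficients(config)
    # mains and interactions on the raw (standard-normal) covariate scale;
    # noise columns carry zero coefficients
    eta <- numeric(nrow(covs))
    mains <- truth[truth$type == "main" & truth$value != 0, ]
    for (r in seq_len(nrow(mains))) {
      eta <- eta + mains$value[r] * covs[[paste0("x", mains$j[r])]]
    }
    ints <- truth[truth$type == "interaction" & truth$value != 0, ]
    for (r in seq_len(nrow(ints))) {
      eta <- eta + ints$value[r] *
        covs[[paste0("x", ints$j[r])]] * covs[[paste0("x", ints$k[r])]]
    }
    return(eta)
  }
  # helius_like: truth lives on the encoded scale
  design <- prepare_design(covs, sim_schema(config))
  linear_predictor(helius_truth(), design)$eta
}

#' Generate a complete simulated dataset with known truth
#'
#' Draws covariates, forms the true linear predictor and adds Gaussian noise
#' with the calibrated `sigma_eps`. Regenerating with the same seed is
#' bit-identical.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param sigma_eps Optional pre-computed noise s.d. (e.g. from
#'   [calibrate_noise()], to avoid re-calibrating per replicate). Default:
#'   calibrated internally with a fixed Monte Carlo seed.
#' @return An object of class `sim_dataset`: `data` (covariates plus
#'   response `y`), `truth` (term-level tibble), `sigma_eps`, `schema`,
#'   `config`, `seed`.
#' @export
simulate_dataset <- function(config, seed = 1, sigma_eps = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sigma_eps)) sigma_eps <- calibrate_noise(config)$sigma_eps
  covs <- simulate_covariates(config, seed = seed)
  eta <- sim_linear_predictor(config, covs)
  # continue the covariate seed stream for the noise
  eps <- stats::rnorm(config$n, 0, sigma_eps)
  data <- covs
  data$y <- eta + eps
  truth <- if (config$setting %in% c("sim1", "sim2")) {
    true_coefficients(config)
  } else {
    helius_truth()
  }
  structure(
    list(data = data, truth = truth, sigma_eps = sigma_eps,
         schema = sim_schema(config), config = config, seed = seed),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", x$config$setting, "| n =", x$config$n,
      "| seed =", x$seed, "| sigma_eps =", round(x$sigma_eps, 3), "\n")
  invisible(x)
}

#' Generate B replicate datasets
#'
#' Replicate b uses seed `seed + b`, so replicates are mutually distinct and
#' individually reproducible. The noise s.d. is calibrated once and shared.
#'
#' @param config A [sim_config()].
#' @param B Number of replicates.
#' @param seed Base seed.
#' @return A list of `sim_dataset` objects.
#' @export
replicate_datasets <- function(config, B, seed = 1) {
  cal <- calibrate_noise(config)
  lapply(seq_len(B), function(b) {
    simulate_dataset(config, seed = seed + b, sigma_eps = cal$sigma_eps)
  })
}
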