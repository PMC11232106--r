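#' Encode a raw covariate table into the model's main-effect design
#'
#' Applies the package's coding conventions: continuous columns are centered
#' and scaled to unit (n-1 denominator) standard deviation; binary columns are
#' contrast-coded so the sorted raw values map to (-1, +1); a categorical
#' column with L schema levels becomes L-1 sum-to-zero contrast columns taking
#' values in \{-1, 0, 1\}, with the last schema level as the reference (its
#' rows are -1 in every contrast column). Centering largely removes the
#' collinearity between main effects and their two-way interactions, and the
#' common scale makes coefficients comparable.
#'
#' When `stats` (a `transform_stats` object from a previous encoding) is
#' supplied, the stored centers, scales, binary value maps and levels are
#' reapplied unchanged, so new data lands on the training scale.
#'
#' @param data A data frame containing (at least) the schema columns. No
#'   missing values are allowed.
#' @param schema A [covariate_schema()]; defaults to [infer_schema()] on
#'   `data`.
#' @param stats Optional `transform_stats` from a training-set encoding.
#' @return An object of class `encoded_design`: a list with the encoded
#'   matrix `X_main` (n x p_enc), a `column_map` tibble (encoded column,
#'   source covariate, kind), `groups` (per-covariate encoded column
#'   indices), and `stats` (the reusable `transform_stats`).
#' @seealso [build_interactions()], [second_moments()], [prepare_design()]
#' @export
encode_covariates <- function(data, schema = infer_schema(data), stats = NULL) {
  schema <- validate_schema(schema)
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols)) {
    stop("schema columns absent from data: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(data[schema$name])) {
    stop("missing values in covariate table; missing-data handling is not supported")
  }
  n <- nrow(data)
  new_stats <- is.null(stats)
  if (new_stats) stats <- list()

  cols <- list()
  map_cov <- character()
  map_kind <- character()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    kd <- schema$kind[i]
    x <- data[[nm]]
    if (kd == "continuous") {
      x <- as.numeric(x)
      if (new_stats) {
        ctr <- mean(x)
        scl <- stats::sd(x)
        if (!is.finite(scl) || scl == 0) {
          stop("constant continuous column '", nm, "': scale undefined")
        }
        stats[[nm]] <- list(kind = kd, center = ctr, scale = scl)
      }
      st <- stats[[nm]]
      cols[[nm]] <- (x - st$center) / st$scale
      map_cov <- c(map_cov, nm)
      map_kind <- c(map_kind, kd)
    } else if (kd == "binary") {
      xc <- as.character(x)
      if (new_stats) {
        vals <- sort(unique(xc))
        if (length(vals) != 2) {
          stop("binary column '", nm, "' has ", length(vals),
               " distinct values; exactly 2 required")
        }
        stats[[nm]] <- list(kind = kd, values = vals)
      }
      vals <- stats[[nm]]$values
      unknown <- setdiff(unique(xc), vals)
      if (length(unknown)) {
        stop("unknown value(s) in binary column '", nm, "': ",
             paste(unknown, collapse = ", "))
      }
      cols[[nm]] <- ifelse(xc == vals[2], 1, -1)
      map_cov <- c(map_cov, nm)
      map_kind <- c(map_kind, kd)
    } else { # categorical
      lv <- schema$levels[[i]]
      if (new_stats) stats[[nm]] <- list(kind = kd, levels = lv)
      lv <- stats[[nm]]$levels
      xc <- as.character(x)
      unknown <- setdiff(unique(xc), lv)
      if (length(unknown)) {
        stop("unknown level(s) in categorical column '", nm, "': ",
             paste(unknown, collapse = ", "))
      }
      L <- length(lv)
      ref <- lv[L]
      for (l in seq_len(L - 1)) {
        cn <- paste0(nm, ".", lv[l])
        cols[[cn]] <- (xc == lv[l]) - (xc == ref)
        map_cov <- c(map_cov, nm)
        map_kind <- c(map_kind, kd)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  column_map <- tibble::tibble(
    column = colnames(X), covariate = map_cov, kind = map_kind
  )
  groups <- split(seq_len(ncol(X)), factor(map_cov, levels = unique(map_cov)))
  class(stats) <- "transform_stats"
  structure(
    list(
      X_main = X, column_map = column_map, groups = groups,
      stats = stats, schema = schema, n = n
    ),
    class = "encoded_design"
  )
}

#' @export
print.encoded_design <- function(x, ...) {
  cat("<encoded_design> n =", x$n, ", p_enc =", ncol(x$X_main))
  if (!is.null(x$pairs)) cat(", q =", nrow(x$pairs))
  cat("\n covariates:", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Add all admissible two-way interaction columns to an encoded design
#'
#' Forms one product column per unordered pair (j, k), j < k, of encoded main
#' columns, excluding pairs whose two columns encode the same categorical
#' covariate (contrast columns of one categorical are never interacted with
#' each other). Pairs are ordered lexicographically by (j, k) and all
#' downstream coefficient indexing follows this order. Interaction columns are
#' named `"a:b"` after their parents.
#'
#' The number of interactions is q = choose(p_enc, 2) - sum_c choose(d_c, 2),
#' with d_c the number of contrast columns of categorical covariate c.
#'
#' @param design An `encoded_design` from [encode_covariates()].
#' @return The design with fields `pairs` (q x 2 integer matrix), `X_int`
#'   (n x q product matrix) and `moments` (see [second_moments()]) filled in.
#' @export
build_interactions <- function(design) {
  stopifnot(inherits(design, "encoded_design"))
  X <- design$X_main
  p <- ncol(X)
  cov_of <- design$column_map$covariate
  kind_of <- design$column_map$kind
  pairs <- matrix(integer(0), 0, 2)
  if (p >= 2) {
    idx <- utils::combn(p, 2)
    same_cat <- cov_of[idx[1, ]] == cov_of[idx[2, ]] &
      kind_of[idx[1, ]] == "categorical"
    pairs <- t(idx[, !same_cat, drop = FALSE])
  }
  colnames(pairs) <- c("j", "k")
  X_int <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  if (nrow(pairs)) {
    colnames(X_int) <- paste0(colnames(X)[pairs[, 1]], ":",
                              colnames(X)[pairs[, 2]])
  }
  design$pairs <- pairs
  design$X_int <- X_int
  design$moments <- list(
    means = colMeans(X),
    cross = colMeans(X_int)
  )
  design
}

#' Sample second moments of the encoded design
#'
#' For each interaction pair (j, k) returns the sample estimate of
#' E\[x_j x_k\], i.e. `mean(X[, j] * X[, k])` over the training rows
#' (denominator n), together with the per-column means E\[x_j\] (zero for
#' centered continuous columns by construction, generally nonzero for binary
#' and categorical contrast columns). These frozen training moments are the
#' marginalization constants of the interventional Shapley values.
#'
#' @param design An `encoded_design` with interactions built.
#' @return A tibble with columns `j`, `k`, `pair` (name) and `moment`; the
#'   per-column means are attached as attribute `"means"`.
#' @export
second_moments <- function(design) {
  stopifnot(inherits(design, "encoded_design"))
  if (is.null(design$pairs)) design <- build_interactions(design)
  out <- tibble::tibble(
    j = design$pairs[, 1],
    k = design$pairs[, 2],
    pair = colnames(design$X_int),
    moment = unname(design$moments$cross)
  )
  attr(out, "means") <- design$moments$means
  out
}

#' Encode, interact and compute moments in one call
#'
#' @inheritParams encode_covariates
#' @return An `encoded_design` with `X_main`, `X_int`, `pairs` and `moments`.
#' @export
prepare_design <- function(data, schema = infer_schema(data), stats = NULL) {
  build_interactions(encode_covariates(data, schema, stats))
}

#' Number of admissible interaction pairs for a design
#'
#' @param design An `encoded_design`.
#' @return Integer q.
#' @export
n_interactions <- function(design) {
  if (is.null(design$pairs)) design <- build_interactions(design)
  nrow(design$pairs)
}

# Full n x (1 + p + q) numeric design including intercept, used by the
# sampler and the OLS baseline.
full_design_matrix <- function(design) {
  if (is.null(design$X_int)) design <- build_interactions(design)
  cbind(`(Intercept)` = 1, design$X_main, design$X_int)
}
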