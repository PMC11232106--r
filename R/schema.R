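#' Declare the type of each covariate column
#'
#' A covariate schema assigns each column of a raw covariate table one of
#' three kinds: `"continuous"`, `"binary"`, or `"categorical"`. The schema
#' drives the encoding conventions used throughout the package: continuous
#' columns are standardized, binary columns are contrast-coded to -1/+1, and a
#' categorical column with L levels becomes L-1 sum-to-zero contrast columns
#' taking values in \{-1, 0, 1\}.
#'
#' @param name Character vector of covariate names (must be unique).
#' @param kind Character vector, one of `"continuous"`, `"binary"`,
#'   `"categorical"` per covariate (recycled if length 1).
#' @param levels A list of character vectors giving the ordered levels of each
#'   categorical covariate (`NULL` entries for non-categorical ones). The
#'   *last* level in schema order is the reference level of the sum-to-zero
#'   contrasts.
#'
#' @return A tibble of class `covariate_schema` with columns `name`, `kind`
#'   and a list-column `levels`.
#' @examples
#' covariate_schema(
#'   name = c("age", "gender", "ethnicity"),
#'   kind = c("continuous", "binary", "categorical"),
#'   levels = list(NULL, NULL, c("A", "B", "C", "D", "E"))
#' )
#' @export
covariate_schema <- function(name, kind, levels = NULL) {
  kind <- rep_len(kind, length(name))
  if (is.null(levels)) levels <- vector("list", length(name))
  schema <- tibble::tibble(name = as.character(name), kind = kind, levels = levels)
  validate_schema(schema)
}

validate_schema <- function(schema) {
  stopifnot(all(c("name", "kind") %in% names(schema)))
  if (!"levels" %in% names(schema)) schema$levels <- vector("list", nrow(schema))
  if (anyDuplicated(schema$name)) {
    stop("covariate names must be unique; duplicated: ",
         paste(unique(schema$name[duplicated(schema$name)]), collapse = ", "))
  }
  bad <- setdiff(schema$kind, c("continuous", "binary", "categorical"))
  if (length(bad)) stop("unknown covariate kind(s): ", paste(bad, collapse = ", "))
  for (i in seq_len(nrow(schema))) {
    if (schema$kind[i] == "categorical") {
      lv <- schema$levels[[i]]
      if (is.null(lv) || length(lv) < 3) {
        stop("categorical covariate '", schema$name[i],
             "' must declare at least 3 levels")
      }
      if (anyDuplicated(lv)) {
        stop("duplicated levels for categorical covariate '", schema$name[i], "'")
      }
    }
  }
  class(schema) <- c("covariate_schema", class(tibble::tibble()))
  schema
}

#' Infer a covariate schema from a data frame
#'
#' Columns with exactly two distinct values become binary; character/factor
#' columns with three or more levels become categorical (levels in sorted
#' order); remaining numeric columns are continuous.
#'
#' @param data A data frame of raw covariates.
#' @param exclude Column names to skip (e.g. the response).
#' @return A [covariate_schema()].
#' @export
infer_schema <- function(data, exclude = character()) {
  cols <- setdiff(names(data), exclude)
  kinds <- character(length(cols))
  lvls <- vector("list", length(cols))
  for (i in seq_along(cols)) {
    x <- data[[cols[i]]]
    ux <- sort(unique(as.character(x[!is.na(x)])))
    if (length(ux) == 2) {
      kinds[i] <- "binary"
    } else if (is.character(x) || is.factor(x)) {
      kinds[i] <- "categorical"
      lvls[[i]] <- ux
    } else {
      kinds[i] <- "continuous"
    }
  }
  covariate_schema(cols, kinds, lvls)
}

#' Read / write a covariate schema as YAML
#'
#' The YAML representation is a list of mappings with fields `name`, `kind`
#' and (for categoricals) `levels`.
#'
#' @param path File path.
#' @return `read_schema()` returns a [covariate_schema()];
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  covariate_schema(
    name = vapply(raw, `[[`, "", "name"),
    kind = vapply(raw, `[[`, "", "kind"),
    levels = lapply(raw, function(x) {
      if (is.null(x$levels)) NULL else as.character(x$levels)
    })
  )
}

#' @rdname read_schema
#' @param schema A [covariate_schema()].
#' @export
write_schema <- function(schema, path) {
  out <- lapply(seq_len(nrow(schema)), function(i) {
    x <- list(name = schema$name[i], kind = schema$kind[i])
    if (!is.null(schema$levels[[i]])) x$levels <- as.list(schema$levels[[i]])
    x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
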