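#' Construct and validate a unit-level causal dataset
#'
#' Bundles an outcome vector, a binary treatment indicator and a covariate
#' table into a validated `causal_data` object, the input to every strata
#' builder and estimator in the package. Binary outcomes are carried as 0/1
#' numerics, so risk differences use the same mean-difference code path as
#' continuous outcomes.
#'
#' @param y Numeric outcome per unit; binary outcomes coded 0/1. No missing
#'   values.
#' @param t Treatment indicator per unit, values 0 and 1 only; both arms must
#'   be represented.
#' @param x Covariate table (data frame or coercible), one row per unit.
#'   Numeric columns are treated as continuous; character/factor/logical
#'   columns as categorical (stored as factors, never auto-ordinalized).
#' @param unit_id Optional vector of unique unit identifiers. When absent,
#'   row order defines unit identity.
#'
#' @return A `causal_data` object: a list with elements `y`, `t`, `x`,
#'   `unit_id`, `n`, `p` and (for synthetic data) an optional `truth`
#'   attribute.
#'
#' @examples
#' d <- causal_data(y = c(1, 3, 5, 3), t = c(0, 0, 1, 1),
#'                  x = data.frame(x1 = c(0.1, 0.4, 0.6, 0.9)))
#' d$n
#' @export
causal_data <- function(y, t, x, unit_id = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  y <- as.numeric(y)
  cc_assert(length(y) == nrow(x) && length(t) == nrow(x),
            "cc_size_error", "y, t and x must describe the same units")
  cc_assert(nrow(x) >= 2L, "cc_size_error", "need at least 2 units")
  cc_assert(ncol(x) >= 1L, "cc_size_error", "need at least 1 covariate")
  if (anyNA(y)) cc_error("cc_missing_data_error", "missing values in outcome")
  if (anyNA(t)) cc_error("cc_missing_data_error", "missing values in treatment")
  if (anyNA(x)) cc_error("cc_missing_data_error", "missing values in covariates")
  t <- as.numeric(t)
  if (!all(t %in% c(0, 1))) {
    cc_error("cc_treatment_error",
             "treatment must be coded 0/1; found other values")
  }
  if (length(unique(t)) < 2L) {
    cc_error("cc_treatment_error", "both treatment arms must be present")
  }
  for (j in seq_along(x)) {
    if (!is.numeric(x[[j]])) x[[j]] <- factor(x[[j]])
  }
  if (!is.null(unit_id)) {
    cc_assert(length(unit_id) == length(y) && !anyNA(unit_id) &&
                !anyDuplicated(unit_id),
              "cc_size_error", "unit_id must be unique, complete, length n")
  } else {
    unit_id <- seq_along(y)
  }
  structure(
    list(y = y, t = as.integer(t), x = x, unit_id = unit_id,
         n = length(y), p = ncol(x)),
    class = "causal_data")
}

#' Read a unit-level dataset from a delimited text file
#'
#' Reads a CSV (or TSV, by file extension) with a header row and maps columns
#' to roles. Categorical covariates are inferred from non-numeric content or
#' declared explicitly.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file with a header row.
#' @param outcome,treatment Column names for the outcome and the 0/1
#'   treatment indicator.
#' @param covariates Character vector of covariate column names; `NULL`
#'   (default) uses all remaining columns.
#' @param categorical Optional character vector of covariate names to force
#'   to categorical even if numeric-looking.
#' @param id Optional unit-identifier column name.
#'
#' @return A validated [causal_data] object; row order is preserved.
#' @export
read_causal_data <- function(path, outcome, treatment, covariates = NULL,
                             categorical = NULL, id = NULL) {
  if (!file.exists(path)) {
    cc_error("cc_file_error", sprintf("input file not found: %s", path))
  }
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  roles <- c(outcome, treatment, covariates, id)
  missing_cols <- setdiff(roles, names(df))
  if (length(missing_cols)) {
    cc_error("cc_role_error",
             sprintf("role columns not in file: %s",
                     paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(c(outcome, treatment, covariates, id))) {
    cc_error("cc_role_error", "a column was assigned more than one role")
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(df), c(outcome, treatment, id))
    if (!length(covariates)) {
      cc_error("cc_role_error", "no covariate columns remain")
    }
  }
  xx <- df[covariates]
  for (nm in intersect(categorical, covariates)) xx[[nm]] <- factor(xx[[nm]])
  causal_data(y = df[[outcome]], t = df[[treatment]], x = xx,
              unit_id = if (!is.null(id)) df[[id]])
}

#' @export
print.causal_data <- function(x, ...) {
  types <- vapply(x$x, function(col) if (is.numeric(col)) "cont" else "cat",
                  character(1))
  cat(sprintf("<causal_data> n = %d units, p = %d covariates (%d continuous, %d categorical)\n",
              x$n, x$p, sum(types == "cont"), sum(types == "cat")))
  cat(sprintf("  treated: %d, control: %d\n", sum(x$t == 1), sum(x$t == 0)))
  invisible(x)
}
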