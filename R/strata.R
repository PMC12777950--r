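# Strata assignments: the common currency between builders and estimators.
# Builders see only the covariate table, never treatment or outcome; treatment
# counts are attached later by the pruning/estimation layer.

new_strata_assignment <- function(labels, method, params = list(),
                                  objective = NA_real_) {
  labels <- as.integer(labels)
  cc_assert(!anyNA(labels) && all(labels >= 1L), "cc_internal_error",
            "labels must be positive integers")
  # compact to 1..J preserving label order (empty strata disappear)
  u <- sort(unique(labels))
  labels <- match(labels, u)
  structure(
    list(labels = labels, J = length(u), n = length(labels),
         method = method, params = params, objective = objective),
    class = "strata_assignment")
}

#' Per-stratum unit and treatment-arm counts
#'
#' @param assignment A `strata_assignment`.
#' @param t Optional 0/1 treatment vector; when supplied, per-arm counts
#'   `n_1j` and `n_0j` are filled in.
#' @return A data frame with one row per stratum: `stratum`, `n_j` and, with
#'   `t`, `n_1j`, `n_0j`.
#' @export
strata_counts <- function(assignment, t = NULL) {
  stopifnot(inherits(assignment, "strata_assignment"))
  J <- assignment$J
  n_j <- tabulate(assignment$labels, nbins = J)
  out <- data.frame(stratum = seq_len(J), n_j = n_j)
  if (!is.null(t)) {
    cc_assert(length(t) == assignment$n, "cc_size_error",
              "treatment vector length must match the assignment")
    out$n_1j <- vapply(seq_len(J), function(j)
      sum(t[assignment$labels == j] == 1), numeric(1))
    out$n_0j <- out$n_j - out$n_1j
  }
  out
}

#' @export
print.strata_assignment <- function(x, ...) {
  cat(sprintf("<strata_assignment> method = %s, J = %d strata over %d units\n",
              x$method, x$J, x$n))
  if (is.finite(x$objective)) cat(sprintf("  objective = %g\n", x$objective))
  sizes <- tabulate(x$labels, nbins = x$J)
  cat(sprintf("  stratum sizes: min %d / median %g / max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Coarsening rules for exact matching
#'
#' Builds per-covariate coarsening rules: continuous covariates are cut into
#' `bins` equal-width intervals over their observed range (last bin
#' right-closed); categorical covariates coarsen to their own levels
#' (identity). The default bin count is Sturges' rule,
#' `ceiling(log2(n)) + 1`, a deterministic choice that depends only on the
#' covariate table.
#'
#' @param x Covariate table (data frame).
#' @param bins Integer bin count(s) for continuous covariates: a scalar
#'   recycled across columns or a vector/named vector per column. Ignored for
#'   categorical columns.
#' @return A `coarsen_spec`: a named list of per-covariate rules, each either
#'   `list(type = "continuous", edges = <numeric>)` with strictly increasing
#'   edges, or `list(type = "categorical", levels = <character>)`.
#' @export
coarsen_spec <- function(x, bins = NULL) {
  x <- as.data.frame(x)
  cc_assert(ncol(x) >= 1L, "cc_size_error", "empty covariate table")
  default_bins <- ceiling(log2(nrow(x))) + 1L
  if (is.null(bins)) bins <- default_bins
  if (length(bins) == 1L) bins <- rep(bins, ncol(x))
  if (!is.null(names(bins))) bins <- bins[names(x)]
  cc_assert(all(bins >= 1L, na.rm = TRUE), "cc_argument_error",
            "bin counts must be >= 1")
  rules <- vector("list", ncol(x))
  names(rules) <- names(x)
  for (j in seq_along(x)) {
    col <- x[[j]]
    if (is.numeric(col)) {
      m <- as.integer(bins[j])
      rng <- range(col)
      edges <- if (rng[1] == rng[2]) rng[1] + c(-0.5, 0.5)
               else seq(rng[1], rng[2], length.out = m + 1L)
      rules[[j]] <- list(type = "continuous", edges = edges)
    } else {
      rules[[j]] <- list(type = "categorical", levels = levels(factor(col)))
    }
  }
  structure(rules, class = "coarsen_spec")
}

#' Coarsened exact matching strata
#'
#' Coarsens each covariate by its rule and forms strata as the occupied
#' unique combinations of the coarsened codes (exact matching on the
#' coarsened vector). Deterministic: no randomness enters. With equal bin
#' count `M` per covariate the number of strata is at most `M^p`. Labels are
#' assigned by the lexicographic order of the code tuples, so permuting rows
#' permutes labels identically.
#'
#' @param x Covariate table (data frame); columns numeric or categorical.
#' @param spec A [coarsen_spec]; defaults to `coarsen_spec(x)`.
#' @return A `strata_assignment` with `method = "cem"`.
#' @examples
#' x <- data.frame(x1 = c(0.1, 0.4, 0.6, 0.9))
#' cem_strata(x, coarsen_spec(x, bins = 2))$labels  # 1 1 2 2
#' @export
cem_strata <- function(x, spec = coarsen_spec(x)) {
  x <- as.data.frame(x)
  cc_assert(ncol(x) >= 1L && nrow(x) >= 1L, "cc_size_error",
            "empty covariate table")
  missing_rules <- setdiff(names(x), names(spec))
  if (length(missing_rules)) {
    cc_error("cc_argument_error",
             sprintf("coarsening spec lacks rules for: %s",
                     paste(missing_rules, collapse = ", ")))
  }
  codes <- matrix(0L, nrow(x), ncol(x))
  for (j in seq_along(x)) {
    rule <- spec[[names(x)[j]]]
    if (rule$type == "continuous") {
      cc_assert(is.numeric(x[[j]]), "cc_argument_error",
                "continuous rule applied to a categorical column")
      cd <- findInterval(x[[j]], rule$edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
      if (any(x[[j]] < rule$edges[1] | x[[j]] > rule$edges[length(rule$edges)])) {
        cc_error("cc_argument_error", "continuous value outside all bins")
      }
      codes[, j] <- cd
    } else {
      f <- factor(x[[j]], levels = rule$levels)
      if (anyNA(f)) cc_error("cc_argument_error",
                             "categorical level absent from the coarsening rule")
      codes[, j] <- as.integer(f)
    }
  }
  # canonical labels: lexicographic rank of each occupied code tuple
  key <- do.call(paste, c(lapply(seq_len(ncol(codes)), function(j)
    formatC(codes[, j], width = 9, flag = "0")), sep = "\r"))
  labels <- match(key, sort(unique(key)))
  new_strata_assignment(labels, method = "cem",
                        params = list(spec = spec))
}
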