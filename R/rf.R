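#' Random-forest proximity strata
#'
#' Builds confounder strata by unsupervised random-forest clustering:
#' a synthetic second class is created by sampling each covariate column
#' independently from its empirical marginal (destroying the joint
#' dependence), a classification forest is grown to separate observed from
#' synthetic units, the proximity between two observed units is the fraction
#' of trees in which they share a terminal node, and Ward agglomeration on
#' the distance `sqrt(1 - proximity)` is cut to yield `k` strata.
#'
#' Two stabilizers keep the proximity informative for Ward clustering: the
#' trees are grown with terminal nodes no smaller than
#' `max(5, n / (5 k))` units, so that co-location probabilities within a
#' would-be stratum stay well away from zero (fully grown trees isolate
#' almost every pair and all distances collapse towards 1); and the
#' proximity is averaged over `n_forests` independent synthetic-class
#' draws, which removes the dependence on a single marginal resample. All
#' randomness still derives from the one `seed`.
#'
#' Identical covariate rows have proximity 1 and distance 0, so duplicated
#' units always co-locate. Proximities lie in `[0, 1]` by construction.
#'
#' @param x Covariate table; numeric and categorical columns are handled
#'   natively by the forest.
#' @param k Target number of strata, `1 <= k <= n`.
#' @param n_trees Total number of trees across forests (default 500).
#' @param seed Integer seed; one seed drives the synthetic-class sampling
#'   and the forests' bootstrap/feature randomness.
#' @param n_forests Number of synthetic-class draws to average over
#'   (default 5).
#' @param nodesize Minimum terminal-node size; default `max(5, n / (5 k))`.
#' @return A `strata_assignment` with `method = "rf"` and
#'   `params$proximity` (the n-by-n observed-unit proximity matrix).
#' @export
rf_proximity_strata <- function(x, k, n_trees = 500L, seed = 1L,
                                n_forests = 5L, nodesize = NULL) {
  x <- as.data.frame(x)
  n <- nrow(x)
  cc_assert(k >= 1L && k <= n, "cc_argument_error",
            "k must satisfy 1 <= k <= n")
  cc_assert(n_trees >= 1L, "cc_argument_error", "n_trees must be >= 1")
  n_forests <- min(n_forests, n_trees)
  nodesize <- nodesize %||% max(5L, ceiling(n / (5 * k)))
  for (j in seq_along(x)) if (!is.numeric(x[[j]])) x[[j]] <- factor(x[[j]])
  ntrees_per <- diff(round(seq(0, n_trees, length.out = n_forests + 1L)))
  res <- with_seed(seed, {
    acc <- matrix(0, n, n)
    for (f in seq_len(n_forests)) {
      synth <- as.data.frame(lapply(x, function(col)
        col[sample.int(n, n, replace = TRUE)]))
      both <- rbind(x, synth)
      cls <- factor(rep(c("observed", "synthetic"), each = n))
      fit <- randomForest::randomForest(
        x = both, y = cls, ntree = ntrees_per[f],
        proximity = TRUE, oob.prox = FALSE, nodesize = nodesize)
      acc <- acc + fit$proximity[seq_len(n), seq_len(n)] * ntrees_per[f]
    }
    acc / n_trees
  })
  prox <- (res + t(res)) / 2   # enforce exact symmetry against rounding
  diag(prox) <- 1
  d <- sqrt(pmax(1 - prox, 0))
  labels <- if (k == 1L) rep(1L, n) else {
    hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    stats::cutree(hc, k = k)
  }
  new_strata_assignment(
    labels, method = "rf",
    params = list(k = k, n_trees = n_trees, seed = seed,
                  n_forests = n_forests, nodesize = nodesize,
                  proximity = prox))
}
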