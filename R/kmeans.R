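# k-means quantization of the covariate table. The cluster centers play the
# role of an m-point codebook: strata are the Voronoi cells of the fitted
# centers and the objective is the empirical quantization error (within-
# cluster sum of squared Euclidean distances) in the working feature space.

# Numeric design matrix for distance-based builders: one-hot encode factors,
# optionally z-score every column (constant columns are left centered at 0).
encode_covariates <- function(x, standardize = TRUE) {
  x <- as.data.frame(x)
  cols <- lapply(seq_along(x), function(j) {
    col <- x[[j]]
    if (is.numeric(col)) {
      m <- matrix(col, ncol = 1L,
                  dimnames = list(NULL, names(x)[j]))
    } else {
      f <- factor(col)
      m <- outer(f, levels(f), `==`) * 1
      colnames(m) <- paste(names(x)[j], levels(f), sep = ".")
    }
    m
  })
  xm <- do.call(cbind, cols)
  if (standardize) {
    ctr <- colMeans(xm)
    sds <- apply(xm, 2L, stats::sd)
    sds[sds == 0] <- 1
    xm <- sweep(sweep(xm, 2L, ctr), 2L, sds, `/`)
  }
  xm
}

# Squared Euclidean distances between rows of xm and rows of centers.
dist2_to_centers <- function(xm, centers) {
  d2 <- outer(rowSums(xm^2), rowSums(centers^2), `+`) -
    2 * xm %*% t(centers)
  pmax(d2, 0)
}

# k-means++ seeding: first center uniform, then each new center drawn with
# probability proportional to the squared distance to the nearest chosen one.
kmeanspp_init <- function(xm, k) {
  n <- nrow(xm)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- dist2_to_centers(xm, xm[idx[1], , drop = FALSE])[, 1]
  for (j in seq_len(k - 1L) + 1L) {
    tot <- sum(d2)
    idx[j] <- if (tot <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / tot)
    d2 <- pmin(d2, dist2_to_centers(xm, xm[idx[j], , drop = FALSE])[, 1])
  }
  xm[idx, , drop = FALSE]
}

# Lloyd iteration. Empty clusters are dropped on the fly; returns labels,
# centers, the final objective (within-cluster SSE) and the per-iteration
# objective trace (non-increasing by construction of the two Lloyd steps).
lloyd_kmeans <- function(xm, centers, iter_max = 300L) {
  labels <- rep(0L, nrow(xm))
  trace <- numeric(0)
  for (it in seq_len(iter_max)) {
    d2 <- dist2_to_centers(xm, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    trace <- c(trace, sum(d2[cbind(seq_len(nrow(xm)), new_labels)]))
    if (identical(new_labels, labels)) break
    labels <- new_labels
    occupied <- sort(unique(labels))
    labels <- match(labels, occupied)
    centers <- do.call(rbind, lapply(seq_along(occupied), function(g)
      colMeans(xm[labels == g, , drop = FALSE])))
  }
  d2 <- dist2_to_centers(xm, centers)
  list(labels = labels, centers = centers,
       objective = sum(d2[cbind(seq_len(nrow(xm)), labels)]),
       trace = trace)
}

#' k-means quantization strata
#'
#' Clusters the covariate table with Lloyd's algorithm, k-means++ seeding and
#' multiple restarts, and returns the cluster memberships as confounder
#' strata. Because the unweighted Euclidean norm is scale-sensitive,
#' continuous columns are z-scored and categorical columns one-hot encoded
#' (then z-scored) by default. The objective recorded on the assignment is
#' the within-cluster sum of squared distances in the working space, the
#' empirical quantization error of the fitted codebook times `n`.
#'
#' @param x Covariate table.
#' @param k Requested number of clusters, `1 <= k <= n`. If the table has
#'   fewer than `k` distinct rows, `k` is lowered to that number with a
#'   warning. Empty clusters are dropped, so the realized `J` can be below
#'   `k`.
#' @param seed Integer seed driving seeding and restarts.
#' @param standardize Standardize/encode covariates first (default `TRUE`).
#' @param nstart Number of k-means++ restarts; the best objective wins.
#' @param iter_max Lloyd iteration cap per restart.
#' @return A `strata_assignment` with `method = "kmeans"`, the winning
#'   objective, and `params$centers` (working-space centers).
#' @examples
#' a <- kmeans_strata(data.frame(x = c(0, 1, 10, 11)), k = 2, seed = 1,
#'                    standardize = FALSE)
#' a$objective  # 1.0
#' @export
kmeans_strata <- function(x, k, seed = 1L, standardize = TRUE,
                          nstart = 10L, iter_max = 300L) {
  x <- as.data.frame(x)
  n <- nrow(x)
  cc_assert(k >= 1L && k <= n, "cc_argument_error",
            "k must satisfy 1 <= k <= n")
  xm <- encode_covariates(x, standardize = standardize)
  n_distinct <- nrow(unique(xm))
  if (n_distinct < k) {
    cc_warn("cc_degenerate_warning",
            sprintf("only %d distinct covariate rows; lowering k from %d",
                    n_distinct, k))
    k <- n_distinct
  }
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(nstart)) {
      init <- kmeanspp_init(xm, k)
      # fast C Lloyd when no cluster empties out; otherwise the internal
      # Lloyd, which drops empty clusters instead of failing
      fit <- tryCatch({
        cfit <- suppressWarnings(stats::kmeans(xm, init, iter.max = iter_max,
                                               algorithm = "Lloyd"))
        list(labels = cfit$cluster, centers = cfit$centers,
             objective = cfit$tot.withinss, trace = NULL)
      }, error = function(e) lloyd_kmeans(xm, init, iter_max = iter_max))
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  new_strata_assignment(
    best$labels, method = "kmeans",
    params = list(k = k, seed = seed, standardize = standardize,
                  nstart = nstart, centers = best$centers,
                  objective_trace = best$trace),
    objective = best$objective)
}

#' Empirical quantization error of a codebook
#'
#' Mean over units of the squared Euclidean distance to the nearest center:
#' the empirical analogue of the order-two quantization error of an m-point
#' quantizer. Zero exactly when every row coincides with some center; with a
#' single center the minimizing choice is the column-mean vector and the
#' value is the mean squared deviation.
#'
#' @param x Covariate table or numeric matrix (no encoding/standardization is
#'   applied; pass the same working space as the centers).
#' @param centers Numeric matrix (or vector for one dimension) of codebook
#'   points, one row per center.
#' @return Nonnegative scalar.
#' @examples
#' quantization_error(c(0, 1, 10, 11), c(0.5, 10.5))  # 0.25
#' @export
quantization_error <- function(x, centers) {
  xm <- if (is.data.frame(x)) as.matrix(x) else
    if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  cm <- if (is.matrix(centers)) centers else
    matrix(as.numeric(centers), ncol = ncol(xm))
  cc_assert(nrow(cm) >= 1L, "cc_argument_error", "need at least one center")
  if (ncol(cm) != ncol(xm)) {
    cc_error("cc_dimension_error",
             "centers and data have different dimensions")
  }
  storage.mode(xm) <- "double"
  mean(apply(dist2_to_centers(xm, cm), 1L, min))
}
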