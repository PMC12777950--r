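# Shared fixtures, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# The two-strata worked example: stratum 1 treated Y = {3,5}, control {1,3};
# stratum 2 treated {8,6}, control {5,3}. A single covariate separates the
# strata so that CEM with 2 bins (and k-means with k = 2) recovers them.
toy_two_strata <- function() {
  causal_data(
    y = c(3, 5, 1, 3, 8, 6, 5, 3),
    t = c(1, 1, 0, 0, 1, 1, 0, 0),
    x = data.frame(x1 = c(0, 0.2, 0.1, 0.3, 10, 10.2, 10.1, 10.3)))
}

toy_pruned <- function(d = toy_two_strata()) {
  a <- cem_strata(d$x, coarsen_spec(d$x, bins = 2))
  prune_strata(a, d$t)
}

# Random dataset with a random stratification, for property tests. Every
# stratum is guaranteed both arms so no pruning interferes.
random_case <- function(seed, n = NULL, J = NULL) {
  set.seed(seed)
  J <- J %||% sample(2:6, 1)
  n <- n %||% (J * sample(4:10, 1))
  labels <- rep(seq_len(J), length.out = n)
  t <- unlist(lapply(seq_len(J), function(j) {
    nj <- sum(labels == j)
    n1 <- sample(seq_len(nj - 1L), 1)
    sample(c(rep(1L, n1), rep(0L, nj - n1)))
  }))
  d <- causal_data(y = rnorm(n, sd = 3), t = t,
                   x = data.frame(x1 = rnorm(n)))
  a <- new_strata_assignment_for_test(labels)
  list(data = d, pruned = suppressWarnings(prune_strata(a, d$t)))
}

# External labels injected as a strata_assignment (the estimator accepts any
# covariate-built stratification; tests may fabricate one directly).
new_strata_assignment_for_test <- function(labels) {
  a <- structure(list(labels = as.integer(labels),
                      J = length(unique(labels)),
                      n = length(labels), method = "external",
                      params = list(), objective = NA_real_),
                 class = "strata_assignment")
  a
}

expect_cc_error <- function(expr, class) {
  expect_error(expr, class = class)
}
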