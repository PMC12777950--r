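# --- CEM coarsening ---------------------------------------------------------

test_that("equal-width coarsening reproduces hand-computed bin membership", {
  x <- data.frame(x1 = c(0.1, 0.4, 0.6, 0.9))
  a <- cem_strata(x, coarsen_spec(x, bins = 2))
  expect_equal(a$labels, c(1L, 1L, 2L, 2L))
  expect_equal(a$J, 2)

  # all-categorical: strata are the occupied covariate patterns
  xc <- data.frame(a = factor(c(0, 0, 1, 1)), b = factor(c(0, 1, 0, 1)))
  ac <- cem_strata(xc)
  expect_equal(ac$J, 4)
  expect_equal(anyDuplicated(ac$labels), 0)

  # degenerate coarsening: one bin per covariate collapses everything
  a1 <- cem_strata(x, coarsen_spec(x, bins = 1))
  expect_equal(a1$J, 1)
  expect_equal(a1$labels, rep(1L, 4))
})

test_that("cem strata respect the M^p codebook bound and are deterministic", {
  set.seed(41)
  x <- data.frame(u = rnorm(60), v = rnorm(60), w = rnorm(60))
  for (m in c(2, 3, 4)) {
    a <- cem_strata(x, coarsen_spec(x, bins = m))
    expect_lte(a$J, m^3)
    expect_equal(sum(strata_counts(a)$n_j), 60)
  }
  expect_identical(cem_strata(x)$labels, cem_strata(x)$labels)
  # default bin count is Sturges' rule
  spec <- coarsen_spec(x)
  expect_length(spec$u$edges, (ceiling(log2(60)) + 1) + 1)
})

test_that("cem coarsening is permutation-equivariant", {
  set.seed(7)
  x <- data.frame(a = rnorm(40), b = factor(sample(letters[1:3], 40, TRUE)))
  spec <- coarsen_spec(x, bins = 3)
  base <- cem_strata(x, spec)$labels
  for (s in 1:5) {
    perm <- sample(40)
    expect_identical(cem_strata(x[perm, , drop = FALSE], spec)$labels,
                     base[perm])
  }
})

# --- k-means quantization ----------------------------------------------------

test_that("k-means recovers the brute-force optimal 2-partition", {
  x <- data.frame(x = c(0, 1, 10, 11))
  # oracle: enumerate all 2-partitions, minimize within-cluster SSE
  best <- Inf
  for (mask in 1:(2^4 - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:3)))
    if (!any(g) || all(g)) next
    sse <- sum((x$x[g] - mean(x$x[g]))^2) + sum((x$x[!g] - mean(x$x[!g]))^2)
    best <- min(best, sse)
  }
  expect_equal(best, 1.0)   # frozen: partition {0,1} | {10,11}

  a <- kmeans_strata(x, k = 2, seed = 1, standardize = FALSE)
  expect_equal(a$objective, best)
  expect_equal(a$labels[1], a$labels[2])
  expect_equal(a$labels[3], a$labels[4])
  expect_false(a$labels[1] == a$labels[3])
  expect_equal(unname(sort(a$params$centers[, 1])), c(0.5, 10.5))

  # seed-invariance at the unique optimum
  for (s in c(2, 17, 99)) {
    expect_equal(kmeans_strata(x, 2, seed = s, standardize = FALSE)$objective,
                 best)
  }
})

test_that("k-means edge cases: k = 1, k = n, too few distinct rows", {
  x <- data.frame(x = c(0, 1, 10, 11))
  a1 <- kmeans_strata(x, 1, seed = 1, standardize = FALSE)
  expect_equal(a1$J, 1)
  expect_equal(a1$objective, sum((x$x - mean(x$x))^2))

  an <- kmeans_strata(x, 4, seed = 1, standardize = FALSE)
  expect_equal(an$J, 4)
  expect_equal(an$objective, 0)

  xdup <- data.frame(x = c(1, 1, 2, 2, 3, 3))
  expect_warning(ad <- kmeans_strata(xdup, 5, seed = 1, standardize = FALSE),
                 class = "cc_degenerate_warning")
  expect_equal(ad$J, 3)
})

test_that("the Lloyd objective trace is non-increasing", {
  set.seed(13)
  x <- data.frame(a = rnorm(200), b = rnorm(200))
  xm <- coarsenCausal:::encode_covariates(x)
  for (k in c(3, 8)) {
    set.seed(k)
    init <- coarsenCausal:::kmeanspp_init(xm, k)
    fit <- coarsenCausal:::lloyd_kmeans(xm, init)
    expect_true(all(diff(fit$trace) <= 1e-8))
    expect_equal(fit$objective, fit$trace[length(fit$trace)])
  }
})

test_that("quantization error matches its definition", {
  expect_equal(quantization_error(c(0, 1, 10, 11), c(0.5, 10.5)), 0.25)
  # perfect quantizer
  expect_equal(quantization_error(c(0, 1, 10, 11), c(0, 1, 10, 11)), 0)
  # single center at the mean = mean squared deviation
  y <- c(2, 4, 9)
  expect_equal(quantization_error(y, mean(y)), mean((y - mean(y))^2))
  expect_cc_error(quantization_error(matrix(1:4, 2), matrix(1:3, 1)),
                  "cc_dimension_error")
})

# --- random-forest proximity clustering --------------------------------------

test_that("rf proximity strata separate two well-separated point clouds", {
  set.seed(11)
  x <- data.frame(x1 = c(rnorm(50), rnorm(50, 20)),
                  x2 = c(rnorm(50), rnorm(50, 20)))
  truth <- rep(1:2, each = 50)
  a <- rf_proximity_strata(x, k = 2, seed = 3)
  tab <- table(a$labels, truth)
  agreement <- max(sum(diag(tab)), tab[1, 2] + tab[2, 1]) / 100
  expect_equal(agreement, 1)

  prox <- a$params$proximity
  expect_equal(prox, t(prox))
  expect_true(all(diag(prox) == 1))
  expect_true(all(prox >= 0 & prox <= 1))
})

test_that("duplicated covariate rows always co-locate", {
  x <- data.frame(u = c(1, 1, 2, 3, 8), v = c(5, 5, 6, 7, 9))
  a <- rf_proximity_strata(x, k = 3, n_trees = 100, seed = 2)
  prox <- a$params$proximity
  expect_equal(prox[1, 2], 1)
  expect_equal(a$labels[1], a$labels[2])
})

# --- builder contract --------------------------------------------------------

test_that("builders never see treatment or outcome", {
  # signature-level: builders take only covariates; additionally, labels are
  # unchanged when Y and T are permuted (they cannot react to them)
  set.seed(5)
  d <- generate_data(cc_scenario("linear"), 120, seed = 5)
  l_cem <- cem_strata(d$x)$labels
  l_km <- kmeans_strata(d$x, 6, seed = 9)$labels
  d_perm <- causal_data(y = rev(d$y), t = sample(d$t), x = d$x)
  expect_identical(cem_strata(d_perm$x)$labels, l_cem)
  expect_identical(kmeans_strata(d_perm$x, 6, seed = 9)$labels, l_km)
})

test_that("strata counts partition the sample and attach arm counts", {
  set.seed(3)
  d <- generate_data(cc_scenario("discrete"), 150, seed = 3)
  a <- cem_strata(d$x)
  cnt <- strata_counts(a, d$t)
  expect_equal(sum(cnt$n_j), 150)
  expect_equal(cnt$n_1j + cnt$n_0j, cnt$n_j)
  expect_true(all(cnt$n_j >= 1))
  expect_equal(sort(unique(a$labels)), seq_len(a$J))
})
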