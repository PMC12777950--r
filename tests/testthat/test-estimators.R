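test_that("the two-strata worked example is reproduced exactly", {
  d <- toy_two_strata()
  pr <- toy_pruned(d)
  est <- ate_estimate(d, pr)
  # tau = 0.5 (4 - 2) + 0.5 (7 - 4); each within-arm variance is 2
  expect_identical(est$tau_hat, 2.5)
  expect_identical(est$se, 1.0)
  expect_identical(est$var_hat, 1.0)
  expect_equal(sum(est$strata_table$weight), 1)
  # ATT with equal prevalence in each stratum collapses to the ATE
  att <- att_estimate(d, pr)
  expect_equal(att$tau_hat, 2.5)
  expect_equal(att$var_hat, est$var_hat)
  expect_true(all(att$strata_table$w_j == 1))
})

test_that("pruning applies the retention rule and records reasons", {
  t <- c(rep(1, 2), rep(0, 2), rep(1, 3), rep(0, 4))
  a <- new_strata_assignment_for_test(c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3, 3))
  expect_warning(pr <- prune_strata(a, t), class = "cc_pruning_warning")
  expect_equal(pr$retained, 1)
  expect_equal(pr$n_used, 4)
  expect_equal(pr$dropped$reason[pr$dropped$stratum == 2], "no_control")
  expect_equal(pr$dropped$reason[pr$dropped$stratum == 3], "no_treated")

  # mixed everywhere: a no-op
  t2 <- c(1, 0, 1, 0, 1, 0)
  a2 <- new_strata_assignment_for_test(c(1, 1, 2, 2, 3, 3))
  pr2 <- prune_strata(a2, t2)
  expect_equal(nrow(pr2$dropped), 0)
  expect_equal(pr2$n_used, 6)

  # min_per_arm = 2 drops a (1, 5) stratum with its own reason
  t3 <- c(1, 0, 0, 0, 0, 0, 1, 1, 0, 0)
  a3 <- new_strata_assignment_for_test(c(rep(1, 6), rep(2, 4)))
  expect_warning(pr3 <- prune_strata(a3, t3, min_per_arm = 2))
  expect_equal(pr3$dropped$reason, "below_min_per_arm")
  expect_equal(pr3$dropped$stratum, 1)

  # nothing retained -> estimation impossible
  expect_cc_error(
    suppressWarnings(prune_strata(
      new_strata_assignment_for_test(c(1, 1, 2, 2)), c(1, 1, 0, 0))),
    "cc_no_strata_error")
})

test_that("ate estimator agrees with the estimating-equation oracle", {
  for (seed in 1:100) {
    case <- random_case(seed)
    est <- suppressWarnings(ate_estimate(case$data, case$pruned))
    root <- estimating_equation_root(case$data, case$pruned)
    expect_lt(abs(est$tau_hat - root), 1e-10)
  }
})

test_that("J = 1 collapses to the classical two-sample comparison", {
  set.seed(21)
  d <- causal_data(y = rnorm(30), t = rbinom(30, 1, 0.5) * 0 + rep(c(0, 1), 15),
                   x = data.frame(x = rnorm(30)))
  a <- new_strata_assignment_for_test(rep(1L, 30))
  est <- ate_estimate(d, prune_strata(a, d$t))
  y1 <- d$y[d$t == 1]; y0 <- d$y[d$t == 0]
  expect_equal(est$tau_hat, mean(y1) - mean(y0))
  expect_equal(est$var_hat, var(y1) / length(y1) + var(y0) / length(y0))
  # oracle agrees here too, and ATT = ATE exactly at J = 1
  expect_equal(estimating_equation_root(d, prune_strata(a, d$t)),
               est$tau_hat)
  att <- att_estimate(d, prune_strata(a, d$t))
  expect_equal(att$strata_table$w_j, 1)
  expect_equal(att$tau_hat, est$tau_hat)
})

test_that("constant outcomes give a zero estimate with zero variance", {
  d <- causal_data(y = rep(4, 8), t = rep(c(1, 0), 4),
                   x = data.frame(x = rep(c(0, 0, 1, 1), 2)))
  a <- new_strata_assignment_for_test(rep(1:2, each = 4))
  est <- ate_estimate(d, prune_strata(a, d$t))
  expect_equal(est$tau_hat, 0)
  expect_equal(est$var_hat, 0)
  expect_equal(estimating_equation_root(d, prune_strata(a, d$t)), 0)
})

test_that("ATT odds weights follow the arm-share ratio", {
  # counts (3,1) and (1,3): w = 3 and 1/3
  t <- c(1, 1, 1, 0, 1, 0, 0, 0)
  y <- c(5, 6, 7, 1, 9, 2, 3, 4)
  d <- causal_data(y, t, data.frame(x = 1:8))
  a <- new_strata_assignment_for_test(rep(1:2, each = 4))
  att <- suppressWarnings(att_estimate(d, prune_strata(a, t)))
  expect_equal(att$strata_table$w_j, c(3, 1 / 3))
  w <- att$strata_table
  expect_equal(att$tau_hat,
               sum(w$n_j / 8 * (w$ybar_1j - w$w_j * w$ybar_0j)))
})

test_that("ATT equals ATE whenever prevalence is constant across strata", {
  for (seed in 1:20) {
    set.seed(seed)
    J <- sample(2:5, 1)
    nj <- sample(c(4, 8), J, replace = TRUE)
    labels <- rep(seq_len(J), nj)
    t <- unlist(lapply(nj, function(m) sample(rep(c(1, 0), m / 2))))
    d <- causal_data(rnorm(sum(nj)), t, data.frame(x = rnorm(sum(nj))))
    pr <- prune_strata(new_strata_assignment_for_test(labels), t)
    ate <- ate_estimate(d, pr); att <- att_estimate(d, pr)
    expect_equal(att$tau_hat, ate$tau_hat)
    expect_equal(att$var_hat, ate$var_hat)
  }
})

test_that("variances are nonnegative and weights sum to one", {
  for (seed in 101:130) {
    case <- random_case(seed)
    est <- suppressWarnings(ate_estimate(case$data, case$pruned))
    expect_gte(est$var_hat, 0)
    expect_equal(sum(est$strata_table$weight), 1)
    expect_true(est$ci[1] <= est$tau_hat && est$tau_hat <= est$ci[2])
  }
})

test_that("singleton arms borrow the pooled within-arm variance", {
  # stratum 2 has a single treated unit; its variance slot must use the
  # pooled within-arm variance, not NA
  y <- c(1, 3, 2, 4, 10, 5, 7)
  t <- c(1, 1, 0, 0, 1, 0, 0)
  d <- causal_data(y, t, data.frame(x = 1:7))
  a <- new_strata_assignment_for_test(c(1, 1, 1, 1, 2, 2, 2))
  expect_warning(est <- ate_estimate(d, prune_strata(a, t)),
                 class = "cc_singleton_warning")
  tab <- est$strata_table
  expect_equal(tab$s2_1j[tab$stratum == 2], 2)  # pooled from stratum 1
  expect_true(is.finite(est$var_hat) && est$var_hat > 0)
})

test_that("wald inference matches the normal reference", {
  w <- wald_inference(-0.021, 0.014)
  expect_equal(w$z, -1.5)
  expect_equal(w$p_value, 2 * pnorm(-1.5))
  expect_equal(round(w$p_value, 2), 0.13)

  w0 <- wald_inference(0, 0.5)
  expect_equal(w0$p_value, 1)
  expect_equal(w0$ci[2], -w0$ci[1])

  wq <- wald_inference(qnorm(0.975), 1)
  expect_equal(wq$p_value, 0.05)
  expect_equal(wq$ci[1], 0, tolerance = 1e-12)

  expect_cc_error(wald_inference(1, -0.1), "cc_argument_error")
  # degenerate SE
  expect_equal(wald_inference(2, 0)$p_value, 0)
  expect_equal(wald_inference(0, 0)$p_value, 1)
})

test_that("L1 imbalance hits its endpoints and hand-computed midpoint", {
  # proportion-matched strata: perfect balance
  t <- rep(c(1, 0), 6)
  a <- new_strata_assignment_for_test(rep(1:3, each = 4))
  expect_equal(l1_imbalance(a, t), 0)

  # pure strata: mutually exclusive arms
  t2 <- c(1, 1, 1, 0, 0, 0)
  a2 <- new_strata_assignment_for_test(c(1, 1, 1, 2, 2, 2))
  expect_equal(l1_imbalance(a2, t2), 1)

  # treated shares (.75, .25) vs control shares (.25, .75)
  t3 <- c(rep(1, 3), rep(0, 1), rep(1, 1), rep(0, 3))
  a3 <- new_strata_assignment_for_test(c(rep(1, 4), rep(2, 4)))
  expect_equal(l1_imbalance(a3, t3), 0.5)

  expect_cc_error(l1_imbalance(a2, rep(1, 6)), "cc_treatment_error")

  # a pruned object delegates to its full underlying assignment
  expect_equal(l1_imbalance(prune_strata(a3, t3), t3),
               l1_imbalance(a3, t3))
})

test_that("the estimator is unbiased under within-stratum randomization", {
  # T assigned independently of Y within fixed strata; 2000 replicates
  set.seed(314)
  n <- 160
  labels <- rep(1:4, each = 40)
  x <- data.frame(g = factor(labels))
  mu <- c(0, 2, 4, 6)[labels]
  tau_true <- 1
  reps <- 2000
  taus <- vapply(seq_len(reps), function(r) {
    t <- rbinom(n, 1, 0.5)
    y <- mu + tau_true * t + rnorm(n)
    d <- causal_data(y, t, x)
    a <- cem_strata(d$x)
    pr <- suppressWarnings(prune_strata(a, d$t))
    suppressWarnings(ate_estimate(d, pr))$tau_hat
  }, numeric(1))
  mc_se <- sd(taus) / sqrt(reps)
  expect_lt(abs(mean(taus) - tau_true), 3 * mc_se)
})
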