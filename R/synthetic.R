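# Synthetic observational data with known potential-outcome structure.
# Covariates X are drawn from a known joint distribution, treatment from a
# logistic propensity e(X) (positivity holds by construction), and potential
# outcomes Y(t) = mu_t(X) + noise; the observed outcome is assembled by
# consistency, Y = (1 - T) Y(0) + T Y(1). Ignorability holds by construction
# because T depends on X only. The generating truth (including the true ATE
# and ATT) travels with each dataset so every estimator property is
# checkable without external data.

#' Define a synthetic generating truth
#'
#' @param name Short scenario label.
#' @param cov_gen Function `n -> data.frame` drawing `n` covariate rows from
#'   the scenario's joint distribution.
#' @param mu0,mu1 Potential-outcome mean functions, each mapping the
#'   covariate data frame to a numeric vector.
#' @param propensity Function mapping the covariate data frame to treatment
#'   probabilities in (0, 1).
#' @param sigma Outcome noise standard deviation (additive Gaussian).
#' @param true_ate Closed-form average effect `E[mu1(X) - mu0(X)]` when
#'   available; `NULL` triggers Monte-Carlo evaluation with `mc_draws` draws
#'   (the Monte-Carlo SE is recorded).
#' @param mc_draws Draws for Monte-Carlo truth evaluation (default `1e6`).
#' @param params Optional list of scenario coefficients, kept for the record.
#' @return A `synthetic_truth` object; `true_att` is always evaluated by
#'   propensity-weighted Monte Carlo, with its SE.
#' @export
synthetic_truth <- function(name, cov_gen, mu0, mu1, propensity, sigma = 1,
                            true_ate = NULL, mc_draws = 1e6,
                            params = list()) {
  cc_assert(sigma >= 0, "cc_argument_error", "sigma must be >= 0")
  mc_seed <- 20260927L  # fixed: truth values are part of the scenario
  mc <- with_seed(mc_seed, {
    xx <- cov_gen(mc_draws)
    tau_x <- mu1(xx) - mu0(xx)
    e_x <- propensity(xx)
    list(ate = mean(tau_x), ate_se = stats::sd(tau_x) / sqrt(mc_draws),
         att = sum(tau_x * e_x) / sum(e_x),
         att_se = stats::sd(tau_x * e_x / mean(e_x)) / sqrt(mc_draws))
  })
  structure(
    list(name = name, cov_gen = cov_gen, mu0 = mu0, mu1 = mu1,
         propensity = propensity, sigma = sigma,
         true_ate = true_ate %||% mc$ate,
         true_ate_mc_se = if (is.null(true_ate)) mc$ate_se else 0,
         true_att = mc$att, true_att_mc_se = mc$att_se,
         params = params),
    class = "synthetic_truth")
}

#' Built-in simulation scenarios
#'
#' Five generating truths spanning the behaviors the stratified estimators
#' must handle. All use two standard-normal covariates and unit outcome
#' noise unless noted:
#' \describe{
#'   \item{`null`}{No effect: `mu1 = mu0 = X1 + X2`; propensity
#'     `plogis(0.5 X1 + 0.5 X2)`; true ATE 0.}
#'   \item{`constant`}{Constant shift `mu1 = mu0 + 2`; true ATE 2.}
#'   \item{`linear`}{Heterogeneous linear benchmark:
#'     `mu1 = mu0 + 1 + 0.5 X1`; true ATE 1 (zero-mean covariates).}
#'   \item{`curved`}{Quadratic surfaces `mu0 = X1 + X2 + X1^2`,
#'     `mu1 = mu0 + 2 + X1^2`, stronger confounding
#'     `plogis(X1 + 0.5 X2)`; true ATE 3. Coarse stratifications are
#'     visibly biased here, which is what the 1/J extrapolation corrects.}
#'   \item{`discrete`}{Four binary (categorical) confounders with
#'     prevalences 0.4, 0.5, 0.3, 0.6; linear means on the indicators and
#'     `mu1 = mu0 + 1 + 0.5 B1`; true ATE 1.2. Emulates studies where all
#'     confounders are categorical and exact matching is natural.}
#' }
#'
#' @param name One of `"null"`, `"constant"`, `"linear"`, `"curved"`,
#'   `"discrete"`.
#' @return A [synthetic_truth].
#' @export
cc_scenario <- function(name = c("null", "constant", "linear", "curved",
                                 "discrete")) {
  name <- match.arg(name)
  gauss2 <- function(n) data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  lin_prop <- function(x) stats::plogis(0.5 * x$x1 + 0.5 * x$x2)
  base_mu <- function(x) x$x1 + x$x2
  switch(name,
    null = synthetic_truth("null", gauss2, base_mu, base_mu, lin_prop,
                           sigma = 1, true_ate = 0,
                           params = list(gamma = c(0.5, 0.5))),
    constant = synthetic_truth("constant", gauss2, base_mu,
                               function(x) base_mu(x) + 2, lin_prop,
                               sigma = 1, true_ate = 2,
                               params = list(gamma = c(0.5, 0.5), tau = 2)),
    linear = synthetic_truth("linear", gauss2, base_mu,
                             function(x) base_mu(x) + 1 + 0.5 * x$x1,
                             lin_prop, sigma = 1, true_ate = 1,
                             params = list(gamma = c(0.5, 0.5))),
    curved = synthetic_truth(
      "curved", gauss2,
      function(x) x$x1 + x$x2 + x$x1^2,
      function(x) x$x1 + x$x2 + x$x1^2 + 2 + x$x1^2,
      function(x) stats::plogis(x$x1 + 0.5 * x$x2),
      sigma = 1, true_ate = 3,
      params = list(gamma = c(1, 0.5))),
    discrete = {
      probs <- c(0.4, 0.5, 0.3, 0.6)
      cov_gen <- function(n) {
        out <- lapply(probs, function(p) stats::rbinom(n, 1L, p))
        names(out) <- paste0("b", seq_along(probs))
        as.data.frame(out)
      }
      ind <- function(x) lapply(x, as.numeric)
      mu0 <- function(x) { b <- ind(x)
        0.5 * b$b1 + b$b2 - 0.5 * b$b3 + 0.25 * b$b4 }
      mu1 <- function(x) { b <- ind(x); mu0(x) + 1 + 0.5 * b$b1 }
      prop <- function(x) { b <- ind(x)
        stats::plogis(-0.2 + 0.8 * b$b1 + 0.5 * b$b2 - 0.4 * b$b3 +
                        0.3 * b$b4) }
      tr <- synthetic_truth("discrete", cov_gen, mu0, mu1, prop, sigma = 1,
                            true_ate = 1 + 0.5 * probs[1],
                            params = list(probs = probs))
      tr$categorical <- paste0("b", seq_along(probs))
      tr
    })
}

#' Draw a synthetic observational dataset
#'
#' @param truth A [synthetic_truth].
#' @param n Number of units (`>= 2`).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A [causal_data] whose `"truth"` attribute carries the generating
#'   truth for scoring. Categorical covariates declared by the scenario are
#'   stored as factors.
#' @export
generate_data <- function(truth, n, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cc_assert(n >= 2L, "cc_size_error", "n must be >= 2")
  d <- with_seed(seed, {
    x <- truth$cov_gen(n)
    e <- truth$propensity(x)
    if (any(e <= .Machine$double.eps) || any(e >= 1 - .Machine$double.eps)) {
      cc_warn("cc_positivity_warning",
              "propensities numerically at 0 or 1: positivity is violated")
    }
    t <- stats::rbinom(n, 1L, e)
    y0 <- truth$mu0(x) + stats::rnorm(n, 0, truth$sigma)
    y1 <- truth$mu1(x) + stats::rnorm(n, 0, truth$sigma)
    for (nm in intersect(truth$categorical %||% character(0), names(x))) {
      x[[nm]] <- factor(x[[nm]])
    }
    causal_data(y = (1 - t) * y0 + t * y1, t = t, x = x)
  })
  attr(d, "truth") <- truth
  d
}

# One replicate: generate, build strata, prune, estimate. Returns NULL when
# estimation is impossible in this replicate.
one_replicate <- function(truth, n, method, strata_count, seed, estimand,
                          alpha, min_per_arm, ...) {
  d <- suppressWarnings(generate_data(truth, n, seed))
  k <- if (is.function(strata_count)) strata_count(n) else strata_count
  tryCatch({
    a <- build_strata(d$x, method, k, seed = seed, ...)
    pr <- suppressWarnings(prune_strata(a, d$t, min_per_arm))
    suppressWarnings(
      if (estimand == "ate") ate_estimate(d, pr, alpha)
      else att_estimate(d, pr, alpha))
  }, cc_no_strata_error = function(e) NULL)
}

#' Replicated performance study of the stratified estimators
#'
#' Runs `generate -> stratify -> prune -> estimate` over independent
#' replicates (one derived seed stream per replicate) and summarizes bias,
#' RMSE, empirical and mean estimated SE, confidence-interval coverage of
#' the true effect, and the mean realized strata count, per scenario and
#' method.
#'
#' @param scenarios A [synthetic_truth] or list of them (see
#'   [cc_scenario]).
#' @param methods Character vector of builders (`"cem"`, `"kmeans"`,
#'   `"rf"`).
#' @param n Units per replicate.
#' @param strata_count Strata count: integer or function of `n` (e.g.
#'   `function(n) ceiling(sqrt(n))`).
#' @param n_reps Number of replicates (`>= 2`).
#' @param seed Master seed.
#' @param estimand,alpha,min_per_arm Passed to the estimators.
#' @param ... Further builder arguments (`nstart`, `n_trees`,
#'   `standardize`).
#' @return A `simulation_report`: a data frame with one row per scenario ×
#'   method (`bias`, `mc_se` of the bias, `rmse`, `empirical_se`,
#'   `mean_estimated_se`, `coverage`, `mean_J_used`, `n_reps_done`,
#'   `true_value`); replicate-level estimates are in the `"replicates"`
#'   attribute.
#' @export
simulate_performance <- function(scenarios, methods = "kmeans", n = 1000,
                                 strata_count = function(n) ceiling(sqrt(n)),
                                 n_reps = 200, seed = 1L, estimand = "ate",
                                 alpha = 0.05, min_per_arm = 1L, ...) {
  if (inherits(scenarios, "synthetic_truth")) scenarios <- list(scenarios)
  cc_assert(n_reps >= 2L, "cc_argument_error", "n_reps must be >= 2")
  seeds <- derive_seeds(seed, n_reps)
  rows <- list(); reps_out <- list()
  for (sc in scenarios) {
    truth_val <- if (estimand == "ate") sc$true_ate else sc$true_att
    for (m in methods) {
      tau <- se <- jj <- rep(NA_real_, n_reps)
      for (r in seq_len(n_reps)) {
        est <- one_replicate(sc, n, m, strata_count, seeds[r], estimand,
                             alpha, min_per_arm, ...)
        if (is.null(est)) next
        tau[r] <- est$tau_hat; se[r] <- est$se; jj[r] <- est$J_used
      }
      ok <- !is.na(tau)
      if (!any(ok)) {
        cc_error("cc_simulation_error",
                 sprintf("every replicate failed for %s/%s", sc$name, m))
      }
      q <- stats::qnorm(1 - alpha / 2)
      cover <- mean(abs(tau[ok] - truth_val) <= q * se[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$name, method = m, estimand = estimand,
        n = n, n_reps_done = sum(ok),
        true_value = truth_val,
        bias = mean(tau[ok]) - truth_val,
        mc_se = stats::sd(tau[ok]) / sqrt(sum(ok)),
        rmse = sqrt(mean((tau[ok] - truth_val)^2)),
        empirical_se = stats::sd(tau[ok]),
        mean_estimated_se = mean(se[ok]),
        coverage = cover,
        mean_J_used = mean(jj[ok]),
        stringsAsFactors = FALSE)
      reps_out[[paste(sc$name, m, sep = "/")]] <-
        data.frame(rep = seq_len(n_reps), seed = seeds,
                   tau_hat = tau, se = se, J_used = jj)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- reps_out
  attr(out, "master_seed") <- seed
  class(out) <- c("simulation_report", class(out))
  out
}

#' Replicated evaluation of the 1/J bias correction
#'
#' For each replicate, estimates the effect over a strata-count grid,
#' extrapolates to `1/J = 0`, and compares the absolute error of the
#' corrected estimate with that of the estimate at the smallest grid strata
#' count. Reports the fraction of replicates the correction improves, plus
#' bias summaries for both estimators.
#'
#' @inheritParams simulate_performance
#' @param scenario A single [synthetic_truth].
#' @param grid Strata-count grid (see [bias_correct]).
#' @param method Strata builder.
#' @return List with `improve_fraction`, `bias_corrected`,
#'   `bias_smallest_J`, `mc_se_corrected`, `mc_se_smallest_J`,
#'   `n_reps_done`, `true_value` and the replicate table `replicates`.
#' @export
simulate_bias_correction <- function(scenario, n = 1000,
                                     grid = c(5, 10, 20, 40, 80),
                                     method = "kmeans", n_reps = 200,
                                     seed = 1L, estimand = "ate",
                                     alpha = 0.05, min_per_arm = 1L, ...) {
  stopifnot(inherits(scenario, "synthetic_truth"))
  truth_val <- if (estimand == "ate") scenario$true_ate else scenario$true_att
  seeds <- derive_seeds(seed, n_reps)
  tau_c <- tau_s <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    d <- suppressWarnings(generate_data(scenario, n, seeds[r]))
    bc <- tryCatch(
      suppressWarnings(bias_correct(d, method = method, grid = grid,
                                    estimand = estimand, seed = seeds[r],
                                    alpha = alpha,
                                    min_per_arm = min_per_arm, ...)),
      cc_error = function(e) NULL)
    if (is.null(bc)) next
    tau_c[r] <- bc$tau_corrected
    tau_s[r] <- bc$smallest_J$tau_hat
  }
  ok <- !is.na(tau_c)
  if (!any(ok)) cc_error("cc_simulation_error", "every replicate failed")
  list(improve_fraction = mean(abs(tau_c[ok] - truth_val) <
                                 abs(tau_s[ok] - truth_val)),
       bias_corrected = mean(tau_c[ok]) - truth_val,
       bias_smallest_J = mean(tau_s[ok]) - truth_val,
       mc_se_corrected = stats::sd(tau_c[ok]) / sqrt(sum(ok)),
       mc_se_smallest_J = stats::sd(tau_s[ok]) / sqrt(sum(ok)),
       n_reps_done = sum(ok), true_value = truth_val,
       replicates = data.frame(rep = seq_len(n_reps), seed = seeds,
                               tau_corrected = tau_c,
                               tau_smallest_J = tau_s))
}
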