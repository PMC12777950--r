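# Stratified estimators of the average causal effect. With strata S_1..S_J
# built from covariates alone, the ATE estimator is the stratum-share
# weighted sum of within-stratum treated/control mean contrasts,
#   tau_hat = sum_j (n_j/n) (Ybar_1j - Ybar_0j),
# with variance
#   sum_j (n_j/n)^2 (s2_1j/n_1j + s2_0j/n_0j).
# The ATT version rescales the control mean by the treatment-odds weight
# w_j = (n_1j/n_1)/(n_0j/n_0) and squares w_j in the variance.

#' Prune strata lacking treated/control support
#'
#' Drops strata that do not contain at least `min_per_arm` units in each
#' treatment arm, recording the reason per dropped stratum
#' (`no_treated`, `no_control`, or `below_min_per_arm`). Estimation then
#' targets the retained subpopulation, the standard restriction when strata
#' with a single arm cannot identify a contrast without extrapolation.
#'
#' @param assignment A `strata_assignment` covering all units.
#' @param t 0/1 treatment vector, one entry per unit.
#' @param min_per_arm Minimum per-arm count for retention (default 1).
#' @return A `pruned_strata` object: `retained`, `dropped` (data frame of
#'   stratum and reason), `n_used`, `counts` (per-stratum table) and the
#'   underlying `assignment`.
#' @export
prune_strata <- function(assignment, t, min_per_arm = 1L) {
  stopifnot(inherits(assignment, "strata_assignment"))
  cc_assert(min_per_arm >= 1L, "cc_argument_error", "min_per_arm must be >= 1")
  cc_assert(all(t %in% c(0, 1)), "cc_treatment_error", "t must be 0/1")
  counts <- strata_counts(assignment, t)
  reason <- rep(NA_character_, nrow(counts))
  reason[counts$n_0j == 0L] <- "no_control"
  reason[counts$n_1j == 0L] <- "no_treated"
  below <- is.na(reason) &
    (counts$n_1j < min_per_arm | counts$n_0j < min_per_arm)
  reason[below] <- "below_min_per_arm"
  retained <- counts$stratum[is.na(reason)]
  dropped <- data.frame(stratum = counts$stratum[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  if (!length(retained)) {
    cc_error("cc_no_strata_error",
             "no stratum retains both treatment arms; estimation impossible")
  }
  n_used <- sum(counts$n_j[retained])
  if (nrow(dropped)) {
    cc_warn("cc_pruning_warning",
            sprintf("dropped %d of %d strata (%.1f%% of units discarded)",
                    nrow(dropped), assignment$J,
                    100 * (1 - n_used / assignment$n)))
  }
  structure(
    list(retained = retained, dropped = dropped, n_used = n_used,
         counts = counts, min_per_arm = min_per_arm,
         assignment = assignment),
    class = "pruned_strata")
}

# Per-stratum summary statistics over retained strata. Singleton arms
# (n_tj = 1) have no within-arm variance of their own; the pooled within-arm
# sample variance across the retained strata is substituted, with a warning
# recommending min_per_arm = 2.
stratum_summaries <- function(y, t, pruned) {
  lab <- pruned$assignment$labels
  rows <- lapply(pruned$retained, function(j) {
    y1 <- y[lab == j & t == 1]; y0 <- y[lab == j & t == 0]
    data.frame(stratum = j, n_j = length(y1) + length(y0),
               n_1j = length(y1), n_0j = length(y0),
               ybar_1j = mean(y1), ybar_0j = mean(y0),
               s2_1j = if (length(y1) > 1L) stats::var(y1) else NA_real_,
               s2_0j = if (length(y0) > 1L) stats::var(y0) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  if (anyNA(tab$s2_1j) || anyNA(tab$s2_0j)) {
    pool <- function(s2, m) {
      dof <- pmax(m - 1L, 0L)
      if (sum(dof[!is.na(s2)]) > 0)
        sum(s2 * dof, na.rm = TRUE) / sum(dof[!is.na(s2)]) else 0
    }
    tab$s2_1j[is.na(tab$s2_1j)] <- pool(tab$s2_1j, tab$n_1j)
    tab$s2_0j[is.na(tab$s2_0j)] <- pool(tab$s2_0j, tab$n_0j)
    cc_warn("cc_singleton_warning",
            paste("singleton arm(s) in retained strata: pooled within-arm",
                  "variance substituted; consider min_per_arm = 2"))
  }
  tab
}

new_effect_estimate <- function(estimand, tau_hat, var_hat, tab, pruned,
                                alpha) {
  var_hat <- max(var_hat, 0)
  se <- sqrt(var_hat)
  inf <- wald_inference(tau_hat, se, alpha)
  structure(
    list(estimand = estimand, tau_hat = tau_hat, var_hat = var_hat, se = se,
         z = inf$z, p_value = inf$p_value, ci = inf$ci, alpha = alpha,
         J_used = length(pruned$retained), n_used = pruned$n_used,
         n_dropped_strata = nrow(pruned$dropped),
         strata_table = tab, method = pruned$assignment$method),
    class = "effect_estimate")
}

#' Stratified average treatment effect (ATE)
#'
#' Computes the stratum-weighted mean-contrast estimator of the average
#' causal effect over the retained strata, with its closed-form variance,
#' Wald statistic, two-sided p-value and normal confidence interval. Weights
#' are `n_j / n` with `n` the retained-strata total, so they sum to 1 and the
#' estimand is the effect on the retained subpopulation. Within-arm
#' variances are unbiased sample variances (denominator `n_tj - 1`).
#'
#' @param data A [causal_data] object.
#' @param pruned A [prune_strata] result for the same units.
#' @param alpha Significance level for the CI (default 0.05).
#' @return An `effect_estimate` with the per-stratum summary table.
#' @export
ate_estimate <- function(data, pruned, alpha = 0.05) {
  stopifnot(inherits(data, "causal_data"), inherits(pruned, "pruned_strata"))
  tab <- stratum_summaries(data$y, data$t, pruned)
  w <- tab$n_j / pruned$n_used
  tab$weight <- w
  tau_hat <- sum(w * (tab$ybar_1j - tab$ybar_0j))
  var_hat <- sum(w^2 * (tab$s2_1j / tab$n_1j + tab$s2_0j / tab$n_0j))
  new_effect_estimate("ate", tau_hat, var_hat, tab, pruned, alpha)
}

#' Stratified average treatment effect on the treated (ATT)
#'
#' Same stratum-share weighting as [ate_estimate] but the control mean in
#' each stratum is rescaled by the treatment-odds weight
#' `w_j = (n_1j/n_1) / (n_0j/n_0)` (arm totals over retained strata), and
#' `w_j` enters the variance squared. When treatment prevalence is constant
#' across strata, `w_j = 1` for every stratum and the ATT estimate equals
#' the ATE estimate exactly.
#'
#' @inheritParams ate_estimate
#' @return An `effect_estimate` whose `strata_table` records each `w_j`.
#' @export
att_estimate <- function(data, pruned, alpha = 0.05) {
  stopifnot(inherits(data, "causal_data"), inherits(pruned, "pruned_strata"))
  tab <- stratum_summaries(data$y, data$t, pruned)
  n1 <- sum(tab$n_1j); n0 <- sum(tab$n_0j)
  tab$w_j <- (tab$n_1j / n1) / (tab$n_0j / n0)
  w <- tab$n_j / pruned$n_used
  tab$weight <- w
  tau_hat <- sum(w * (tab$ybar_1j - tab$w_j * tab$ybar_0j))
  var_hat <- sum(w^2 * (tab$s2_1j / tab$n_1j + tab$w_j^2 * tab$s2_0j / tab$n_0j))
  new_effect_estimate("att", tau_hat, var_hat, tab, pruned, alpha)
}

#' Estimating-equation root for the stratified ATE
#'
#' Independent cross-check of [ate_estimate]: the stratified ATE solves the
#' estimating equation `U(tau) = 0` where `U` accumulates, unit by unit, the
#' stratum-share weighted treated/control outcome contributions minus `tau`.
#' The root is located numerically by bisection, deliberately through code
#' disjoint from the closed-form path.
#'
#' @inheritParams ate_estimate
#' @return The root of `U`, a scalar.
#' @export
estimating_equation_root <- function(data, pruned) {
  stopifnot(inherits(data, "causal_data"), inherits(pruned, "pruned_strata"))
  lab <- pruned$assignment$labels
  keep <- lab %in% pruned$retained
  n <- sum(keep)
  n1 <- vapply(pruned$retained, function(j)
    sum(lab == j & data$t == 1 & keep), numeric(1))
  n0 <- vapply(pruned$retained, function(j)
    sum(lab == j & data$t == 0 & keep), numeric(1))
  nj <- n1 + n0
  U <- function(tau) {
    acc <- 0
    for (i in which(keep)) {
      jj <- match(lab[i], pruned$retained)
      share <- nj[jj] / n
      acc <- acc + share *
        (data$t[i] * data$y[i] / n1[jj] -
           (1 - data$t[i]) * data$y[i] / n0[jj])
    }
    acc - tau
  }
  hi <- max(abs(data$y)) * 2 + 1
  while (U(-hi) * U(hi) > 0) hi <- hi * 4
  stats::uniroot(U, c(-hi, hi), tol = .Machine$double.eps^0.75)$root
}

#' Wald inference from an estimate and its standard error
#'
#' @param tau_hat Point estimate.
#' @param se Standard error, `>= 0`. With `se = 0` the CI degenerates to the
#'   point and the p-value is 0 (nonzero estimate) or 1 (zero estimate).
#' @param alpha Significance level in (0, 1).
#' @return List with `z`, `p_value` and `ci = c(lower, upper)` at level
#'   `1 - alpha`.
#' @examples
#' wald_inference(-0.021, 0.014)$p_value  # ~0.13
#' @export
wald_inference <- function(tau_hat, se, alpha = 0.05) {
  cc_assert(is.finite(se) && se >= 0, "cc_argument_error",
            "se must be a nonnegative number")
  cc_assert(alpha > 0 && alpha < 1, "cc_argument_error",
            "alpha must lie in (0, 1)")
  if (se == 0) {
    return(list(z = if (tau_hat == 0) 0 else sign(tau_hat) * Inf,
                p_value = if (tau_hat == 0) 1 else 0,
                ci = c(tau_hat, tau_hat)))
  }
  z <- tau_hat / se
  q <- stats::qnorm(1 - alpha / 2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       ci = c(tau_hat - q * se, tau_hat + q * se))
}

#' L1 covariate-balance statistic of a stratification
#'
#' Half the summed absolute difference between the treated and control
#' stratum-membership proportions, over all strata of the (unpruned)
#' assignment: 0 means each stratum holds equal shares of the two arms
#' (perfect balance); 1 means every stratum is pure (mutually exclusive
#' arms).
#'
#' @param assignment A `strata_assignment`, or a [prune_strata] result (the
#'   statistic is always computed over all strata of the underlying raw
#'   assignment).
#' @param t 0/1 treatment vector; both arms must be nonempty overall.
#' @return A scalar in `[0, 1]`.
#' @export
l1_imbalance <- function(assignment, t) {
  if (inherits(assignment, "pruned_strata")) {
    assignment <- assignment$assignment
  }
  stopifnot(inherits(assignment, "strata_assignment"))
  cc_assert(all(t %in% c(0, 1)), "cc_treatment_error", "t must be 0/1")
  if (!any(t == 1) || !any(t == 0)) {
    cc_error("cc_treatment_error", "both arms must be nonempty overall")
  }
  counts <- strata_counts(assignment, t)
  0.5 * sum(abs(counts$n_1j / sum(counts$n_1j) -
                  counts$n_0j / sum(counts$n_0j)))
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s (%s strata)\n",
              toupper(x$estimand), x$method))
  cat(sprintf("  tau = %.6g  SE = %.6g  z = %.3f  p = %.4g\n",
              x$tau_hat, x$se, x$z, x$p_value))
  cat(sprintf("  %d%% CI [%.6g, %.6g]\n", round(100 * (1 - x$alpha)),
              x$ci[1], x$ci[2]))
  cat(sprintf("  strata used: %d (dropped %d), units used: %d\n",
              x$J_used, x$n_dropped_strata, x$n_used))
  invisible(x)
}
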