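# Finite-strata bias correction. With a finite number of strata J the
# stratified estimator carries a coarsening bias that vanishes as J grows;
# following the simulation-extrapolation idea, the estimate is computed on a
# grid of J values, regressed linearly on 1/J, and read off at 1/J = 0.

# One strata builder dispatcher shared by the grid runner, the simulation
# module and the CLI. For CEM the requested J controls the per-covariate bin
# count M = max(2, ceiling(J^(1/p))) so the codebook size M^p tracks J; the
# realized (occupied, post-pruning) count J_used is what downstream code uses.
build_strata <- function(x, method, J, seed = 1L, standardize = TRUE,
                         n_trees = 500L, nstart = 10L) {
  method <- match.arg(method, c("cem", "kmeans", "rf"))
  switch(method,
    cem = {
      m <- max(2L, ceiling(J^(1 / ncol(as.data.frame(x)))))
      cem_strata(x, coarsen_spec(x, bins = m))
    },
    kmeans = kmeans_strata(x, k = J, seed = seed,
                           standardize = standardize, nstart = nstart),
    rf = rf_proximity_strata(x, k = J, n_trees = n_trees, seed = seed))
}

#' Estimate the causal effect over a grid of strata counts
#'
#' For each requested strata count, builds strata from the covariates,
#' prunes unsupported strata and estimates the effect. Each grid point draws
#' its own seed stream derived from `seed`, so the whole grid is
#' reproducible from one master seed. Grid points where estimation is
#' impossible (no stratum retains both arms) are dropped with a warning; if
#' fewer than 3 points survive the run fails.
#'
#' @param data A [causal_data] object.
#' @param method Strata builder: `"cem"`, `"kmeans"` or `"rf"`.
#' @param grid Strictly increasing integer strata counts, all `>= 2`.
#' @param estimand `"ate"` or `"att"`.
#' @param seed Master seed.
#' @param alpha,min_per_arm Passed to pruning/estimation.
#' @param ... Further arguments to [build_strata] (`standardize`, `n_trees`,
#'   `nstart`).
#' @return Data frame with one row per surviving grid point: `J_requested`,
#'   `J_used` (retained strata), `tau_hat`, `var_hat`, `n_used`; the
#'   `effect_estimate` objects are attached as the `"estimates"` attribute.
#' @export
run_grid <- function(data, method, grid, estimand = "ate", seed = 1L,
                     alpha = 0.05, min_per_arm = 1L, ...) {
  stopifnot(inherits(data, "causal_data"))
  estimand <- match.arg(estimand, c("ate", "att"))
  grid <- as.integer(grid)
  cc_assert(length(grid) >= 3L && all(grid >= 2L) && !is.unsorted(grid, strictly = TRUE),
            "cc_grid_error",
            "grid must be >= 3 strictly increasing values, all >= 2")
  seeds <- derive_seeds(seed, length(grid))
  rows <- list(); ests <- list()
  for (g in seq_along(grid)) {
    est <- tryCatch({
      a <- build_strata(data$x, method, grid[g], seed = seeds[g], ...)
      pr <- suppressWarnings(prune_strata(a, data$t, min_per_arm))
      est <- if (estimand == "ate") ate_estimate(data, pr, alpha)
             else att_estimate(data, pr, alpha)
      est
    }, cc_no_strata_error = function(e) {
      cc_warn("cc_grid_warning",
              sprintf("grid point J = %d dropped: %s", grid[g],
                      conditionMessage(e)))
      NULL
    })
    if (is.null(est)) next
    rows[[length(rows) + 1L]] <- data.frame(
      J_requested = grid[g], J_used = est$J_used, tau_hat = est$tau_hat,
      var_hat = est$var_hat, n_used = est$n_used)
    ests[[length(ests) + 1L]] <- est
  }
  if (length(rows) < 3L) {
    cc_error("cc_grid_error",
             "fewer than 3 grid points produced an estimate")
  }
  out <- do.call(rbind, rows)
  attr(out, "estimates") <- ests
  out
}

#' Extrapolate a grid of stratified estimates to infinitely many strata
#'
#' Ordinary least squares of the grid estimates on the reciprocal realized
#' strata count; the corrected estimate is the fitted value at `1/J = 0`,
#' i.e. the intercept. The variance is extrapolated with the same device and
#' floored at `1e-6` times the smallest grid variance to stay positive.
#'
#' @param grid_df Data frame with columns `J_used`, `tau_hat`, `var_hat`
#'   (as returned by [run_grid]); at least 3 distinct `J_used` values.
#' @return A `bias_correction` object: `grid`, `intercept`, `slope`,
#'   `tau_corrected` (= intercept), `var_corrected`, `se_corrected`,
#'   `r_squared`.
#' @examples
#' g <- data.frame(J_used = c(2, 4, 8), tau_hat = 2 - 4 / c(2, 4, 8),
#'                 var_hat = c(1, 1, 1))
#' extrapolate(g)$tau_corrected  # 2
#' @export
extrapolate <- function(grid_df) {
  need <- c("J_used", "tau_hat", "var_hat")
  cc_assert(all(need %in% names(grid_df)), "cc_argument_error",
            "grid_df needs columns J_used, tau_hat, var_hat")
  if (length(unique(grid_df$J_used)) < 3L) {
    cc_error("cc_grid_error",
             "need >= 3 distinct realized strata counts to extrapolate")
  }
  invJ <- 1 / grid_df$J_used
  fit <- stats::lm(tau_hat ~ invJ, data = data.frame(
    tau_hat = grid_df$tau_hat, invJ = invJ))
  tau_corrected <- unname(stats::predict(fit, data.frame(invJ = 0)))
  vfit <- stats::lm(var_hat ~ invJ, data = data.frame(
    var_hat = grid_df$var_hat, invJ = invJ))
  var_corrected <- max(unname(stats::predict(vfit, data.frame(invJ = 0))),
                       min(grid_df$var_hat) * 1e-6)
  structure(
    list(grid = as.data.frame(grid_df), intercept = unname(coef(fit)[1]),
         slope = unname(coef(fit)[2]), tau_corrected = tau_corrected,
         var_corrected = var_corrected, se_corrected = sqrt(var_corrected),
         r_squared = suppressWarnings(summary(fit)$r.squared)),
    class = "bias_correction")
}

#' Bias-corrected stratified causal effect
#'
#' Convenience wrapper: run the grid, optionally truncate it to points
#' retaining at least `min_retained` of the units after pruning (coarsening
#' loss grows with the strata count), and extrapolate. The default grid is
#' `c(5, 10, 20, 40, 80)` capped at `n/2`.
#'
#' @inheritParams run_grid
#' @param grid Strata counts; default `c(5, 10, 20, 40, 80)` (values above
#'   `n/2` are dropped).
#' @param min_retained Minimum retained-unit fraction for a grid point to
#'   enter the extrapolation (default 0.9); at least the 3 smallest
#'   surviving points are always kept.
#' @return A `bias_correction` object (see [extrapolate]); the estimate at
#'   the smallest grid strata count is attached as `$smallest_J`.
#' @export
bias_correct <- function(data, method = "kmeans", grid = c(5, 10, 20, 40, 80),
                         estimand = "ate", seed = 1L, alpha = 0.05,
                         min_per_arm = 1L, min_retained = 0.9, ...) {
  grid <- grid[grid <= data$n / 2]
  gdf <- run_grid(data, method, grid, estimand = estimand, seed = seed,
                  alpha = alpha, min_per_arm = min_per_arm, ...)
  keep <- gdf$n_used >= min_retained * data$n
  keep[seq_len(min(3L, nrow(gdf)))] <- TRUE
  gdf_kept <- gdf[keep, , drop = FALSE]
  res <- extrapolate(gdf_kept)
  res$estimand <- estimand
  res$method <- method
  res$smallest_J <- attr(gdf, "estimates")[[1L]]
  res
}

#' @export
print.bias_correction <- function(x, ...) {
  cat("<bias_correction> linear extrapolation in 1/J\n")
  print(x$grid, row.names = FALSE)
  cat(sprintf("  intercept (corrected tau) = %.6g, slope = %.6g, R^2 = %.3f\n",
              x$tau_corrected, x$slope, x$r_squared))
  cat(sprintf("  corrected SE = %.6g\n", x$se_corrected))
  invisible(x)
}
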