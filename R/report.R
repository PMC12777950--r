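# Machine-readable analysis reports. JSON with full numeric precision so a
# write -> read cycle reproduces every field exactly; the companion reader
# rebuilds the original S3 object.

#' Write an analysis report to JSON
#'
#' Serializes an [ate_estimate]/[att_estimate] result or a [bias_correct]
#' result, together with a configuration echo (method, seed, ...), to a JSON
#' file at full numeric precision. Non-finite point estimates are refused.
#' Reports always carry the pruning audit (number of dropped strata), since
#' discarding strata changes the population the estimand refers to.
#'
#' @param estimate An `effect_estimate` or `bias_correction` object.
#' @param path Output file path.
#' @param config Optional named list echoed verbatim into the report (seed,
#'   resolved options, input path, ...).
#' @return `path`, invisibly.
#' @export
write_report <- function(estimate, path, config = list()) {
  UseMethod("write_report")
}

#' @export
write_report.effect_estimate <- function(estimate, path, config = list()) {
  if (!is.finite(estimate$tau_hat) || !is.finite(estimate$se)) {
    cc_error("cc_finiteness_error",
             "refusing to write a non-finite estimate")
  }
  payload <- list(
    report_type = "effect_estimate",
    package_version = as.character(utils::packageVersion("coarsenCausal")),
    config = config,
    estimand = estimate$estimand, method = estimate$method,
    tau_hat = estimate$tau_hat, var_hat = estimate$var_hat,
    se = estimate$se, z = estimate$z, p_value = estimate$p_value,
    ci = estimate$ci, alpha = estimate$alpha,
    J_used = estimate$J_used, n_used = estimate$n_used,
    n_dropped_strata = estimate$n_dropped_strata,
    strata_table = estimate$strata_table)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @export
write_report.bias_correction <- function(estimate, path, config = list()) {
  if (!is.finite(estimate$tau_corrected) || !is.finite(estimate$se_corrected)) {
    cc_error("cc_finiteness_error",
             "refusing to write a non-finite estimate")
  }
  payload <- list(
    report_type = "bias_correction",
    package_version = as.character(utils::packageVersion("coarsenCausal")),
    config = config,
    estimand = estimate$estimand %||% NA, method = estimate$method %||% NA,
    grid = estimate$grid, intercept = estimate$intercept,
    slope = estimate$slope, tau_corrected = estimate$tau_corrected,
    var_corrected = estimate$var_corrected,
    se_corrected = estimate$se_corrected, r_squared = estimate$r_squared)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a JSON analysis report back into its S3 object
#'
#' @param path Path written by [write_report].
#' @return An `effect_estimate` or `bias_correction` object with the
#'   configuration echo in attribute `"config"`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    cc_error("cc_file_error", sprintf("report not found: %s", path))
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- switch(p$report_type,
    effect_estimate = structure(
      list(estimand = p$estimand, tau_hat = p$tau_hat, var_hat = p$var_hat,
           se = p$se, z = p$z, p_value = p$p_value, ci = p$ci,
           alpha = p$alpha, J_used = p$J_used, n_used = p$n_used,
           n_dropped_strata = p$n_dropped_strata,
           strata_table = as.data.frame(p$strata_table),
           method = p$method),
      class = "effect_estimate"),
    bias_correction = structure(
      list(grid = as.data.frame(p$grid), intercept = p$intercept,
           slope = p$slope, tau_corrected = p$tau_corrected,
           var_corrected = p$var_corrected, se_corrected = p$se_corrected,
           r_squared = p$r_squared, estimand = p$estimand,
           method = p$method),
      class = "bias_correction"),
    cc_error("cc_file_error", "unrecognized report type"))
  attr(obj, "config") <- p$config
  obj
}

#' Export per-unit stratum assignments as CSV
#'
#' @param assignment A `strata_assignment`.
#' @param path Output CSV path.
#' @param unit_id Optional identifiers; defaults to row numbers.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignment, path, unit_id = NULL) {
  stopifnot(inherits(assignment, "strata_assignment"))
  utils::write.csv(
    data.frame(unit_id = unit_id %||% seq_len(assignment$n),
               stratum_label = assignment$labels),
    path, row.names = FALSE)
  invisible(path)
}
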