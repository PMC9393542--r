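#' Contribution-to-variance sensitivity of a Monte Carlo output
#'
#' For each stochastic input, the Spearman rank correlation with the output
#' is computed; the signed contribution of input i is
#' sign(rho_i) * 100 * rho_i^2 / sum_j rho_j^2, the normalization used by
#' spreadsheet Monte Carlo tools. Absolute contributions therefore sum to
#' 100. Constant inputs receive a contribution of 0 with a warning;
#' rank-based, the measure is invariant under strictly monotone transforms
#' of any input.
#'
#' @param inputs Named list of input draw vectors, all the same length as
#'   `output` (at least 100 draws).
#' @param output Vector of output draws (HI or TCR).
#' @param method "contribution" (default) or "rank_correlation" to report
#'   the raw Spearman coefficients unnormalized.
#' @return data.frame of class `sensitivity_report` with columns
#'   `variable`, `rho`, `contribution`.
#' @export
contribution_to_variance <- function(inputs, output,
                                     method = c("contribution", "rank_correlation")) {
  method <- match.arg(method)
  stopifnot(is.list(inputs), !is.null(names(inputs)))
  lens <- vapply(inputs, length, 1L)
  if (any(lens != length(output))) stop("all input vectors must match the output length")
  if (length(output) < 100L) stop("need at least 100 draws for a stable rank correlation")
  if (stats::sd(output) == 0) stop("output draws are constant; sensitivity undefined")
  rho <- vapply(names(inputs), function(v) {
    x <- inputs[[v]]
    if (stats::sd(x) == 0) {
      warning("input '", v, "' is constant; contribution set to 0")
      return(0)
    }
    stats::cor(x, output, method = "spearman")
  }, 1)
  contribution <- if (method == "rank_correlation") {
    100 * rho
  } else if (all(rho == 0)) {
    rep(0, length(rho))
  } else {
    sign(rho) * 100 * rho^2 / sum(rho^2)
  }
  structure(data.frame(variable = names(inputs), rho = unname(rho),
                       contribution = unname(contribution)),
            class = c("sensitivity_report", "data.frame"),
            method = method)
}

#' Pool per-element concentration contributions into a single C term
#'
#' The concentration factor enters the risk model once per element; for
#' reporting it is treated as one input by summing the squared rank
#' correlations of all concentration variables before normalizing. The
#' pooled term keeps the sign of the dominant direction.
#'
#' @param report A `sensitivity_report` from [contribution_to_variance()].
#' @param conc_variables Character vector naming the concentration
#'   variables in `report` to pool (default: those starting with "C_").
#' @param pooled_name Label for the pooled row.
#' @return A new `sensitivity_report` with one pooled concentration row. The
#'   pooled row's `rho` is the signed square root of the summed squared
#'   correlations — a magnitude, not a correlation, and it can exceed 1.
#' @export
aggregate_concentration_sensitivity <- function(report,
                                                conc_variables = grep("^C_", report$variable, value = TRUE),
                                                pooled_name = "C") {
  stopifnot(all(conc_variables %in% report$variable))
  is_c <- report$variable %in% conc_variables
  if (!any(is_c)) stop("no concentration variables to pool")
  signed_r2 <- sign(report$rho) * report$rho^2
  pooled_r2 <- sum(report$rho[is_c]^2)
  pooled_sign <- if (sum(signed_r2[is_c]) >= 0) 1 else -1
  others <- report[!is_c, , drop = FALSE]
  r2 <- c(pooled_r2, others$rho^2)
  total <- sum(r2)
  sgn <- c(pooled_sign, sign(others$rho))
  contribution <- if (total == 0) rep(0, length(r2)) else sgn * 100 * r2 / total
  out <- data.frame(
    variable = c(pooled_name, others$variable),
    rho = c(pooled_sign * sqrt(pooled_r2), others$rho),
    contribution = contribution)
  structure(out, class = c("sensitivity_report", "data.frame"),
            method = attr(report, "method"))
}

#' Sensitivity report for a simulated endpoint
#'
#' Convenience wrapper: assembles the stored input draws of a
#' [run_simulation()] result (per-element concentrations plus BW, IR, ED of
#' one group), computes contribution-to-variance against the group's HI or
#' TCR draws, and pools the element concentrations into a single C term.
#' Requires a simulation run with `exposure = "probabilistic"` for the
#' exposure parameters to vary; under point exposure they are constant and
#' receive zero contribution.
#'
#' @param sim A `risk_simulation` object.
#' @param group Population group id.
#' @param endpoint "HI" or "TCR".
#' @param pool_concentrations Pool element concentrations into one C term.
#' @return A `sensitivity_report`.
#' @export
sensitivity_report <- function(sim, group, endpoint = c("HI", "TCR"),
                               pool_concentrations = TRUE) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(sim, "risk_simulation"), group %in% names(sim$draws))
  output <- sim$draws[[group]][[endpoint]]
  els <- if (endpoint == "HI") colnames(sim$draws[[group]]$HQ) else colnames(sim$draws[[group]]$CR)
  inputs <- stats::setNames(
    lapply(els, function(el) sim$inputs$C[, el]), paste0("C_", els))
  inputs$BW <- sim$inputs[[group]]$BW
  inputs$IR <- sim$inputs[[group]]$IR
  inputs$ED <- sim$inputs[[group]]$ED
  rep0 <- contribution_to_variance(inputs, output)
  if (pool_concentrations) aggregate_concentration_sensitivity(rep0) else rep0
}
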