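#' Summarize a vector of Monte Carlo draws
#'
#' Mean, median, sample SD and empirical 5th / 90th / 95th percentiles
#' using the linear-interpolation quantile convention
#' ([stats::quantile()] type 7, recorded in the result).
#'
#' @param draws Non-empty numeric vector.
#' @return Named list: `mean`, `median`, `sd`, `p5`, `p90`, `p95`,
#'   `quantile_type`.
#' @export
summarize_draws <- function(draws) {
  if (length(draws) == 0L) stop("empty draws")
  qs <- stats::quantile(draws, c(0.05, 0.90, 0.95), type = 7, names = FALSE)
  list(mean = mean(draws), median = stats::median(draws),
       sd = if (length(draws) > 1L) stats::sd(draws) else 0,
       p5 = qs[1], p90 = qs[2], p95 = qs[3], quantile_type = 7L)
}

#' Probability that draws exceed a threshold
#'
#' The empirical complement of the cumulative distribution: the fraction of
#' draws strictly above `threshold`.
#'
#' @param draws Numeric vector of simulated values.
#' @param threshold Finite threshold.
#' @return Fraction in [0, 1].
#' @export
exceedance_probability <- function(draws, threshold) {
  stopifnot(is.finite(threshold))
  mean(draws > threshold)
}

# deterministic per-variable substream seed derived from the root seed,
# so adding a variable never perturbs another variable's draws
substream_seed <- function(root, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(root) %% 1048573) * 1009 + h) %% 2147483647L
}

draw_substream <- function(spec, n, root_seed, name) {
  set.seed(substream_seed(root_seed, name))
  draw_dist(spec, n)
}

# exposure-parameter specs for one population group
exposure_specs <- function(pop, mode = c("point", "probabilistic"),
                           bw_cv = 0.15, ir_cv = 0.25, ed_spread = 0.20) {
  mode <- match.arg(mode)
  if (mode == "point") {
    return(list(bw = dist_spec("point", value = pop$bw),
                ir = dist_spec("point", value = pop$ir),
                ed = dist_spec("point", value = pop$ed)))
  }
  sdlog <- sqrt(log(1 + ir_cv^2))
  list(
    bw = dist_spec("normal", mean = pop$bw, sd = bw_cv * pop$bw,
                   truncation = pop$bw * c(1 - 3 * bw_cv, 1 + 3 * bw_cv)),
    ir = dist_spec("lognormal", meanlog = log(pop$ir) - sdlog^2 / 2, sdlog = sdlog),
    ed = dist_spec("uniform", min = (1 - ed_spread) * pop$ed,
                   max = (1 + ed_spread) * pop$ed)
  )
}

#' Monte Carlo simulation of dietary PTE risk
#'
#' Propagates uncertainty through the hazard-quotient and carcinogenic-risk
#' equations. Element concentrations are drawn from distributions fitted to
#' the supplied table (or from `conc_specs` given directly); exposure
#' parameters are either held at their point values (`exposure = "point"`,
#' the default, which reproduces deterministic mean risks) or given
#' conventional spreads (`exposure = "probabilistic"`: truncated-normal BW
#' with CV 0.15, lognormal IR with CV 0.25, uniform ED within +/-20%) for
#' sensitivity analysis. Within each draw HI is the sum of the element HQs
#' and TCR the sum of the element CRs.
#'
#' Each stochastic variable draws from its own seeded substream derived
#' from `seed`, so runs are bit-reproducible and adding an element does not
#' perturb the others' draws.
#'
#' @param table Concentration data.frame used to fit element distributions;
#'   may be `NULL` when `conc_specs` is given.
#' @param pops Population table ([pte_populations()]).
#' @param tox Toxicity table ([pte_toxicity()]).
#' @param n_iterations Number of Monte Carlo draws (>= 1000 recommended for
#'   percentile reporting).
#' @param seed Integer root seed (required).
#' @param exposure "point" (configuration A) or "probabilistic"
#'   (configuration B).
#' @param conc_specs Optional named list of [dist_spec()] per element,
#'   bypassing the fit.
#' @param conc_sampling "independent" (default) draws each element's
#'   concentration independently; "joint" couples elements through a
#'   Gaussian copula on the table's Spearman correlations.
#' @return Object of class `risk_simulation`: `draws` (per group: `HQ` and
#'   `CR` matrices, `HI` and `TCR` vectors), `inputs` (concentration and
#'   exposure draws, for sensitivity analysis), `summary` data.frame,
#'   `specs`, `seed`, `n_iterations`, `exposure`, `quantile_type`.
#' @export
run_simulation <- function(table = NULL, pops = pte_populations(),
                           tox = pte_toxicity(), n_iterations = 10000,
                           seed, exposure = c("point", "probabilistic"),
                           conc_specs = NULL,
                           conc_sampling = c("independent", "joint")) {
  exposure <- match.arg(exposure)
  conc_sampling <- match.arg(conc_sampling)
  if (missing(seed)) stop("a seed is required for reproducibility")
  n <- as.integer(n_iterations)
  if (n < 1L) stop("n_iterations must be at least 1")

  if (is.null(conc_specs)) {
    if (is.null(table)) stop("supply either a concentration table or conc_specs")
    els <- intersect(element_columns(table), tox$element)
    conc_specs <- list()
    for (el in els) {
      sp <- tryCatch(fit_concentration_distribution(table[[el]]),
                     error = function(e) {
                       warning("element ", el, " excluded: ", conditionMessage(e))
                       NULL
                     })
      if (!is.null(sp)) conc_specs[[el]] <- sp
    }
  }
  if (length(conc_specs) == 0L) stop("no element distribution could be fitted")
  els <- names(conc_specs)

  # concentration draws, one substream per element
  if (conc_sampling == "independent" || length(els) == 1L) {
    conc_draws <- vapply(els, function(el)
      draw_substream(conc_specs[[el]], n, seed, paste0("C_", el)), numeric(n))
  } else {
    if (is.null(table)) stop("joint concentration sampling needs the data table")
    rho_s <- spearman_matrix(table[, c("sample_id", els)])$rho
    set.seed(substream_seed(seed, "C_joint"))
    u <- copula_uniforms(n, rho_s)
    conc_draws <- vapply(seq_along(els), function(j) {
      sp <- conc_specs[[els[j]]]
      uj <- u[, j]
      if (!is.null(sp$truncation)) {
        lo <- dist_cdf(sp, sp$truncation[1]); hi <- dist_cdf(sp, sp$truncation[2])
        uj <- lo + uj * (hi - lo)
      }
      dist_quantile(sp, uj)
    }, numeric(n))
    colnames(conc_draws) <- els
  }
  if (is.null(dim(conc_draws))) conc_draws <- matrix(conc_draws, ncol = length(els),
                                                    dimnames = list(NULL, els))

  draws <- list(); inputs <- list(C = conc_draws)
  summary_rows <- list()
  for (g in seq_len(nrow(pops))) {
    pop <- pops[g, ]
    ex <- exposure_specs(pop, exposure)
    bw <- draw_substream(ex$bw, n, seed, paste0("BW_", pop$group))
    ir <- draw_substream(ex$ir, n, seed, paste0("IR_", pop$group))
    ed <- draw_substream(ex$ed, n, seed, paste0("ED_", pop$group))
    pop_draws <- list(group = pop$group, bw = bw, ir = ir, ed = ed,
                      ef = pop$ef, lifetime_years = pop$lifetime_years)
    hq <- matrix(NA_real_, n, 0)
    cr <- matrix(NA_real_, n, 0)
    for (el in els) {
      tx <- config_row(tox, "element", el)
      cvec <- conc_draws[, el]
      if (!is.na(tx$rfd)) {
        hq <- cbind(hq, hazard_quotient(cvec, pop_draws, tx))
        colnames(hq)[ncol(hq)] <- el
      }
      if (tx$carcinogenic && !is.na(tx$sf)) {
        cr <- cbind(cr, carcinogenic_risk(cvec, pop_draws, tx))
        colnames(cr)[ncol(cr)] <- el
      }
    }
    hi <- rowSums(hq)
    tcr <- rowSums(cr)
    draws[[pop$group]] <- list(HQ = hq, CR = cr, HI = hi, TCR = tcr)
    inputs[[pop$group]] <- list(BW = bw, IR = ir, ED = ed)

    add_summary <- function(el, endpoint, v) {
      s <- summarize_draws(v)
      data.frame(group = pop$group, element = el, endpoint = endpoint,
                 mean = s$mean, median = s$median, sd = s$sd,
                 p5 = s$p5, p90 = s$p90, p95 = s$p95)
    }
    for (el in colnames(hq)) summary_rows[[length(summary_rows) + 1L]] <-
      add_summary(el, "HQ", hq[, el])
    summary_rows[[length(summary_rows) + 1L]] <- add_summary("total", "HI", hi)
    for (el in colnames(cr)) summary_rows[[length(summary_rows) + 1L]] <-
      add_summary(el, "CR", cr[, el])
    summary_rows[[length(summary_rows) + 1L]] <- add_summary("total", "TCR", tcr)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  structure(list(draws = draws, inputs = inputs, summary = summary,
                 specs = conc_specs, seed = seed, n_iterations = n,
                 exposure = exposure, conc_sampling = conc_sampling,
                 quantile_type = 7L),
            class = "risk_simulation")
}

#' @export
print.risk_simulation <- function(x, ...) {
  cat("Monte Carlo risk simulation:", x$n_iterations, "iterations, seed", x$seed,
      "\nexposure mode:", x$exposure, "| elements:",
      paste(names(x$specs), collapse = ", "), "\n\n")
  print(x$summary, digits = 3)
  invisible(x)
}
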