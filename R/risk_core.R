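#' Hazard quotient for chronic ingestion of a non-carcinogen
#'
#' Computes HQ = (C * EF * IR * ED) / (BW * AT * RfD) with the
#' non-carcinogenic averaging time AT = ED * 365 days. Because EF defaults
#' to 365 days/year, the expression reduces algebraically to
#' C * IR / (BW * RfD): the hazard quotient is independent of exposure
#' duration under this averaging-time convention.
#'
#' @param conc Concentration(s) in the grain, mg/kg dry weight. Vectorised.
#' @param pop A single-row population data.frame (see [pte_populations()])
#'   or a list with fields `bw`, `ir`, `ed`, `ef`.
#' @param tox A single-row toxicity data.frame (see [pte_toxicity()]) or a
#'   list with fields `element` and `rfd`.
#' @return Dimensionless HQ, same length as `conc`.
#' @export
#' @examples
#' tox <- pte_toxicity(); pops <- pte_populations()
#' hazard_quotient(0.055, pops[pops$group == "children", ],
#'                 tox[tox$element == "As", ])
hazard_quotient <- function(conc, pop, tox) {
  if (any(conc < 0)) stop("negative concentration supplied")
  rfd <- tox$rfd
  if (is.null(rfd) || length(rfd) != 1L || is.na(rfd)) {
    stop("no oral reference dose configured for element '", tox$element, "'")
  }
  at <- pop$ed * 365
  (conc * pop$ef * pop$ir * pop$ed) / (pop$bw * at * rfd)
}

#' Hazard index: sum of co-occurring hazard quotients
#'
#' @param hqs Numeric vector of hazard quotients for one population group
#'   and exposure route.
#' @return The hazard index, the plain sum of the inputs.
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0L) stop("empty hazard-quotient list")
  if (any(!is.finite(hqs)) || any(hqs < 0)) {
    stop("hazard quotients must be finite and non-negative")
  }
  sum(hqs)
}

#' Incremental lifetime carcinogenic risk for one element
#'
#' Computes CR = (C * EF * IR * ED) / (BW * AT) * SF with the carcinogenic
#' averaging time AT = lifetime * 365 days. The exposure duration used for
#' the carcinogenic endpoint is the lifetime itself (ED = 70 years for every
#' group), so EF * ED / AT = 1 and CR reduces to C * IR / BW * SF. See the
#' methods vignette for the rationale behind this convention.
#'
#' @inheritParams hazard_quotient
#' @return Dimensionless lifetime cancer risk, same length as `conc`.
#' @export
carcinogenic_risk <- function(conc, pop, tox) {
  if (any(conc < 0)) stop("negative concentration supplied")
  if (!isTRUE(tox$carcinogenic)) {
    stop("element '", tox$element, "' is not flagged carcinogenic")
  }
  sf <- tox$sf
  if (is.null(sf) || length(sf) != 1L || is.na(sf)) {
    stop("no slope factor configured for element '", tox$element, "'")
  }
  lifetime <- pop$lifetime_years %||% 70
  at <- lifetime * 365
  ed <- lifetime
  (conc * pop$ef * pop$ir * ed) / (pop$bw * at) * sf
}

#' Total carcinogenic risk: sum of element-wise risks
#'
#' @param crs Numeric vector of carcinogenic risks for one population group.
#' @return The total carcinogenic risk (TCR).
#' @export
total_carcinogenic_risk <- function(crs) {
  if (length(crs) == 0L) stop("empty carcinogenic-risk list")
  if (any(!is.finite(crs)) || any(crs < 0)) {
    stop("carcinogenic risks must be finite and non-negative")
  }
  sum(crs)
}

#' Classify a risk value against its regulatory tier boundaries
#'
#' Non-carcinogenic endpoints (HQ, HI) use a single boundary at 1: values
#' strictly greater than 1 indicate risk. Carcinogenic endpoints (CR, TCR)
#' use the conventional 1e-6 / 1e-4 band: below 1e-6 the risk is
#' negligible, within the band it is cautionary, strictly above 1e-4 it is
#' unacceptable. Values falling exactly on a boundary are assigned to the
#' lower tier.
#'
#' @param value Non-negative risk value(s). Vectorised.
#' @param endpoint One of "HQ", "HI", "CR", "TCR".
#' @return Character vector of tier labels: "safe"/"risk" for HQ and HI,
#'   "negligible"/"cautionary"/"unacceptable" for CR and TCR.
#' @export
#' @examples
#' classify_risk(1.02, "HQ")
#' classify_risk(c(5e-7, 5e-5, 5e-3), "CR")
classify_risk <- function(value, endpoint = c("HQ", "HI", "CR", "TCR")) {
  endpoint <- match.arg(endpoint)
  if (any(value < 0)) stop("risk values must be non-negative")
  if (endpoint %in% c("HQ", "HI")) {
    ifelse(value > 1, "risk", "safe")
  } else {
    ifelse(value < 1e-6, "negligible",
           ifelse(value > 1e-4, "unacceptable", "cautionary"))
  }
}

#' Deterministic point-estimate risk table
#'
#' Evaluates the hazard quotient for every element with an RfD and the
#' carcinogenic risk for every element with a slope factor, for every
#' population group, from point concentrations (typically the sample
#' means), and appends the HI and TCR totals per group with their tier
#' classifications.
#'
#' @param conc Named numeric vector of concentrations (mg/kg), names being
#'   element symbols present in `tox`.
#' @param pops Population table from [pte_populations()].
#' @param tox Toxicity table from [pte_toxicity()].
#' @return data.frame with columns `group`, `element` (or "total"),
#'   `endpoint`, `value`, `tier`.
#' @export
point_estimate_risk <- function(conc, pops = pte_populations(), tox = pte_toxicity()) {
  stopifnot(!is.null(names(conc)))
  rows <- list()
  for (g in seq_len(nrow(pops))) {
    pop <- pops[g, ]
    hqs <- c(); crs <- c()
    for (el in names(conc)) {
      tx <- config_row(tox, "element", el)
      if (!is.na(tx$rfd)) {
        hq <- hazard_quotient(conc[[el]], pop, tx)
        hqs[el] <- hq
        rows[[length(rows) + 1L]] <- data.frame(
          group = pop$group, element = el, endpoint = "HQ",
          value = hq, tier = classify_risk(hq, "HQ"))
      }
      if (tx$carcinogenic && !is.na(tx$sf)) {
        cr <- carcinogenic_risk(conc[[el]], pop, tx)
        crs[el] <- cr
        rows[[length(rows) + 1L]] <- data.frame(
          group = pop$group, element = el, endpoint = "CR",
          value = cr, tier = classify_risk(cr, "CR"))
      }
    }
    hi <- hazard_index(hqs)
    tcr <- total_carcinogenic_risk(crs)
    rows[[length(rows) + 1L]] <- data.frame(
      group = pop$group, element = "total", endpoint = "HI",
      value = hi, tier = classify_risk(hi, "HI"))
    rows[[length(rows) + 1L]] <- data.frame(
      group = pop$group, element = "total", endpoint = "TCR",
      value = tcr, tier = classify_risk(tcr, "TCR"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
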