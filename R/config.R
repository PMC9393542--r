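#' Element toxicity and regulatory-limit configuration
#'
#' Returns the packaged default toxicity table for the six elements assessed
#' in wheat grain: oral reference doses (RfD, mg/kg/day), cancer slope
#' factors (SF, (mg/kg/day)^-1) for the carcinogens Cr, As, Cd and Pb, and
#' FAO maximum limits in grain (mg/kg). Fluoride has no current grain limit;
#' Ni and F carry no slope factor.
#'
#' The chromium RfD (1.5 mg/kg/day, the conventional oral value for
#' trivalent chromium in food-ingestion work) is a package default and can
#' be overridden through a user configuration file.
#'
#' @param path Optional path to a JSON file keyed by element symbol with
#'   fields `rfd`, `sf`, `standard_limit` and `carcinogenic`. When `NULL`
#'   the packaged defaults are returned.
#' @return A data.frame with columns `element`, `rfd`, `sf`,
#'   `standard_limit`, `carcinogenic`. Missing entries are `NA`.
#' @export
#' @examples
#' pte_toxicity()
pte_toxicity <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "toxicity.json", package = "grainrisk")
  }
  raw <- jsonlite::read_json(path)
  out <- data.frame(
    element = names(raw),
    rfd = vapply(raw, function(x) as.numeric(x$rfd %||% NA_real_), 1),
    sf = vapply(raw, function(x) as.numeric(x$sf %||% NA_real_), 1),
    standard_limit = vapply(raw, function(x) as.numeric(x$standard_limit %||% NA_real_), 1),
    carcinogenic = vapply(raw, function(x) isTRUE(x$carcinogenic), TRUE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  bad <- !is.na(out$rfd) & out$rfd <= 0
  if (any(bad)) {
    stop("non-positive RfD for element(s): ", paste(out$element[bad], collapse = ", "))
  }
  bad <- !is.na(out$sf) & out$sf <= 0
  if (any(bad)) {
    stop("non-positive slope factor for element(s): ", paste(out$element[bad], collapse = ", "))
  }
  out
}

#' Population exposure-parameter configuration
#'
#' Returns exposure parameters for the three assessed population groups:
#' body weight BW (kg), daily wheat intake IR (kg dry grain/day), exposure
#' duration ED (years), exposure frequency EF (days/year) and the lifetime
#' (years) used in the carcinogenic averaging time. Defaults are the
#' standard Chinese exposure-factor values: children (16.88 kg, 0.094
#' kg/day, 6 y), adult females (57.03 kg, 0.160 kg/day, 70 y) and adult
#' males (66.2 kg, 0.160 kg/day, 70 y), all with EF = 365.
#'
#' @param path Optional JSON file keyed by group id with fields `bw`, `ir`,
#'   `ed`, `ef` and optionally `lifetime_years` (default 70).
#' @return data.frame with columns `group`, `bw`, `ir`, `ed`, `ef`,
#'   `lifetime_years`.
#' @export
#' @examples
#' pte_populations()
pte_populations <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "populations.json", package = "grainrisk")
  }
  raw <- jsonlite::read_json(path)
  out <- data.frame(
    group = names(raw),
    bw = vapply(raw, function(x) as.numeric(x$bw), 1),
    ir = vapply(raw, function(x) as.numeric(x$ir), 1),
    ed = vapply(raw, function(x) as.numeric(x$ed), 1),
    ef = vapply(raw, function(x) as.numeric(x$ef), 1),
    lifetime_years = vapply(raw, function(x) as.numeric(x$lifetime_years %||% 70), 1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  with(out, {
    if (any(bw <= 0) || any(ir <= 0) || any(ed <= 0) || any(ef <= 0)) {
      stop("bw, ir, ed and ef must all be strictly positive")
    }
    if (any(ef > 366)) stop("ef cannot exceed 366 days/year")
  })
  out
}

# take a single group / element row from a config data.frame
config_row <- function(df, key_col, key) {
  i <- match(key, df[[key_col]])
  if (is.na(i)) stop("unknown ", key_col, ": ", key)
  df[i, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
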