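#' Read a sample-by-element concentration table
#'
#' Expects a CSV whose first column holds sample identifiers and whose
#' remaining columns, named by element symbol, hold concentrations in mg/kg
#' dry weight. Empty cells are read as missing.
#'
#' @param path Path to the CSV file.
#' @return data.frame with a `sample_id` character column followed by one
#'   numeric column per element.
#' @export
read_concentrations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  for (j in seq(2, ncol(df))) df[[j]] <- as.numeric(df[[j]])
  validate_concentrations(df)
  df
}

#' Write a concentration table in the package CSV dialect
#' @param table Concentration data.frame (first column `sample_id`).
#' @param path Output path.
#' @export
write_concentrations <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
}

validate_concentrations <- function(table) {
  vals <- as.matrix(table[, -1, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  invisible(table)
}

element_columns <- function(table) {
  setdiff(names(table), "sample_id")
}

element_matrix <- function(table) {
  as.matrix(table[, element_columns(table), drop = FALSE])
}

#' Classify a coefficient of variation
#'
#' CV below 10% is classed as weak variation (dominantly natural control),
#' 10-90% as moderate, and above 90% as strong variation (dominantly
#' anthropogenic control). Boundary values belong to the moderate class.
#'
#' @param cv_percent Non-negative CV value(s) in percent. Vectorised.
#' @return Character vector among "weak", "moderate", "strong".
#' @export
classify_cv <- function(cv_percent) {
  if (any(is.na(cv_percent)) || any(cv_percent < 0)) {
    stop("cv_percent must be non-negative")
  }
  ifelse(cv_percent < 10, "weak",
         ifelse(cv_percent > 90, "strong", "moderate"))
}

#' Descriptive summary of a concentration table
#'
#' Per element: mean, median, sample standard deviation (n-1 denominator),
#' minimum, maximum, coefficient of variation (percent) with its
#' variability class, and -- for elements with a configured standard limit
#' -- the exceedance count and ratio. Exceedance is strict: a sample equal
#' to the limit meets it. Elements whose mean is zero get an absent CV.
#' All-missing columns are skipped with a warning.
#'
#' @param table Concentration data.frame as from [read_concentrations()] or
#'   [generate_concentrations()].
#' @param tox Toxicity table supplying `standard_limit` per element.
#' @return data.frame with one row per element: `element`, `n`, `mean`,
#'   `median`, `sd`, `minimum`, `maximum`, `cv_percent`, `cv_class`,
#'   `exceed_count`, `exceeding_ratio_percent`. An attribute `sd_denominator`
#'   records the n-1 convention.
#' @export
summarize_concentrations <- function(table, tox = pte_toxicity()) {
  validate_concentrations(table)
  els <- element_columns(table)
  if (length(els) == 0L) stop("no element columns in table")
  rows <- lapply(els, function(el) {
    x <- table[[el]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      warning("element ", el, " has no non-missing values; skipped")
      return(NULL)
    }
    if (length(x) < 3L) {
      warning("element ", el, ": fewer than 3 samples, only min/max reported")
      return(data.frame(element = el, n = length(x), mean = NA_real_,
                        median = NA_real_, sd = NA_real_,
                        minimum = min(x), maximum = max(x),
                        cv_percent = NA_real_, cv_class = NA_character_,
                        exceed_count = NA_integer_,
                        exceeding_ratio_percent = NA_real_))
    }
    m <- mean(x); s <- stats::sd(x)
    cv <- if (m > 0) 100 * s / m else NA_real_
    lim <- if (el %in% tox$element) config_row(tox, "element", el)$standard_limit else NA_real_
    if (!is.na(lim)) {
      k <- sum(x > lim)
      ratio <- 100 * k / length(x)
    } else {
      k <- NA_integer_; ratio <- NA_real_
    }
    data.frame(element = el, n = length(x), mean = m, median = stats::median(x),
               sd = s, minimum = min(x), maximum = max(x),
               cv_percent = cv,
               cv_class = if (is.na(cv)) NA_character_ else classify_cv(cv),
               exceed_count = k, exceeding_ratio_percent = ratio)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sd_denominator") <- "n-1"
  out
}

#' Standard-limit exceedance screen
#'
#' Counts, per element with a configured limit, the samples strictly above
#' the limit and the corresponding percentage of n.
#'
#' @inheritParams summarize_concentrations
#' @return data.frame with `element`, `n`, `limit`, `exceed_count`,
#'   `exceeding_ratio_percent`.
#' @export
exceedance_report <- function(table, tox = pte_toxicity()) {
  validate_concentrations(table)
  els <- intersect(element_columns(table), tox$element[!is.na(tox$standard_limit)])
  rows <- lapply(els, function(el) {
    x <- table[[el]]; x <- x[!is.na(x)]
    lim <- config_row(tox, "element", el)$standard_limit
    k <- sum(x > lim)
    data.frame(element = el, n = length(x), limit = lim,
               exceed_count = k,
               exceeding_ratio_percent = 100 * k / length(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
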