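#' Spearman correlation matrix with two-sided p-values
#'
#' Rank correlation between every pair of element columns, with average
#' ranks for ties and two-sided p-values from [stats::cor.test()]. Constant
#' columns yield NA correlations for their pairs, with a warning.
#'
#' @param table Concentration data.frame (first column `sample_id`) or a
#'   plain numeric data.frame/matrix of variables.
#' @return List of class `correlation_matrix` with components `elements`,
#'   `rho` (k x k), `p` (k x k, NA diagonal), `n`.
#' @export
spearman_matrix <- function(table) {
  x <- as_variable_matrix(table)
  k <- ncol(x)
  if (nrow(x) < 4L) stop("need at least 4 complete observations")
  consts <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(consts)) {
    warning("constant column(s): ", paste(colnames(x)[consts], collapse = ", "),
            "; correlations set to NA")
  }
  rho <- matrix(NA_real_, k, k, dimnames = list(colnames(x), colnames(x)))
  p <- rho
  diag(rho) <- 1
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (consts[i] || consts[j]) next
      ok <- stats::complete.cases(x[, c(i, j)])
      ct <- suppressWarnings(
        stats::cor.test(x[ok, i], x[ok, j], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(elements = colnames(x), rho = rho, p = p, n = nrow(x)),
            class = "correlation_matrix")
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO compares marginal and partial correlations:
#' sum(r^2) / (sum(r^2) + sum(q^2)) over the off-diagonal entries, where the
#' partial correlations q come from the anti-image (inverse) of the Pearson
#' correlation matrix. Values above 0.5 are conventionally taken to mean
#' the data carry enough shared variance for factor-style analysis.
#'
#' @param table A concentration data.frame, a numeric matrix of
#'   observations, or (with `is_cor = TRUE`) a correlation matrix directly.
#' @param is_cor Set TRUE when `table` is already a correlation matrix.
#' @return Overall KMO in [0, 1].
#' @export
kmo_measure <- function(table, is_cor = FALSE) {
  R <- if (is_cor) as.matrix(table) else stats::cor(as_variable_matrix(table),
                                                   use = "pairwise.complete.obs")
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; remove redundant columns"))
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(d, d)   # partial correlations
  off <- upper.tri(R)
  if (sum(R[off]^2) < 1e-12) return(0)  # no shared variance at all
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Bartlett test of sphericity
#'
#' Tests whether the correlation matrix is the identity using
#' chi2 = -(n - 1 - (2k + 5)/6) * log det(R) on k(k-1)/2 degrees of
#' freedom. A small p-value licenses correlation-based dimension reduction.
#'
#' @inheritParams kmo_measure
#' @param n Number of observations; required when `is_cor = TRUE`.
#' @return List with `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(table, n = NULL, is_cor = FALSE) {
  if (is_cor) {
    R <- as.matrix(table)
    if (is.null(n)) stop("supply n when passing a correlation matrix")
  } else {
    x <- as_variable_matrix(table)
    R <- stats::cor(x, use = "pairwise.complete.obs")
    n <- nrow(x)
  }
  k <- ncol(R)
  if (n <= k) stop("need more observations than variables")
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix determinant is non-positive")
  chi2 <- -(n - 1 - (2 * k + 5) / 6) * log(detR)
  df <- k * (k - 1) / 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Principal component analysis of a concentration table
#'
#' Correlation-matrix PCA: columns are z-scored, components are unrotated,
#' and loadings are reported as eigenvector * sqrt(eigenvalue) so each
#' entry is the correlation between a variable and a component. Component
#' sign is fixed so the largest-magnitude loading in each column is
#' positive. Zero-variance columns are dropped with a warning. KMO and
#' Bartlett diagnostics are attached.
#'
#' @param table Concentration data.frame or numeric matrix.
#' @param n_components Number of components to report; default is the
#'   Kaiser rule (eigenvalues > 1).
#' @param log_transform Log-transform the data before z-scoring.
#' @return List of class `pca_result`: `loadings` (k x m),
#'   `explained_variance_percent` (all k components), `eigenvalues`, `kmo`,
#'   `bartlett` (chi2/df/p list), `n_components`, `scaling`.
#' @export
pca_concentrations <- function(table, n_components = NULL, log_transform = FALSE) {
  x <- as_variable_matrix(table)
  if (log_transform) {
    if (any(x <= 0, na.rm = TRUE)) stop("log transform requires positive values")
    x <- log(x)
  }
  v <- apply(x, 2, stats::var, na.rm = TRUE)
  if (any(v == 0)) {
    warning("zero-variance column(s) removed: ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  if (nrow(x) <= ncol(x)) stop("need more observations than variables")
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  k <- ncol(x)
  expl <- 100 * eig / sum(eig)
  if (is.null(n_components)) n_components <- max(1L, sum(eig > 1))
  if (n_components > k) stop("n_components exceeds the number of variables")
  load <- pc$rotation %*% diag(sqrt(eig), k, k)
  colnames(load) <- paste0("PC", seq_len(k))
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  structure(list(
    loadings = load[, seq_len(n_components), drop = FALSE],
    loadings_full = load,
    explained_variance_percent = expl,
    eigenvalues = eig,
    kmo = kmo_measure(stats::cor(x, use = "pairwise.complete.obs"), is_cor = TRUE),
    bartlett = bartlett_sphericity(x),
    n_components = n_components,
    scaling = "eigenvector * sqrt(eigenvalue) (variable-component correlations)"
  ), class = "pca_result")
}

as_variable_matrix <- function(table) {
  if (is.matrix(table)) return(table)
  df <- as.data.frame(table)
  if ("sample_id" %in% names(df)) df <- df[, setdiff(names(df), "sample_id"), drop = FALSE]
  as.matrix(df)
}
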