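#' Construct a sampling-distribution specification
#'
#' Light-weight container for the distribution families the risk engine and
#' the synthetic generator draw from.
#'
#' Families and their parameters:
#' \describe{
#'   \item{point}{`value` (a degenerate distribution)}
#'   \item{normal}{`mean`, `sd`}
#'   \item{lognormal}{`meanlog`, `sdlog`}
#'   \item{uniform}{`min`, `max`}
#'   \item{triangular}{`min`, `mode`, `max`}
#'   \item{lnorm_mix2}{two-component lognormal mixture: `w` (weight of the
#'     first component), `meanlog1`, `sdlog1`, `meanlog2`, `sdlog2`}
#' }
#'
#' @param family One of the families above.
#' @param ... Named parameters for the family.
#' @param truncation Optional `c(low, high)`; sampling is then restricted to
#'   the interval by inverse-CDF conditioning.
#' @return Object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("point", "normal", "lognormal", "uniform",
                                 "triangular", "lnorm_mix2"),
                      ..., truncation = NULL) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
    point = "value",
    normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    uniform = c("min", "max"),
    triangular = c("min", "mode", "max"),
    lnorm_mix2 = c("w", "meanlog1", "sdlog1", "meanlog2", "sdlog2"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("family '", family, "' needs parameter(s): ", paste(missing, collapse = ", "))
  }
  params <- params[need]
  if (family == "normal" && params$sd <= 0) stop("sd must be positive")
  if (family == "lognormal" && params$sdlog <= 0) stop("sdlog must be positive")
  if (family == "uniform" && params$min >= params$max) stop("min must be below max")
  if (family == "triangular" &&
      !(params$min <= params$mode && params$mode <= params$max &&
        params$min < params$max)) stop("need min <= mode <= max, min < max")
  if (family == "lnorm_mix2") {
    if (params$w <= 0 || params$w >= 1) stop("mixture weight must be in (0,1)")
    if (params$sdlog1 <= 0 || params$sdlog2 <= 0) stop("sdlog must be positive")
  }
  if (!is.null(truncation)) {
    if (length(truncation) != 2L || truncation[1] >= truncation[2]) {
      stop("truncation must be an ordered pair")
    }
  }
  structure(list(family = family, params = params, truncation = truncation),
            class = "dist_spec")
}

# untruncated CDF
dist_cdf <- function(spec, q) {
  p <- spec$params
  switch(spec$family,
    point = as.numeric(q >= p$value),
    normal = stats::pnorm(q, p$mean, p$sd),
    lognormal = stats::plnorm(q, p$meanlog, p$sdlog),
    uniform = stats::punif(q, p$min, p$max),
    triangular = ptri(q, p$min, p$mode, p$max),
    lnorm_mix2 = p$w * stats::plnorm(q, p$meanlog1, p$sdlog1) +
      (1 - p$w) * stats::plnorm(q, p$meanlog2, p$sdlog2))
}

# untruncated quantile function; u may be a vector in [0,1]
dist_quantile <- function(spec, u) {
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, length(u)),
    normal = stats::qnorm(u, p$mean, p$sd),
    lognormal = stats::qlnorm(u, p$meanlog, p$sdlog),
    uniform = stats::qunif(u, p$min, p$max),
    triangular = qtri(u, p$min, p$mode, p$max),
    lnorm_mix2 = qlnorm_mix2(u, p))
}

ptri <- function(q, a, c, b) {
  ifelse(q <= a, 0,
  ifelse(q >= b, 1,
  ifelse(q < c, (q - a)^2 / ((b - a) * (c - a)),
         1 - (b - q)^2 / ((b - a) * (b - c)))))
}

qtri <- function(u, a, c, b) {
  fc <- (c - a) / (b - a)
  ifelse(u < fc, a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

# numeric inversion of the two-component lognormal mixture CDF
qlnorm_mix2 <- function(u, p) {
  lo0 <- pmin(stats::qlnorm(1e-12, p$meanlog1, p$sdlog1),
              stats::qlnorm(1e-12, p$meanlog2, p$sdlog2))
  hi0 <- pmax(stats::qlnorm(1 - 1e-12, p$meanlog1, p$sdlog1),
              stats::qlnorm(1 - 1e-12, p$meanlog2, p$sdlog2))
  cdf <- function(q) p$w * stats::plnorm(q, p$meanlog1, p$sdlog1) +
    (1 - p$w) * stats::plnorm(q, p$meanlog2, p$sdlog2)
  vapply(u, function(ui) {
    if (ui <= 0) return(0)
    if (ui >= 1) return(hi0)
    stats::uniroot(function(q) cdf(q) - ui, c(lo0, hi0), tol = 1e-10)$root
  }, 1)
}

#' Draw from a distribution specification
#'
#' Inverse-CDF sampling (so draws are a deterministic function of the
#' uniform stream); truncation is honoured by conditioning the uniforms on
#' the truncation interval's CDF image.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n) {
  if (spec$family == "point") return(rep(spec$params$value, n))
  u <- stats::runif(n)
  if (!is.null(spec$truncation)) {
    lo <- dist_cdf(spec, spec$truncation[1])
    hi <- dist_cdf(spec, spec$truncation[2])
    u <- lo + u * (hi - lo)
  }
  dist_quantile(spec, u)
}

#' Analytic mean of a distribution specification
#'
#' Closed forms for point, normal, lognormal and the lognormal mixture
#' (including truncation); numeric integration otherwise. Used as the
#' convergence oracle for Monte Carlo means.
#'
#' @param spec A [dist_spec()].
#' @return The expectation of the (possibly truncated) distribution.
#' @export
dist_mean <- function(spec) {
  p <- spec$params
  tr <- spec$truncation
  if (spec$family == "point") return(p$value)
  if (is.null(tr)) {
    return(switch(spec$family,
      normal = p$mean,
      lognormal = exp(p$meanlog + p$sdlog^2 / 2),
      uniform = (p$min + p$max) / 2,
      triangular = (p$min + p$mode + p$max) / 3,
      lnorm_mix2 = p$w * exp(p$meanlog1 + p$sdlog1^2 / 2) +
        (1 - p$w) * exp(p$meanlog2 + p$sdlog2^2 / 2)))
  }
  a <- tr[1]; b <- tr[2]
  if (spec$family == "normal") {
    al <- (a - p$mean) / p$sd; be <- (b - p$mean) / p$sd
    Z <- stats::pnorm(be) - stats::pnorm(al)
    return(p$mean + p$sd * (stats::dnorm(al) - stats::dnorm(be)) / Z)
  }
  if (spec$family == "lognormal") {
    return(trunc_lnorm_mean(a, b, p$meanlog, p$sdlog))
  }
  if (spec$family == "lnorm_mix2") {
    z1 <- stats::plnorm(b, p$meanlog1, p$sdlog1) - stats::plnorm(a, p$meanlog1, p$sdlog1)
    z2 <- stats::plnorm(b, p$meanlog2, p$sdlog2) - stats::plnorm(a, p$meanlog2, p$sdlog2)
    m1 <- trunc_lnorm_mean(a, b, p$meanlog1, p$sdlog1)
    m2 <- trunc_lnorm_mean(a, b, p$meanlog2, p$sdlog2)
    return((p$w * z1 * m1 + (1 - p$w) * z2 * m2) / (p$w * z1 + (1 - p$w) * z2))
  }
  # numeric fallback for the remaining truncated families
  Z <- dist_cdf(spec, b) - dist_cdf(spec, a)
  stats::integrate(function(q) q * num_pdf(spec, q), a, b)$value / Z
}

trunc_lnorm_mean <- function(a, b, mu, s) {
  la <- if (a <= 0) -Inf else (log(a) - mu) / s
  lb <- (log(b) - mu) / s
  Z <- stats::pnorm(lb) - stats::pnorm(la)
  exp(mu + s^2 / 2) * (stats::pnorm(lb - s) - stats::pnorm(la - s)) / Z
}

num_pdf <- function(spec, q) {
  p <- spec$params
  switch(spec$family,
    normal = stats::dnorm(q, p$mean, p$sd),
    lognormal = stats::dlnorm(q, p$meanlog, p$sdlog),
    uniform = stats::dunif(q, p$min, p$max),
    triangular = {
      ifelse(q < p$min | q > p$max, 0,
      ifelse(q < p$mode, 2 * (q - p$min) / ((p$max - p$min) * (p$mode - p$min)),
             2 * (p$max - q) / ((p$max - p$min) * (p$max - p$mode))))
    },
    lnorm_mix2 = p$w * stats::dlnorm(q, p$meanlog1, p$sdlog1) +
      (1 - p$w) * stats::dlnorm(q, p$meanlog2, p$sdlog2))
}

#' Fit a sampling distribution to one element's concentrations
#'
#' Default fit is a lognormal by log-moment matching (mean and SD of the
#' log values). A bimodality screen then compares one- and two-component
#' Gaussian mixtures on the log scale (EM via the mclust package): when the
#' two-component fit improves the log-likelihood by more than
#' `bimodal_margin` on the deviance scale, a two-component lognormal
#' mixture is returned instead. Fits are truncated to
#' `[min(x)/2, 2*max(x)]` to keep simulated tails physical.
#'
#' Zeros (non-detects) are replaced by half the smallest positive value
#' with a message. Fewer than 10 values falls back to a point mass at the
#' mean, with a warning. If the fitted distribution's analytic mean strays
#' more than 10% from the sample mean, a warning is attached (attribute
#' `mean_mismatch`).
#'
#' @param x Numeric vector of concentrations, non-negative.
#' @param bimodal_margin Deviance improvement (2 * delta log-likelihood)
#'   required to prefer the two-component mixture. Default 15.
#' @return A [dist_spec()].
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_concentration_distribution <- function(x, bimodal_margin = 15) {
  x <- x[!is.na(x)]
  if (any(x < 0)) stop("concentrations must be non-negative")
  if (any(x == 0)) {
    pos <- x[x > 0]
    if (length(pos) == 0L) stop("all values are zero; nothing to fit")
    message("replacing ", sum(x == 0), " zero value(s) by half the minimum positive value")
    x[x == 0] <- min(pos) / 2
  }
  if (stats::sd(x) == 0) return(dist_spec("point", value = x[1]))
  if (length(x) < 10L) {
    warning("fewer than 10 values; falling back to a point mass at the mean")
    return(dist_spec("point", value = mean(x)))
  }
  lx <- log(x)
  tr <- c(min(x) / 2, 2 * max(x))
  spec <- dist_spec("lognormal", meanlog = mean(lx), sdlog = stats::sd(lx),
                    truncation = tr)
  fit1 <- tryCatch(mclust::Mclust(lx, G = 1, modelNames = "V", verbose = FALSE),
                   error = function(e) NULL)
  fit2 <- tryCatch(mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE),
                   error = function(e) NULL)
  if (!is.null(fit1) && !is.null(fit2) &&
      2 * (fit2$loglik - fit1$loglik) > bimodal_margin) {
    mu <- unname(fit2$parameters$mean)
    sg <- sqrt(unname(fit2$parameters$variance$sigmasq))
    if (length(sg) == 1L) sg <- rep(sg, 2)
    spec <- dist_spec("lnorm_mix2", w = fit2$parameters$pro[1],
                      meanlog1 = mu[1], sdlog1 = sg[1],
                      meanlog2 = mu[2], sdlog2 = sg[2],
                      truncation = tr)
  }
  fitted_mean <- dist_mean(spec)
  if (abs(fitted_mean - mean(x)) > 0.1 * mean(x)) {
    attr(spec, "mean_mismatch") <- c(fitted = fitted_mean, sample = mean(x))
    warning("fitted mean ", signif(fitted_mean, 4), " deviates more than 10% from sample mean ",
            signif(mean(x), 4))
  }
  spec
}
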