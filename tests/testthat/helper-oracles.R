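# equicorrelation matrix: unit diagonal, constant off-diagonal r
equicorr <- function(k, r) {
  R <- matrix(r, k, k)
  diag(R) <- 1
  R
}

# data whose *sample* correlation matrix is exactly R: whiten a random
# matrix to the identity sample covariance, then colour by chol(R)
exact_cor_data <- function(n, R, seed = 1) {
  set.seed(seed)
  k <- ncol(R)
  X <- matrix(rnorm(n * k), n, k)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- X %*% solve(chol(stats::cov(X)))
  X <- X %*% chol(R)
  colnames(X) <- paste0("V", seq_len(k))
  X
}

# closed-form KMO of an equicorrelation matrix: the partial correlation of
# an equicorrelated system is r / (1 + (k-2) r)
kmo_equicorr_oracle <- function(k, r) {
  q <- r / (1 + (k - 2) * r)
  m <- k * (k - 1) / 2
  (m * r^2) / (m * r^2 + m * q^2)
}

children <- function() {
  pops <- pte_populations()
  pops[pops$group == "children", ]
}

tox_row <- function(el) {
  tox <- pte_toxicity()
  tox[tox$element == el, ]
}
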