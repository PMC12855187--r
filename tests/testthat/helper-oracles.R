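# Independent oracles, deliberately naive and separate from the package code.

# One-component PLS1 by the textbook NIPALS recursion; returns training
# predictions of the centered response.
pls1_oracle <- function(X, y) {
  X <- as.matrix(X)
  yc <- y - mean(y)
  w <- crossprod(X, yc)
  w <- w / sqrt(sum(w^2))
  tt <- X %*% w
  c1 <- sum(tt * yc) / sum(tt^2)
  as.vector(tt) * c1
}

# Upper-tail hypergeometric p by exhaustive enumeration of all draws of size n
# from a universe of size N containing K marked items.
hyper_enum_oracle <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Two-sided exact Mann-Whitney p by enumeration of all group labelings.
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  labelings <- utils::combn(length(pooled), n1)
  us <- apply(labelings, 2, function(ix)
    u_stat(pooled[ix], pooled[-ix]))
  dev_obs <- abs(u_obs - n1 * length(y) / 2)
  mean(abs(us - n1 * length(y) / 2) >= dev_obs - 1e-9)
}

# Lorentzian area between a and b by fine quadrature.
lorentz_area_oracle <- function(center, area, width, a, b) {
  hw <- width / 2
  f <- function(x) (area / pi) * hw / ((x - center)^2 + hw^2)
  stats::integrate(f, a, b, rel.tol = 1e-10)$value
}

# Small two-peak spectrum set used by several bucketing tests.
two_peak_spectra <- function(centers = c(2.006, 2.030), widths = c(0.008, 0.008),
                             areas = c(1, 1), n_points = 16384) {
  ppm <- seq(0, 8.6, length.out = n_points)
  y <- numeric(n_points)
  for (i in seq_along(centers)) {
    hw <- widths[i] / 2
    y <- y + (areas[i] / pi) * hw / ((ppm - centers[i])^2 + hw^2)
  }
  spectrum_set(ppm, rbind(s1 = y))
}
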