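# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, where the package wraps a stats function,
# avoid that function too).

# Newton-Raphson maximizer of the grouped binomial log-likelihood, written
# directly from the score and observed information.
newton_binom <- function(X, y, n, tol = 1e-12, max_iter = 60) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    score <- drop(crossprod(X, y - n * p))
    info <- crossprod(X * sqrt(n * p * (1 - p)))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

binom_dev_oracle <- function(y, n, p) {
  term <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  2 * sum(term(y, n * p) + term(n - y, n * (1 - p)))
}

# upper-tail chi-square probability by numerical integration of the density
chisq_upper_by_integration <- function(q, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, q, Inf, rel.tol = 1e-10)$value
}

# two-sided Fisher p by exhaustive enumeration of tables with fixed margins,
# probability-mass convention with a small relative tolerance
fisher_enum <- function(a, b, c, d, rel_tol = 1e-7) {
  m <- a + b
  nn <- c + d
  k <- a + c
  support <- max(0, k - nn):min(k, m)
  logp <- stats::dhyper(support, m, nn, k, log = TRUE)
  obs <- logp[support == a]
  sum(exp(logp[logp <= obs + log(1 + rel_tol)]))
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all assignments of
# ranks to the x-sample (untied data only, small n)
wilcox_enum <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  all_ranks <- seq_len(nx + ny)
  w_all <- apply(combs, 2, function(ix) sum(all_ranks[ix])) -
    nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# brute-force distance to range: scan every cell, recompute haversine from
# first principles (spherical law of cosines-free haversine formula)
haversine_oracle <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

distance_to_range_oracle <- function(grid, interval, lat, lon) {
  v <- grid$values / 10
  best <- Inf
  for (r in seq_len(nrow(v))) for (cc in seq_len(ncol(v))) {
    if (is.na(v[r, cc]) || v[r, cc] < interval[1] || v[r, cc] > interval[2])
      next
    clat <- grid$lat_nw - (r - 0.5) * grid$cell_size
    clon <- grid$lon_nw + (cc - 0.5) * grid$cell_size
    # is the query point in this cell?
    if (lat <= grid$lat_nw - (r - 1) * grid$cell_size &&
        lat > grid$lat_nw - r * grid$cell_size &&
        lon >= grid$lon_nw + (cc - 1) * grid$cell_size &&
        lon < grid$lon_nw + cc * grid$cell_size)
      return(0)
    best <- min(best, haversine_oracle(lat, lon, clat, clon))
  }
  best
}

# small random grouped-binomial dataset for GLM tests
random_binom_data <- function(n_obs, n_cov = 1, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n_obs * n_cov), n_obs))
  beta <- rnorm(ncol(X), 0, 0.8)
  n <- sample(2:8, n_obs, replace = TRUE)
  p <- 1 / (1 + exp(-drop(X %*% beta)))
  y <- rbinom(n_obs, n, p)
  d <- as.data.frame(X[, -1, drop = FALSE])
  names(d) <- paste0("x", seq_len(n_cov))
  d$y <- y
  d$n <- n
  list(data = d, X = X, y = y, n = n)
}
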