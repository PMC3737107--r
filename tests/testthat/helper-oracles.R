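# Independent oracles used across tests.  These deliberately avoid the
# package's own quadrature/likelihood code paths.

# truncated half-normal log-likelihood via adaptive quadrature
oracle_hn_loglik <- function(sigma, y, w) {
  mu <- stats::integrate(function(u) exp(-u^2 / (2 * sigma^2)), 0, w,
                         rel.tol = 1e-10)$value
  sum(-y^2 / (2 * sigma^2)) - length(y) * log(mu)
}

# truncated uniform + 1-cosine log-likelihood
oracle_unifcos_loglik <- function(a1, y, w) {
  g <- function(u) 1 + a1 * cos(pi * u / w)
  mu <- stats::integrate(g, 0, w, rel.tol = 1e-10)$value
  sum(log(g(y))) - length(y) * log(mu)
}

# draw from a truncated half-normal by rejection
r_trunc_halfnormal <- function(n, sigma, w) {
  out <- numeric(0)
  while (length(out) < n) {
    y <- abs(stats::rnorm(2 * n, 0, sigma))
    out <- c(out, y[y <= w])
  }
  out[seq_len(n)]
}

# axis-aligned membership test for a vertical transect band (flat caps),
# independent of the package's geometry code
in_vertical_band <- function(px, py, x0, y0, y1, hw) {
  abs(px - x0) <= hw & py >= y0 & py <= y1
}
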