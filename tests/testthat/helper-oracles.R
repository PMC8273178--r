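# Independent numerical oracles used across the suite.

# Composite-Simpson quadrature of the Heaviside-gated Gaussian pulse
# window, at a ~1 ms step.
quad_pulse_integral <- function(T, alpha, lower, upper, step = 0.001) {
  lo <- max(lower, 0)
  up <- max(upper, 0)
  if (up <= lo) {
    return(0)
  }
  n <- 2L * ceiling((up - lo) / (2 * step))
  tau <- seq(lo, up, length.out = n + 1L)
  f <- exp(-(tau - T)^2 / (2 * alpha^2))
  h <- (up - lo) / n
  h / 3 * (f[1] + f[n + 1L] +
    4 * sum(f[seq(2, n, by = 2)]) + 2 * sum(f[seq(3, n - 1, by = 2)]))
}

# Direct double-loop re-summation of the relative squared-error objective.
loop_error_value <- function(observed, fitted, eps = 1e-3) {
  total <- 0
  for (j in seq_len(ncol(observed))) {
    for (i in seq_len(nrow(observed))) {
      m <- fitted[i, j]
      denom <- if (abs(m) < eps) sign(m + (m == 0)) * eps else m
      total <- total + ((observed[i, j] - m) / denom)^2
    }
  }
  total
}

# Upper-tail probability of the studentized range by direct numerical
# integration (independent of stats::ptukey): the CDF is
#   P(Q < q) = int_0^inf f_s(s) * F_range(q s) ds
# with s the scale factor sqrt(chi^2_df / df) and
#   F_range(w) = k * int phi(z) * (Phi(z) - Phi(z - w))^(k-1) dz.
quad_ptukey_upper <- function(q, k, df) {
  f_range <- function(w) {
    stats::integrate(
      function(z) k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1),
      -9, 9,
      rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 400L
    )$value
  }
  fs <- function(s) {
    exp(
      log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
        (df - 1) * log(s) - df * s^2 / 2
    )
  }
  cdf <- stats::integrate(
    function(s) {
      vapply(s, function(si) fs(si) * f_range(q * si), numeric(1))
    },
    0, Inf,
    rel.tol = 1e-9, subdivisions = 400L
  )$value
  1 - cdf
}

# Bisection inverse of the cumulative Gaussian, for threshold checks.
bisect_gaussian_quantile <- function(p, mu, sigma, tol = 1e-12) {
  lo <- mu - 12 * sigma
  hi <- mu + 12 * sigma
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm((mid - mu) / sigma) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Small display for fast rendering tests (8 px/deg).
test_geometry <- function() {
  display_geometry(69, 31.5, 25.2, 252, 202)
}

# Noise-free four-condition model data from known parameters.
make_truth <- function(a1 = c(0.9, 0.55, 0.65, 0.8), b = 0.002, d = 0.05,
                       temporal = hrf_temporal_params()) {
  conds <- lapply(a1, function(a) condition_params(a, -0.15 * a, b, d))
  names(conds) <- c("/0", "/2", "/4", "/6")
  resp <- sapply(conds, function(cp) model_response(temporal, cp))
  list(temporal = temporal, conds = conds, resp = resp)
}
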