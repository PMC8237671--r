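# Independent oracles and small fixture builders used across the suite.

# Brute-force fixed-point oracle: sign-change scan of p(f) - f on a dense
# grid, midpoint of each bracketing interval. Independent of the bisection
# code path in fixed_points().
brute_fixed_points <- function(curve, n = 1e6) {
  f <- seq(0, 1, length.out = n)
  g <- adoption_share(curve, f) - f
  sc <- which(g[-n] * g[-1L] < 0)
  roots <- (f[sc] + f[sc + 1L]) / 2
  hit <- which(g == 0)
  sort(c(roots, f[hit]))
}

# Quadrature oracle for the gaussian-threshold curve: direct integration of
# the normal density over [0, f], renormalized over [0, 1].
quadrature_curve_value <- function(p0, p1, mu, sigma, f) {
  dens <- function(x) stats::dnorm(x, mean = mu, sd = sigma)
  total <- stats::integrate(dens, 0, 1, rel.tol = 1e-13)$value
  part <- if (f > 0) stats::integrate(dens, 0, f, rel.tol = 1e-13)$value else 0
  p0 + (p1 - p0) * part / total
}

random_gaussian_curve <- function() {
  p0 <- stats::runif(1, 0, 0.4)
  p1 <- stats::runif(1, 0.6, 1)
  mu <- stats::runif(1, 0.2, 0.8)
  sigma <- stats::runif(1, 0.05, 0.3)
  make_gaussian_curve(p0, p1, mu, sigma)
}

# Tiny deterministic panel: one row per respondent-wave from explicit
# Likert vectors (both items equal unless given separately).
toy_panel <- function(w1, w2, w1_vol = w1, w2_vol = w2,
                      trust1 = NULL, trust2 = NULL) {
  n <- length(w1)
  t1 <- if (is.null(trust1)) rep(4, n) else trust1
  t2 <- if (is.null(trust2)) rep(4, n) else trust2
  rbind(
    data.frame(id = seq_len(n), wave = 1, agree_voluntary = w1_vol,
               agree_enforced = w1, trust = t1, altruism = 0, female = 0,
               east = 0, effectiveness = NA_real_, freedom = NA_real_,
               pandemic_critical = 0),
    data.frame(id = seq_len(n), wave = 2, agree_voluntary = w2_vol,
               agree_enforced = w2, trust = t2, altruism = 0, female = 0,
               east = 0, effectiveness = 0, freedom = 0,
               pandemic_critical = 0)
  )
}

demo_pair <- function() {
  regime_curve_pair(make_gaussian_curve(0.2, 1, 0.4, 0.18),
                    make_gaussian_curve(0.15, 0.85, 0.5, 0.22))
}
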