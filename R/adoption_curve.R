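#' Adoption curves for vaccination preferences
#'
#' An adoption curve maps the fraction of the population already vaccinated,
#' `f`, to the fraction who *prefer* being vaccinated to not being vaccinated
#' under a given policy regime. Its upward slope encodes conformism: the more
#' people are vaccinated, the more others come to prefer vaccination.
#'
#' Two families are supported. The `gaussian_threshold` family arises from a
#' heterogeneous population whose conformity thresholds (the coverage level
#' just sufficient to make an individual favour vaccination) are normally
#' distributed; truncation-renormalization pins the curve to its anchors so
#' that `p(0) = p0` and `p(1) = p1` exactly. The `linear` family arises from
#' uniformly distributed thresholds.
#'
#' @name adoption_curve
#' @keywords internal
NULL

new_adoption_curve <- function(family, p0, p1, mu = NA_real_, sigma = NA_real_) {
  structure(
    list(family = family, p0 = p0, p1 = p1, mu = mu, sigma = sigma),
    class = "adoption_curve"
  )
}

check_anchors <- function(p0, p1) {
  if (!is.numeric(p0) || !is.numeric(p1) || length(p0) != 1L || length(p1) != 1L ||
      is.na(p0) || is.na(p1)) {
    stop("invalid-anchor: p0 and p1 must be single non-missing numbers", call. = FALSE)
  }
  if (p0 < 0 || p1 > 1 || p0 > p1) {
    stop("invalid-anchor: require 0 <= p0 <= p1 <= 1 (got p0=", p0,
         ", p1=", p1, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a gaussian-threshold adoption curve
#'
#' Builds the S-shaped adoption curve of a population whose conformity
#' thresholds are normally distributed with mean `mu` and spread `sigma`,
#' truncated to coverage values in \[0, 1\] and renormalized so the anchors
#' are hit exactly:
#' \deqn{p(f) = p_0 + (p_1 - p_0)\,
#'   \frac{\Phi((f-\mu)/\sigma) - \Phi((0-\mu)/\sigma)}
#'        {\Phi((1-\mu)/\sigma) - \Phi((0-\mu)/\sigma)}}
#' so that `p(0) = p0` (the share preferring vaccination when nobody is
#' vaccinated) and `p(1) = p1`.
#'
#' @param p0 Preference share at zero coverage, in \[0, 1\].
#' @param p1 Preference share at full coverage, in \[0, 1\], `p1 >= p0`.
#' @param mu Mean of the threshold distribution (a coverage fraction).
#' @param sigma Positive spread of the threshold distribution.
#' @return An object of class `adoption_curve`.
#' @examples
#' cv <- make_gaussian_curve(0.3, 0.9, mu = 0.5, sigma = 0.15)
#' adoption_share(cv, c(0, 0.5, 1))
#' @seealso [make_linear_curve()], [adoption_share()], [fixed_points()]
#' @export
make_gaussian_curve <- function(p0, p1, mu, sigma) {
  check_anchors(p0, p1)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("degenerate: sigma must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu)) {
    stop("invalid-anchor: mu must be a single number", call. = FALSE)
  }
  new_adoption_curve("gaussian_threshold", p0, p1, mu, sigma)
}

#' Construct a linear adoption curve
#'
#' The linear family `p(f) = p0 + (p1 - p0) f` corresponds to uniformly
#' distributed conformity thresholds: every additional vaccinated individual
#' converts the same number of others, irrespective of current coverage.
#'
#' @inheritParams make_gaussian_curve
#' @return An object of class `adoption_curve`.
#' @examples
#' adoption_share(make_linear_curve(0.1, 0.6), 0.5)
#' @export
make_linear_curve <- function(p0, p1) {
  check_anchors(p0, p1)
  new_adoption_curve("linear", p0, p1)
}

#' Evaluate an adoption curve
#'
#' Returns the share of the population preferring vaccination at prior
#' coverage `f`. Vectorized over `f`.
#'
#' @param curve An `adoption_curve`.
#' @param f Numeric vector of coverage fractions in \[0, 1\].
#' @return Numeric vector of preference shares in `[p0, p1]`.
#' @export
adoption_share <- function(curve, f) {
  stopifnot(inherits(curve, "adoption_curve"))
  if (any(f < -1e-12 | f > 1 + 1e-12, na.rm = TRUE)) {
    stop("coverage f must lie in [0, 1]", call. = FALSE)
  }
  f <- pmin(pmax(f, 0), 1)
  switch(curve$family,
    linear = curve$p0 + (curve$p1 - curve$p0) * f,
    gaussian_threshold = {
      lo <- stats::pnorm((0 - curve$mu) / curve$sigma)
      hi <- stats::pnorm((1 - curve$mu) / curve$sigma)
      z <- (stats::pnorm((f - curve$mu) / curve$sigma) - lo) / (hi - lo)
      curve$p0 + (curve$p1 - curve$p0) * z
    },
    stop("unknown curve family: ", curve$family)
  )
}

#' @export
predict.adoption_curve <- function(object, f, ...) adoption_share(object, f)

#' @export
print.adoption_curve <- function(x, ...) {
  if (x$family == "linear") {
    cat(sprintf("<adoption_curve> linear: p(f) = %.4g + %.4g f\n",
                x$p0, x$p1 - x$p0))
  } else {
    cat(sprintf(
      "<adoption_curve> gaussian_threshold: p0=%.4g p1=%.4g mu=%.4g sigma=%.4g\n",
      x$p0, x$p1, x$mu, x$sigma))
  }
  invisible(x)
}

#' Pair the voluntary and enforced adoption curves of one population
#'
#' Crowding-out of intrinsic motivation by enforcement implies (i) the
#' enforced curve lies weakly below the voluntary one at every coverage level
#' and (ii) the conformist signal of observed vaccinations is weaker under
#' enforcement, so the enforced curve's maximum slope does not exceed the
#' voluntary curve's. Both conditions are checked on a dense grid at
#' construction and violations are rejected.
#'
#' @param voluntary,enforced `adoption_curve` objects.
#' @param grid_n Number of grid points used for the ordering checks.
#' @return An object of class `regime_curve_pair` with elements `voluntary`
#'   and `enforced`.
#' @examples
#' pair <- regime_curve_pair(
#'   voluntary = make_gaussian_curve(0.2, 1, 0.4, 0.18),
#'   enforced  = make_gaussian_curve(0.15, 0.85, 0.5, 0.22)
#' )
#' @export
regime_curve_pair <- function(voluntary, enforced, grid_n = 1001L) {
  stopifnot(inherits(voluntary, "adoption_curve"),
            inherits(enforced, "adoption_curve"))
  f <- seq(0, 1, length.out = grid_n)
  pv <- adoption_share(voluntary, f)
  pe <- adoption_share(enforced, f)
  if (any(pe > pv + 1e-10)) {
    bad <- f[which.max(pe - pv)]
    stop("regime-ordering: enforced curve exceeds voluntary curve (e.g. at f = ",
         signif(bad, 4), ")", call. = FALSE)
  }
  slope_v <- max(diff(pv) / diff(f))
  slope_e <- max(diff(pe) / diff(f))
  if (slope_e > slope_v + 1e-10) {
    stop("regime-ordering: enforced curve is steeper than voluntary curve ",
         "(max slopes ", signif(slope_e, 4), " > ", signif(slope_v, 4), ")",
         call. = FALSE)
  }
  structure(list(voluntary = voluntary, enforced = enforced),
            class = "regime_curve_pair")
}

#' @export
print.regime_curve_pair <- function(x, ...) {
  cat("<regime_curve_pair>\n  voluntary: ")
  print(x$voluntary)
  cat("  enforced:  ")
  print(x$enforced)
  invisible(x)
}

#' Survey-implied vertical gap between the two adoption curves
#'
#' Converts regime-specific support shares measured in a survey into the
#' implied vertical distance, in percentage points, between the voluntary and
#' enforced adoption curves.
#'
#' @param voluntary_support,enforced_support Support shares in \[0, 1\].
#' @return The gap `100 * (voluntary_support - enforced_support)` in
#'   percentage points. Negative gaps are returned as-is with a warning.
#' @examples
#' gap_from_survey_shares(2 / 3, 0.42) # about 25 points
#' @export
gap_from_survey_shares <- function(voluntary_support, enforced_support) {
  stopifnot(is.numeric(voluntary_support), is.numeric(enforced_support),
            voluntary_support >= 0, voluntary_support <= 1,
            enforced_support >= 0, enforced_support <= 1)
  gap <- 100 * (voluntary_support - enforced_support)
  if (any(gap < 0)) {
    warning("negative gap: enforced support exceeds voluntary support")
  }
  gap
}
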