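#' Locate and classify the equilibria of an adoption curve
#'
#' Coverage dynamics under a purely voluntary regime follow the ratchet map
#' `f -> max(f, p(f))`, whose rest points are the solutions of `p(f) = f`,
#' i.e. the intersections of the adoption curve with the 45-degree line.
#' Roots are located by a sign-change scan of `p(f) - f` over a dense grid
#' followed by bisection, and classified by the direction in which the curve
#' crosses the line:
#' * `tipping` - the curve crosses from below to above (local slope > 1);
#'   coverage just above such a point grows on its own, just below it stalls.
#' * `stable_low` / `stable_high` - attracting crossings from above to below;
#'   `stable_high` marks attractors reached only after passing a tipping
#'   point (or full coverage), `stable_low` those reachable from zero.
#' * `boundary` - the point `f = 0` when `p(0) = 0` and the curve leaves the
#'   line from above (a repelling lower boundary).
#'
#' A touching (tangent, non-crossing) intersection is conservatively
#' classified as `tipping`: it is not treated as a safely attracting state.
#'
#' @param curve An [adoption_curve][make_gaussian_curve].
#' @param tol Positive solver tolerance; each returned root satisfies
#'   `|p(f*) - f*| <= tol` and is located to within `tol`.
#' @param grid_n Number of scan-grid points.
#' @return An object of class `equilibrium_set`: a data frame with columns
#'   `f` (the root) and `kind`, sorted ascending in `f`.
#' @examples
#' fixed_points(make_linear_curve(0.1, 0.6)) # single stable point at 0.2
#' fixed_points(make_gaussian_curve(0.05, 0.95, 0.5, 0.08)) # low/tipping/high
#' @export
fixed_points <- function(curve, tol = 1e-8, grid_n = 4097L) {
  stopifnot(inherits(curve, "adoption_curve"), is.numeric(tol), tol > 0)
  f <- seq(0, 1, length.out = grid_n)
  g <- adoption_share(curve, f) - f

  if (mean(abs(g) < tol) > 0.5) {
    stop("degenerate-continuum: |p(f) - f| < tol on more than half the grid ",
         "(identity-like curve has no isolated equilibria)", call. = FALSE)
  }

  gfun <- function(x) adoption_share(curve, x) - x
  roots <- numeric(0)

  # exact zeros on the grid (up to floating noise)
  hit <- which(abs(g) < .Machine$double.eps * 8)
  roots <- c(roots, f[hit])

  # sign changes between adjacent grid points -> bisection
  # bisection refines each bracket essentially to machine precision (the
  # cost is ~50 halvings per root); `tol` governs residual checks and
  # stability classification, not the final bracket width
  sc <- which(g[-grid_n] * g[-1L] < 0)
  for (i in sc) {
    lo <- f[i]; hi <- f[i + 1L]
    glo <- g[i]
    while (hi - lo > 1e-15) {
      mid <- (lo + hi) / 2
      gm <- gfun(mid)
      if (gm == 0) { lo <- mid; hi <- mid; break }
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }

  # tangency: local minima of |g| that dip within tol without a sign change
  small <- which(abs(g) <= tol)
  if (length(small)) {
    for (grp in split(small, cumsum(c(1, diff(small) != 1)))) {
      cand <- f[grp[which.min(abs(g[grp]))]]
      if (!length(roots) || min(abs(roots - cand)) > 2 * tol) {
        roots <- c(roots, cand)
      }
    }
  }

  roots <- sort(roots)
  if (length(roots) > 1) {
    roots <- roots[c(TRUE, diff(roots) > 2 * tol)]
  }

  # endpoint f = 1 counts as an attracting state when p(1) reaches 1
  p1 <- adoption_share(curve, 1)
  if (p1 >= 1 - tol && (!length(roots) || max(roots) < 1 - 2 * tol)) {
    roots <- c(roots, 1)
  }

  kind <- character(length(roots))
  delta <- max(4 * tol, 1e-6)
  n_tip_below <- 0L
  for (k in seq_along(roots)) {
    r <- roots[k]
    gl <- if (r - delta >= 0) gfun(r - delta) else NA_real_
    gr <- if (r + delta <= 1) gfun(r + delta) else NA_real_
    kk <- if (is.na(gl)) {
      # f = 0 root: repelling if the curve leaves above the line
      if (!is.na(gr) && gr > 0) "boundary" else "stable_low"
    } else if (is.na(gr)) {
      "stable_high"
    } else if (gl < -tol && gr > tol) {
      "tipping"
    } else if (gl > tol && gr < -tol) {
      if (n_tip_below > 0L) "stable_high" else "stable_low"
    } else {
      # tangency (no sign change resolved at delta): conservative
      "tipping"
    }
    if (kk == "tipping") n_tip_below <- n_tip_below + 1L
    kind[k] <- kk
  }
  if (length(roots) && roots[length(roots)] >= 1 - tol &&
      kind[length(roots)] != "tipping") {
    kind[length(roots)] <- "stable_high"
  }

  out <- data.frame(f = roots, kind = kind, stringsAsFactors = FALSE)
  structure(out, class = c("equilibrium_set", "data.frame"), tol = tol)
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("<equilibrium_set> ", nrow(x), " point(s), tol = ",
      format(attr(x, "tol")), "\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Rest point of the voluntary ratchet started at f0, from a located
# equilibrium set: f0 itself if the curve is already at/below the line there,
# otherwise the first fixed point above f0 (or 1 if the curve stays above).
rest_point_from <- function(curve, f0, eq = NULL, tol = 1e-8) {
  if (is.null(eq)) eq <- fixed_points(curve, tol = tol)
  if (adoption_share(curve, f0) <= f0 + tol) return(f0)
  above <- eq$f[eq$f > f0 + tol]
  if (length(above)) min(above) else 1
}

#' Classify a policy scenario and measure the enforcement burden
#'
#' A scenario is *optimistic* when voluntary uptake alone, started from zero
#' coverage, reaches the policy target `fT`; otherwise it is *pessimistic*
#' and enforcement is required. Under enforcement the minimal burden is the
#' fraction that must be vaccinated against their preference to push coverage
#' from the enforced curve's low rest point past its tipping point, after
#' which conformism carries uptake to the high equilibrium.
#'
#' @param pair A [regime_curve_pair()].
#' @param target Target coverage `fT` in (0, 1].
#' @param tol Positive solver tolerance.
#' @return An object of class `scenario_report`: a list with
#'   `classification` (`"optimistic"` or `"pessimistic"`), `target`,
#'   `voluntary_limit`, `enforced_limit` (rest points of unaided dynamics
#'   from `f = 0` under each curve) and `enforcement_burden`.
#' @examples
#' pair <- regime_curve_pair(make_gaussian_curve(0.2, 1, 0.4, 0.18),
#'                           make_gaussian_curve(0.15, 0.85, 0.5, 0.22))
#' classify_scenario(pair, target = 0.8)
#' @export
classify_scenario <- function(pair, target, tol = 1e-8) {
  stopifnot(inherits(pair, "regime_curve_pair"),
            is.numeric(target), length(target) == 1L, target > 0, target <= 1)
  vol_limit <- rest_point_from(pair$voluntary, 0, tol = tol)
  enf_eq <- fixed_points(pair$enforced, tol = tol)
  enf_limit <- rest_point_from(pair$enforced, 0, eq = enf_eq, tol = tol)
  burden <- if (enf_limit >= target - tol) {
    0
  } else {
    minimal_enforcement(pair$enforced, target, tol = tol)
  }
  structure(
    list(
      classification = if (vol_limit >= target - tol) "optimistic" else "pessimistic",
      target = target,
      voluntary_limit = vol_limit,
      enforced_limit = enf_limit,
      enforcement_burden = burden
    ),
    class = "scenario_report"
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report> ", x$classification, "\n", sep = "")
  cat(sprintf("  target coverage fT:   %.4f\n", x$target))
  cat(sprintf("  voluntary rest point: %.4f\n", x$voluntary_limit))
  cat(sprintf("  enforced rest point:  %.4f\n", x$enforced_limit))
  cat(sprintf("  enforcement burden:   %.4f\n", x$enforcement_burden))
  invisible(x)
}
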