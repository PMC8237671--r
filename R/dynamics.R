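#' Specify a vaccination policy plan
#'
#' @param regime `"voluntary"` (vaccination recommended, uptake purely
#'   willing) or `"enforced"` (legally required, with state top-up of
#'   unwilling individuals when voluntary uptake stalls below the target).
#' @param target Target coverage `fT` in (0, 1] that the policy maker judges
#'   necessary to end the pandemic. Exogenous to the model.
#' @param capacity Maximum fraction of the population the state can vaccinate
#'   against their preference per period; `1` means a stall is cleared in a
#'   single period (unlimited capacity).
#' @param horizon Maximum number of periods to simulate.
#' @return An object of class `policy_plan`.
#' @export
policy_plan <- function(regime = c("voluntary", "enforced"), target,
                        capacity = 1, horizon = 10000L) {
  regime <- match.arg(regime)
  stopifnot(is.numeric(target), length(target) == 1L, target > 0, target <= 1,
            is.numeric(capacity), capacity >= 0, capacity <= 1,
            horizon >= 1)
  structure(list(regime = regime, target = target, capacity = capacity,
                 horizon = as.integer(horizon)),
            class = "policy_plan")
}

#' One period of willing-first (voluntary) uptake
#'
#' At the start of a period citizens observe last period's coverage `f`; the
#' share `p(f)` then prefers being vaccinated, and every unvaccinated citizen
#' who prefers vaccination receives it. Since vaccination is irreversible the
#' update is the ratchet map `max(f, p(f))`: coverage never falls.
#'
#' @param curve An adoption curve.
#' @param f Current coverage in \[0, 1\].
#' @return New coverage fraction.
#' @export
step_voluntary <- function(curve, f) {
  pmax(f, adoption_share(curve, f))
}

# Coverage level an enforcement campaign should push to, starting from a
# stalled state at `f`: the lowest tipping point from which conformist growth
# alone reaches the target (nudged just past the located root so growth
# actually resumes), or the target itself when no tipping point high enough
# exists. NA when voluntary dynamics from `f` already reach the target.
enforcement_stop <- function(curve, f, target, tol = 1e-8, eq = NULL) {
  if (is.null(eq)) eq <- fixed_points(curve, tol = tol)
  if (rest_point_from(curve, f, eq = eq, tol = tol) >= target - tol) {
    return(NA_real_)
  }
  tips <- eq$f[eq$kind == "tipping" & eq$f >= f - tol]
  for (t in sort(tips)) {
    above <- eq$f[eq$f > t + tol]
    basin_top <- if (length(above)) min(above) else 1
    if (basin_top >= target - tol) {
      cand <- t
      it <- 0L
      while (adoption_share(curve, cand) <= cand && cand < 1 && it < 64L) {
        cand <- cand + tol / 4
        it <- it + 1L
      }
      return(min(cand, target))
    }
  }
  target
}

#' One period under an enforced vaccination policy
#'
#' Willing citizens are vaccinated first (the ratchet step). Only when the
#' resulting coverage is a rest point of the voluntary dynamics
#' (`p(f') <= f'`) and still below the target does the state vaccinate
#' unwilling citizens, up to `capacity` per period and never beyond what is
#' needed: enforcement stops once coverage passes the tipping point from
#' which conformist growth reaches the target on its own (or at the target
#' when no such tipping point exists).
#'
#' @param curve The enforced-regime adoption curve.
#' @param f Current coverage.
#' @param plan A [policy_plan()] with `regime = "enforced"`.
#' @param tol Solver tolerance.
#' @return A list with `f` (new coverage) and `enforced_added` (fraction
#'   vaccinated against their preference this period).
#' @export
step_enforced <- function(curve, f, plan, tol = 1e-8) {
  stopifnot(inherits(plan, "policy_plan"), plan$regime == "enforced")
  f1 <- max(f, adoption_share(curve, f))
  stalled <- f1 < plan$target - tol && adoption_share(curve, f1) <= f1 + tol
  res <- enforce_topup(curve, f1, plan$target, plan$capacity, tol = tol,
                       stalled = stalled)
  list(f = res$f, enforced_added = res$add)
}

# Capacity-limited top-up from a stalled state. Doses administered between
# the current coverage and the willing rest point are taken up willingly
# (the stall trigger fires within tol of the rest point, slightly below
# it), so only the mass beyond the rest point counts as enforced.
enforce_topup <- function(curve, f1, target, capacity, tol, eq = NULL,
                          stalled = TRUE) {
  if (!stalled) return(list(f = f1, add = 0))
  if (is.null(eq)) eq <- fixed_points(curve, tol = tol)
  stop_at <- enforcement_stop(curve, f1, target, tol = tol, eq = eq)
  if (is.na(stop_at) || stop_at <= f1) return(list(f = f1, add = 0))
  f2 <- min(f1 + capacity, stop_at, 1)
  willing_base <- if (adoption_share(curve, f1) > f1) {
    above <- eq$f[eq$f > f1]
    if (length(above)) min(above) else 1
  } else {
    f1
  }
  add <- f2 - min(max(f1, willing_base), f2)
  list(f = f2, add = add)
}

#' Simulate the coverage trajectory under a policy plan
#'
#' Iterates the period map of the chosen regime from initial coverage `f0`
#' for at most `plan$horizon` periods. Each step records the preference share
#' formed from last period's coverage, the regret share
#' `max(0, f_t - p(f_t))` (vaccinated individuals who prefer not to have
#' been), and any enforced top-up. The run converges when coverage changes by
#' less than `tol` with no enforcement in that period.
#'
#' @param curve_pair A [regime_curve_pair()].
#' @param plan A [policy_plan()].
#' @param f0 Initial coverage in \[0, 1\].
#' @param tol Convergence tolerance.
#' @return An `uptake_trajectory`: a data frame with columns `t`, `f`,
#'   `pref`, `regret`, `enforced_added` and attributes `converged`,
#'   `rest_point`, `target_reached` and `regime`.
#' @examples
#' pair <- regime_curve_pair(make_gaussian_curve(0.2, 1, 0.4, 0.18),
#'                           make_gaussian_curve(0.15, 0.85, 0.5, 0.22))
#' tr <- simulate_uptake(pair, policy_plan("voluntary", target = 0.8), f0 = 0)
#' attr(tr, "rest_point")
#' @export
simulate_uptake <- function(curve_pair, plan, f0 = 0, tol = 1e-9) {
  stopifnot(inherits(curve_pair, "regime_curve_pair"),
            inherits(plan, "policy_plan"),
            is.numeric(f0), f0 >= 0, f0 <= 1, tol > 0)
  curve <- if (plan$regime == "voluntary") curve_pair$voluntary else curve_pair$enforced
  eq <- if (plan$regime == "enforced") fixed_points(curve, tol = max(tol, 1e-10))

  n <- plan$horizon + 1L
  t_ <- integer(n); fv <- pref <- regret <- added <- numeric(n)
  t_[1L] <- 0L; fv[1L] <- f0; pref[1L] <- NA_real_
  regret[1L] <- max(0, f0 - adoption_share(curve, f0)); added[1L] <- 0
  converged <- FALSE
  f <- f0
  k <- 1L
  # prev_grow tracks last period's willing (un-enforced) growth: declaring
  # convergence additionally requires the growth to be non-increasing, so a
  # state just past a tipping point - where growth is still tiny but
  # compounding - is not mistaken for a rest point
  prev_grow <- Inf
  for (step in seq_len(plan$horizon)) {
    p_prev <- adoption_share(curve, f)
    grow <- max(f, p_prev) - f
    if (plan$regime == "voluntary") {
      f_new <- max(f, p_prev)
      add <- 0
    } else {
      f1 <- max(f, p_prev)
      # stalled only on the attracting side (non-increasing growth): a state
      # freshly nudged past a tipping point grows slower than tol at first
      # but is escaping, not stalled
      stalled <- f1 < plan$target - tol &&
        adoption_share(curve, f1) <= f1 + tol && grow <= prev_grow
      res <- enforce_topup(curve, f1, plan$target, plan$capacity, tol = tol,
                           eq = eq, stalled = stalled)
      f_new <- res$f
      add <- res$add
    }
    k <- k + 1L
    t_[k] <- step; fv[k] <- f_new; pref[k] <- p_prev
    regret[k] <- max(0, f_new - adoption_share(curve, f_new))
    added[k] <- add
    done <- abs(f_new - f) < tol && add == 0 && grow <= prev_grow
    prev_grow <- if (add > 0) 0 else grow
    f <- f_new
    if (done) { converged <- TRUE; break }
  }
  out <- data.frame(t = t_[1:k], f = fv[1:k], pref = pref[1:k],
                    regret = regret[1:k], enforced_added = added[1:k])
  if (!converged) {
    warning("horizon-exhausted: trajectory did not converge within ",
            plan$horizon, " periods")
  }
  structure(out,
            class = c("uptake_trajectory", "data.frame"),
            converged = converged,
            rest_point = f,
            target_reached = f >= plan$target - tol,
            regime = plan$regime)
}

#' @export
print.uptake_trajectory <- function(x, ...) {
  cat(sprintf("<uptake_trajectory> regime=%s, %d period(s), rest point %.6f%s\n",
              attr(x, "regime"), nrow(x) - 1L, attr(x, "rest_point"),
              if (attr(x, "converged")) "" else " (horizon exhausted)"))
  df <- as.data.frame(x)
  if (nrow(df) > 12L) {
    print(utils::head(df, 6L), row.names = FALSE)
    cat("  ...\n")
    print(utils::tail(df, 3L), row.names = FALSE)
  } else {
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Minimal enforced fraction needed to reach a coverage target
#'
#' The fraction of the population that must be vaccinated despite preferring
#' not to be, in order to move coverage from the curve's low rest point (from
#' `f = 0`) past the lowest tipping point whose basin reaches the target.
#' Returns 0 when voluntary dynamics alone reach the target, and
#' `target - rest point` when no tipping point high enough exists (every
#' additional dose up to the target must then be enforced).
#'
#' @param curve The enforced-regime adoption curve.
#' @param target Target coverage in (0, 1].
#' @param tol Solver tolerance.
#' @return Fraction in \[0, 1\].
#' @export
minimal_enforcement <- function(curve, target, tol = 1e-8) {
  stopifnot(is.numeric(target), length(target) == 1L, target > 0, target <= 1)
  eq <- fixed_points(curve, tol = tol)
  r <- rest_point_from(curve, 0, eq = eq, tol = tol)
  if (r >= target - tol) return(0)
  tips <- sort(eq$f[eq$kind == "tipping" & eq$f >= r - tol])
  for (t in tips) {
    above <- eq$f[eq$f > t + tol]
    basin_top <- if (length(above)) min(above) else 1
    if (basin_top >= target - tol) return(t - r)
  }
  target - r
}
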