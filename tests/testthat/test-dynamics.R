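test_that("voluntary step is the ratchet max(f, p(f))", {
  lin <- make_linear_curve(0.1, 0.6)
  expect_equal(step_voluntary(lin, 0), 0.1)
  expect_equal(step_voluntary(lin, 0.2), 0.2) # fixed point stays put
  expect_equal(step_voluntary(lin, 0.9), 0.9) # above the curve: unchanged
})

test_that("enforced step tops up by capacity only at stalled states", {
  cv <- make_gaussian_curve(0.05, 0.95, 0.5, 0.08)
  eq <- fixed_points(cv)
  rest <- eq$f[eq$kind == "stable_low"]
  tip <- eq$f[eq$kind == "tipping"]
  plan <- policy_plan("enforced", target = 0.9, capacity = 0.05)
  st <- step_enforced(cv, rest, plan)
  expect_equal(st$enforced_added, 0.05, tolerance = 1e-12)
  expect_equal(st$f, rest + 0.05, tolerance = 1e-12)
  # just above the tipping point conformist growth resumes unaided
  st2 <- step_enforced(cv, tip + 0.01, plan)
  expect_identical(st2$enforced_added, 0)
  expect_gt(st2$f, tip + 0.01)
})

test_that("zero capacity freezes coverage below the target", {
  cv <- make_gaussian_curve(0.05, 0.95, 0.5, 0.08)
  pair <- regime_curve_pair(make_gaussian_curve(0.1, 1, 0.5, 0.07), cv)
  tr <- simulate_uptake(pair, policy_plan("enforced", 0.9, capacity = 0),
                        f0 = 0, tol = 1e-8)
  expect_true(attr(tr, "converged"))
  expect_false(attr(tr, "target_reached"))
  expect_equal(attr(tr, "rest_point"),
               fixed_points(cv)$f[1], tolerance = 1e-7)
})

test_that("simulate reproduces the textbook trajectories", {
  pair <- demo_pair()
  # optimistic voluntary dynamics run to full coverage
  tr <- simulate_uptake(pair, policy_plan("voluntary", 0.8), f0 = 0)
  expect_equal(attr(tr, "rest_point"), 1, tolerance = 1e-6)
  # full coverage is absorbing: immediate convergence
  tr1 <- simulate_uptake(pair, policy_plan("voluntary", 0.8), f0 = 1)
  expect_true(attr(tr1, "converged"))
  expect_equal(attr(tr1, "rest_point"), 1)
  expect_lte(nrow(tr1), 2L)
  # enforced with unlimited capacity: total top-up equals tipping - rest
  cv <- make_gaussian_curve(0.05, 0.95, 0.5, 0.08)
  pr <- regime_curve_pair(make_gaussian_curve(0.1, 1, 0.5, 0.07), cv)
  oracle <- brute_fixed_points(cv)
  tre <- simulate_uptake(pr, policy_plan("enforced", 0.9, capacity = 1),
                         f0 = 0, tol = 1e-8)
  expect_equal(sum(tre$enforced_added), oracle[2] - oracle[1],
               tolerance = 1e-5)
  expect_gte(attr(tre, "rest_point"), 0.9 - 1e-8)
})

test_that("trajectories are monotone and voluntary runs have zero regret", {
  set.seed(909)
  for (i in 1:20) {
    cv <- random_gaussian_curve()
    shift <- min(0.05, 1 - cv$p1)
    pair <- regime_curve_pair(
      make_gaussian_curve(cv$p0 + shift, cv$p1 + shift, cv$mu, cv$sigma), cv)
    for (regime in c("voluntary", "enforced")) {
      plan <- policy_plan(regime, target = stats::runif(1, 0.5, 0.95),
                          capacity = stats::runif(1))
      tr <- simulate_uptake(pair, plan, f0 = 0, tol = 1e-8)
      expect_true(all(diff(tr$f) >= -1e-12))
      expect_true(all(tr$f <= 1 + 1e-12))
      if (regime == "voluntary") expect_true(all(tr$regret == 0))
    }
  }
})

test_that("linear-curve dynamics converge to p0 / (1 - s)", {
  set.seed(313)
  for (i in 1:10) {
    p0 <- stats::runif(1, 0.05, 0.3)
    s <- stats::runif(1, 0.1, 0.85)
    pair <- regime_curve_pair(make_linear_curve(p0, p0 + s),
                              make_linear_curve(p0 / 2, p0 / 2 + s * 0.9))
    tr <- simulate_uptake(pair, policy_plan("voluntary", 0.99), f0 = 0,
                          tol = 1e-10)
    expect_equal(attr(tr, "rest_point"), p0 / (1 - s), tolerance = 1e-8)
  }
})

test_that("willing-first stepping never ends below enforcement-first stepping", {
  # alternative ordering: enforce at a stalled state first, then let the
  # willing present themselves within the same period
  enforcement_first_final <- function(curve, plan, tol = 1e-8) {
    f <- 0
    for (k in 1:10000) {
      f1 <- f
      if (f1 < plan$target - tol &&
          adoption_share(curve, f1) <= f1 + tol) {
        f1 <- min(f1 + plan$capacity, plan$target, 1)
      }
      f_new <- max(f1, adoption_share(curve, f1))
      if (abs(f_new - f) < tol) return(f_new)
      f <- f_new
    }
    f
  }
  set.seed(606)
  for (i in 1:50) {
    cv <- random_gaussian_curve()
    shift <- min(0.05, 1 - cv$p1)
    pair <- regime_curve_pair(
      make_gaussian_curve(cv$p0 + shift, cv$p1 + shift, cv$mu, cv$sigma),
      cv)
    plan <- policy_plan("enforced", target = stats::runif(1, 0.6, 0.95),
                        capacity = stats::runif(1, 0.02, 1))
    tr <- simulate_uptake(pair, plan, f0 = 0, tol = 1e-8)
    alt <- enforcement_first_final(cv, plan)
    expect_gte(attr(tr, "rest_point"), alt - 1e-6)
  }
})

test_that("minimal enforcement follows the rest-point / tipping arithmetic", {
  # rest point above target: nothing to enforce
  cv_easy <- make_gaussian_curve(0.1, 0.9, 0.35, 0.2) # rest ~0.9
  expect_identical(minimal_enforcement(cv_easy, 0.8), 0)
  # three-fixed-point curve: tipping - low rest, against the brute oracle
  cv <- make_gaussian_curve(0.05, 0.95, 0.5, 0.08)
  oracle <- brute_fixed_points(cv)
  expect_equal(minimal_enforcement(cv, 0.85), oracle[2] - oracle[1],
               tolerance = 1e-5)
  # single stable point below target, no tipping: target - rest point
  lin <- make_linear_curve(0.2, 0.7) # rest 0.2 / (1 - 0.5) = 0.4
  expect_equal(minimal_enforcement(lin, 0.7), 0.3, tolerance = 1e-8)
})
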