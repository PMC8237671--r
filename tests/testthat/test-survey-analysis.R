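test_that("likert_summary reproduces hand-tabulated cumulative shares", {
  # wave-1 enforced counts per 100: level4 44, level3 12, level2 15,
  # level1 6, level0 23 -> cumulative 0.44 / 0.56 / 0.71 / 0.77
  counts <- c(`4` = 44, `3` = 12, `2` = 15, `1` = 6, `0` = 23)
  levels1 <- rep(as.integer(names(counts)), counts)
  # hand-summation oracle
  oracle_ge <- vapply(4:1, function(k) sum(counts[as.integer(names(counts)) >= k]) / 100,
                      numeric(1))
  p <- toy_panel(w1 = levels1, w2 = levels1)
  ls_ <- likert_summary(p, "enforced")
  expect_equal(unlist(ls_[1, c("ge4", "ge3", "ge2", "ge1")],
                      use.names = FALSE),
               oracle_ge)
  expect_equal(oracle_ge, c(0.44, 0.56, 0.71, 0.77))
  # opposition (levels 0-1) is the complement of the >=2 share
  expect_equal(1 - ls_$ge2[1], 0.29)
  # constant data: exact mean, degenerate CI
  pc <- toy_panel(w1 = rep(4L, 10), w2 = rep(4L, 10))
  lc <- likert_summary(pc, "enforced")
  expect_equal(lc$mean, c(4, 4))
  expect_equal(lc$ci_lo, lc$ci_hi)
  expect_equal(lc$ge4, c(1, 1))
})

test_that("likert_summary cumulative shares are coherent", {
  p <- generate_panel(panel_config(n = 2000, seed = 17))
  for (item in c("voluntary", "enforced")) {
    ls_ <- likert_summary(p, item)
    for (i in seq_len(nrow(ls_))) {
      shares <- unlist(ls_[i, c("ge4", "ge3", "ge2", "ge1")])
      expect_true(all(diff(shares) >= 0))
      expect_lte(shares[4], 1)
      expect_gte(ls_$mean[i], ls_$ci_lo[i])
      expect_lte(ls_$mean[i], ls_$ci_hi[i])
    }
  }
})

test_that("transition shares match direct enumeration of a toy panel", {
  # wave1 -> wave2 enforced levels: 4->2, 3->3, 0->4, 1->1, 4->4
  p <- toy_panel(w1 = c(4, 3, 0, 1, 4), w2 = c(2, 3, 4, 1, 4))
  ts_ <- transition_stats(p, "enforced")
  expect_equal(ts_$share_withdrew_among_prior_supporters, 1 / 3)
  expect_equal(ts_$share_became_supporters_among_prior_nonsupporters, 1 / 2)
  expect_equal(ts_$share_reduced_any, 1 / 5)
  expect_equal(ts_$share_increased_any, 1 / 5)
  expect_equal(unname(ts_$share_level0), c(1 / 5, 0))

  # identical waves: no transitions
  p2 <- toy_panel(w1 = c(4, 2, 0), w2 = c(4, 2, 0))
  ts2 <- transition_stats(p2, "enforced")
  expect_equal(ts2$share_reduced_any, 0)
  expect_equal(ts2$share_increased_any, 0)
  expect_equal(ts2$share_withdrew_among_prior_supporters, 0)

  # everyone collapses from full support to none
  p3 <- toy_panel(w1 = rep(4L, 4), w2 = rep(0L, 4))
  ts3 <- transition_stats(p3, "enforced")
  expect_equal(ts3$share_withdrew_among_prior_supporters, 1)
  expect_equal(ts3$share_reduced_any, 1)
})

test_that("transition_stats demands both waves for every respondent", {
  p <- toy_panel(w1 = c(4, 3), w2 = c(4, 3))
  expect_error(transition_stats(p[p$wave == 1 | p$id == 1, ], "enforced"),
               "unmatched-respondent")
})

test_that("standardized OLS recovers exact linear structure", {
  set.seed(33)
  n <- 400
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n); x3 <- stats::rnorm(n)
  p <- rbind(
    data.frame(id = 1:n, wave = 1, agree_voluntary = 0, agree_enforced = 0,
               trust = x1, altruism = x2, female = x3,
               east = stats::rnorm(n), pandemic_critical = stats::rnorm(n),
               effectiveness = NA_real_, freedom = NA_real_),
    data.frame(id = 1:n, wave = 2, agree_voluntary = 0, agree_enforced = x1,
               trust = x1, altruism = x2, female = x3,
               east = stats::rnorm(n), pandemic_critical = stats::rnorm(n),
               effectiveness = 0, freedom = 0)
  )
  fit <- standardized_ols(p, "enforced", predictors =
                            c("trust", "altruism", "female"))
  expect_equal(coef_row(fit, "trust")$estimate, 1, tolerance = 1e-9)
  expect_lt(abs(coef_row(fit, "altruism")$estimate), 1e-9)
  expect_lt(abs(coef_row(fit, "female")$estimate), 1e-9)
  expect_true(all(fit$coefficients$ci_lo <= fit$coefficients$estimate &
                    fit$coefficients$estimate <= fit$coefficients$ci_hi))
})

test_that("zero-variance and collinear predictors raise named rank errors", {
  p <- generate_panel(panel_config(n = 200, seed = 9))
  p$constant_var <- 1
  expect_error(standardized_ols(p, "enforced",
                                predictors = c("trust", "constant_var")),
               "rank-deficiency.*constant_var")
  p$trust_copy <- p$trust
  expect_error(standardized_ols(p, "enforced",
                                predictors = c("trust", "trust_copy")),
               "rank-deficiency")
})

test_that("insufficient complete cases raise an error", {
  p <- generate_panel(panel_config(n = 3, seed = 4))
  expect_error(standardized_ols(p, "enforced", model_id = "B"),
               "insufficient-n")
})

test_that("standardization is idempotent", {
  p <- generate_panel(panel_config(n = 3000, seed = 14))
  w2 <- p$wave == 2
  fit1 <- standardized_ols(p, "enforced", model_id = "A")
  q <- p
  for (nm in c("agree_enforced", "trust", "altruism", "female", "east",
               "pandemic_critical")) {
    x <- q[[nm]][w2]
    q[[nm]][w2] <- (x - mean(x)) / stats::sd(x)
  }
  fit2 <- standardized_ols(q, "enforced", model_id = "A")
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-12)
})

test_that("change regression is exact on a deterministic linear link", {
  set.seed(55)
  n <- 200
  t1 <- stats::rnorm(n, 4, 0.5); t2 <- stats::rnorm(n, 4, 0.5)
  a1 <- rep(2, n); a2 <- 2 + 0.5 * (t2 - t1)
  p <- toy_panel(w1 = a1, w2 = a2, trust1 = t1, trust2 = t2)
  fit <- change_regression(p, "enforced")
  expect_equal(coef_row(fit, "d_trust")$estimate, 1, tolerance = 1e-9)
  # constant trust change: no variance to identify the coefficient
  p2 <- toy_panel(w1 = a1, w2 = a1, trust1 = t1, trust2 = t1 + 0.3)
  expect_error(change_regression(p2, "enforced"), "rank-deficiency")
})

test_that("panel change effect is materially smaller than the cross-section effect", {
  p <- generate_panel(panel_config(n = 50000, seed = 66))
  cs <- coef_row(standardized_ols(p, "enforced", model_id = "A"), "trust")$estimate
  ch <- coef_row(change_regression(p, "enforced"), "d_trust")$estimate
  expect_gt(ch, 0)
  expect_lt(ch, cs / 3 * 1.5) # well below the cross-section association
  expect_lt(ch, cs)
})

test_that("trust attribution is the stated ratio with guarded edge cases", {
  expect_equal(trust_attribution(0.1, 1, -0.27), 0.1 / 0.27)
  expect_equal(round(trust_attribution(0.1, 1, -0.27), 3), 0.370)
  expect_equal(trust_attribution(0.2, 0, -0.1), 0)
  expect_error(trust_attribution(0.1, 1, 0), "division-by-zero")
})

test_that("attribution from the default panel matches the generator-based oracle", {
  p <- generate_panel(panel_config(n = 200000, seed = 31),
                      keep_latent = TRUE)
  rs <- raw_trust_slope(p, "enforced")
  att <- trust_attribution(rs$beta_raw, 1, rs$mean_change)
  # independent recomputation from the planted quantities: slope of the
  # between-wave change in the Likert response on the change in the trust
  # composite, via direct moment arithmetic on the latent draw
  w1 <- p[p$wave == 1, ]; w2 <- p[p$wave == 2, ]
  dL <- w2$agree_enforced - w1$agree_enforced
  dT <- w2$trust - w1$trust
  beta_oracle <- sum((dT - mean(dT)) * (dL - mean(dL))) /
    sum((dT - mean(dT))^2)
  att_oracle <- beta_oracle * 1 / abs(mean(dL))
  expect_equal(att, att_oracle, tolerance = 0.1)
})

test_that("coefficient bias for the planted trust effect shrinks with n", {
  # population change-model coefficient from one large oracle draw:
  # the standardized single-predictor coefficient is the correlation
  big <- generate_panel(panel_config(n = 500000, seed = 1234))
  b1 <- big[big$wave == 1, ]; b2 <- big[big$wave == 2, ]
  truth <- stats::cor(b2$agree_enforced - b1$agree_enforced,
                      b2$trust - b1$trust)
  bias_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      p <- generate_panel(panel_config(n = n, seed = s))
      abs(coef_row(change_regression(p, "enforced"), "d_trust")$estimate -
            truth)
    }, numeric(1)))
  }
  b_small <- bias_at(2000, 101:104)
  b_mid <- bias_at(20000, 101:104)
  b_big <- bias_at(200000, 101:102)
  expect_gt(b_small, b_mid)
  expect_gt(b_mid, b_big)
})

test_that("heteroskedasticity-robust errors are available and close to classical", {
  p <- generate_panel(panel_config(n = 5000, seed = 12))
  f1 <- standardized_ols(p, "enforced", model_id = "A")
  f2 <- standardized_ols(p, "enforced", model_id = "A", robust = TRUE)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate)
  expect_false(identical(f1$coefficients$se, f2$coefficients$se))
  expect_equal(f1$coefficients$se, f2$coefficients$se, tolerance = 0.2)
})
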