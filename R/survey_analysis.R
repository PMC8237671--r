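item_column <- function(item = c("voluntary", "enforced")) {
  paste0("agree_", match.arg(item, c("voluntary", "enforced")))
}

check_panel <- function(panel) {
  need <- c("id", "wave", "agree_voluntary", "agree_enforced")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("panel lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(panel)
}

#' Per-wave Likert summary of an agreement item
#'
#' Mean agreement (in Likert units, 0-4) with a normal-approximation 95%
#' confidence interval and the cumulative distribution (share of respondents
#' at level >= k for k = 4, 3, 2, 1) per survey wave.
#'
#' @param panel A panel data frame (see [generate_panel()] for the schema).
#' @param item `"voluntary"` or `"enforced"`.
#' @return A `likert_summary`: a data frame with one row per wave and columns
#'   `wave`, `n`, `mean`, `ci_lo`, `ci_hi`, `ge4`, `ge3`, `ge2`, `ge1`.
#' @export
likert_summary <- function(panel, item = c("voluntary", "enforced")) {
  check_panel(panel)
  col <- item_column(item)
  waves <- sort(unique(panel$wave))
  rows <- lapply(waves, function(w) {
    x <- panel[[col]][panel$wave == w]
    x <- x[!is.na(x)]
    if (!length(x)) stop("empty-wave: no responses in wave ", w, call. = FALSE)
    m <- mean(x)
    half <- stats::qnorm(0.975) * stats::sd(x) / sqrt(length(x))
    if (is.na(half)) half <- 0 # single respondent
    data.frame(wave = w, n = length(x), mean = m,
               ci_lo = m - half, ci_hi = m + half,
               ge4 = mean(x >= 4), ge3 = mean(x >= 3),
               ge2 = mean(x >= 2), ge1 = mean(x >= 1))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("likert_summary", "data.frame"),
            item = match.arg(item))
}

#' @export
print.likert_summary <- function(x, ...) {
  cat("<likert_summary> item:", attr(x, "item"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Between-wave transition shares for an agreement item
#'
#' Classifies respondents as supporters (Likert level 3 or 4, "agreed fully
#' or mostly") or non-supporters in each wave and computes:
#' the share of wave-1 supporters who withdrew support (moved below level 3),
#' the share of wave-1 non-supporters who became supporters, the shares who
#' reduced or increased their agreement level at all, and the share at level
#' 0 ("not agree at all") per wave.
#'
#' @inheritParams likert_summary
#' @return A list of class `transition_stats`.
#' @export
transition_stats <- function(panel, item = c("voluntary", "enforced")) {
  check_panel(panel)
  col <- item_column(item)
  w1 <- panel[panel$wave == 1, c("id", col)]
  w2 <- panel[panel$wave == 2, c("id", col)]
  if (!setequal(w1$id, w2$id) || anyDuplicated(w1$id) || anyDuplicated(w2$id)) {
    stop("unmatched-respondent: every respondent must appear exactly once ",
         "in each wave", call. = FALSE)
  }
  m <- merge(w1, w2, by = "id", suffixes = c(".1", ".2"))
  a1 <- m[[paste0(col, ".1")]]
  a2 <- m[[paste0(col, ".2")]]
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]; a2 <- a2[keep]
  sup1 <- a1 >= 3
  structure(list(
    share_withdrew_among_prior_supporters =
      if (any(sup1)) mean(a2[sup1] < 3) else NA_real_,
    share_became_supporters_among_prior_nonsupporters =
      if (any(!sup1)) mean(a2[!sup1] >= 3) else NA_real_,
    share_reduced_any = mean(a2 < a1),
    share_increased_any = mean(a2 > a1),
    share_level0 = c(wave1 = mean(a1 == 0), wave2 = mean(a2 == 0)),
    n = length(a1)
  ), class = "transition_stats", item = match.arg(item))
}

#' @export
print.transition_stats <- function(x, ...) {
  cat("<transition_stats> item:", attr(x, "item"), "(n =", x$n, ")\n")
  cat(sprintf("  withdrew among prior supporters:  %.3f\n",
              x$share_withdrew_among_prior_supporters))
  cat(sprintf("  became supporters (prior non):    %.3f\n",
              x$share_became_supporters_among_prior_nonsupporters))
  cat(sprintf("  reduced any / increased any:      %.3f / %.3f\n",
              x$share_reduced_any, x$share_increased_any))
  cat(sprintf("  level 0 share wave1 / wave2:      %.3f / %.3f\n",
              x$share_level0[["wave1"]], x$share_level0[["wave2"]]))
  invisible(x)
}

# z-score a numeric vector on the estimation sample; zero-variance columns
# are reported by name as a rank-deficiency error.
zscore_matrix <- function(df) {
  for (nm in names(df)) {
    x <- df[[nm]]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      stop("rank-deficiency: variable '", nm, "' has zero variance ",
           "on the estimation sample", call. = FALSE)
    }
    df[[nm]] <- (x - mean(x)) / s
  }
  df
}

fit_standardized <- function(df, outcome_name, model_id, robust = FALSE) {
  df <- zscore_matrix(df)
  X <- as.matrix(cbind(`(Intercept)` = 1, df[, setdiff(names(df), ".y"),
                                             drop = FALSE]))
  y <- df$.y
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficiency: collinear predictor(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  if (robust) {
    # HC1 sandwich
    meat <- crossprod(X * as.numeric(res))
    vc <- XtXinv %*% meat %*% XtXinv * n / (n - p)
  } else {
    vc <- s2 * XtXinv
  }
  se <- sqrt(diag(vc))
  zc <- stats::qt(0.975, df = n - p)
  keep <- colnames(X) != "(Intercept)"
  coefs <- data.frame(
    term = colnames(X)[keep],
    estimate = beta[keep],
    se = se[keep],
    ci_lo = beta[keep] - zc * se[keep],
    ci_hi = beta[keep] + zc * se[keep],
    row.names = NULL
  )
  structure(list(outcome = outcome_name, model_id = model_id, n = n,
                 coefficients = coefs, robust = robust),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> model ", x$model_id, ": standardized OLS of ",
      x$outcome, " (n = ", x$n, ")\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Extract one coefficient from a regression result
#'
#' @param result A `regression_result`.
#' @param term Predictor name.
#' @return One-row data frame with `estimate`, `se`, `ci_lo`, `ci_hi`.
#' @export
coef_row <- function(result, term) {
  stopifnot(inherits(result, "regression_result"))
  row <- result$coefficients[result$coefficients$term == term, ]
  if (!nrow(row)) stop("no such term: ", term, call. = FALSE)
  row
}

#' Standardized cross-section OLS of vaccination agreement
#'
#' Regresses an agreement item, observed in one wave, on a set of respondent
#' covariates. Outcome and predictors are z-scored on the estimation sample
#' (after list-wise exclusion of incomplete cases), so coefficients are in
#' SD units. Confidence intervals use the classical homoskedastic covariance
#' by default; `robust = TRUE` switches to an HC1 sandwich estimator.
#'
#' The default predictor sets mirror the two cross-section models of the
#' analysis: model `"A"` uses trust, altruism, gender, East German origin and
#' perceived pandemic severity; model `"B"` is identical except that the
#' wave-2 vaccine-effectiveness and freedom-restriction measures are added.
#'
#' @param panel Panel data frame.
#' @param item `"voluntary"` or `"enforced"` (the outcome item).
#' @param wave Wave whose responses form the outcome (and time-varying
#'   predictors), default 2.
#' @param predictors Character vector of predictor column names; `NULL`
#'   selects the default set for `model_id`.
#' @param model_id `"A"` or `"B"` (or any label for custom predictor sets).
#' @param robust Use heteroskedasticity-robust (HC1) standard errors.
#' @return A `regression_result`.
#' @export
standardized_ols <- function(panel, item = c("voluntary", "enforced"),
                             wave = 2L, predictors = NULL, model_id = "A",
                             robust = FALSE) {
  check_panel(panel)
  col <- item_column(item)
  if (is.null(predictors)) {
    predictors <- c("trust", "altruism", "female", "east", "pandemic_critical")
    if (identical(model_id, "B")) {
      predictors <- c(predictors, "effectiveness", "freedom")
    }
  }
  dat <- panel[panel$wave == wave, c(col, predictors)]
  names(dat)[1L] <- ".y"
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(predictors) + 2L) {
    stop("insufficient-n: ", nrow(dat), " complete cases for ",
         length(predictors), " predictors", call. = FALSE)
  }
  fit_standardized(dat, outcome_name = paste0(col, "@wave", wave),
                   model_id = model_id, robust = robust)
}

#' First-difference (change) regression between the two waves
#'
#' Regresses the standardized within-person change in agreement (wave 2
#' minus wave 1) on the standardized within-person change in public trust,
#' plus any configured controls. Differencing removes all time-invariant
#' individual characteristics, so - unlike the cross-section models - the
#' trust coefficient is not confounded by stable traits.
#'
#' @param panel Panel data frame with both waves for every respondent.
#' @param item `"voluntary"` or `"enforced"`.
#' @param controls Character vector of additional *time-invariant* columns to
#'   include in levels (default none).
#' @param robust Use HC1 standard errors.
#' @return A `regression_result` with `model_id = "C"`; the trust-change
#'   coefficient is named `d_trust`.
#' @export
change_regression <- function(panel, item = c("voluntary", "enforced"),
                              controls = character(), robust = FALSE) {
  check_panel(panel)
  col <- item_column(item)
  keep <- c("id", col, "trust", controls)
  w1 <- panel[panel$wave == 1, keep]
  w2 <- panel[panel$wave == 2, keep]
  if (!setequal(w1$id, w2$id) || anyDuplicated(w1$id) || anyDuplicated(w2$id)) {
    stop("unmatched-respondent: both waves required per respondent",
         call. = FALSE)
  }
  m <- merge(w1, w2, by = "id", suffixes = c(".1", ".2"))
  dat <- data.frame(
    .y = m[[paste0(col, ".2")]] - m[[paste0(col, ".1")]],
    d_trust = m$trust.2 - m$trust.1
  )
  for (cc in controls) dat[[cc]] <- m[[paste0(cc, ".1")]]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < ncol(dat) + 2L) {
    stop("insufficient-n: too few complete change observations", call. = FALSE)
  }
  fit_standardized(dat, outcome_name = paste0("d_", col), model_id = "C",
                   robust = robust)
}

#' Share of an observed mean change attributable to a trust drop
#'
#' Given an unstandardized trust effect `beta_raw` (Likert units of support
#' per point of the 1-6.6 public-trust composite, from a change regression in
#' raw units), a hypothetical drop in trust, and the observed mean change in
#' support, returns the fraction of the observed reduction that the trust
#' drop would account for: `(beta_raw * trust_drop) / |observed_mean_change|`.
#'
#' @param beta_raw Positive trust effect in Likert units per trust point.
#' @param trust_drop Size of the trust drop in trust points (>= 0).
#' @param observed_mean_change Observed mean change in support (negative for
#'   a reduction), Likert units.
#' @return Attribution fraction (may exceed 1 if the drop over-explains the
#'   change).
#' @examples
#' trust_attribution(0.1, 1, -0.27) # 0.370
#' @export
trust_attribution <- function(beta_raw, trust_drop, observed_mean_change) {
  stopifnot(is.numeric(beta_raw), is.numeric(trust_drop),
            is.numeric(observed_mean_change), beta_raw > 0, trust_drop >= 0)
  if (observed_mean_change == 0) {
    stop("division-by-zero: observed mean change is zero", call. = FALSE)
  }
  (beta_raw * trust_drop) / abs(observed_mean_change)
}

#' Unstandardized change-regression trust effect in raw units
#'
#' Companion to [trust_attribution()]: the slope of the within-person change
#' in agreement (Likert units) on the within-person change in the public
#' trust composite (trust points), estimated by OLS without standardization.
#'
#' @inheritParams change_regression
#' @return Named list with `beta_raw` (Likert units per trust point) and
#'   `mean_change` (observed mean change in the item).
#' @export
raw_trust_slope <- function(panel, item = c("voluntary", "enforced")) {
  check_panel(panel)
  col <- item_column(item)
  w1 <- panel[panel$wave == 1, c("id", col, "trust")]
  w2 <- panel[panel$wave == 2, c("id", col, "trust")]
  m <- merge(w1, w2, by = "id", suffixes = c(".1", ".2"))
  dy <- m[[paste0(col, ".2")]] - m[[paste0(col, ".1")]]
  dt <- m$trust.2 - m$trust.1
  keep <- !is.na(dy) & !is.na(dt)
  dy <- dy[keep]; dt <- dt[keep]
  list(beta_raw = stats::cov(dy, dt) / stats::var(dt),
       mean_change = mean(dy))
}
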