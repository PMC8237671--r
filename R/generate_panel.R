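# RNG discipline: all generator entry points fix the generator kinds and
# restore the caller's RNG state on exit, so the same (config, seed) always
# yields the same panel regardless of session history.
with_panel_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Inverse of the gaussian-threshold adoption curve, viewed as the CDF of the
# conformity threshold: u <= p0 -> 0 (prefers at any coverage), u > p1 ->
# +Inf (never converts), else the truncated-normal quantile on [0, 1].
threshold_from_uniform <- function(u, th) {
  lo <- stats::pnorm((0 - th$mu) / th$sigma)
  hi <- stats::pnorm((1 - th$mu) / th$sigma)
  tau <- rep(Inf, length(u))
  tau[u <= th$p0] <- 0
  mid <- u > th$p0 & u <= th$p1
  if (any(mid)) {
    z <- lo + (u[mid] - th$p0) / (th$p1 - th$p0) * (hi - lo)
    tau[mid] <- th$mu + th$sigma * stats::qnorm(z)
  }
  tau
}

# Draw all latent components and the four continuous support indices.
# Separated from the Likert discretization so the calibration routine can
# reuse the latent draw.
gen_latent <- function(config, n = config$n, seed = config$seed) {
  ef <- config$effects
  with_panel_rng(seed, {
    S  <- stats::rnorm(n)
    H1 <- stats::rnorm(n)
    H2 <- stats::rnorm(n)
    A  <- stats::rnorm(n)
    C  <- stats::rnorm(n)
    Fb <- stats::rbinom(n, 1L, config$p_female)
    Eb <- stats::rbinom(n, 1L, config$p_east)
    Ze <- stats::rnorm(n)
    Zf <- stats::rnorm(n)
    u  <- stats::rnorm(n, sd = config$sigma_u)
    eps <- matrix(stats::rnorm(4L * n, sd = config$sigma_eps), nrow = n)
    u_tau <- stats::runif(n)

    sh <- config$trust_shock
    sd_T <- sqrt(1 + sh$sd^2)
    T1_raw <- S + sh$sd * H1
    T2_raw <- S + sh$mean + sh$sd * H2
    T1 <- T1_raw / sd_T
    T2 <- T2_raw / sd_T

    rho_e <- config$eff_trust_loading
    rho_f <- config$freedom_trust_loading
    Eff  <-  rho_e * S + sqrt(1 - rho_e^2) * Ze
    Free <- -rho_f * S + sqrt(1 - rho_f^2) * Zf

    Fz <- (Fb - config$p_female) / sqrt(config$p_female * (1 - config$p_female))
    Ez <- (Eb - config$p_east) / sqrt(config$p_east * (1 - config$p_east))

    idx <- function(regime, Tw, eps_col) {
      sfx <- paste0("_", regime)
      ef[[paste0("trust", sfx)]] * Tw +
        ef[[paste0("trust_stable", sfx)]] * S +
        ef[[paste0("altruism", sfx)]] * A +
        ef[[paste0("female", sfx)]] * Fz +
        ef[[paste0("east", sfx)]] * Ez +
        ef[[paste0("effectiveness", sfx)]] * Eff +
        ef[[paste0("freedom", sfx)]] * Free +
        ef[[paste0("critical", sfx)]] * C +
        u + eps_col -
        if (regime == "enforced") config$crowding_out_shift else 0
    }

    sc <- config$trust_scale
    trust1 <- pmin(pmax(sc$mean + sc$sd * T1, sc$min), sc$max)
    trust2 <- pmin(pmax(sc$mean + sc$sd * T2, sc$min), sc$max)

    list(
      n = n,
      y = list(
        voluntary = list(wave1 = idx("voluntary", T1, eps[, 1L]),
                         wave2 = idx("voluntary", T2, eps[, 2L])),
        enforced  = list(wave1 = idx("enforced", T1, eps[, 3L]),
                         wave2 = idx("enforced", T2, eps[, 4L]))
      ),
      trust = list(wave1 = trust1, wave2 = trust2),
      altruism = A, female = Fb, east = Eb,
      effectiveness = Eff, freedom = Free, pandemic_critical = C,
      tau_voluntary = threshold_from_uniform(u_tau, config$thresholds$voluntary),
      tau_enforced  = threshold_from_uniform(u_tau, config$thresholds$enforced),
      miss_draw = if (config$missing_rate > 0) {
        matrix(stats::runif(5L * n), nrow = n)
      }
    )
  })
}

likert_cut <- function(y, cutpoints) {
  l <- integer(length(y))
  for (c_k in cutpoints) l <- l + (y >= c_k)
  l
}

#' Generate a synthetic two-wave vaccination-attitude panel
#'
#' Draws a respondent-level panel from the latent-variable process described
#' in [panel_config()]: each respondent appears in both waves and answers
#' both the voluntary and the enforced agreement item on the 0-4 Likert
#' scale, alongside a public-trust composite (1 to 6.6), altruism, gender,
#' East German origin, perceived pandemic severity, and - in wave 2 only -
#' vaccine-effectiveness belief and freedom-restriction perception.
#' Conformity thresholds (`tau_voluntary`, `tau_enforced`) record the
#' hypothetical coverage at which the respondent would come to prefer
#' vaccination under each regime; see [implied_adoption_curve()].
#'
#' @param config A [panel_config()].
#' @param keep_latent If `TRUE`, the continuous latent support indices are
#'   attached as columns `latent_voluntary` / `latent_enforced` (useful for
#'   calibration and testing; not part of the survey schema).
#' @return A long-format data frame, one row per respondent-wave, with
#'   columns `id`, `wave`, `agree_voluntary`, `agree_enforced`, `trust`,
#'   `altruism`, `female`, `east`, `effectiveness`, `freedom`,
#'   `pandemic_critical`, `tau_voluntary`, `tau_enforced`. Wave-1 rows have
#'   `NA` effectiveness and freedom by design. Deterministic given
#'   `config$seed`.
#' @examples
#' panel <- generate_panel(panel_config(n = 500, seed = 42))
#' table(panel$wave)
#' @export
generate_panel <- function(config, keep_latent = FALSE) {
  stopifnot(inherits(config, "panel_config"))
  validate_panel_config(config)
  lat <- gen_latent(config)
  n <- lat$n
  cp <- config$cutpoints

  row_for <- function(w) {
    wn <- paste0("wave", w)
    df <- data.frame(
      id = seq_len(n),
      wave = w,
      agree_voluntary = likert_cut(lat$y$voluntary[[wn]], cp$voluntary[[wn]]),
      agree_enforced  = likert_cut(lat$y$enforced[[wn]], cp$enforced[[wn]]),
      trust = lat$trust[[wn]],
      altruism = lat$altruism,
      female = lat$female,
      east = lat$east,
      effectiveness = if (w == 2L) lat$effectiveness else NA_real_,
      freedom = if (w == 2L) lat$freedom else NA_real_,
      pandemic_critical = lat$pandemic_critical,
      tau_voluntary = lat$tau_voluntary,
      tau_enforced = lat$tau_enforced
    )
    if (keep_latent) {
      df$latent_voluntary <- lat$y$voluntary[[wn]]
      df$latent_enforced <- lat$y$enforced[[wn]]
    }
    df
  }
  panel <- rbind(row_for(1L), row_for(2L))
  panel <- panel[order(panel$id, panel$wave), ]
  rownames(panel) <- NULL

  if (config$missing_rate > 0) {
    m <- lat$miss_draw < config$missing_rate
    vars <- c("trust", "altruism", "pandemic_critical", "effectiveness", "freedom")
    for (j in seq_along(vars)) {
      hit <- rep(m[, j], each = 2L)
      panel[[vars[j]]][hit] <- NA_real_
    }
  }
  panel
}

#' Calibrate generator cutpoints to printed Likert marginals
#'
#' Adjusts the regime- and wave-specific latent cutpoints of a
#' [panel_config()] - holding all effect loadings, the crowding-out shift
#' and the trust-shock distribution fixed - so that the simulated cumulative
#' Likert distribution matches the supplied targets. Because the Likert
#' response is a deterministic cut of the latent index, the matching
#' cutpoints are the latent quantiles at the target cumulative shares; they
#' are computed from one large deterministic calibration draw and then
#' verified (and, if needed, refined) against that draw until every share is
#' within `tol_pp` percentage points.
#'
#' @param targets Nested list `targets$<regime>$<wave1|wave2>`, each a named
#'   cumulative-share vector `c(ge4, ge3, ge2, ge1)` (share at Likert level
#'   >= k); see [printed_enforced_targets()]. Regimes or waves not present are
#'   left at their current cutpoints.
#' @param config Base [panel_config()] to calibrate.
#' @param n_sim Size of the calibration draw.
#' @param tol_pp Convergence tolerance in percentage points.
#' @param max_iter Iteration cap; exceeding it raises a
#'   non-convergence error.
#' @param calibration_seed Seed of the deterministic calibration draw.
#' @return A new `panel_config` with updated cutpoints and an attribute
#'   `calibration` recording the seed, draw size, achieved deviations, and a
#'   `boundary_warning` flag set when degenerate targets pushed cutpoints to
#'   the configured bounds.
#' @examples
#' \donttest{
#' cfg <- calibrate_to_marginals(printed_enforced_targets(),
#'                               panel_config(n = 1000, seed = 7),
#'                               n_sim = 20000)
#' }
#' @export
calibrate_to_marginals <- function(targets, config = panel_config(),
                                   n_sim = 200000L, tol_pp = 0.5,
                                   max_iter = 10L,
                                   calibration_seed = 20210607L) {
  stopifnot(inherits(config, "panel_config"))
  bound <- 8
  boundary_warning <- FALSE
  for (r in names(targets)) {
    stopifnot(r %in% c("voluntary", "enforced"))
    for (w in names(targets[[r]])) {
      tg <- targets[[r]][[w]]
      if (length(tg) != 4L || any(tg < 0) || any(tg > 1) ||
          any(diff(tg) < 0)) { # stored ge4..ge1, so nondecreasing
        stop("invalid-targets: ", r, "/", w, " must be cumulative shares ",
             "c(ge4, ge3, ge2, ge1) with ge4 <= ge3 <= ge2 <= ge1 in [0,1]",
             call. = FALSE)
      }
    }
  }

  lat <- gen_latent(config, n = as.integer(n_sim), seed = calibration_seed)
  cfg <- config
  achieved <- list()
  for (r in names(targets)) {
    for (w in names(targets[[r]])) {
      tg <- targets[[r]][[w]]              # c(ge4, ge3, ge2, ge1)
      y <- lat$y[[r]][[w]]
      ge_target <- rev(tg)                 # ge1 .. ge4 for cutpoints c1 < .. < c4
      ge_work <- ge_target
      ok <- FALSE
      for (iter in seq_len(max_iter)) {
        cp <- stats::quantile(y, probs = 1 - ge_work, names = FALSE, type = 7)
        if (any(!is.finite(cp)) || any(cp < -bound) || any(cp > bound)) {
          cp <- pmin(pmax(cp, -bound), bound)
          boundary_warning <- TRUE
        }
        if (any(diff(cp) <= 0)) {
          cp <- cummax(cp) + seq(0, 3e-6, length.out = 4L)
          boundary_warning <- TRUE
        }
        sim <- likert_cut(y, cp)
        got <- vapply(1:4, function(k) mean(sim >= k), numeric(1)) # ge1..ge4
        dev_pp <- 100 * abs(got - ge_target)
        if (max(dev_pp) <= tol_pp) { ok <- TRUE; break }
        # refine: nudge the working shares by the residual mass
        ge_work <- pmin(pmax(ge_work + (ge_target - got), 0), 1)
      }
      if (!ok) {
        stop("calibration-non-convergence: ", r, "/", w,
             " not matched within ", tol_pp, " pp after ", max_iter,
             " iterations", call. = FALSE)
      }
      cfg$cutpoints[[r]][[w]] <- cp
      achieved[[paste(r, w, sep = ".")]] <- max(dev_pp)
    }
  }
  if (boundary_warning) {
    warning("calibration hit cutpoint bounds for a degenerate target")
  }
  attr(cfg, "calibration") <- list(seed = calibration_seed, n_sim = n_sim,
                                   max_dev_pp = achieved,
                                   boundary_warning = boundary_warning)
  validate_panel_config(cfg)
  cfg
}

#' Empirical adoption curve implied by a generated panel
#'
#' Aggregates the respondent-level conformity thresholds of a panel into an
#' empirical adoption curve: for each hypothetical coverage level `f`, the
#' share of respondents whose threshold under the given regime is at most
#' `f` (i.e. who would prefer being vaccinated once a fraction `f` of the
#' population is vaccinated). This is the micro-to-macro link between the
#' survey generator and the dynamic model's regime curves.
#'
#' @param panel A data frame from [generate_panel()].
#' @param regime `"voluntary"` or `"enforced"`.
#' @param f_grid Coverage fractions at which to evaluate the curve.
#' @return Numeric vector of preference shares, one per grid point.
#' @export
implied_adoption_curve <- function(panel, regime = c("voluntary", "enforced"),
                                   f_grid = seq(0, 1, by = 0.05)) {
  regime <- match.arg(regime)
  if (is.null(panel) || !nrow(panel)) {
    stop("empty-panel: no respondents to aggregate", call. = FALSE)
  }
  col <- paste0("tau_", regime)
  if (!col %in% names(panel)) {
    stop("panel lacks conformity thresholds (column ", col, ")", call. = FALSE)
  }
  tau <- panel[[col]][panel$wave == min(panel$wave)] # time-invariant
  vapply(f_grid, function(f) mean(tau <= f), numeric(1))
}
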