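#' Configuration of the synthetic two-wave panel generator
#'
#' Describes a latent-variable ordered-response data-generating process for a
#' two-wave survey panel in which every respondent states agreement (Likert
#' 0-4) to getting vaccinated under a voluntary and under an enforced regime,
#' in both waves.
#'
#' The latent support index for respondent `i`, regime `r`, wave `w` is a
#' linear combination of standardized components:
#' a stable public-trust component `S` plus a wave-specific trust shock (the
#' current standardized trust level carries the causal loading
#' `effects$trust_<r>`, while `effects$trust_stable_<r>` loads on `S` alone
#' and acts as a time-invariant confounder, so cross-section trust
#' associations exceed within-person change effects); altruism; gender; East
#' German origin; vaccine-effectiveness belief and freedom-restriction
#' perception (both correlated with stable trust, observed only in wave 2);
#' perceived local pandemic severity; an individual propensity `u_i`; and
#' item-wave noise. Enforced-regime support is additionally lowered by
#' `crowding_out_shift` (crowding-out of intrinsic motivation by
#' enforcement). Ordered cutpoints per regime and wave map the latent index
#' to the observed 0-4 Likert levels.
#'
#' Each respondent also carries a conformity threshold per regime (the
#' hypothetical coverage level at which they would come to prefer
#' vaccination), drawn from the threshold model of the configured adoption
#' curves with a shared uniform draw across regimes, so the enforced
#' threshold never lies below the voluntary one.
#'
#' @param n Number of respondents (each contributes two rows, one per wave).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param effects Named list of standardized effect loadings; see Details.
#' @param crowding_out_shift Mean latent voluntary-minus-enforced gap
#'   (latent-scale units, >= 0 under the crowding-out hypothesis).
#' @param trust_shock List with `mean` and `sd` of the wave-2 trust shock on
#'   the standardized latent trust scale.
#' @param trust_scale List with `mean`, `sd`, `min`, `max` mapping latent
#'   trust to the observed public-trust composite (a 1 to 6.6 scale).
#' @param sigma_u SD of the individual support propensity shared across
#'   items and waves.
#' @param sigma_eps SD of item-wave idiosyncratic noise.
#' @param p_female,p_east Bernoulli rates of the binary covariates.
#' @param eff_trust_loading,freedom_trust_loading Correlation of the wave-2
#'   attitude measures with stable trust (freedom loads negatively).
#' @param thresholds List with elements `voluntary` and `enforced`, each a
#'   list `(p0, p1, mu, sigma)` describing the gaussian-threshold adoption
#'   curve the respondent-level conformity thresholds are drawn from.
#' @param cutpoints List `cutpoints$<regime>$<wave1|wave2>`, each a strictly
#'   ascending numeric vector of 4 latent-scale cutpoints.
#' @param missing_rate Missing-at-random rate applied to the non-mandatory
#'   survey measures (trust, altruism, severity, and the wave-2 attitude
#'   items); 0 disables missingness.
#' @return An object of class `panel_config`.
#' @seealso [generate_panel()], [calibrate_to_marginals()]
#' @export
panel_config <- function(n = 2653L,
                         seed = 1L,
                         effects = default_panel_effects(),
                         crowding_out_shift = 0.4,
                         trust_shock = list(mean = -0.05, sd = 0.6),
                         trust_scale = list(mean = 4.8, sd = 0.9,
                                            min = 1, max = 6.6),
                         sigma_u = 0.8,
                         sigma_eps = 0.6,
                         p_female = 0.47,
                         p_east = 0.3,
                         eff_trust_loading = 0.35,
                         freedom_trust_loading = 0.35,
                         thresholds = default_panel_thresholds(),
                         cutpoints = default_panel_cutpoints(),
                         missing_rate = 0) {
  cfg <- structure(
    list(n = as.integer(n), seed = as.integer(seed), effects = effects,
         crowding_out_shift = crowding_out_shift, trust_shock = trust_shock,
         trust_scale = trust_scale, sigma_u = sigma_u, sigma_eps = sigma_eps,
         p_female = p_female, p_east = p_east,
         eff_trust_loading = eff_trust_loading,
         freedom_trust_loading = freedom_trust_loading,
         thresholds = thresholds, cutpoints = cutpoints,
         missing_rate = missing_rate),
    class = "panel_config"
  )
  validate_panel_config(cfg)
  cfg
}

#' @rdname panel_config
#' @export
default_panel_effects <- function() {
  list(
    trust_voluntary = 0.05,  trust_enforced = 0.10,
    trust_stable_voluntary = 0.15, trust_stable_enforced = 0.25,
    altruism_voluntary = 0.15, altruism_enforced = 0.0,
    female_voluntary = 0.0,  female_enforced = -0.15,
    east_voluntary = -0.10,  east_enforced = 0.10,
    effectiveness_voluntary = 0.15, effectiveness_enforced = 0.30,
    freedom_voluntary = 0.0, freedom_enforced = -0.25,
    critical_voluntary = 0.10, critical_enforced = 0.15
  )
}

#' @rdname panel_config
#' @export
default_panel_thresholds <- function() {
  # survey-calibrated regime gap: enforced curve sits about 25 points below
  # the voluntary one in the interior and has the lower maximum slope
  list(
    voluntary = list(p0 = 0.20, p1 = 1.00, mu = 0.40, sigma = 0.18),
    enforced  = list(p0 = 0.15, p1 = 0.85, mu = 0.50, sigma = 0.22)
  )
}

#' @rdname panel_config
#' @export
default_panel_cutpoints <- function() {
  # latent-scale cutpoints reproducing the default marginal targets (see
  # default_marginal_targets()); obtained with calibrate_to_marginals() under
  # the default effect structure and frozen here
  list(
    voluntary = list(wave1 = c(-1.2499, -0.8231, -0.4631, 0.2682),
                     wave2 = c(-1.2542, -0.8277, -0.4613, 0.2659)),
    enforced  = list(wave1 = c(-1.2948, -1.0696, -0.5836, -0.2203),
                     wave2 = c(-1.0421, -0.6489, -0.1583, 0.3045))
  )
}

validate_panel_config <- function(cfg) {
  if (!is.numeric(cfg$n) || cfg$n < 1) {
    stop("invalid-config: n must be >= 1", call. = FALSE)
  }
  for (r in c("voluntary", "enforced")) {
    for (w in c("wave1", "wave2")) {
      cp <- cfg$cutpoints[[r]][[w]]
      if (is.null(cp) || length(cp) != 4L || anyNA(cp) ||
          any(diff(cp) <= 0)) {
        stop("invalid-config: cutpoints$", r, "$", w,
             " must be 4 strictly ascending numbers", call. = FALSE)
      }
    }
    th <- cfg$thresholds[[r]]
    check_anchors(th$p0, th$p1)
    if (th$sigma <= 0) stop("invalid-config: threshold sigma must be > 0",
                            call. = FALSE)
  }
  if (cfg$trust_shock$sd <= 0) {
    stop("invalid-config: trust_shock sd must be > 0", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("invalid-config: missing_rate must be in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config> n =", x$n, ", seed =", x$seed, "\n")
  cat("  crowding_out_shift =", x$crowding_out_shift,
      ", trust_shock = N(", x$trust_shock$mean, ",",
      x$trust_shock$sd, "^2 )\n")
  cat("  effects:", paste(names(x$effects), unlist(x$effects),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Printed cumulative Likert targets for the enforced item
#'
#' The published wave-specific cumulative distribution of agreement with
#' *enforced* vaccination: shares at Likert level >= k for k = 4, 3, 2, 1
#' (fully agree downwards). Wave 1: 44% fully agreed, 56% at levels 3-4,
#' 71% at levels 2-4, and 23% did not agree at all (so 77% at >= 1);
#' wave 2: 28%, 42%, 58% and 70% respectively.
#'
#' @return Nested list `targets$enforced$<wave1|wave2>`, each a named vector
#'   `c(ge4, ge3, ge2, ge1)` of cumulative shares, usable directly by
#'   [calibrate_to_marginals()].
#' @export
printed_enforced_targets <- function() {
  list(enforced = list(
    wave1 = c(ge4 = 0.44, ge3 = 0.56, ge2 = 0.71, ge1 = 0.77),
    wave2 = c(ge4 = 0.28, ge3 = 0.42, ge2 = 0.58, ge1 = 0.70)
  ))
}

#' @rdname printed_enforced_targets
#' @export
default_marginal_targets <- function() {
  # enforced: printed values; voluntary: two-thirds support (levels 3-4) in
  # both waves with a plausible spread, support essentially unchanged between
  # waves (a stated-world choice; only the 2/3 share is published)
  tg <- printed_enforced_targets()
  tg$voluntary <- list(
    wave1 = c(ge4 = 0.40, ge3 = 2 / 3, ge2 = 0.78, ge1 = 0.88),
    wave2 = c(ge4 = 0.40, ge3 = 2 / 3, ge2 = 0.78, ge1 = 0.88)
  )
  tg
}
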