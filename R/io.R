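#' Read and write panel CSV files
#'
#' The on-disk panel dialect is long-format CSV, one row per
#' respondent-wave, with missing values as empty fields. A column-mapped
#' import of externally deposited panels is supported through `col_map`.
#'
#' @param panel Panel data frame.
#' @param path File path.
#' @param col_map Optional named character vector mapping package column
#'   names to file column names, e.g. `c(agree_enforced = "vac_mandatory")`.
#' @return `read_panel_csv()` returns the panel data frame;
#'   `write_panel_csv()` returns `path` invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  panel <- utils::read.csv(path, na.strings = c("", "NA"))
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (col_map[[nm]] %in% names(panel)) {
        names(panel)[names(panel) == col_map[[nm]]] <- nm
      }
    }
  }
  check_panel(panel)
  panel
}

curve_from_spec <- function(spec) {
  fam <- spec$family %||% "gaussian_threshold"
  if (fam == "linear") {
    make_linear_curve(spec$p0, spec$p1)
  } else {
    make_gaussian_curve(spec$p0, spec$p1, spec$mu, spec$sigma)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a regime curve pair from a configuration list
#'
#' @param config A list with elements `curves$voluntary` and
#'   `curves$enforced`, each a mapping with `family` (`gaussian_threshold`
#'   or `linear`), `p0`, `p1` and, for the gaussian family, `mu` and
#'   `sigma` - the structure produced by reading a scenario YAML file.
#' @return A [regime_curve_pair()].
#' @export
pair_from_config <- function(config) {
  cv <- config$curves
  if (is.null(cv$voluntary) || is.null(cv$enforced)) {
    stop("config must define curves$voluntary and curves$enforced",
         call. = FALSE)
  }
  regime_curve_pair(curve_from_spec(cv$voluntary), curve_from_spec(cv$enforced))
}

panel_config_from_list <- function(pc) {
  base <- panel_config()
  args <- list()
  for (nm in c("n", "seed", "crowding_out_shift", "sigma_u", "sigma_eps",
               "p_female", "p_east", "eff_trust_loading",
               "freedom_trust_loading", "missing_rate")) {
    if (!is.null(pc[[nm]])) args[[nm]] <- pc[[nm]]
  }
  for (nm in c("trust_shock", "trust_scale")) {
    if (!is.null(pc[[nm]])) args[[nm]] <- utils::modifyList(base[[nm]], pc[[nm]])
  }
  if (!is.null(pc$effects)) {
    args$effects <- utils::modifyList(base$effects, pc$effects)
  }
  if (!is.null(pc$thresholds)) {
    args$thresholds <- utils::modifyList(base$thresholds, pc$thresholds)
  }
  if (!is.null(pc$cutpoints)) {
    cp <- base$cutpoints
    for (r in names(pc$cutpoints)) {
      for (w in names(pc$cutpoints[[r]])) {
        cp[[r]][[w]] <- as.numeric(pc$cutpoints[[r]][[w]])
      }
    }
    args$cutpoints <- cp
  }
  do.call(panel_config, args)
}

scenario_report_list <- function(report, traj_v, traj_e) {
  list(
    classification = report$classification,
    target = report$target,
    voluntary_limit = report$voluntary_limit,
    enforced_limit = report$enforced_limit,
    enforcement_burden = report$enforcement_burden,
    trajectories = list(
      voluntary = list(periods = nrow(traj_v) - 1L,
                       rest_point = attr(traj_v, "rest_point"),
                       converged = attr(traj_v, "converged"),
                       target_reached = attr(traj_v, "target_reached")),
      enforced = list(periods = nrow(traj_e) - 1L,
                      rest_point = attr(traj_e, "rest_point"),
                      converged = attr(traj_e, "converged"),
                      target_reached = attr(traj_e, "target_reached"),
                      total_enforced = sum(traj_e$enforced_added))
    )
  )
}

write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  for (nm in c("f", "pref", "regret", "enforced_added")) {
    df[[nm]] <- ifelse(is.na(df[[nm]]), NA, sprintf("%.6f", df[[nm]]))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

write_provenance <- function(out_dir, config, seed = NULL, stem = "provenance") {
  prov <- list(
    package = "vaxpref",
    version = as.character(utils::packageVersion("vaxpref")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config
  )
  jsonlite::write_json(prov, file.path(out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(prov)
}

#' Draw the two-curve scenario diagram
#'
#' Plots both adoption curves against the 45-degree line, marks the located
#' fixed points of each curve and the target coverage - the standard
#' diagram for reading off rest points, tipping points and the enforcement
#' burden.
#'
#' @param pair A [regime_curve_pair()].
#' @param target Optional target coverage to mark.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_scenario <- function(pair, target = NULL, ...) {
  f <- seq(0, 1, length.out = 401)
  pv <- adoption_share(pair$voluntary, f)
  pe <- adoption_share(pair$enforced, f)
  graphics::plot(f, pv, type = "l", col = "blue", lwd = 2, xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "fraction vaccinated f(t)",
                 ylab = "fraction preferring vaccination at t+1", ...)
  graphics::lines(f, pe, col = "red", lwd = 2)
  graphics::abline(0, 1, col = "grey50")
  for (cv in list(pair$voluntary, pair$enforced)) {
    eq <- tryCatch(fixed_points(cv), error = function(e) NULL)
    if (!is.null(eq) && nrow(eq)) {
      graphics::points(eq$f, eq$f, pch = ifelse(eq$kind == "tipping", 1, 19))
    }
  }
  if (!is.null(target)) graphics::abline(v = target, lty = 2)
  graphics::legend("bottomright", c("voluntary", "enforced"),
                   col = c("blue", "red"), lwd = 2, bty = "n")
  invisible(NULL)
}
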