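Package: vaxpref
Title: Dynamics of Vaccine Acceptance Under Voluntary and Enforced Policies
Version: 0.1.0
Authors@R:
    person("Analysis", "Team", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how population-level vaccination preferences
    evolve when vaccination is recommended (voluntary) versus legally required
    (enforced). Implements regime-specific conformist adoption curves with
    fixed-point and tipping-point analysis, discrete-time ratchet dynamics of
    coverage with willing-first enforcement top-up and regret accounting, a
    seeded generator of two-wave respondent-level Likert panel data with
    regime-specific crowding-out and trust shocks, and the accompanying survey
    analysis pipeline (Likert summaries, between-wave transition shares,
    standardized cross-section OLS, and first-difference change regressions).
    A small command-line layer ties the stages into a reproducible scenario
    pipeline driven by YAML configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
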