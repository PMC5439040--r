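Package: cvdproj
Title: Projecting Cardiovascular Disease Burden Under Demographic Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the disability-adjusted life year (DALY) burden of
    cardiovascular disease in an aging population by combining a
    cohort-component population projection under named fertility scenarios
    with age-interpolated, base-year-constant DALY rates. Includes a
    synthetic demography generator (base pyramid, survivorship and
    fertility schedules, coarse-age-group DALY tables), ordinary
    least-squares interpolation of DALY rates from coarse to 5-year age
    groups, table-style burden projections with summary statistics, a
    six-scenario sensitivity grid (population-estimate error by mortality
    undercounting) with Monte Carlo 95% confidence intervals, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
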