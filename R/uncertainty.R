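#' The six sensitivity scenarios
#'
#' The sensitivity grid crossing population-estimate error (2%, 5%) with
#' cardiovascular-death undercounting (5%, 10%, 20%), in the canonical
#' order 2x5, 2x10, 2x20, 5x5, 5x10, 5x20.
#'
#' @return data.frame with columns `scenario`, `pop_error`, `undercount`.
#' @export
sensitivity_scenarios <- function() {
  data.frame(scenario = 1:6,
             pop_error  = rep(c(0.02, 0.05), each = 3),
             undercount = rep(c(0.05, 0.10, 0.20), times = 2))
}

check_fractions <- function(pop_error, undercount) {
  if (any(!is.finite(pop_error) | pop_error < 0 | pop_error >= 1))
    stop("`pop_error` must lie in [0, 1)")
  if (any(!is.finite(undercount) | undercount < 0 | undercount >= 1))
    stop("`undercount` must lie in [0, 1)")
}

#' Correct a DALY total for death undercounting
#'
#' If a fraction `u` of true cardiovascular deaths is missing from the
#' registration data, the recorded burden is a `(1 - u)` fraction of the
#' truth; the correction divides by `(1 - u)`. Undercounting can only
#' raise the estimate.
#'
#' @param daly recorded DALYs.
#' @param u undercount fraction in \[0, 1).
#' @return corrected DALYs, `daly / (1 - u)`.
#' @export
#' @examples
#' undercount_correct(100, 0.20)  # 125
undercount_correct <- function(daly, u) {
  check_fractions(0, u)
  daly / (1 - u)
}

new_interval <- function(point, lower, upper, method, level = 95, seed = NULL) {
  stopifnot(lower <= upper)
  structure(list(point = point, lower = lower, upper = upper,
                 level = level, method = method, seed = seed),
            class = "uncertainty_interval")
}

#' @export
print.uncertainty_interval <- function(x, ...) {
  cat(sprintf("<uncertainty_interval %s>  %.2f [%.2f, %.2f] (%g%%)\n",
              x$method, x$point, x$lower, x$upper, x$level))
  invisible(x)
}

#' Deterministic interval bounds for one sensitivity scenario
#'
#' Interval propagation of the two error sources: population error is
#' two-sided (`point x (1 - e)` to `point x (1 + e)`), undercounting is
#' a one-sided upward correction applied at the upper end
#' (`/(1 - u)`). These bounds are the support of the Monte Carlo
#' sampling distribution, so every Monte Carlo interval is nested
#' inside them.
#'
#' @param point point-estimate DALYs (>= 0).
#' @param pop_error population-estimate error fraction in \[0, 1).
#' @param undercount death-undercount fraction in \[0, 1).
#' @return an `uncertainty_interval` with `method = "bounds"`.
#' @export
#' @examples
#' scenario_bounds(1000, 0.02, 0.05)  # [980, 1073.68]
scenario_bounds <- function(point, pop_error, undercount) {
  stopifnot(point >= 0)
  check_fractions(pop_error, undercount)
  new_interval(point,
               lower = point * (1 - pop_error),
               upper = point * (1 + pop_error) / (1 - undercount),
               method = "bounds")
}

#' Interval bounds for every cell of the sensitivity grid
#'
#' @param point point-estimate DALYs.
#' @param specs scenario grid (default [sensitivity_scenarios()]).
#' @return data.frame with one row per scenario: `scenario`,
#'   `pop_error`, `undercount`, `point`, `lower`, `upper`, `method`.
#' @export
scenario_grid <- function(point, specs = sensitivity_scenarios()) {
  iv <- mapply(scenario_bounds, pop_error = specs$pop_error,
               undercount = specs$undercount, MoreArgs = list(point = point),
               SIMPLIFY = FALSE)
  cbind(specs,
        point = point,
        lower = vapply(iv, `[[`, 0, "lower"),
        upper = vapply(iv, `[[`, 0, "upper"),
        method = "bounds")
}

#' Monte Carlo confidence interval for one sensitivity scenario
#'
#' Samples a population-error factor `e ~ Uniform(-pop_error, pop_error)`
#' and an undercount fraction `u ~ Uniform(0, undercount)`, forms
#' `point x (1 + e) / (1 - u)`, and returns the empirical percentile
#' interval at the requested level. Uniform distributions are the
#' maximum-entropy choice on the stated ranges; the result is
#' deterministic given the seed and always contained in
#' [scenario_bounds()].
#'
#' @param point point-estimate DALYs (>= 0).
#' @param pop_error,undercount scenario fractions in \[0, 1).
#' @param draws number of Monte Carlo draws (>= 100; default 100,000).
#' @param level interval level in percent (default 95).
#' @param seed integer seed (default 20050101).
#' @return an `uncertainty_interval` with `method = "monte_carlo"`.
#' @export
#' @examples
#' monte_carlo_ci(1728836.74, 0.02, 0.05, draws = 1e4, seed = 1)
monte_carlo_ci <- function(point, pop_error, undercount, draws = 1e5,
                           level = 95, seed = 20050101) {
  stopifnot(point >= 0)
  check_fractions(pop_error, undercount)
  if (!is.finite(draws) || draws < 100) stop("`draws` must be at least 100")
  if (!is.finite(level) || level <= 0 || level >= 100)
    stop("`level` must lie in (0, 100)")
  x <- sample_sensitivity(point, pop_error, undercount, draws, seed)
  q <- stats::quantile(x, probs = c((100 - level), (100 + level)) / 200,
                       names = FALSE, type = 7)
  new_interval(point, q[1], q[2], method = "monte_carlo",
               level = level, seed = seed)
}

# Draws from the sensitivity sampling distribution; shared by the CI and
# by coverage experiments.
sample_sensitivity <- function(point, pop_error, undercount, draws, seed) {
  rng <- local_rng(seed)
  e <- rng$runif(draws, -pop_error, pop_error)
  u <- rng$runif(draws, 0, undercount)
  point * (1 + e) / (1 - u)
}

#' Sensitivity table for a burden projection
#'
#' Evaluates every sensitivity-grid cell at the projected total DALYs of
#' one year, with both deterministic bounds and Monte Carlo intervals.
#'
#' @param proj a [project_burden()] result.
#' @param year year to evaluate (default: last projected year).
#' @param stratum sex stratum.
#' @param specs scenario grid (default [sensitivity_scenarios()]).
#' @param draws,level,seed Monte Carlo settings (see [monte_carlo_ci()]).
#' @return data.frame with one row per scenario: the grid columns plus
#'   `point`, `lower`, `upper`, `mc_lower`, `mc_upper`, `level`,
#'   `draws`, `seed`.
#' @export
sensitivity_table <- function(proj, year = NULL, stratum = "both",
                              specs = sensitivity_scenarios(),
                              draws = 1e5, level = 95, seed = 20050101) {
  stopifnot(inherits(proj, "burden_projection"))
  if (is.null(year)) year <- max(as.integer(names(proj$tables)))
  point <- total_daly(proj$tables[[as.character(year)]], stratum)
  grid <- scenario_grid(point, specs)
  mc <- mapply(function(pe, uc, i)
                 monte_carlo_ci(point, pe, uc, draws = draws, level = level,
                                seed = seed + i),
               grid$pop_error, grid$undercount, seq_len(nrow(grid)),
               SIMPLIFY = FALSE)
  grid$mc_lower <- vapply(mc, `[[`, 0, "lower")
  grid$mc_upper <- vapply(mc, `[[`, 0, "upper")
  grid$level <- level
  grid$draws <- draws
  grid$seed <- seed + seq_len(nrow(grid))
  grid$year <- year
  grid
}
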