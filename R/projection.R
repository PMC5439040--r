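#' Total-fertility-rate paths of the five named fertility scenarios
#'
#' The per-period TFR targets (children per woman) of the 2015-revision
#' World Population Prospects fertility variants for Iran, one value per
#' 5-year projection period from 2000-2005 through 2020-2025:
#' medium, high (optimistic), low (pessimistic), constant, and instant
#' replacement (2.1 throughout). Shipped as an immutable built-in
#' fixture; other paths must be supplied explicitly.
#'
#' @param scenario optional scenario name; if given, returns that
#'   column as a named numeric vector (periods as names).
#' @return with no argument, a data.frame with column `period` plus one
#'   column per scenario; otherwise a named vector of five TFRs.
#' @export
#' @examples
#' tfr_scenarios()
#' tfr_scenarios("medium")
tfr_scenarios <- function(scenario = NULL) {
  tab <- data.frame(
    period = c("2000-2005", "2005-2010", "2010-2015", "2015-2020", "2020-2025"),
    medium              = c(1.96, 1.77, 1.59, 1.45, 1.36),
    high                = c(1.96, 1.77, 1.84, 1.85, 1.86),
    low                 = c(1.96, 1.77, 1.34, 1.05, 0.86),
    constant            = c(1.96, 1.77, 1.77, 1.77, 1.77),
    instant_replacement = c(2.10, 2.10, 2.10, 2.10, 2.10),
    stringsAsFactors = FALSE)
  if (is.null(scenario)) return(tab)
  scenario <- match.arg(scenario, names(tab)[-1])
  stats::setNames(tab[[scenario]], tab$period)
}

#' Rescale a fertility schedule to a target TFR
#'
#' Multiplies every age-specific rate by a single scalar so the implied
#' TFR (5 x sum of 5-year-group ASFRs) hits `tfr_target` exactly; the
#' age pattern (ratios between groups) is unchanged. This is how a
#' scenario's per-period TFR path drives the projection.
#'
#' @param schedule a [make_fertility_schedule()] object.
#' @param tfr_target children per woman (> 0).
#' @return a rescaled `fertility_schedule`.
#' @export
scale_to_tfr <- function(schedule, tfr_target) {
  stopifnot(inherits(schedule, "fertility_schedule"))
  if (!is.finite(tfr_target) || tfr_target <= 0)
    stop("`tfr_target` must be positive")
  tfr0 <- implied_tfr(schedule)
  if (tfr0 <= 0) stop("input schedule has zero implied TFR; cannot rescale")
  schedule$asfr <- schedule$asfr * (tfr_target / tfr0)
  schedule
}

#' Advance a pyramid one 5-year step by the cohort-component method
#'
#' Each cohort is survived into the next 5-year age group using the
#' sex-specific survivorship ratios; the open-ended terminal group keeps
#' its own survivors in addition to new entrants. Births over the period
#' are 5 x the sum over reproductive age groups of female count x ASFR,
#' split by the sex ratio at birth and survived into the 0-4 group.
#' Migration is zero.
#'
#' @param pyramid a [population_pyramid()].
#' @param mortality a [make_mortality_schedule()] object (or any list
#'   with conforming `survival` and `birth_survival`).
#' @param fertility a [make_fertility_schedule()] object.
#' @param exposure `"start"` (default) uses start-of-period female
#'   counts as the birth exposure; `"mid"` averages start and end-period
#'   survived counts.
#' @return the pyramid 5 years later.
#' @export
project_step <- function(pyramid, mortality, fertility,
                         exposure = c("start", "mid")) {
  stopifnot(inherits(pyramid, "population_pyramid"))
  exposure <- match.arg(exposure)
  groups <- fine_age_groups()
  n <- nrow(groups)
  surv <- mortality$survival
  if (is.null(surv) || !all(dim(surv) == c(n, 2)))
    stop("mortality schedule does not cover every fine age group")
  if (is.null(fertility$asfr) || length(fertility$asfr) != 7)
    stop("fertility schedule must cover the seven groups 15-19 ... 45-49")
  old <- pyramid$counts
  new <- matrix(0, n, 2, dimnames = dimnames(old))
  new[2:n, ] <- old[1:(n - 1), ] * surv[1:(n - 1), ]
  new[n, ] <- new[n, ] + old[n, ] * surv[n, ]   # open group keeps its survivors
  repro <- match(names(fertility$asfr), groups$label)
  fem <- switch(exposure,
    start = old[repro, "female"],
    mid   = (old[repro, "female"] + new[repro, "female"]) / 2)
  births <- 5 * sum(fem * fertility$asfr)
  srb <- fertility$srb
  new[1, "male"]   <- births * srb / (1 + srb) * mortality$birth_survival[["male"]]
  new[1, "female"] <- births * 1   / (1 + srb) * mortality$birth_survival[["female"]]
  population_pyramid(pyramid$year + 5L, new)
}

#' Project a population series under a fertility-scenario TFR path
#'
#' Iterates [project_step()] from the base year to `horizon_year`,
#' rescaling the base fertility schedule to the scenario's TFR for each
#' 5-year period (period labels `"Y-Y+5"`). The result holds one pyramid
#' per quinquennial year, endpoints inclusive. Entirely deterministic.
#'
#' @param base base-year [population_pyramid()].
#' @param mortality a mortality schedule (held constant).
#' @param base_fertility fertility schedule giving the age pattern.
#' @param path either a scenario name (see [tfr_scenarios()]) or a named
#'   numeric vector of TFRs with period labels as names.
#' @param horizon_year final calendar year; must be the base year plus a
#'   non-negative multiple of 5.
#' @param exposure passed to [project_step()].
#' @return object of class `population_series`: list with `scenario` and
#'   `pyramids` (named by year).
#' @export
#' @examples
#' base <- make_base_population(70122200, seed = 1)
#' mort <- make_mortality_schedule(seed = 1)
#' fert <- make_fertility_schedule(1.77)
#' proj <- project_series(base, mort, fert, "medium", 2025)
#' sapply(proj$pyramids, function(p) summarize_pyramid(p)$total)
project_series <- function(base, mortality, base_fertility, path = "medium",
                           horizon_year = 2025, exposure = "start") {
  stopifnot(inherits(base, "population_pyramid"))
  name <- "custom"
  if (is.character(path) && length(path) == 1) {
    name <- match.arg(path, names(tfr_scenarios())[-1])
    path <- tfr_scenarios(name)
  }
  if (horizon_year < base$year || (horizon_year - base$year) %% 5 != 0)
    stop("`horizon_year` must be the base year plus a multiple of 5")
  years <- seq(base$year, horizon_year, by = 5)
  pyramids <- stats::setNames(vector("list", length(years)), years)
  pyramids[[1]] <- base
  cur <- base
  for (i in seq_along(years)[-1]) {
    period <- paste0(cur$year, "-", cur$year + 5)
    if (!period %in% names(path))
      stop("TFR path has no entry for period ", period)
    fert <- scale_to_tfr(base_fertility, path[[period]])
    cur <- project_step(cur, mortality, fert, exposure = exposure)
    pyramids[[i]] <- cur
  }
  structure(list(scenario = name, pyramids = pyramids),
            class = "population_series")
}

#' @export
print.population_series <- function(x, ...) {
  cat(sprintf("<population_series '%s'>  years %s\n", x$scenario,
              paste(names(x$pyramids), collapse = ", ")))
  invisible(x)
}

#' Interpolate a quinquennial population series to annual pyramids
#'
#' Cell-wise linear interpolation between bracketing quinquennial
#' pyramids; quinquennial years are returned unchanged. Used to draw
#' annual burden curves from a 5-yearly projection.
#'
#' @param series a [project_series()] result with at least two pyramids.
#' @param years years to return (default: every year spanned).
#' @return named list of [population_pyramid()] objects.
#' @export
interpolate_years <- function(series, years = NULL) {
  stopifnot(inherits(series, "population_series"))
  yrs <- as.integer(names(series$pyramids))
  if (length(yrs) < 2) stop("need at least two pyramids to interpolate")
  if (is.null(years)) years <- seq(min(yrs), max(yrs))
  out <- lapply(years, function(y) {
    if (y < min(yrs) || y > max(yrs)) stop("year ", y, " outside the series")
    i <- findInterval(y, yrs)
    if (yrs[i] == y) return(series$pyramids[[i]])
    w <- (y - yrs[i]) / (yrs[i + 1] - yrs[i])
    counts <- (1 - w) * series$pyramids[[i]]$counts +
              w * series$pyramids[[i + 1]]$counts
    population_pyramid(y, counts)
  })
  stats::setNames(out, years)
}
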