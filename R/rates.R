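#' A straight-line model of DALY rate against age
#'
#' `rate_line` couples an intercept and slope describing how the
#' cardiovascular DALY rate (per 100,000 population per year, by default)
#' varies linearly with age-group midpoint within one sex stratum.
#'
#' @param stratum `"both"`, `"male"` or `"female"`.
#' @param intercept rate at age 0 (may be negative; predictions are
#'   clamped at zero).
#' @param slope rate change per year of age.
#' @return object of class `rate_line`.
#' @export
rate_line <- function(stratum, intercept, slope) {
  stratum <- match_stratum(stratum)
  stopifnot(is.finite(intercept), is.finite(slope))
  structure(list(stratum = stratum, intercept = intercept, slope = slope),
            class = "rate_line")
}

#' @export
print.rate_line <- function(x, ...) {
  cat(sprintf("<rate_line %s>  rate = %.2f %+.2f * age\n",
              x$stratum, x$intercept, x$slope))
  invisible(x)
}

#' Reference regression lines for adult cardiovascular DALY rates
#'
#' The three built-in regression equations relating cardiovascular DALY
#' rate to coarse-age-group midpoint in Iranian adults aged 30 and over,
#' derived from the 2003 national burden-of-disease data:
#' \deqn{both: -5047.25 + 173.71 \cdot age}
#' \deqn{male: -4896.54 + 171.17 \cdot age}
#' \deqn{female: -5190.07 + 176.11 \cdot age}
#' Age is the interval midpoint in years. The rate unit is interpreted as
#' DALYs per 100,000 population per year (see the methods vignette for
#' why this denominator is adopted).
#'
#' @return named list of three [rate_line()] objects (`both`, `male`,
#'   `female`); fresh copies on every call.
#' @export
#' @examples
#' reference_rate_lines()$both
reference_rate_lines <- function() {
  list(both   = rate_line("both",   -5047.25, 173.71),
       male   = rate_line("male",   -4896.54, 171.17),
       female = rate_line("female", -5190.07, 176.11))
}

#' Fit a rate line to a coarse burden table by ordinary least squares
#'
#' Regresses the DALY rate on the coarse-age-group midpoint for one sex
#' stratum, reproducing the interpolation step that turns five coarse
#' observations into a straight line usable at any age.
#'
#' @param table a `coarse_burden_table` (see [make_coarse_daly_table()]).
#' @param stratum sex stratum to fit.
#' @param open_width passed to [group_midpoint()] for the open 80+ group.
#' @return a [rate_line()] holding the exact OLS solution.
#' @export
fit_rate_line <- function(table, stratum, open_width = 10) {
  stratum <- match_stratum(stratum)
  rows <- table[table$sex == stratum, , drop = FALSE]
  if (nrow(rows) < 2) stop("need at least 2 coarse groups to fit a line")
  mid <- group_midpoint(rows$age_lo, rows$age_hi, open_width = open_width)
  if (length(unique(mid)) < 2) stop("all age-group midpoints identical; fit degenerate")
  fit <- stats::lm(rate_per_100k ~ mid, data = data.frame(mid = mid,
                   rate_per_100k = rows$rate_per_100k))
  co <- stats::coef(fit)
  rate_line(stratum, unname(co[1]), unname(co[2]))
}

#' Predict a DALY rate at a given age
#'
#' Evaluates a [rate_line()] at an age and clamps negative predictions to
#' zero (a rate cannot be negative; for the built-in reference lines the
#' clamp never activates at ages 30 and above, since all three lines
#' cross zero near age 29).
#'
#' @param line a [rate_line()].
#' @param age age(s) in years (>= 0).
#' @return DALY rate(s) per 100,000.
#' @export
#' @examples
#' predict_rate(reference_rate_lines()$both, 32)  # 511.47
predict_rate <- function(line, age) {
  stopifnot(inherits(line, "rate_line"), all(age >= 0))
  pmax(line$intercept + line$slope * age, 0)
}

#' Expand a rate line to fine 5-year age groups
#'
#' Evaluates a [rate_line()] at the midpoint of every fine adult age
#' group (30-34 through 95-99). The terminal `100+` group is assigned a
#' rate of zero: the reference burden projections carry no burden above
#' age 100 and the extrapolated line is not trusted there.
#'
#' @param line a [rate_line()].
#' @param groups data.frame of fine age groups (default
#'   `fine_age_groups(min_age = 30)`); must be disjoint, ordered and
#'   cover 30 to 100+.
#' @return a `fine_rate_table`: data.frame with columns `sex`, `age_lo`,
#'   `age_hi`, `rate_per_100k`.
#' @export
#' @examples
#' expand_to_fine(reference_rate_lines()$both)
expand_to_fine <- function(line, groups = fine_age_groups(min_age = 30)) {
  stopifnot(inherits(line, "rate_line"))
  need <- c("age_lo", "age_hi")
  if (!all(need %in% names(groups)) || nrow(groups) < 1)
    stop("`groups` must be a data.frame with age_lo and age_hi columns")
  if (is.unsorted(groups$age_lo, strictly = TRUE))
    stop("`groups` must be ordered by age_lo")
  rate <- predict_rate(line, group_midpoint(groups$age_lo, groups$age_hi))
  rate[groups$age_lo >= 100] <- 0
  out <- data.frame(sex = line$stratum, age_lo = groups$age_lo,
                    age_hi = groups$age_hi, rate_per_100k = rate,
                    stringsAsFactors = FALSE)
  class(out) <- c("fine_rate_table", "data.frame")
  out
}

#' @rdname expand_to_fine
#' @param table a `fine_rate_table`.
#' @param path CSV path (`sex,age_lo,age_hi,rate_per_100k`).
#' @export
write_fine_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
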