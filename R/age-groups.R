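#' Five-year age groups spanning 0 to 100+
#'
#' The fine age grid used throughout the package: 5-year intervals
#' `0-4`, `5-9`, ..., `95-99` plus the open-ended terminal group `100+`.
#' Interval bounds are inclusive; the open upper bound is `NA`.
#'
#' @param min_age lowest lower bound to include (default 0). Use 30 for
#'   the adult grid over which DALY rates are modelled.
#' @return data.frame with columns `age_lo`, `age_hi` (`NA` for `100+`)
#'   and `label`.
#' @export
#' @examples
#' fine_age_groups()
#' fine_age_groups(min_age = 30)
fine_age_groups <- function(min_age = 0) {
  lo <- seq(0L, 100L, by = 5L)
  hi <- c(lo[-length(lo)] + 4L, NA_integer_)
  out <- data.frame(age_lo = lo, age_hi = hi,
                    label = age_group_label(lo, hi),
                    stringsAsFactors = FALSE)
  out[out$age_lo >= min_age, , drop = FALSE]
}

#' Coarse adult age groups of the national burden-of-disease inputs
#'
#' The five coarse strata in which adult cardiovascular DALY rates are
#' reported by the 2003 Iranian national burden-of-disease study:
#' 30-44, 45-59, 60-69, 70-79 and the open-ended 80+.
#'
#' @return data.frame with columns `age_lo`, `age_hi` (`NA` for `80+`)
#'   and `label`.
#' @export
coarse_age_groups <- function() {
  data.frame(age_lo = c(30L, 45L, 60L, 70L, 80L),
             age_hi = c(44L, 59L, 69L, 79L, NA_integer_),
             label  = c("30-44", "45-59", "60-69", "70-79", "80+"),
             stringsAsFactors = FALSE)
}

age_group_label <- function(lo, hi) {
  ifelse(is.na(hi), paste0(lo, "+"), paste0(lo, "-", hi))
}

#' Midpoint age of an age interval
#'
#' Closed intervals \code{[lo, hi]} (both bounds inclusive) map to
#' \code{(lo + hi) / 2}; open-ended intervals are closed by convention at
#' `open_width` years above the lower bound, except that the terminal
#' `100+` group maps to exactly 100 (population above 100 is treated as
#' concentrated at the boundary).
#'
#' @param age_lo integer lower bound(s), years.
#' @param age_hi integer upper bound(s), years, inclusive; `NA` marks an
#'   open-ended interval.
#' @param open_width years added to the lower bound to close an
#'   open-ended interval below 100 (default 10, so `80+` has midpoint 85).
#' @return numeric midpoint age(s) in years.
#' @export
#' @examples
#' group_midpoint(30, 34)   # 32
#' group_midpoint(45, 59)   # 52
#' group_midpoint(80, NA)   # 85
#' group_midpoint(100, NA)  # 100
group_midpoint <- function(age_lo, age_hi, open_width = 10) {
  stopifnot(length(age_lo) == length(age_hi))
  mid <- (age_lo + age_hi) / 2
  open <- is.na(age_hi)
  mid[open] <- ifelse(age_lo[open] >= 100, 100, age_lo[open] + open_width / 2)
  mid
}

SEXES <- c("male", "female")
STRATA <- c("both", "male", "female")

match_stratum <- function(stratum) {
  match.arg(stratum, STRATA)
}
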