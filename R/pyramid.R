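#' Construct a population pyramid
#'
#' A pyramid holds person-counts by sex and 5-year age group (`0-4`
#' through `100+`) for one reference year, the object stepped forward in
#' time by the cohort-component projection.
#'
#' @param year calendar reference year (the pyramid describes mid-year).
#' @param counts numeric matrix, rows = the 21 fine age groups in order,
#'   columns = `male`, `female`; all entries non-negative.
#' @return object of class `population_pyramid`: a list with elements
#'   `year` and `counts`.
#' @export
population_pyramid <- function(year, counts) {
  groups <- fine_age_groups()
  if (!is.matrix(counts) || nrow(counts) != nrow(groups) || ncol(counts) != 2)
    stop("`counts` must be a ", nrow(groups), " x 2 matrix (age group x sex)")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("pyramid counts must be finite and non-negative")
  dimnames(counts) <- list(groups$label, SEXES)
  structure(list(year = as.integer(year), counts = counts),
            class = "population_pyramid")
}

#' @export
print.population_pyramid <- function(x, ...) {
  s <- summarize_pyramid(x)
  cat(sprintf(
    "<population_pyramid %d>  total %.0f | 30+ %.2f%% | 65+ %.2f%% | male-female 30+ gap %.0f\n",
    x$year, s$total, s$share_30plus, s$share_over65, s$sex_gap_30plus))
  invisible(x)
}

#' @export
as.data.frame.population_pyramid <- function(x, ...) {
  groups <- fine_age_groups()
  data.frame(year = x$year,
             sex = rep(SEXES, each = nrow(groups)),
             age_lo = rep(groups$age_lo, 2),
             age_hi = rep(groups$age_hi, 2),
             count = c(x$counts[, "male"], x$counts[, "female"]),
             stringsAsFactors = FALSE)
}

#' Summary statistics of a population pyramid
#'
#' Computes the aggregates used to characterise population aging: the
#' grand total, the percentage of the population aged 30 and over, the
#' percentage aged 65 and over, and the signed male-minus-female count
#' difference among those aged 30 and over.
#'
#' @param pyramid a [population_pyramid()].
#' @return list with elements `total` (persons), `share_30plus` and
#'   `share_over65` (percent), and `sex_gap_30plus` (persons, signed).
#' @export
summarize_pyramid <- function(pyramid) {
  stopifnot(inherits(pyramid, "population_pyramid"))
  groups <- fine_age_groups()
  total <- sum(pyramid$counts)
  if (total <= 0) stop("pyramid has zero total population; shares undefined")
  i30 <- groups$age_lo >= 30
  i65 <- groups$age_lo >= 65
  list(total = total,
       share_30plus = 100 * sum(pyramid$counts[i30, ]) / total,
       share_over65 = 100 * sum(pyramid$counts[i65, ]) / total,
       sex_gap_30plus = sum(pyramid$counts[i30, "male"]) -
                        sum(pyramid$counts[i30, "female"]))
}

#' Write / read pyramids as CSV
#'
#' The pyramid CSV dialect has header `year,sex,age_lo,age_hi,count`;
#' `age_hi` is empty for the open-ended `100+` group. Any file in this
#' layout (for example hand-converted external projections) can be read
#' back.
#'
#' @param pyramid a [population_pyramid()] (or for reading, a file path).
#' @param path file path.
#' @return `read_pyramid_csv` returns a [population_pyramid()] (or a list
#'   of them, named by year, if the file holds several years).
#' @export
write_pyramid_csv <- function(pyramid, path) {
  utils::write.csv(as.data.frame(pyramid), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_pyramid_csv
#' @param file path of a pyramid CSV.
#' @export
read_pyramid_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("year", "sex", "age_lo", "age_hi", "count")
  if (!all(need %in% names(df)))
    stop("pyramid CSV must have columns ", paste(need, collapse = ","))
  groups <- fine_age_groups()
  one <- function(d) {
    counts <- matrix(0, nrow(groups), 2, dimnames = list(groups$label, SEXES))
    idx <- match(age_group_label(d$age_lo, d$age_hi), groups$label)
    if (anyNA(idx)) stop("unknown age group in pyramid CSV")
    counts[cbind(idx, match(d$sex, SEXES))] <- d$count
    population_pyramid(d$year[1], counts)
  }
  years <- sort(unique(df$year))
  if (length(years) == 1L) return(one(df))
  stats::setNames(lapply(years, function(y) one(df[df$year == y, ])), years)
}
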