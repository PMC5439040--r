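#' Construct a burden table
#'
#' DALYs by sex stratum and fine adult age group (30-34 through 100+)
#' for one calendar year — the shape of the reference projection table.
#' Strata are independent: the both-sex column is computed from its own
#' rate line applied to the sex-summed population, not as male + female
#' (see the methods vignette; the reference table itself is not
#' cross-stratum additive, disagreeing by about 0.05%).
#'
#' @param year calendar year.
#' @param cells numeric matrix, rows = the 15 fine adult age groups,
#'   columns = strata (any subset of `both`, `male`, `female`); entries
#'   are DALYs, non-negative.
#' @param recorded_totals optional named vector of column totals as
#'   recorded in a source table; kept alongside (and re-emitted by
#'   [write_table2()]) so a transcribed table round-trips exactly even
#'   when its printed totals differ from the cell sums in the last
#'   decimal. Must agree with the column sums within 0.05.
#' @return object of class `burden_table`.
#' @export
burden_table <- function(year, cells, recorded_totals = NULL) {
  groups <- fine_age_groups(min_age = 30)
  if (!is.matrix(cells) || nrow(cells) != nrow(groups))
    stop("`cells` must be a matrix with ", nrow(groups), " age-group rows")
  if (is.null(colnames(cells)) || !all(colnames(cells) %in% STRATA))
    stop("`cells` columns must be named from: ", paste(STRATA, collapse = ", "))
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("burden cells must be finite and non-negative")
  rownames(cells) <- groups$label
  if (!is.null(recorded_totals)) {
    if (!all(names(recorded_totals) %in% colnames(cells)))
      stop("`recorded_totals` names must match cell columns")
    dev <- abs(recorded_totals - colSums(cells)[names(recorded_totals)])
    if (any(dev > 0.05))
      stop("recorded totals deviate from cell sums by more than 0.05")
  }
  structure(list(year = as.integer(year), cells = cells,
                 recorded_totals = recorded_totals),
            class = "burden_table")
}

#' @export
print.burden_table <- function(x, ...) {
  tot <- colSums(x$cells)
  cat(sprintf("<burden_table %d>  %s\n", x$year,
              paste(sprintf("%s %.2f", names(tot), tot), collapse = " | ")))
  invisible(x)
}

#' Compute DALYs from rates and a population pyramid
#'
#' Cell DALYs = rate per 100,000 / 100,000 x group population. For the
#' `both` stratum the pyramid's male and female counts are summed before
#' multiplication. Rates are whatever the supplied table holds — under
#' the package's core assumption they stay constant at base-year level
#' while the population changes.
#'
#' @param rates a `fine_rate_table` (see [expand_to_fine()]) whose age
#'   groups match the pyramid's fine groups from 30 upward.
#' @param pyramid a [population_pyramid()].
#' @param stratum sex stratum to fill.
#' @param denominator population denominator of the rate unit (default
#'   100,000).
#' @return a [burden_table()] with the one requested stratum.
#' @export
compute_burden <- function(rates, pyramid, stratum = "both",
                           denominator = 1e5) {
  stratum <- match_stratum(stratum)
  stopifnot(inherits(pyramid, "population_pyramid"))
  groups <- fine_age_groups(min_age = 30)
  r <- rates[match(groups$label, age_group_label(rates$age_lo, rates$age_hi)), ]
  if (anyNA(r$rate_per_100k))
    stop("rate table does not cover every fine age group from 30 to 100+")
  idx <- match(groups$label, rownames(pyramid$counts))
  pop <- switch(stratum,
                both = rowSums(pyramid$counts[idx, , drop = FALSE]),
                pyramid$counts[idx, stratum])
  cells <- matrix(r$rate_per_100k / denominator * pop,
                  ncol = 1, dimnames = list(groups$label, stratum))
  burden_table(pyramid$year, cells)
}

#' Project DALY burden over a population series
#'
#' Expands each per-stratum rate line once to fine age groups, then
#' applies [compute_burden()] to every pyramid of the series. Rates
#' never vary with year: the projection isolates the effect of
#' demographic change alone.
#'
#' @param series a [project_series()] result.
#' @param lines named list of [rate_line()] objects (default
#'   [reference_rate_lines()]); names select the strata computed.
#' @param denominator rate denominator (default 100,000).
#' @return object of class `burden_projection`: list with `scenario` and
#'   `tables` (one [burden_table()] per year).
#' @export
#' @examples
#' base <- make_base_population(70122200, seed = 1)
#' proj <- project_series(base, make_mortality_schedule(seed = 1),
#'                        make_fertility_schedule(1.77), "medium", 2025)
#' bp <- project_burden(proj)
#' sapply(bp$tables, total_daly)
project_burden <- function(series, lines = reference_rate_lines(),
                           denominator = 1e5) {
  stopifnot(inherits(series, "population_series"))
  if (inherits(lines, "rate_line")) lines <- stats::setNames(list(lines), lines$stratum)
  fine <- lapply(lines, expand_to_fine)
  tables <- lapply(series$pyramids, function(p) {
    cols <- lapply(names(fine), function(st)
      compute_burden(fine[[st]], p, st, denominator = denominator)$cells)
    burden_table(p$year, do.call(cbind, cols))
  })
  structure(list(scenario = series$scenario, tables = tables),
            class = "burden_projection")
}

#' @export
print.burden_projection <- function(x, ...) {
  cat(sprintf("<burden_projection '%s'>  years %s\n", x$scenario,
              paste(names(x$tables), collapse = ", ")))
  invisible(x)
}

#' Total DALYs of a burden table
#'
#' Sums cells for a stratum, optionally restricted by an age filter.
#'
#' @param table a [burden_table()].
#' @param stratum sex stratum.
#' @param age_filter optional predicate `function(age_lo, age_hi)`
#'   returning a logical vector selecting age groups (`age_hi` is `NA`
#'   for `100+`).
#' @return total DALYs (unrounded).
#' @export
total_daly <- function(table, stratum = "both", age_filter = NULL) {
  stopifnot(inherits(table, "burden_table"))
  if (!stratum %in% colnames(table$cells)) stop("stratum not present: ", stratum)
  groups <- fine_age_groups(min_age = 30)
  keep <- if (is.null(age_filter)) rep(TRUE, nrow(groups))
          else age_filter(groups$age_lo, groups$age_hi)
  sum(table$cells[keep, stratum])
}

#' Ratio of total burden between two years
#'
#' @param proj a [project_burden()] result (or any list of
#'   [burden_table()]s named by year).
#' @param year0,year1 comparison years present in the projection.
#' @param stratum sex stratum.
#' @return `total(year1) / total(year0)`.
#' @export
fold_change <- function(proj, year0, year1, stratum = "both") {
  tabs <- if (inherits(proj, "burden_projection")) proj$tables else proj
  for (y in c(year0, year1))
    if (!as.character(y) %in% names(tabs)) stop("year not in projection: ", y)
  denom <- total_daly(tabs[[as.character(year0)]], stratum)
  if (denom <= 0) stop("zero burden in year ", year0, "; fold change undefined")
  total_daly(tabs[[as.character(year1)]], stratum) / denom
}

#' Male-minus-female total burden
#'
#' @param table a [burden_table()] with `male` and `female` strata.
#' @return signed DALY difference (male total minus female total).
#' @export
sex_difference <- function(table) {
  if (!all(c("male", "female") %in% colnames(table$cells)))
    stop("table must hold both male and female strata")
  total_daly(table, "male") - total_daly(table, "female")
}

#' Percentage of burden below an age cutoff
#'
#' @param table a [burden_table()].
#' @param cutoff_age exclusive upper age bound in years; a group counts
#'   if its (inclusive) upper bound is below the cutoff.
#' @param stratum sex stratum.
#' @return percentage of the stratum total.
#' @export
#' @examples
#' share_under(reference_table2()$tables[["2025"]], 65)  # about 70.3
share_under <- function(table, cutoff_age, stratum = "both") {
  tot <- total_daly(table, stratum)
  if (tot <= 0) stop("zero total burden; share undefined")
  part <- total_daly(table, stratum,
                     age_filter = function(lo, hi) !is.na(hi) & hi < cutoff_age)
  100 * part / tot
}

table2_columns <- function(proj, years) {
  tabs <- proj$tables
  cols <- list()
  for (y in years) {
    tb <- tabs[[as.character(y)]]
    if (is.null(tb)) stop("year not in projection: ", y)
    for (st in intersect(STRATA, colnames(tb$cells)))
      cols[[paste0(st, "_", y)]] <-
        list(cells = tb$cells[, st],
             total = if (!is.null(tb$recorded_totals) &&
                         st %in% names(tb$recorded_totals))
                       tb$recorded_totals[[st]]
                     else sum(tb$cells[, st]))
  }
  cols
}

#' Write a burden projection in the wide reference-table layout
#'
#' One row per fine adult age group plus a `Total` row; one column per
#' stratum and year (`both_2005`, `male_2005`, ...), every value
#' formatted with two decimals (rounded half-even). The Total row equals
#' the column sums within 0.05; where a table carries recorded source
#' totals those are written, so a transcribed reference table
#' round-trips byte-for-byte.
#'
#' @param proj a [project_burden()] result.
#' @param years years to include (default: all in the projection).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table2 <- function(proj, path, years = NULL) {
  stopifnot(inherits(proj, "burden_projection"))
  if (is.null(years)) years <- as.integer(names(proj$tables))
  cols <- table2_columns(proj, years)
  groups <- fine_age_groups(min_age = 30)
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  body <- vapply(cols, function(cl) fmt(c(cl$cells, cl$total)),
                 character(nrow(groups) + 1))
  df <- data.frame(age_group = c(groups$label, "Total"), body,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide reference-layout burden table
#'
#' Inverse of [write_table2()]: reads a CSV with an `age_group` column,
#' stratum-by-year value columns and a `Total` row, returning a
#' `burden_projection` whose tables carry the file's recorded totals.
#'
#' @param file CSV path.
#' @return a `burden_projection`.
#' @export
read_table2 <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  groups <- fine_age_groups(min_age = 30)
  body <- df[df$age_group != "Total", , drop = FALSE]
  tot  <- df[df$age_group == "Total", , drop = FALSE]
  if (!identical(body$age_group, groups$label))
    stop("age_group rows must be the fine adult groups 30-34 ... 100+")
  vc <- setdiff(names(df), "age_group")
  parts <- regmatches(vc, regexec("^(both|male|female)_(\\d{4})$", vc))
  if (any(lengths(parts) != 3)) stop("value columns must be <stratum>_<year>")
  strat <- vapply(parts, `[`, "", 2)
  yr    <- as.integer(vapply(parts, `[`, "", 3))
  tables <- lapply(sort(unique(yr)), function(y) {
    sel <- which(yr == y)
    cells <- as.matrix(body[, vc[sel], drop = FALSE])
    colnames(cells) <- strat[sel]
    rec <- stats::setNames(as.numeric(tot[1, vc[sel]]), strat[sel])
    burden_table(y, cells, recorded_totals = rec)
  })
  structure(list(scenario = "reference",
                 tables = stats::setNames(tables, sort(unique(yr)))),
            class = "burden_projection")
}

#' The packaged reference DALY projection table
#'
#' The reference projection of cardiovascular DALYs for Iranian adults
#' by sex and 5-year age group in 2005 and 2025 (the published
#' projection table), shipped as a plain-text fixture and used as
#' in-package ground truth for summary operations.
#'
#' @return a `burden_projection` with years 2005 and 2025 and strata
#'   `both`, `male`, `female`.
#' @export
#' @examples
#' ref <- reference_table2()
#' total_daly(ref$tables[["2005"]])
#' fold_change(ref, 2005, 2025)
reference_table2 <- function() {
  read_table2(system.file("extdata", "reference_table2.csv",
                          package = "cvdproj", mustWork = TRUE))
}
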