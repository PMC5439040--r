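test_that("compute_burden multiplies rates by population at the right denominator", {
  p <- single_cell_pyramid("30-34", "male", 6e6)
  p$counts["30-34", "female"] <- 0
  fine <- expand_to_fine(reference_rate_lines()$both)
  tb <- compute_burden(fine, p, "both")
  expect_equal(tb$cells["30-34", "both"], 511.47e-5 * 6e6,  # 30688.2
               tolerance = 1e-9)
  expect_equal(sum(tb$cells[-1, ]), 0)  # zero population elsewhere
  # homogeneity of degree 1 in the pyramid
  p2 <- population_pyramid(p$year, p$counts * 2)
  expect_equal(compute_burden(fine, p2, "both")$cells, tb$cells * 2,
               tolerance = 1e-12)
})

test_that("the both stratum uses the sex-summed population, not male + female results", {
  p <- make_base_population(1e7, 40, 15, 2e5, seed = 6)
  lines <- reference_rate_lines()
  both <- compute_burden(expand_to_fine(lines$both), p, "both")
  male <- compute_burden(expand_to_fine(lines$male), p, "male")
  fem  <- compute_burden(expand_to_fine(lines$female), p, "female")
  # both-sex line applied to summed pyramid
  fine <- expand_to_fine(lines$both)
  adult <- fine_age_groups(min_age = 30)$label
  expect_equal(unname(both$cells[, "both"]),
               unname(fine$rate_per_100k / 1e5 * rowSums(p$counts[adult, ])),
               tolerance = 1e-9)
  # cross-stratum additivity must NOT hold (separate regression lines)
  expect_false(isTRUE(all.equal(total_daly(both),
                                total_daly(male, "male") + total_daly(fem, "female"))))
})

test_that("project_burden holds rates constant so burden tracks population only", {
  base <- make_base_population(2e6, 50, 12, 0, seed = 7)
  flat <- structure(list(scenario = "custom",
                         pyramids = list(`2005` = base,
                                         `2010` = population_pyramid(2010, base$counts))),
                    class = "population_series")
  bp <- project_burden(flat)
  expect_equal(bp$tables[["2005"]]$cells, bp$tables[["2010"]]$cells)
  # growing a group grows its burden cells proportionally
  grown <- base$counts; grown["55-59", ] <- grown["55-59", ] * 1.5
  s2 <- structure(list(scenario = "custom",
                       pyramids = list(`2005` = base,
                                       `2010` = population_pyramid(2010, grown))),
                  class = "population_series")
  b2 <- project_burden(s2)
  expect_gt(b2$tables[["2010"]]$cells["55-59", "both"],
            b2$tables[["2005"]]$cells["55-59", "both"])
  expect_equal(b2$tables[["2010"]]$cells["60-64", "both"],
               b2$tables[["2005"]]$cells["60-64", "both"])
})

test_that("total_daly sums cells, with and without age filters, additively over partitions", {
  ref <- reference_table2()
  t25 <- ref$tables[["2025"]]
  expect_equal(total_daly(t25), 1728836.74, tolerance = 0.05)
  under65 <- total_daly(t25, age_filter = function(lo, hi) !is.na(hi) & hi < 65)
  expect_equal(under65, 1215778.88, tolerance = 0.05)
  over65 <- total_daly(t25, age_filter = function(lo, hi) lo >= 65)
  expect_equal(under65 + over65, total_daly(t25), tolerance = 1e-9)
  expect_equal(total_daly(t25, age_filter = function(lo, hi) lo > 200), 0)
})

test_that("fold change, sex difference and age shares reproduce the reference table", {
  ref <- reference_table2()
  expect_equal(fold_change(ref, 2005, 2025), 1728836.74 / 847309.93,
               tolerance = 5e-4)
  expect_equal(fold_change(ref, 2005, 2005), 1)
  # telescoping: forward times backward fold change is unity
  expect_equal(fold_change(ref, 2005, 2025) * fold_change(ref, 2025, 2005), 1,
               tolerance = 1e-12)
  expect_equal(sex_difference(ref$tables[["2025"]]), 6320.12, tolerance = 0.05)
  expect_equal(sex_difference(ref$tables[["2005"]]), 38696.65, tolerance = 0.05)
  expect_equal(share_under(ref$tables[["2025"]], 65), 70.32, tolerance = 0.01)
  expect_equal(share_under(ref$tables[["2025"]], 101), 100)
  expect_equal(share_under(ref$tables[["2025"]], 30), 0)
})

test_that("a synthetic Iran-like run more than 1.5-folds its burden by 2025", {
  base <- make_base_population(70122200, 22, 18, 889000, seed = 1)
  s <- project_series(base, make_mortality_schedule(seed = 1),
                      make_fertility_schedule(1.77), "medium", 2025)
  bp <- project_burden(s)
  expect_gt(fold_change(bp, 2005, 2025), 1.5)
})

test_that("the wide table round-trips byte-for-byte and totals match column sums", {
  fixture <- system.file("extdata", "reference_table2.csv", package = "cvdproj")
  ref <- read_table2(fixture)
  out <- tempfile(fileext = ".csv")
  write_table2(ref, out)
  expect_identical(readLines(out), readLines(fixture))
  # recorded totals stay within rounding slack of recomputed sums
  for (tb in ref$tables)
    expect_true(all(abs(tb$recorded_totals - colSums(tb$cells)) <= 0.05))
  # a table without recorded totals writes recomputed sums
  base <- make_base_population(1e6, 40, 10, 0, seed = 8)
  bp <- project_burden(structure(list(scenario = "custom",
                                      pyramids = list(`2005` = base)),
                                 class = "population_series"))
  out2 <- tempfile(fileext = ".csv")
  write_table2(bp, out2)
  back <- read_table2(out2)
  tb <- back$tables[["2005"]]
  expect_true(all(abs(tb$recorded_totals - colSums(tb$cells)) <= 0.05))
})

test_that("burden_table validation guards shapes, signs and total mismatches", {
  groups <- fine_age_groups(min_age = 30)
  cells <- matrix(1, nrow(groups), 1, dimnames = list(groups$label, "both"))
  expect_s3_class(burden_table(2005, cells), "burden_table")
  expect_error(burden_table(2005, cells[-1, , drop = FALSE]), "age-group rows")
  expect_error(burden_table(2005, -cells), "non-negative")
  expect_error(burden_table(2005, cells, recorded_totals = c(both = 99)),
               "more than 0.05")
  expect_error(sex_difference(burden_table(2005, cells)), "male and female")
})
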