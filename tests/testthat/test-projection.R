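test_that("the five scenario TFR paths hold the published per-period values", {
  tab <- tfr_scenarios()
  expect_equal(tab$period, c("2000-2005", "2005-2010", "2010-2015",
                             "2015-2020", "2020-2025"))
  expect_equal(tab$medium,   c(1.96, 1.77, 1.59, 1.45, 1.36))
  expect_equal(tab$high,     c(1.96, 1.77, 1.84, 1.85, 1.86))
  expect_equal(tab$low,      c(1.96, 1.77, 1.34, 1.05, 0.86))
  expect_equal(tab$constant, c(1.96, 1.77, 1.77, 1.77, 1.77))
  expect_equal(tab$instant_replacement, rep(2.1, 5))
})

test_that("scale_to_tfr rescales by a single scalar, preserving the age pattern", {
  f <- make_fertility_schedule(2.0)
  half <- scale_to_tfr(f, 1.0)
  expect_equal(half$asfr, f$asfr / 2, tolerance = 1e-12)
  expect_equal(scale_to_tfr(f, 2.0), f)            # identity at own TFR
  g <- scale_to_tfr(make_fertility_schedule(1.77), 1.86)
  expect_equal(5 * sum(g$asfr), 1.86, tolerance = 1e-9)
  zero <- f; zero$asfr[] <- 0
  expect_error(scale_to_tfr(zero, 1), "zero implied TFR")
})

test_that("a single cohort is survived into the next group", {
  p <- single_cell_pyramid("30-34", "male", 100)
  m <- flat_mortality(1); m$survival["30-34", "male"] <- 0.9
  out <- project_step(p, m, spot_fertility())
  expect_equal(out$counts["35-39", "male"], 90)
  expect_equal(sum(out$counts), 90)
  expect_equal(out$year, 2010)
})

test_that("with survivorship 1 and zero fertility mass is conserved and shifted", {
  p <- make_base_population(1e6, 30, 15, 0, seed = 5)
  out <- project_step(p, flat_mortality(1), spot_fertility())
  expect_equal(sum(out$counts), sum(p$counts), tolerance = 1e-9)
  expect_equal(out$counts["40-44", ], p$counts["35-39", ])
  # terminal open group accumulates its own survivors plus entrants
  expect_equal(out$counts["100+", ], p$counts["95-99", ] + p$counts["100+", ])
})

test_that("births follow the ASFR arithmetic and the sex ratio at birth", {
  p <- single_cell_pyramid("25-29", "female", 1000)
  fert <- spot_fertility("25-29", asfr = 0.04, srb = 1.05)
  out <- project_step(p, flat_mortality(1, birth = 1), fert)
  births <- sum(out$counts["0-4", ])
  expect_equal(births, 200, tolerance = 1e-9)                 # 5 * 1000 * 0.04
  expect_equal(out$counts["0-4", "male"], 200 * 1.05 / 2.05,  # 102.439...
               tolerance = 1e-9)
})

test_that("project_series iterates periods, rescaling fertility to the path", {
  base <- make_base_population(1e6, 22, 18, 0, seed = 1)
  mort <- make_mortality_schedule(seed = 1)
  fert <- make_fertility_schedule(1.77)
  # zero steps: horizon equal to base year returns just the base
  s0 <- project_series(base, mort, fert, "medium", 2005)
  expect_equal(names(s0$pyramids), "2005")
  expect_identical(s0$pyramids[["2005"]], base)

  s <- project_series(base, mort, fert, "medium", 2025)
  expect_equal(names(s$pyramids), as.character(seq(2005, 2025, 5)))
  expect_equal(vapply(s$pyramids, function(p) p$year, 0L),
               c(`2005` = 2005L, `2010` = 2010L, `2015` = 2015L,
                 `2020` = 2020L, `2025` = 2025L))
  # deterministic: identical inputs give identical series
  expect_identical(s, project_series(base, mort, fert, "medium", 2025))
  expect_error(project_series(base, mort, fert, "medium", 2024), "multiple of 5")
})

test_that("instant replacement holds fertility at 2.1 in every period", {
  base <- make_base_population(1e6, 22, 18, 0, seed = 1)
  mort <- make_mortality_schedule(seed = 1)
  fert <- make_fertility_schedule(1.77)
  s_ir <- project_series(base, mort, fert, "instant_replacement", 2025)
  manual <- base
  f21 <- scale_to_tfr(fert, 2.1)
  for (i in 1:4) manual <- project_step(manual, mort, f21)
  expect_equal(s_ir$pyramids[["2025"]]$counts, manual$counts, tolerance = 1e-12)
})

test_that("projected totals are weakly increasing in the scenario TFR path", {
  base <- make_base_population(5e6, 22, 18, 0, seed = 2)
  mort <- make_mortality_schedule(seed = 2)
  fert <- make_fertility_schedule(1.77)
  tot <- function(sc) vapply(
    project_series(base, mort, fert, sc, 2025)$pyramids,
    function(p) sum(p$counts), 0)
  lo <- tot("low"); me <- tot("medium"); hi <- tot("high")
  expect_true(all(lo <= me + 1e-9))
  expect_true(all(me <= hi + 1e-9))
})

test_that("cohorts never grow when survivorship is at most one", {
  base <- make_base_population(5e6, 22, 18, 0, seed = 3)
  mort <- make_mortality_schedule(0.97, seed = 3)
  s <- project_series(base, mort, make_fertility_schedule(1.77), "medium", 2025)
  labs <- fine_age_groups()$label
  for (i in seq_along(s$pyramids)[-1]) {
    prev <- s$pyramids[[i - 1]]$counts
    cur <- s$pyramids[[i]]$counts
    for (g in 2:20)  # closed groups receiving exactly one cohort
      expect_true(all(cur[labs[g], ] <= prev[labs[g - 1], ] + 1e-9))
  }
})

test_that("pyramid summaries compute shares and the sex gap", {
  p <- single_cell_pyramid("80-84", "male", 500)
  p$counts["80-84", "female"] <- 500
  s <- summarize_pyramid(p)
  expect_equal(s$share_30plus, 100)
  expect_equal(s$share_over65, 100)
  expect_equal(s$sex_gap_30plus, 0)
  q <- make_base_population(1e6, 22, 18, 0, seed = 1)
  q$counts[, "female"] <- q$counts[, "male"]  # force symmetry
  expect_equal(summarize_pyramid(q)$sex_gap_30plus, 0)
  empty <- single_cell_pyramid("0-4", "male", 0)
  expect_error(summarize_pyramid(empty), "zero total")
})

test_that("annual interpolation is linear, exact at knots, and monotone between them", {
  base <- make_base_population(1e6, 22, 18, 0, seed = 4)
  mort <- make_mortality_schedule(seed = 4)
  s <- project_series(base, mort, make_fertility_schedule(1.5), "medium", 2015)
  ann <- interpolate_years(s)
  expect_equal(names(ann), as.character(2005:2015))
  expect_equal(ann[["2010"]]$counts, s$pyramids[["2010"]]$counts)
  # hand-checkable linear formula: 2/5 of the way from 2005 to 2010
  expect_equal(ann[["2007"]]$counts,
               0.6 * s$pyramids[["2005"]]$counts +
               0.4 * s$pyramids[["2010"]]$counts, tolerance = 1e-12)
  # every interpolated cell lies between its bracketing knot values
  for (y in 2006:2009) {
    a <- s$pyramids[["2005"]]$counts; b <- s$pyramids[["2010"]]$counts
    v <- ann[[as.character(y)]]$counts
    expect_true(all(v >= pmin(a, b) - 1e-9 & v <= pmax(a, b) + 1e-9))
  }
  # constant series interpolates to itself
  flat <- structure(list(scenario = "custom",
                         pyramids = list(`2005` = base,
                                         `2010` = population_pyramid(2010, base$counts))),
                    class = "population_series")
  mid <- interpolate_years(flat, 2007)[[1]]
  expect_equal(mid$counts, base$counts, tolerance = 1e-12)
})
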