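# Shared builders for small deterministic test objects.

# Pyramid with a single occupied cell.
single_cell_pyramid <- function(label, sex, count, year = 2005) {
  groups <- fine_age_groups()
  counts <- matrix(0, nrow(groups), 2,
                   dimnames = list(groups$label, c("male", "female")))
  counts[label, sex] <- count
  population_pyramid(year, counts)
}

# Mortality schedule with uniform survivorship everywhere.
flat_mortality <- function(s = 1, birth = 1) {
  groups <- fine_age_groups()
  list(survival = matrix(s, nrow(groups), 2,
                         dimnames = list(groups$label, c("male", "female"))),
       birth_survival = c(male = birth, female = birth))
}

# Fertility schedule that is zero except (optionally) one group.
spot_fertility <- function(group = NULL, asfr = 0, srb = 1.05) {
  f <- make_fertility_schedule(1)  # shape irrelevant, overwritten
  f$asfr[] <- 0
  if (!is.null(group)) f$asfr[group] <- asfr
  f$srb <- srb
  f
}

# Hand-rolled OLS via normal equations: the independent oracle for
# fit_rate_line.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Coarse table holding given rates for one stratum.
coarse_table_from_rates <- function(rates, stratum = "both") {
  g <- coarse_age_groups()
  out <- data.frame(sex = stratum, age_lo = g$age_lo, age_hi = g$age_hi,
                    rate_per_100k = rates, stringsAsFactors = FALSE)
  class(out) <- c("coarse_burden_table", "data.frame")
  out
}
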