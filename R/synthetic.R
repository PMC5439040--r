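#' Generate a synthetic base-year population pyramid
#'
#' Builds a pyramid with a unimodal (discretised Gaussian) age profile —
#' emulating the young-adult bulge of the 2005 Iranian population — with
#' an exact grand total and an exact male-minus-female gap among those
#' aged 30 and over. A small seeded multiplicative jitter roughens the
#' profile so downstream code never relies on a perfectly smooth shape.
#'
#' @param total_size grand total person-count (> 0).
#' @param bulge_age age (years, 0-100) at which the profile peaks.
#' @param spread standard deviation (years, > 0) of the Gaussian profile.
#' @param sex_gap_30plus male-minus-female person-count difference among
#'   ages 30+, enforced exactly (mass is transferred between the sexes
#'   within the 30+ groups, so the total is unaffected).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param floor baseline weight added to every age group, as a fraction
#'   of the peak weight (default 0: pure Gaussian profile).
#' @param jitter_sd standard deviation of the lognormal cell jitter
#'   (default 0.005, small enough to never displace the modal group;
#'   0 disables).
#' @return a [population_pyramid()] for `reference_year` (default 2005).
#' @param reference_year calendar year the pyramid describes.
#' @export
#' @examples
#' p <- make_base_population(70122200, bulge_age = 22, spread = 18,
#'                           sex_gap_30plus = 889000, seed = 1)
#' summarize_pyramid(p)
make_base_population <- function(total_size, bulge_age = 22, spread = 18,
                                 sex_gap_30plus = 0, seed = 1,
                                 floor = 0, jitter_sd = 0.005,
                                 reference_year = 2005) {
  if (!is.finite(total_size) || total_size <= 0)
    stop("`total_size` must be positive")
  if (!is.finite(spread) || spread <= 0)
    stop("`spread` must be positive")
  if (bulge_age < 0 || bulge_age > 100)
    stop("`bulge_age` must lie in [0, 100]")
  groups <- fine_age_groups()
  mid <- group_midpoint(groups$age_lo, groups$age_hi)
  mid[is.na(groups$age_hi)] <- 102.5  # nominal centre of the 100+ group
  w <- exp(-((mid - bulge_age) / spread)^2 / 2)
  w <- w + floor * max(w)
  if (jitter_sd > 0) {
    rng <- local_rng(seed)
    w <- w * exp(rng$rnorm(length(w), sd = jitter_sd))
  }
  counts <- cbind(male = w / 2, female = w / 2)
  counts <- counts * (total_size / sum(counts))
  # enforce the 30+ sex gap exactly by a within-30+ transfer
  i30 <- groups$age_lo >= 30
  gap0 <- sum(counts[i30, "male"]) - sum(counts[i30, "female"])
  delta <- (sex_gap_30plus - gap0) / 2
  m30 <- sum(counts[i30, "male"]); f30 <- sum(counts[i30, "female"])
  counts[i30, "male"]   <- counts[i30, "male"]   * (m30 + delta) / m30
  counts[i30, "female"] <- counts[i30, "female"] * (f30 - delta) / f30
  if (any(counts < 0))
    stop("`sex_gap_30plus` too large for the requested profile")
  population_pyramid(reference_year, counts)
}

# Self-contained RNG stream: seeded draws that do not disturb (and are not
# disturbed by) the global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  assign("state", {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }, envir = env)
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", get("state", env), envir = globalenv())
    out <- fn(...)
    assign("state", get(".Random.seed", globalenv()), envir = env)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
       runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max))
}

#' Generate a synthetic survivorship schedule
#'
#' Five-year survivorship proportions by sex and age group following a
#' Gompertz mortality law (hazard growing exponentially with age), with
#' a childhood dip, a small seeded jitter, weakly decreasing survivorship
#' beyond age 30, and the 30-34 survivorship anchored at
#' `adult_level * 0.995` in both sexes. Female old-age hazards grow
#' slightly more slowly than male ones.
#'
#' @param adult_level overall adult survival level in (0, 1]; 1 gives a
#'   30-34 five-year survivorship of 0.995.
#' @param seed integer seed (jitter only); output is deterministic given
#'   the seed.
#' @return object of class `mortality_schedule`: list with `survival`
#'   (21 x 2 matrix in \[0,1\]) and `birth_survival` (named vector, the
#'   proportion of births surviving into the 0-4 group).
#' @export
make_mortality_schedule <- function(adult_level = 1, seed = 1) {
  if (!is.finite(adult_level) || adult_level <= 0 || adult_level > 1)
    stop("`adult_level` must lie in (0, 1]")
  groups <- fine_age_groups()
  mid <- group_midpoint(groups$age_lo, groups$age_hi)
  mid[is.na(groups$age_hi)] <- 102.5
  rng <- local_rng(seed)
  growth <- c(male = 0.088, female = 0.082)  # Gompertz log-hazard slope
  surv <- sapply(SEXES, function(sex) {
    h <- exp(growth[[sex]] * (mid - 32))            # relative hazard
    h[groups$age_lo < 15] <- h[groups$age_lo < 15] * c(4, 1.5, 1)  # childhood dip
    h <- h * exp(rng$rnorm(length(h), sd = 0.03))
    adult <- groups$age_lo >= 30
    h[adult] <- cummax(h[adult])                    # monotone hazard beyond 30
    # anchor: 5-year survival in 30-34 equals 0.995 before level scaling
    h <- h * (-log(0.995) / h[groups$age_lo == 30])
    pmin(exp(-h), 1)
  })
  dimnames(surv) <- list(groups$label, SEXES)
  surv <- surv * adult_level
  structure(list(survival = surv,
                 birth_survival = c(male = 0.99, female = 0.992) * adult_level),
            class = "mortality_schedule")
}

#' Generate a synthetic age-specific fertility schedule
#'
#' A standard hump-shaped age-specific fertility rate (ASFR) profile over
#' maternal ages 15-49 (Gaussian in age, centred at 27), normalised so
#' the implied total fertility rate (TFR = 5 x sum of the seven 5-year
#' group ASFRs) equals `tfr_target` exactly.
#'
#' @param tfr_target implied total fertility rate, children per woman (> 0).
#' @param srb sex ratio at birth, male births per female birth (> 0;
#'   default 1.05, the demographic convention).
#' @param peak_age,width centre and spread (years) of the ASFR hump.
#' @return object of class `fertility_schedule`: list with `asfr` (named
#'   vector, births per woman per year, groups 15-19 ... 45-49) and `srb`.
#' @export
#' @examples
#' f <- make_fertility_schedule(2.1)
#' 5 * sum(f$asfr)  # 2.1
make_fertility_schedule <- function(tfr_target, srb = 1.05,
                                    peak_age = 27, width = 6) {
  if (!is.finite(tfr_target) || tfr_target <= 0)
    stop("`tfr_target` must be positive")
  if (!is.finite(srb) || srb <= 0) stop("`srb` must be positive")
  mids <- seq(17.5, 47.5, by = 5)
  shape <- exp(-((mids - peak_age) / width)^2 / 2)
  asfr <- shape * tfr_target / (5 * sum(shape))
  names(asfr) <- age_group_label(seq(15L, 45L, 5L), seq(19L, 49L, 5L))
  structure(list(asfr = asfr, srb = srb), class = "fertility_schedule")
}

implied_tfr <- function(fertility) 5 * sum(fertility$asfr)

#' Generate a synthetic coarse-age-group DALY rate table
#'
#' Evaluates per-stratum rate lines at the midpoints of the five coarse
#' adult age groups (30-44, 45-59, 60-69, 70-79, 80+) and adds Gaussian
#' noise on the rate scale, truncated at zero — the noise model under
#' which ordinary least-squares refitting is unbiased. This emulates the
#' coarse DALY-rate inputs of a national burden-of-disease study.
#'
#' @param lines a single [rate_line()] or a list of them (one per
#'   stratum, e.g. [reference_rate_lines()]).
#' @param noise_sd standard deviation of the additive rate noise, per
#'   100,000 (>= 0; 0 reproduces the lines exactly at the midpoints).
#' @param seed integer seed; deterministic given the seed.
#' @return a `coarse_burden_table`: data.frame with columns `sex`,
#'   `age_lo`, `age_hi`, `rate_per_100k`.
#' @export
#' @examples
#' make_coarse_daly_table(reference_rate_lines(), noise_sd = 0)
make_coarse_daly_table <- function(lines, noise_sd = 0, seed = 1) {
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (inherits(lines, "rate_line")) lines <- list(lines)
  groups <- coarse_age_groups()
  mid <- group_midpoint(groups$age_lo, groups$age_hi)
  rng <- local_rng(seed)
  rows <- lapply(lines, function(ln) {
    rate <- ln$intercept + ln$slope * mid
    if (noise_sd > 0) rate <- rate + rng$rnorm(length(rate), sd = noise_sd)
    data.frame(sex = ln$stratum, age_lo = groups$age_lo, age_hi = groups$age_hi,
               rate_per_100k = pmax(rate, 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coarse_burden_table", "data.frame")
  out
}

#' @rdname make_coarse_daly_table
#' @param table a `coarse_burden_table`.
#' @param path,file CSV path (`sex,age_lo,age_hi,rate_per_100k`).
#' @export
write_coarse_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname make_coarse_daly_table
#' @export
read_coarse_table_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sex", "age_lo", "age_hi", "rate_per_100k")
  if (!all(need %in% names(df)))
    stop("coarse table CSV must have columns ", paste(need, collapse = ","))
  class(df) <- c("coarse_burden_table", "data.frame")
  df
}
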