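# Builders for small, fully controlled configurations used across the suite.

# A configuration with point-mass distributions and constant penetration.
# `tavr`/`savr` are year-named count vectors; unspecified horizon years are
# zero. Ages, durabilities and survivals are degenerate unless an sd is
# given, so outcomes are hand-countable.
tiny_config <- function(start_year = 2000L, end_year = 2012L,
                        tavr = NULL, savr = NULL,
                        age = 75L,
                        dur_tavr = 5, dur_savr_lt70 = 5, dur_savr_ge70 = 5,
                        dur_sd = 0,
                        surv = 10, surv_sd = 0,
                        pen_tavr = 1, pen_savr = 1,
                        redo = NULL,
                        n_replicates = 1L, master_seed = 1L, ...) {
  years <- seq(start_year, end_year)
  mk <- function(named, class) {
    counts <- integer(length(years))
    if (!is.null(named)) {
      idx <- match(as.integer(names(named)), years)
      stopifnot(!anyNA(idx))
      counts[idx] <- as.integer(named)
    }
    volume_series(class, years, counts, "synthetic")
  }
  w <- numeric(36)
  w[age - 59L] <- 1
  if (is.null(redo)) {
    redo <- data.frame(year = years, savr_after_savr = 0L,
                       savr_after_tavr = 0L)
  }
  pm <- function(m, s = dur_sd) data.frame(weight = 1, mean_years = m,
                                           sd_years = s)
  args <- list(
    start_year = start_year, end_year = end_year,
    n_replicates = n_replicates, master_seed = master_seed,
    tavr_volumes = mk(tavr, "TAVR"), savr_volumes = mk(savr, "SAVR"),
    age_model = list(support = 60:95, weights = w),
    risk_mix = data.frame(
      proc = c("TAVR", "SAVR"), from = start_year,
      to_excl = end_year + 1L, fraction_low_risk = 0,
      stringsAsFactors = FALSE),
    durability_models = list(TAVR = list(components = pm(dur_tavr)),
                             SAVR_lt70 = list(components = pm(dur_savr_lt70)),
                             SAVR_ge70 = list(components = pm(dur_savr_ge70))),
    survival_models = list(
      low = list(family = "normal", median_years = surv, sd_years = surv_sd),
      intermediate_high = list(family = "normal", median_years = surv,
                               sd_years = surv_sd)),
    penetration = list(
      TAVR = data.frame(year = start_year, fraction = pen_tavr),
      SAVR = data.frame(year = start_year, fraction = pen_savr)),
    redo_series = redo
  )
  extra <- list(...)
  for (nm in names(extra)) args[[nm]] <- extra[[nm]]
  do.call(simulation_config, args)
}

# A randomized degenerate scenario: point masses everywhere, penetration in
# {0, 1}, optional random redo counts. Deterministic given the stream state.
random_degenerate_config <- function() {
  start <- sample(1995:2005, 1)
  end <- start + sample(5:15, 1)
  years <- seq(start, end)
  pick_cohorts <- function() {
    k <- sample(0:3, 1)
    if (k == 0L) return(NULL)
    ys <- sample(years, k)
    stats::setNames(sample(1:200, k, replace = TRUE), ys)
  }
  redo <- data.frame(
    year = years,
    savr_after_savr = sample(0:30, length(years), replace = TRUE),
    savr_after_tavr = sample(0:30, length(years), replace = TRUE))
  tiny_config(
    start_year = start, end_year = end,
    tavr = pick_cohorts(), savr = pick_cohorts(),
    age = sample(60:95, 1),
    dur_tavr = round(runif(1, 0.5, 12), 2),
    dur_savr_lt70 = round(runif(1, 0.5, 12), 2),
    dur_savr_ge70 = round(runif(1, 0.5, 12), 2),
    surv = round(runif(1, 0.5, 15), 2),
    pen_tavr = sample(0:1, 1), pen_savr = sample(0:1, 1),
    redo = redo)
}
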