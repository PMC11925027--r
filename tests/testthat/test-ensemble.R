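# construct a bare ensemble summary for the pure-arithmetic operations
fake_summary <- function(years, tins, tint) {
  out <- data.frame(year = years, tins_mean = tins, tins_sd = 0,
                    tint_mean = tint, tint_sd = 0,
                    total_mean = tins + tint, total_sd = 0)
  class(out) <- c("viv_ensemble", "data.frame")
  attr(out, "n_replicates") <- 1L
  out
}

test_that("ensemble means are exactly the average of the replicates", {
  sc <- synthesize_scenario("linear-growth",
                            list(from = 2000, to = 2012, tavr_intercept = 400,
                                 tavr_slope = 100, savr_intercept = 900,
                                 savr_slope = 0))
  cfg <- tiny_config(start_year = 2000L, end_year = 2012L, dur_sd = 2,
                     surv_sd = 3, surv = 8, pen_tavr = 0.5, pen_savr = 0.5,
                     tavr_volumes = sc$tavr, savr_volumes = sc$savr,
                     n_replicates = 6L, master_seed = 31L)
  ens <- run_ensemble(cfg)
  reps <- attr(ens, "replicates")
  expect_length(reps, 6L)
  tot <- sapply(reps, `[[`, "total_viv")
  expect_equal(ens$total_mean, rowMeans(tot))
  expect_equal(ens$total_sd, apply(tot, 1, stats::sd))
  expect_equal(ens$total_mean, ens$tins_mean + ens$tint_mean,
               tolerance = 1e-12)
  expect_true(all(ens$total_sd >= 0))
})

test_that("degenerate scenarios have zero ensemble dispersion", {
  cfg1 <- tiny_config(tavr = c(`2000` = 100), n_replicates = 1L)
  e1 <- run_ensemble(cfg1)
  expect_true(all(e1$total_sd == 0))  # single replicate: SD 0 by convention

  cfg5 <- tiny_config(tavr = c(`2000` = 100), n_replicates = 5L)
  e5 <- run_ensemble(cfg5)
  expect_true(all(e5$total_sd == 0))  # point masses, penetration 1
  expect_identical(e5$tint_mean[e5$year == 2005], 100)
})

test_that("per-year summaries are the sample mean and n-1 sample SD of the replicates", {
  cfg <- tiny_config(tavr = c(`2005` = 2000), dur_tavr = 3, surv = 9,
                     pen_tavr = 0.5, n_replicates = 2L, master_seed = 8L,
                     start_year = 2000L, end_year = 2010L)
  ens <- run_ensemble(cfg)
  reps <- sapply(attr(ens, "replicates"), `[[`, "total_viv")
  y <- which(ens$year == 2008)
  expect_equal(ens$total_mean[y], mean(reps[y, ]))
  expect_equal(ens$total_sd[y], stats::sd(reps[y, ]))
})

test_that("the ViV share follows the all-TAVR denominator convention", {
  years <- 2020:2022
  tavr <- volume_series("TAVR", years, c(85, 85, 85), "synthetic")
  s0 <- fake_summary(years, tins = c(0, 0, 0), tint = c(0, 0, 0))
  expect_equal(viv_share(s0, tavr, 2021), 0)
  s <- fake_summary(years, tins = c(10, 10, 10), tint = c(5, 5, 5))
  expect_equal(viv_share(s, tavr, 2021), 0.15)  # 15 / (85 + 15)
  expect_equal(viv_share(s, tavr, 2021, series_includes_viv = TRUE), 15 / 85)
  expect_error(viv_share(s, tavr, 2035), "not in ensemble horizon")
})

test_that("crossover scanning finds the first catch-up year", {
  years <- 2025:2030
  none <- fake_summary(years, tins = rep(100, 6), tint = rep(0, 6))
  expect_true(is.na(crossover_year(none, 0.9)))

  equal <- fake_summary(years, tins = rep(100, 6), tint = rep(100, 6))
  expect_identical(crossover_year(equal, 1.0), 2025L)

  ramp <- fake_summary(years,
                       tins = rep(100, 6),
                       tint = c(10, 50, 80, 95, 120, 150))
  expect_identical(crossover_year(ramp, 0.9), 2028L)
  expect_identical(crossover_year(ramp, 1.0), 2029L)
  expect_error(crossover_year(ramp, 0), "threshold")
})

test_that("outputs are written completely and deterministically", {
  cfg <- tiny_config(tavr = c(`2000` = 100), start_year = 2000L,
                     end_year = 2006L, n_replicates = 3L)
  ens <- run_ensemble(cfg)
  hl <- headline_summary(ens, cfg$tavr_volumes, share_year = 2005L,
                         sd_years = 2006L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_outputs(ens, hl, d1, config = cfg)
  write_outputs(ens, hl, d2, config = cfg)

  lines <- readLines(file.path(d1, "forecast.csv"))
  expect_identical(lines[1],
                   "year,tinS_mean,tinS_sd,tinT_mean,tinT_sd,total_mean,total_sd")
  expect_identical(lines[grepl("^2005,", lines)], "2005,0,0,100,0,100,0")
  expect_identical(lines, readLines(file.path(d2, "forecast.csv")))

  hj <- jsonlite::read_json(file.path(d1, "headline.json"))
  expect_true("crossover_year" %in% names(hj))
  expect_equal(as.numeric(hj$crossover_year), 2005)

  # absent crossover is serialized as an explicit null
  none <- fake_summary(2020:2022, tins = rep(100, 3), tint = rep(0, 3))
  attr(none, "n_replicates") <- 1L
  tavr <- volume_series("TAVR", 2020:2022, rep(1000, 3))
  hl0 <- headline_summary(none, tavr, sd_years = integer(0))
  d3 <- withr::local_tempdir()
  write_outputs(none, hl0, d3)
  raw <- paste(readLines(file.path(d3, "headline.json")), collapse = "")
  expect_match(raw, "\"crossover_year\"\\s*:\\s*null")
})

test_that("ensemble dispersion scales roughly with the square root of volume", {
  mk <- function(n) {
    tiny_config(tavr = stats::setNames(n, 2000), start_year = 2000L,
                end_year = 2006L, dur_tavr = 5, surv = 20, pen_tavr = 0.5,
                n_replicates = 100L, master_seed = 13L)
  }
  e1 <- run_ensemble(mk(10000L))
  e2 <- run_ensemble(mk(20000L))
  sd1 <- e1$total_sd[e1$year == 2005]
  sd2 <- e2$total_sd[e2$year == 2005]
  expect_gt(sd1, 0)
  ratio <- sd2 / sd1
  expect_gt(ratio, 1.15)
  expect_lt(ratio, 1.75)
})
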