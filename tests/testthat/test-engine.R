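test_that("cohort simulation applies the competing-risk filter", {
  cfg <- tiny_config(tavr = c(`2000` = 100), dur_tavr = 5, surv = 10)
  ev <- simulate_cohort(2000, "TAVR", 100, cfg, seed = 1L)
  expect_identical(nrow(ev), 100L)
  expect_true(all(ev$candidate))
  expect_true(all(ev$failure_year == 2005L))

  # durability beyond survival: patients die before the valve fails
  cfg2 <- tiny_config(tavr = c(`2000` = 100), dur_tavr = 10, surv = 6)
  ev2 <- simulate_cohort(2000, "TAVR", 100, cfg2, seed = 1L)
  expect_identical(nrow(ev2), 100L)
  expect_false(any(ev2$candidate))

  expect_identical(nrow(simulate_cohort(2000, "TAVR", 0, cfg)), 0L)
})

test_that("failure-year rule floor vs round is honoured", {
  cfg <- tiny_config(tavr = c(`2000` = 10), dur_tavr = 5.7, surv = 20)
  ev <- simulate_cohort(2000, "TAVR", 10, cfg, seed = 1L)
  expect_true(all(ev$failure_year == 2005L))
  cfg_r <- tiny_config(tavr = c(`2000` = 10), dur_tavr = 5.7, surv = 20,
                       failure_year_rule = "round")
  ev_r <- simulate_cohort(2000, "TAVR", 10, cfg_r, seed = 1L)
  expect_true(all(ev_r$failure_year == 2006L))
})

test_that("redo subtraction removes surgical redo patients, clamped at zero", {
  redo <- data.frame(year = 2000:2002, savr_after_savr = c(0L, 30L, 25L),
                     savr_after_tavr = c(5L, 0L, 0L))
  pool <- data.frame(year = 2000:2002, count = c(100L, 100L, 10L))
  out <- subtract_redo(pool, "SAVR", redo)
  expect_identical(out$count, c(100, 70, 0))
  out_t <- subtract_redo(pool, "TAVR", redo)
  expect_identical(out_t$count, c(95, 100, 10))
  zero <- data.frame(year = 2000:2002, savr_after_savr = 0L,
                     savr_after_tavr = 0L)
  expect_identical(subtract_redo(pool, "SAVR", zero)$count,
                   as.numeric(pool$count))
  expect_error(subtract_redo(data.frame(year = 1990, count = 1), "SAVR", redo),
               "1990")
})

test_that("penetration thinning is Bernoulli with the scheduled fraction", {
  sched0 <- list(SAVR = data.frame(year = 2000, fraction = 0),
                 TAVR = data.frame(year = 2000, fraction = 0))
  sched1 <- list(SAVR = data.frame(year = 2000, fraction = 1),
                 TAVR = data.frame(year = 2000, fraction = 1))
  pool <- data.frame(year = 2018:2022, count = c(0L, 5L, 10000L, 7L, 3L))
  expect_true(all(apply_penetration(pool, "SAVR", sched0, seed = 1)$count == 0))
  expect_identical(apply_penetration(pool, "SAVR", sched1, seed = 1)$count,
                   as.integer(pool$count))

  sched <- list(SAVR = data.frame(year = 2000, fraction = 0.60))
  treated <- apply_penetration(data.frame(year = 2020, count = 10000L),
                               "SAVR", sched, seed = 42)$count
  se <- sqrt(10000 * 0.6 * 0.4)  # ~49
  expect_lt(abs(treated - 6000), 4 * se)
})

test_that("a degenerate full pipeline matches its hand count", {
  cfg <- tiny_config(tavr = c(`2000` = 100), dur_tavr = 5, surv = 10,
                     pen_tavr = 1, pen_savr = 1)
  f <- run_single_replicate(cfg, 7L)
  expect_identical(f$tavr_in_tavr[f$year == 2005], 100L)
  expect_identical(sum(f$total_viv), 100L)
  expect_true(all(f$tavr_in_savr == 0L))
  expect_identical(f$total_viv, f$tavr_in_savr + f$tavr_in_tavr)

  f0 <- run_single_replicate(tiny_config(tavr = c(`2000` = 100), pen_tavr = 0),
                             7L)
  expect_true(all(f0$total_viv == 0L))

  fd <- run_single_replicate(tiny_config(tavr = c(`2000` = 100), dur_tavr = 5,
                                         surv = 3), 7L)
  expect_true(all(fd$total_viv == 0L))
})

test_that("the engine equals a brute-force oracle on randomized degenerate scenarios", {
  set.seed(20240339)
  for (i in 1:25) {
    cfg <- random_degenerate_config()
    got <- run_single_replicate(cfg, i)
    want <- oracle_forecast(cfg)
    expect_identical(got$tavr_in_savr, as.integer(want$tavr_in_savr))
    expect_identical(got$tavr_in_tavr, as.integer(want$tavr_in_tavr))
    expect_identical(got$total_viv, as.integer(want$total_viv))
  }
})

test_that("identical configuration and seed give bit-identical forecasts", {
  sc <- synthesize_scenario("linear-growth",
                            list(from = 2000, to = 2015, tavr_intercept = 500,
                                 tavr_slope = 200, savr_intercept = 1000,
                                 savr_slope = 0))
  cfg <- tiny_config(start_year = 2000L, end_year = 2015L, dur_sd = 2,
                     surv_sd = 3, pen_tavr = 0.4, pen_savr = 0.7,
                     tavr_volumes = sc$tavr, savr_volumes = sc$savr)
  expect_identical(run_single_replicate(cfg, 11L),
                   run_single_replicate(cfg, 11L))
  # a different seed produces a different realisation
  expect_false(identical(run_single_replicate(cfg, 11L)$total_viv,
                         run_single_replicate(cfg, 12L)$total_viv))
})

test_that("no patient returns more than once: treated totals never exceed seeding", {
  sc <- synthesize_scenario("linear-growth",
                            list(from = 2000, to = 2015, tavr_intercept = 200,
                                 tavr_slope = 100, savr_intercept = 800,
                                 savr_slope = 20))
  cfg <- tiny_config(start_year = 2000L, end_year = 2015L, dur_sd = 3,
                     surv_sd = 4, surv = 8, dur_tavr = 6, dur_savr_lt70 = 7,
                     dur_savr_ge70 = 9, pen_tavr = 1, pen_savr = 1,
                     tavr_volumes = sc$tavr, savr_volumes = sc$savr)
  f <- run_single_replicate(cfg, 5L)
  expect_lte(sum(f$tavr_in_tavr), sum(sc$tavr$count))
  expect_lte(sum(f$tavr_in_savr), sum(sc$savr$count))
  expect_true(all(f$total_viv >= 0L))
})

test_that("raising a penetration anchor never lowers any annual count (common random numbers)", {
  sc <- synthesize_scenario("linear-growth",
                            list(from = 2000, to = 2015, tavr_intercept = 500,
                                 tavr_slope = 150, savr_intercept = 1500,
                                 savr_slope = 0))
  base_pen <- list(
    TAVR = data.frame(year = c(2005L, 2015L), fraction = c(0.1, 0.5)),
    SAVR = data.frame(year = c(2005L, 2015L), fraction = c(0.4, 0.6)))
  mk <- function(pen) {
    tiny_config(start_year = 2000L, end_year = 2015L, dur_sd = 2,
                surv_sd = 3, surv = 9, pen_tavr = 1, pen_savr = 1,
                tavr_volumes = sc$tavr, savr_volumes = sc$savr,
                penetration = pen)
  }
  f0 <- run_single_replicate(mk(base_pen), 3L)
  for (tp in c("TAVR", "SAVR")) {
    for (anchor in 1:2) {
      pen <- base_pen
      pen[[tp]]$fraction[anchor] <- min(1, pen[[tp]]$fraction[anchor] + 0.3)
      f1 <- run_single_replicate(mk(pen), 3L)
      expect_true(all(f1$tavr_in_tavr >= f0$tavr_in_tavr))
      expect_true(all(f1$tavr_in_savr >= f0$tavr_in_savr))
    }
  }
})

test_that("extending the horizon leaves earlier years' draws untouched", {
  sc <- synthesize_scenario("linear-growth",
                            list(from = 2000, to = 2010, tavr_intercept = 300,
                                 tavr_slope = 100, savr_intercept = 500,
                                 savr_slope = 0))
  cfg_short <- tiny_config(start_year = 2000L, end_year = 2010L, dur_sd = 2,
                           surv_sd = 2, surv = 7, pen_tavr = 0.5,
                           pen_savr = 0.5, tavr_volumes = sc$tavr,
                           savr_volumes = sc$savr)
  long_tavr <- pad_zero_years(sc$tavr, to = 2015L)
  long_savr <- pad_zero_years(sc$savr, to = 2015L)
  cfg_long <- tiny_config(start_year = 2000L, end_year = 2015L, dur_sd = 2,
                          surv_sd = 2, surv = 7, pen_tavr = 0.5,
                          pen_savr = 0.5, tavr_volumes = long_tavr,
                          savr_volumes = long_savr)
  f_short <- run_single_replicate(cfg_short, 21L)
  f_long <- run_single_replicate(cfg_long, 21L)
  expect_identical(f_short$total_viv,
                   f_long$total_viv[f_long$year <= 2010])
})
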