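# Independent oracles, implemented without reusing the engine's code paths.

# Brute-force forecast for configurations whose age, durability and survival
# are point masses and whose penetration is 0 or 1 everywhere: a direct loop
# over cohorts applying the model's rules one by one.
oracle_forecast <- function(config) {
  years <- seq(config$start_year, config$end_year)
  pool <- list(TAVR = stats::setNames(numeric(length(years)), years),
               SAVR = stats::setNames(numeric(length(years)), years))
  age <- config$age_model$support[which(config$age_model$weights > 0)]
  stopifnot(length(age) == 1L)
  surv_raw <- config$survival_models$low$median_years
  stopifnot(surv_raw == config$survival_models$intermediate_high$median_years)
  surv <- min(surv_raw, (config$survival_age_cap %||% 100) - age)
  for (proc in c("TAVR", "SAVR")) {
    series <- if (proc == "TAVR") config$tavr_volumes else config$savr_volumes
    dur <- if (proc == "TAVR") {
      config$durability_models$TAVR$components$mean_years
    } else if (age < (config$savr_age_split %||% 70)) {
      config$durability_models$SAVR_lt70$components$mean_years
    } else {
      config$durability_models$SAVR_ge70$components$mean_years
    }
    for (i in seq_len(nrow(series))) {
      y <- series$year[i]; n <- series$count[i]
      if (n == 0L || y < config$start_year || y > config$end_year) next
      if (!(dur < surv)) next        # died before the valve failed
      fy <- if (identical(config$failure_year_rule, "round")) {
        y + round(dur)
      } else {
        y + floor(dur)
      }
      if (fy <= config$end_year) {
        pool[[proc]][as.character(fy)] <- pool[[proc]][as.character(fy)] + n
      }
    }
  }
  res <- data.frame(year = years, tavr_in_savr = 0L, tavr_in_tavr = 0L)
  for (ft in c("TAVR", "SAVR")) {
    counts <- pool[[ft]]
    col <- if (ft == "SAVR") "savr_after_savr" else "savr_after_tavr"
    for (y in years) {
      k <- as.character(y)
      c0 <- max(counts[[k]] - config$redo_series[[col]][
        config$redo_series$year == y], 0)
      p <- oracle_penetration(config$penetration[[ft]], y)
      stopifnot(p %in% c(0, 1))
      val <- if (p == 1) c0 else 0
      if (ft == "SAVR") {
        res$tavr_in_savr[res$year == y] <- val
      } else {
        res$tavr_in_tavr[res$year == y] <- val
      }
    }
  }
  res$total_viv <- res$tavr_in_savr + res$tavr_in_tavr
  res
}

oracle_penetration <- function(anchors, year) {
  if (nrow(anchors) == 1L) return(anchors$fraction)
  if (year <= anchors$year[1L]) return(anchors$fraction[1L])
  n <- nrow(anchors)
  if (year >= anchors$year[n]) return(anchors$fraction[n])
  i <- findInterval(year, anchors$year)
  y0 <- anchors$year[i]; y1 <- anchors$year[i + 1L]
  f0 <- anchors$fraction[i]; f1 <- anchors$fraction[i + 1L]
  f0 + (f1 - f0) * (year - y0) / (y1 - y0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form CDF of a normal mixture truncated to (0, Inf); used as the
# reference law in Kolmogorov-Smirnov checks of the samplers.
oracle_truncmix_cdf <- function(components) {
  G <- function(q) {
    sapply(q, function(qq) {
      sum(components$weight *
            stats::pnorm(qq, components$mean_years, components$sd_years))
    })
  }
  g0 <- G(0)
  function(q) pmax(0, (G(q) - g0) / (1 - g0))
}

# Mean of N(mu, sigma) truncated to (0, Inf).
oracle_truncnorm_mean <- function(mu, sigma) {
  a <- -mu / sigma
  mu + sigma * stats::dnorm(a) / (1 - stats::pnorm(a))
}
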