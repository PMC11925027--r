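#' Simulate one seeding cohort
#'
#' Samples `n` patients implanted in `year` with procedure `proc`: age,
#' risk class, valve durability and post-procedure survival. Each patient
#' yields one failure event; the event is a ViV *candidate* only when the
#' valve degenerates strictly before death (`durability < survival`,
#' the competing-risk filter). Non-candidates are retained, flagged, for
#' audit and excluded downstream. The failure calendar year is
#' `year + floor(durability)` under the default rule (`"round"` is
#' available for sensitivity runs).
#'
#' @param year seeding calendar year.
#' @param proc `"TAVR"` or `"SAVR"`.
#' @param n cohort size (>= 0).
#' @param config a `viv_config`.
#' @param seed optional integer; if given, the global stream is positioned
#'   with `set.seed(seed)` before sampling.
#' @return data frame with columns `index_type`, `index_year`,
#'   `age_at_index`, `risk_class`, `durability_years`, `survival_years`,
#'   `failure_year`, `candidate`.
#' @export
simulate_cohort <- function(year, proc, n, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n < 0L) stop("cohort size must be >= 0")
  age <- sample_age(n, config$age_model)
  risk <- assign_risk_class(n, year, proc, config$risk_mix)
  dur <- sample_durability(n, proc, age, config$durability_models,
                           age_split = config$savr_age_split %||% 70L)
  surv <- sample_survival(n, risk, age, config$survival_models,
                          cap = config$survival_age_cap %||% 100L)
  fy <- if (identical(config$failure_year_rule, "round")) {
    as.integer(year + round(dur))
  } else {
    as.integer(year + floor(dur))
  }
  data.frame(
    index_type = rep(proc, n),
    index_year = rep(as.integer(year), n),
    age_at_index = age,
    risk_class = risk,
    durability_years = dur,
    survival_years = surv,
    failure_year = fy,
    candidate = dur < surv,
    stringsAsFactors = FALSE
  )
}

#' Subtract redo surgical procedures from the candidate pool
#'
#' Patients treated by redo *surgery* leave the transcatheter candidate
#' pool: SAVR-after-SAVR counts are removed from SAVR-failure candidates
#' and SAVR-after-TAVR (surgical TAVR explant) counts from TAVR-failure
#' candidates, clamped at zero.
#'
#' @param candidates_by_year data frame with columns `year`, `count`.
#' @param failure_type `"TAVR"` or `"SAVR"` (the failed valve's type).
#' @param redo the configuration's `redo_series` table.
#' @return the input with `count` reduced.
#' @export
subtract_redo <- function(candidates_by_year, failure_type, redo) {
  idx <- match(candidates_by_year$year, redo$year)
  if (anyNA(idx)) {
    stop("redo series undefined for year ",
         candidates_by_year$year[which(is.na(idx))[1L]])
  }
  col <- if (failure_type == "SAVR") "savr_after_savr" else "savr_after_tavr"
  candidates_by_year$count <- pmax(candidates_by_year$count - redo[[col]][idx],
                                   0)
  candidates_by_year
}

#' Apply the treatment-penetration schedule by Bernoulli thinning
#'
#' Each failed-valve candidate is independently treated with the year's
#' penetration fraction. Thinning is per patient (one uniform per
#' candidate, in year order), not a deterministic rounding of expectations,
#' so replicate-to-replicate dispersion is meaningful and, under common
#' random numbers, raising the schedule pointwise never decreases any
#' annual treated count.
#'
#' @param candidates_by_year data frame with columns `year`, `count`.
#' @param failure_type `"TAVR"` or `"SAVR"`.
#' @param schedule the configuration's `penetration` list.
#' @param seed optional integer stream position.
#' @return the input data frame with `count` replaced by treated counts.
#' @export
apply_penetration <- function(candidates_by_year, failure_type, schedule,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  o <- order(candidates_by_year$year)
  candidates_by_year <- candidates_by_year[o, , drop = FALSE]
  p <- penetration_at(schedule, failure_type, candidates_by_year$year)
  treated <- integer(nrow(candidates_by_year))
  for (i in seq_along(treated)) {
    n <- candidates_by_year$count[i]
    if (n > 0L) treated[i] <- sum(stats::runif(n) < p[i])
  }
  candidates_by_year$count <- treated
  candidates_by_year
}

#' Run one full model replicate
#'
#' Seeds every configured (year, procedure-class) cohort, collects
#' candidate failure events by calendar year and failed-valve type,
#' removes redo surgical procedures from each pool, applies the
#' penetration schedule, and returns annual TAVR-in-SAVR, TAVR-in-TAVR and
#' total ViV counts over the horizon. Failures beyond `end_year` are
#' discarded; treated ViV procedures are not re-entered as new index TAVR
#' (no third interventions). Each (seeding year, procedure class) cohort
#' and each penetration pass uses its own derived random stream, so the
#' result is a deterministic function of (config, replicate_seed).
#'
#' @param config a `viv_config`.
#' @param replicate_seed integer seed for this replicate's streams.
#' @return a `viv_forecast` data frame: `year`, `tavr_in_savr`,
#'   `tavr_in_tavr`, `total_viv`, with attribute `replicate_seed`.
#' @export
run_single_replicate <- function(config, replicate_seed) {
  years <- seq(config$start_year, config$end_year)
  n_years <- length(years)
  pools <- list(TAVR = integer(n_years), SAVR = integer(n_years))

  for (proc in c("TAVR", "SAVR")) {
    series <- if (proc == "TAVR") config$tavr_volumes else config$savr_volumes
    seeding <- series[series$year >= config$start_year &
                        series$year <= config$end_year & series$count > 0, ]
    for (i in seq_len(nrow(seeding))) {
      yr <- seeding$year[i]
      ev <- simulate_cohort(
        yr, proc, seeding$count[i], config,
        seed = mix_seed(replicate_seed, yr, .PROC_CODE[[proc]],
                        .RNG_PURPOSE[["cohort"]])
      )
      fy <- ev$failure_year[ev$candidate]
      fy <- fy[fy <= config$end_year]
      if (length(fy)) {
        pools[[proc]] <- pools[[proc]] +
          tabulate(fy - config$start_year + 1L, nbins = n_years)
      }
    }
  }

  treated <- list()
  for (ft in c("TAVR", "SAVR")) {
    pool <- data.frame(year = years, count = pools[[ft]])
    pen_seed <- mix_seed(replicate_seed, .PROC_CODE[[ft]],
                         .RNG_PURPOSE[["penetration"]])
    if (isTRUE(config$redo_before_penetration)) {
      pool <- subtract_redo(pool, ft, config$redo_series)
      pool <- apply_penetration(pool, ft, config$penetration, seed = pen_seed)
    } else {
      pool <- apply_penetration(pool, ft, config$penetration, seed = pen_seed)
      pool <- subtract_redo(pool, ft, config$redo_series)
    }
    treated[[ft]] <- pool$count
  }

  out <- data.frame(
    year = years,
    tavr_in_savr = as.integer(treated$SAVR),
    tavr_in_tavr = as.integer(treated$TAVR),
    total_viv = as.integer(treated$SAVR + treated$TAVR)
  )
  class(out) <- c("viv_forecast", "data.frame")
  attr(out, "replicate_seed") <- as.integer(replicate_seed)
  out
}
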