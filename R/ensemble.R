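#' Run the replicate ensemble
#'
#' Runs `n_replicates` independent replicates of the model with seeds
#' derived from the master seed and returns per-year sample means and
#' sample standard deviations (denominator n-1) of annual TAVR-in-SAVR,
#' TAVR-in-TAVR and total ViV counts. With a single replicate the SDs are
#' reported as 0 by convention.
#'
#' @param config a `viv_config`.
#' @return a `viv_ensemble` data frame: `year`, `tins_mean`, `tins_sd`,
#'   `tint_mean`, `tint_sd`, `total_mean`, `total_sd`; attributes
#'   `n_replicates`, `master_seed` and `replicates` (the per-replicate
#'   forecasts).
#' @export
run_ensemble <- function(config) {
  validate_config(config)
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    run_single_replicate(
      config, mix_seed(config$master_seed, r, .RNG_PURPOSE[["replicate"]]))
  })
  years <- reps[[1L]]$year
  col <- function(nm) {
    sapply(reps, function(f) f[[nm]])  # years x replicates
  }
  msd <- function(nm) {
    m <- matrix(col(nm), nrow = length(years))
    s <- if (ncol(m) > 1L) apply(m, 1L, stats::sd) else rep(0, length(years))
    list(mean = rowMeans(m), sd = s)
  }
  tins <- msd("tavr_in_savr"); tint <- msd("tavr_in_tavr")
  tot <- msd("total_viv")
  out <- data.frame(
    year = years,
    tins_mean = tins$mean, tins_sd = tins$sd,
    tint_mean = tint$mean, tint_sd = tint$sd,
    total_mean = tot$mean, total_sd = tot$sd
  )
  class(out) <- c("viv_ensemble", "data.frame")
  attr(out, "n_replicates") <- config$n_replicates
  attr(out, "master_seed") <- config$master_seed
  attr(out, "replicates") <- reps
  out
}

#' ViV share of all TAVR procedures in a year
#'
#' "All TAVR" is the native index TAVR volume plus the ViV TAVR performed
#' that year: `share = viv / (native + viv)`. If the configured TAVR
#' series already includes ViV procedures, set
#' `series_includes_viv = TRUE`, in which case `share = viv / series`.
#'
#' @param summary a `viv_ensemble`.
#' @param tavr_volumes the TAVR [volume_series()] used for seeding.
#' @param year calendar year.
#' @param series_includes_viv interpretation switch (default `FALSE`:
#'   series is native-only).
#' @return proportion in `[0, 1]`.
#' @export
viv_share <- function(summary, tavr_volumes, year,
                      series_includes_viv = FALSE) {
  i <- match(as.integer(year), summary$year)
  if (is.na(i)) stop("year ", year, " not in ensemble horizon")
  viv <- summary$total_mean[i]
  native <- as.numeric(volume_at(tavr_volumes, year))
  denom <- if (series_includes_viv) native else native + viv
  if (denom <= 0) stop("viv_share: zero TAVR denominator in ", year)
  viv / denom
}

#' First year TAVR-in-TAVR catches up with TAVR-in-SAVR
#'
#' Scans ensemble means for the smallest year with
#' `tint_mean >= threshold * tins_mean`. Years with zero TAVR-in-TAVR mean
#' cannot qualify (the all-zero early horizon is not a crossover).
#'
#' @param summary a `viv_ensemble`.
#' @param threshold proportion in `(0, 1]`; 0.9 operationalises "nearly
#'   match", 1.0 a strict crossover.
#' @return the calendar year, or `NA_integer_` if never reached.
#' @export
crossover_year <- function(summary, threshold = 0.9) {
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]")
  }
  hit <- summary$tint_mean > 0 &
    summary$tint_mean >= threshold * summary$tins_mean
  if (!any(hit)) return(NA_integer_)
  summary$year[which(hit)[1L]]
}

#' Headline summary of an ensemble run
#'
#' @param summary a `viv_ensemble`.
#' @param tavr_volumes the native TAVR [volume_series()].
#' @param share_year year for the ViV-share headline (default: last horizon
#'   year).
#' @param sd_years years at which to report the ensemble SD of total ViV.
#' @param series_includes_viv see [viv_share()].
#' @return a list: `total_viv_<last>`, `viv_share`, `crossover_year`
#'   (threshold 0.9), `crossover_year_strict` (threshold 1.0), and
#'   `sd_total_<year>` entries.
#' @export
headline_summary <- function(summary, tavr_volumes,
                             share_year = max(summary$year),
                             sd_years = c(2020L, max(summary$year)),
                             series_includes_viv = FALSE) {
  last <- max(summary$year)
  out <- list(
    final_year = last,
    total_viv_final = summary$total_mean[summary$year == last],
    viv_share = viv_share(summary, tavr_volumes, share_year,
                          series_includes_viv),
    share_year = as.integer(share_year),
    crossover_year = crossover_year(summary, 0.9),
    crossover_year_strict = crossover_year(summary, 1.0)
  )
  for (y in sd_years) {
    if (y %in% summary$year) {
      out[[paste0("sd_total_", y)]] <- summary$total_sd[summary$year == y]
    }
  }
  out
}

#' Write ensemble outputs to a directory
#'
#' Writes `forecast.csv` (year, tinS_mean, tinS_sd, tinT_mean, tinT_sd,
#' total_mean, total_sd), `headline.json` (always containing a
#' `crossover_year` key, `null` when absent) and `run_log.json` (config
#' hash, seed, replicate count, versions). `forecast.csv` is byte-identical
#' across reruns with the same configuration and master seed.
#'
#' @param summary a `viv_ensemble`.
#' @param headline a [headline_summary()] list.
#' @param out_dir output directory (created if missing).
#' @param config optionally, the `viv_config` used (hashed into the run
#'   log).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(summary, headline, out_dir, config = NULL) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  fc <- data.frame(
    year = summary$year,
    tinS_mean = summary$tins_mean, tinS_sd = summary$tins_sd,
    tinT_mean = summary$tint_mean, tinT_sd = summary$tint_sd,
    total_mean = summary$total_mean, total_sd = summary$total_sd
  )
  paths <- c(forecast = file.path(out_dir, "forecast.csv"),
             headline = file.path(out_dir, "headline.json"),
             log = file.path(out_dir, "run_log.json"))
  utils::write.csv(fc, paths[["forecast"]], row.names = FALSE, quote = FALSE)
  hl <- headline
  hl$crossover_year <- if (is.na(hl$crossover_year)) NULL_json() else
    hl$crossover_year
  hl$crossover_year_strict <- if (is.na(headline$crossover_year_strict))
    NULL_json() else headline$crossover_year_strict
  jsonlite::write_json(hl, paths[["headline"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  log <- list(
    package_version = as.character(utils::packageVersion("vivforecast")),
    r_version = R.version.string,
    n_replicates = attr(summary, "n_replicates"),
    master_seed = attr(summary, "master_seed"),
    config_md5 = if (!is.null(config)) config_hash(config) else NA,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(log, paths[["log"]], auto_unbox = TRUE, null = "null")
  invisible(paths)
}

NULL_json <- function() NA  # jsonlite renders NA as null with null="null"

#' MD5 hash of a serialized configuration
#' @param config a `viv_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
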