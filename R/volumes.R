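#' Annual procedure-volume series
#'
#' A `viv_volume_series` is a data frame with columns `year`, `count` and
#' `provenance`, one row per calendar year, carrying the annual implant
#' volume of one procedure class (native transcatheter aortic valve
#' replacement, TAVR, or bioprosthetic surgical replacement, SAVR).
#' Provenance records where each year's number came from: `observed`
#' (registry value), `extrapolated` (fitted line), `assumed` (stated
#' modelling assumption such as the constant SAVR plateau) or `synthetic`
#' (test scenario).
#'
#' @param proc_class `"TAVR"` or `"SAVR"`.
#' @param years contiguous integer calendar years.
#' @param counts non-negative integer counts, one per year.
#' @param provenance character vector (recycled) of provenance tags.
#' @return a data frame of class `viv_volume_series` with attribute
#'   `proc_class`.
#' @export
volume_series <- function(proc_class, years, counts, provenance = "synthetic") {
  proc_class <- match.arg(proc_class, c("TAVR", "SAVR"))
  years <- as.integer(years)
  counts <- as.numeric(counts)
  provenance <- rep_len(as.character(provenance), length(years))
  ord <- order(years)
  years <- years[ord]; counts <- counts[ord]; provenance <- provenance[ord]
  validate_volume_series(years, counts, provenance, proc_class)
  out <- data.frame(year = years, count = as.integer(round(counts)),
                    provenance = provenance, stringsAsFactors = FALSE)
  class(out) <- c("viv_volume_series", "data.frame")
  attr(out, "proc_class") <- proc_class
  out
}

validate_volume_series <- function(years, counts, provenance, proc_class) {
  if (length(years) == 0L) stop("volume series invariant violated: series is empty")
  if (anyDuplicated(years)) {
    stop("volume series invariant violated: duplicated year ",
         years[duplicated(years)][1L])
  }
  if (!identical(years, seq(min(years), max(years)))) {
    stop("volume series invariant violated: years not contiguous over [",
         min(years), ", ", max(years), "]")
  }
  if (any(counts < 0)) {
    stop("volume series invariant violated: negative count in year ",
         years[which(counts < 0)[1L]])
  }
  bad <- setdiff(unique(provenance),
                 c("observed", "extrapolated", "assumed", "synthetic"))
  if (length(bad)) {
    stop("volume series invariant violated: unknown provenance tag '",
         bad[1L], "'")
  }
  invisible(TRUE)
}

#' Look up the count of a volume series in a given year
#' @param series a [volume_series()].
#' @param year calendar year (vectorised).
#' @return integer counts; error if a year is outside the series.
#' @export
volume_at <- function(series, year) {
  idx <- match(as.integer(year), series$year)
  if (anyNA(idx)) {
    stop("year ", year[which(is.na(idx))[1L]], " not covered by the ",
         attr(series, "proc_class"), " volume series")
  }
  series$count[idx]
}

#' Build the annual TAVR volume series by linear extrapolation
#'
#' Observed registry years are kept verbatim; years outside the observed
#' range are filled from an ordinary least-squares line fitted on
#' `fit_window` (default: the six most recent observed years, honouring the
#' unsaturated-market assumption by weighting recent growth), clamped at
#' zero and rounded half-to-even to integer counts.
#'
#' @param observed data frame with columns `year`, `count` (or a named
#'   numeric vector, names = years) of observed annual volumes; must cover
#'   a contiguous span of at least two years.
#' @param back_to first year of the output series (backward extrapolation).
#' @param forward_to last year of the output series.
#' @param fit_window integer years (subset of observed years) used for the
#'   OLS fit; `NULL` selects the most recent `min(6, n_obs)` observed years.
#' @return a `"TAVR"` [volume_series()] with provenance `observed` on
#'   observed years and `extrapolated` elsewhere.
#' @export
build_tavr_series <- function(observed, back_to, forward_to, fit_window = NULL) {
  obs <- as_year_count(observed)
  if (nrow(obs) < 2L) stop("build_tavr_series: need at least 2 observed years")
  if (!identical(obs$year, seq(min(obs$year), max(obs$year)))) {
    stop("build_tavr_series: observed years must be contiguous")
  }
  back_to <- as.integer(back_to); forward_to <- as.integer(forward_to)
  if (back_to > min(obs$year)) {
    stop("build_tavr_series: back_to (", back_to,
         ") is after the first observed year (", min(obs$year), ")")
  }
  if (forward_to < max(obs$year)) {
    stop("build_tavr_series: forward_to (", forward_to,
         ") is before the last observed year (", max(obs$year), ")")
  }
  if (is.null(fit_window)) {
    fit_window <- utils::tail(obs$year, 6L)
  }
  fit_window <- as.integer(fit_window)
  if (!all(fit_window %in% obs$year)) {
    stop("build_tavr_series: fit_window must be a subset of observed years")
  }
  if (length(fit_window) < 2L) {
    stop("build_tavr_series: fit_window needs at least 2 years")
  }
  fit <- stats::lm(count ~ year, data = obs[obs$year %in% fit_window, ])
  years <- seq(back_to, forward_to)
  line <- stats::predict(fit, newdata = data.frame(year = years))
  counts <- round(pmax(line, 0))
  prov <- rep("extrapolated", length(years))
  keep <- match(obs$year, years)
  counts[keep] <- obs$count
  prov[keep] <- "observed"
  volume_series("TAVR", years, counts, prov)
}

#' Build the annual bioprosthetic SAVR volume series
#'
#' Combines three sources without overlap: literature-derived bioprosthetic
#' counts for an early period, a bioprosthetic fraction applied to total
#' surgical AVR registry volumes, and a constant plateau for the late
#' horizon.
#'
#' @param total_surgical data frame/named vector of total surgical AVR
#'   volumes by year; bioprosthetic count = `round(fraction * total)`.
#' @param bioprosthetic_fraction fraction of surgical valves that are
#'   bioprosthetic (tissue), in `(0, 1]`.
#' @param pre_period data frame/named vector of directly given bioprosthetic
#'   counts (early literature years); may be `NULL`.
#' @param constant_from first year of the constant plateau.
#' @param constant_value plateau count.
#' @param end_year last year of the series.
#' @return a `"SAVR"` [volume_series()]; provenance is `assumed` for
#'   pre-period and plateau years, `observed` for fraction-derived years.
#' @export
build_savr_series <- function(total_surgical, bioprosthetic_fraction = 0.8,
                              pre_period = NULL, constant_from, constant_value,
                              end_year) {
  if (!(bioprosthetic_fraction > 0 && bioprosthetic_fraction <= 1)) {
    stop("build_savr_series: bioprosthetic_fraction must be in (0, 1]")
  }
  constant_from <- as.integer(constant_from)
  end_year <- as.integer(end_year)
  if (constant_from > end_year) {
    stop("build_savr_series: constant_from must be <= end_year")
  }
  pieces <- list()
  if (!is.null(pre_period)) {
    pre <- as_year_count(pre_period)
    pieces$pre <- data.frame(year = pre$year, count = pre$count,
                             provenance = "assumed")
  }
  if (!is.null(total_surgical)) {
    tot <- as_year_count(total_surgical)
    pieces$frac <- data.frame(year = tot$year,
                              count = round(bioprosthetic_fraction * tot$count),
                              provenance = "observed")
  }
  pieces$plateau <- data.frame(year = seq(constant_from, end_year),
                               count = constant_value, provenance = "assumed")
  all <- do.call(rbind, pieces)
  dup <- unique(all$year[duplicated(all$year)])
  if (length(dup)) {
    vals <- vapply(dup, function(y) length(unique(all$count[all$year == y])),
                   integer(1))
    if (any(vals > 1L)) {
      stop("build_savr_series: conflicting sources for year ",
           dup[which(vals > 1L)[1L]])
    }
    all <- all[!duplicated(all$year), ]
  }
  volume_series("SAVR", all$year, all$count, all$provenance)
}

#' Generate synthetic volume scenarios
#'
#' Emits paired (TAVR, SAVR) volume series so the whole pipeline can be
#' exercised without registry inputs.
#'
#' * `tiny-deterministic` — hand-countable cohorts for oracle tests.
#'   `params`: `tavr`/`savr` named vectors (names = years, values = counts),
#'   `years` optional span to pad with zeros.
#' * `linear-growth` — straight-line counts. `params`: per class
#'   `intercept` (count at `from`), `slope` (per year), `from`, `to`.
#' * `paper-scale` — the packaged US-scale construction: linearly
#'   extrapolated TAVR (unsaturated market) and SAVR constant at 50,000
#'   from 2021.
#'
#' All kinds are deterministic in (`kind`, `params`, `seed`).
#'
#' @param kind one of `"tiny-deterministic"`, `"linear-growth"`,
#'   `"paper-scale"`.
#' @param params scenario parameter list (see details).
#' @param seed integer; part of the determinism contract.
#' @return `list(tavr = <series>, savr = <series>)`.
#' @export
synthesize_scenario <- function(kind, params = list(), seed = 1L) {
  kind <- as.character(kind)[1L]
  if (!kind %in% c("tiny-deterministic", "linear-growth", "paper-scale")) {
    stop("synthesize_scenario: unknown kind '", kind, "'")
  }
  set.seed(mix_seed(seed, 55L))
  if (kind == "tiny-deterministic") {
    span <- scenario_span(params, c(params$tavr, params$savr))
    list(tavr = pad_series("TAVR", params$tavr, span),
         savr = pad_series("SAVR", params$savr, span))
  } else if (kind == "linear-growth") {
    from <- params$from %||% 2000L
    to <- params$to %||% 2010L
    years <- seq(as.integer(from), as.integer(to))
    mk <- function(class, intercept, slope) {
      counts <- round(pmax(intercept + slope * (years - years[1L]), 0))
      volume_series(class, years, counts, "synthetic")
    }
    list(tavr = mk("TAVR", params$tavr_intercept %||% 0,
                   params$tavr_slope %||% 10),
         savr = mk("SAVR", params$savr_intercept %||% 50,
                   params$savr_slope %||% 0))
  } else {
    list(tavr = build_tavr_series(tavr_observed_us(), back_to = 2007,
                                  forward_to = 2035),
         savr = build_savr_series(savr_total_surgical_us(),
                                  bioprosthetic_fraction = 0.8,
                                  pre_period = savr_bioprosthetic_pre2012_us(),
                                  constant_from = 2021,
                                  constant_value = 50000,
                                  end_year = 2035))
  }
}

scenario_span <- function(params, named) {
  if (!is.null(params$years)) return(range(as.integer(params$years)))
  if (is.null(named) || !length(named)) {
    stop("tiny-deterministic scenario needs at least one cohort or a 'years' span")
  }
  range(as.integer(names(named)))
}

pad_series <- function(class, named, span) {
  years <- seq(span[1L], span[2L])
  counts <- integer(length(years))
  if (!is.null(named) && length(named)) {
    idx <- match(as.integer(names(named)), years)
    if (anyNA(idx)) stop("cohort year outside scenario span")
    counts[idx] <- as.integer(named)
  }
  volume_series(class, years, counts, "synthetic")
}

as_year_count <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("year", "count") %in% names(x))) {
      stop("expected columns 'year' and 'count'")
    }
    out <- data.frame(year = as.integer(x$year), count = as.numeric(x$count))
  } else if (is.numeric(x) && !is.null(names(x))) {
    out <- data.frame(year = as.integer(names(x)), count = as.numeric(x))
  } else {
    stop("expected a data frame with year/count or a year-named numeric vector")
  }
  out[order(out$year), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extend a volume series with zero-count years
#'
#' Pads the series with zeros (provenance `assumed`) so it covers
#' `[from, to]`; used e.g. for pre-introduction TAVR years.
#'
#' @param series a [volume_series()].
#' @param from,to target span (defaults keep the existing ends).
#' @return a [volume_series()].
#' @export
pad_zero_years <- function(series, from = min(series$year),
                           to = max(series$year)) {
  years <- seq(min(from, min(series$year)), max(to, max(series$year)))
  counts <- integer(length(years))
  prov <- rep("assumed", length(years))
  idx <- match(series$year, years)
  counts[idx] <- series$count
  prov[idx] <- series$provenance
  volume_series(attr(series, "proc_class"), years, counts, prov)
}

#' Read / write a volume-series CSV
#'
#' Plain CSV with header `year,count,provenance`; lines starting with `#`
#' are treated as comments (the packaged fixtures carry their per-year
#' citations there).
#'
#' @param path file path.
#' @param proc_class `"TAVR"` or `"SAVR"`.
#' @return [read_volume_csv()] returns a [volume_series()];
#'   [write_volume_csv()] returns `path` invisibly.
#' @export
read_volume_csv <- function(path, proc_class) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("year", "count", "provenance") %in% names(df))) {
    stop("volume CSV must have header year,count,provenance: ", path)
  }
  volume_series(proc_class, df$year, df$count, df$provenance)
}

#' @rdname read_volume_csv
#' @param series a [volume_series()].
#' @export
write_volume_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- packaged US input fixtures -------------------------------------------
# Values the registry papers behind this model do not print are shipped as
# clearly-flagged approximations; see the fixture CSV headers and the
# methods vignette.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "vivforecast")
  if (!nzchar(p)) {
    # during development (package loaded via pkgload) fall back to source tree
    p <- file.path("inst", "extdata", name)
  }
  if (!file.exists(p)) stop("packaged fixture not found: ", name)
  p
}

#' Packaged US input fixtures
#'
#' Annual US commercial TAVR volumes (observed 2012-2019 from public
#' TVT-registry annual reports; 2020-2022 approximations from public
#' summaries), total surgical AVR volumes 2012-2020, literature-scale
#' bioprosthetic SAVR approximations 1998-2011, and the assumed
#' redo-surgery series. Citations and assumption flags are in each CSV's
#' comment header.
#'
#' @return [tavr_observed_us()], [savr_total_surgical_us()] and
#'   [savr_bioprosthetic_pre2012_us()] return `year`/`count` data frames;
#'   [default_redo_series_us()] returns a `year`/`savr_after_savr`/
#'   `savr_after_tavr` data frame.
#' @export
tavr_observed_us <- function() {
  df <- utils::read.csv(fixture_path("tavr_observed_us.csv"),
                        comment.char = "#")
  df[, c("year", "count")]
}

#' @rdname tavr_observed_us
#' @export
savr_total_surgical_us <- function() {
  utils::read.csv(fixture_path("savr_total_surgical_us.csv"),
                  comment.char = "#")[, c("year", "count")]
}

#' @rdname tavr_observed_us
#' @export
savr_bioprosthetic_pre2012_us <- function() {
  utils::read.csv(fixture_path("savr_bioprosthetic_pre2012_us.csv"),
                  comment.char = "#")[, c("year", "count")]
}

#' @rdname tavr_observed_us
#' @export
default_redo_series_us <- function() {
  utils::read.csv(fixture_path("redo_series_us.csv"), comment.char = "#")
}
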