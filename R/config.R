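#' The packaged default model configuration
#'
#' Returns the full parameter set of the US valve-in-valve forecast model:
#' every published model constant (durability mixtures, survival
#' distributions, risk-class eras, penetration anchors, the 50,000-case SAVR
#' plateau, 20 replicates, horizon 1998-2035) plus the packaged volume,
#' redo-surgery and age-distribution fixtures. Quantities the source
#' registries do not publish per year (low-risk survival, age weights, redo
#' counts, some volume years) are documented assumptions; see the fixture
#' headers and the methods vignette.
#'
#' @param master_seed integer master seed for the replicate ensemble.
#' @return a validated `viv_config` list.
#' @export
paper_default_config <- function(master_seed = 20240339L) {
  start_year <- 1998L
  end_year <- 2035L
  ages <- 60:95
  w <- stats::dnorm(ages, mean = 77, sd = 7)
  cfg <- list(
    start_year = start_year,
    end_year = end_year,
    n_replicates = 20L,
    master_seed = as.integer(master_seed),
    # TAVR did not exist before its trial era; the linearly back-extrapolated
    # series starts in 2007 and earlier horizon years are zero
    tavr_volumes = pad_zero_years(
      build_tavr_series(tavr_observed_us(), back_to = 2007,
                        forward_to = end_year),
      from = start_year),
    savr_volumes = build_savr_series(savr_total_surgical_us(),
                                     bioprosthetic_fraction = 0.8,
                                     pre_period = savr_bioprosthetic_pre2012_us(),
                                     constant_from = 2021,
                                     constant_value = 50000,
                                     end_year = end_year),
    age_model = list(support = ages, weights = w / sum(w)),
    # fraction_low_risk per procedure class and half-open era [from, to_excl)
    risk_mix = data.frame(
      proc = c("SAVR", "TAVR", "TAVR", "TAVR"),
      from = c(start_year, start_year, 2019L, 2024L),
      to_excl = c(end_year + 1L, 2019L, 2024L, end_year + 1L),
      fraction_low_risk = c(0.85, 0, 1 / 3, 0.5),
      stringsAsFactors = FALSE
    ),
    durability_models = list(
      TAVR = list(components = data.frame(
        weight = c(0.2, 0.8), mean_years = c(4, 11.5), sd_years = c(1.5, 3.5))),
      SAVR_lt70 = list(components = data.frame(
        weight = 1, mean_years = 10, sd_years = 5)),
      SAVR_ge70 = list(components = data.frame(
        weight = 1, mean_years = 17, sd_years = 5))
    ),
    savr_age_split = 70L,
    survival_models = list(
      low = list(family = "normal", median_years = 12, sd_years = 4),
      intermediate_high = list(family = "normal", median_years = 6,
                               sd_years = 2)
    ),
    survival_age_cap = 100L,
    penetration = list(
      TAVR = data.frame(year = c(2022L, 2035L), fraction = c(0.10, 0.60)),
      SAVR = data.frame(year = c(2022L, 2035L), fraction = c(0.60, 0.80))
    ),
    redo_series = default_redo_series_us(),
    failure_year_rule = "floor",
    redo_before_penetration = TRUE,
    tavr_series_includes_viv = FALSE
  )
  class(cfg) <- c("viv_config", "list")
  validate_config(cfg)
  cfg
}

#' Build a configuration by overriding the packaged defaults
#'
#' Any field not supplied is taken from [paper_default_config()]; the result
#' is validated. Volume series may be given as `viv_volume_series` objects
#' or plain `year`/`count`(/`provenance`) data frames.
#'
#' @param ... named fields of the configuration (see
#'   [paper_default_config()] for the full set).
#' @return a validated `viv_config`.
#' @export
simulation_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  cfg <- unclass(paper_default_config())
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("configuration error: unknown key '", unknown[1L], "'")
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg$tavr_volumes <- coerce_series(cfg$tavr_volumes, "TAVR")
  cfg$savr_volumes <- coerce_series(cfg$savr_volumes, "SAVR")
  cfg$start_year <- as.integer(cfg$start_year)
  cfg$end_year <- as.integer(cfg$end_year)
  cfg$n_replicates <- as.integer(cfg$n_replicates)
  cfg$master_seed <- as.integer(cfg$master_seed)
  class(cfg) <- c("viv_config", "list")
  validate_config(cfg)
  cfg
}

coerce_series <- function(x, class_) {
  if (inherits(x, "viv_volume_series")) return(x)
  if (is.data.frame(x)) {
    return(volume_series(class_, x$year, x$count,
                         x$provenance %||% "synthetic"))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(volume_series(class_, as.integer(names(x)), x, "synthetic"))
  }
  stop("configuration error: cannot interpret ", class_, " volume series")
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the parameter set and stops with a
#' message naming the violated invariant.
#'
#' @param cfg a `viv_config`.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  fail <- function(...) stop("config invariant violated: ", ...)
  if (!(cfg$start_year < cfg$end_year)) fail("start_year < end_year")
  if (!(cfg$n_replicates >= 1L)) fail("n_replicates >= 1")

  horizon <- seq(cfg$start_year, cfg$end_year)
  for (nm in c("tavr_volumes", "savr_volumes")) {
    s <- cfg[[nm]]
    missing <- setdiff(horizon, s$year)
    if (length(missing)) {
      fail(nm, " must cover every year in [start_year, end_year]; missing ",
           missing[1L])
    }
  }

  am <- cfg$age_model
  if (!identical(as.integer(am$support), 60:95)) {
    fail("age support must be exactly 60..95")
  }
  if (any(am$weights < 0)) fail("age weights must be non-negative")
  if (abs(sum(am$weights) - 1) > 1e-9) fail("age weights must sum to 1")

  rm_ <- cfg$risk_mix
  if (any(rm_$fraction_low_risk < 0 | rm_$fraction_low_risk > 1)) {
    fail("fraction_low_risk must be in [0, 1]")
  }
  for (p in unique(rm_$proc)) {
    e <- rm_[rm_$proc == p, , drop = FALSE]
    covered <- unlist(Map(seq, e$from, e$to_excl - 1L))
    if (anyDuplicated(covered)) fail("risk-mix eras overlap for ", p)
    if (length(setdiff(horizon, covered))) {
      fail("risk-mix eras for ", p, " do not cover all seeding years")
    }
  }

  for (nm in names(cfg$durability_models)) {
    comp <- cfg$durability_models[[nm]]$components
    if (abs(sum(comp$weight) - 1) > 1e-9) {
      fail("durability mixture weights for ", nm, " must sum to 1")
    }
    if (any(comp$weight <= 0)) fail("durability weights must be in (0, 1]")
    if (any(comp$mean_years <= 0)) fail("durability means must be > 0")
    if (any(comp$sd_years < 0)) fail("durability SDs must be >= 0")
  }
  needed <- c("TAVR", "SAVR_lt70", "SAVR_ge70")
  if (length(setdiff(needed, names(cfg$durability_models)))) {
    fail("durability models must cover TAVR, SAVR_lt70 and SAVR_ge70")
  }

  for (nm in c("low", "intermediate_high")) {
    sm <- cfg$survival_models[[nm]]
    if (is.null(sm)) fail("survival model missing for risk class ", nm)
    if (!(sm$median_years > 0)) fail("survival median must be > 0")
    if (!(sm$sd_years >= 0)) fail("survival SD must be >= 0")
  }

  for (tp in c("TAVR", "SAVR")) {
    pa <- cfg$penetration[[tp]]
    if (is.null(pa)) fail("penetration schedule missing for ", tp, " failures")
    if (any(pa$fraction < 0 | pa$fraction > 1)) {
      fail("penetration fractions must be in [0, 1]")
    }
    if (is.unsorted(pa$year, strictly = TRUE)) {
      fail("penetration anchor years must be strictly increasing")
    }
  }

  rs <- cfg$redo_series
  missing <- setdiff(horizon, rs$year)
  if (length(missing)) {
    fail("redo series must cover every simulated year; missing ", missing[1L])
  }
  if (any(rs$savr_after_savr < 0) || any(rs$savr_after_tavr < 0)) {
    fail("redo counts must be >= 0")
  }
  if (!cfg$failure_year_rule %in% c("floor", "round")) {
    fail("failure_year_rule must be 'floor' or 'round'")
  }
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML (or JSON, which YAML parses) configuration and merges it
#' over the packaged defaults: an empty file yields
#' [paper_default_config()] exactly; any key present overrides only that
#' key. Distribution-bearing fields use the same `{family, params}` layout
#' that [write_config()] emits.
#'
#' @param path path to the YAML/JSON configuration file.
#' @return a validated `viv_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: no such file: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("configuration error: cannot parse ", path, ": ",
         conditionMessage(e))
  })
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration error: top level must be a mapping")
  simulation_config(config_from_plain(raw))
}

#' Serialize a configuration to YAML
#'
#' The written file round-trips: `load_config(write_config(cfg, path))`
#' reproduces `cfg` field by field.
#'
#' @param cfg a `viv_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(config_to_plain(cfg), path, precision = 15L)
  invisible(path)
}

# plain-list (YAML-safe) representation <-> internal representation
config_to_plain <- function(cfg) {
  plain <- unclass(cfg)
  ser <- function(s) {
    lapply(seq_len(nrow(s)), function(i) {
      list(year = as.integer(s$year[i]), count = as.integer(s$count[i]),
           provenance = s$provenance[i])
    })
  }
  plain$tavr_volumes <- ser(cfg$tavr_volumes)
  plain$savr_volumes <- ser(cfg$savr_volumes)
  plain$age_model <- list(support = as.integer(cfg$age_model$support),
                          weights = as.numeric(cfg$age_model$weights))
  plain$risk_mix <- lapply(seq_len(nrow(cfg$risk_mix)), function(i) {
    as.list(cfg$risk_mix[i, ])
  })
  plain$durability_models <- lapply(cfg$durability_models, function(m) {
    list(family = "truncated_normal_mixture",
         components = lapply(seq_len(nrow(m$components)), function(i) {
           as.list(m$components[i, ])
         }))
  })
  plain$penetration <- lapply(cfg$penetration, function(pa) {
    list(interpolation = "linear",
         anchors = lapply(seq_len(nrow(pa)), function(i) {
           list(year = as.integer(pa$year[i]), fraction = pa$fraction[i])
         }))
  })
  plain$redo_series <- lapply(seq_len(nrow(cfg$redo_series)), function(i) {
    as.list(cfg$redo_series[i, ])
  })
  plain
}

config_from_plain <- function(raw) {
  out <- raw
  deser <- function(x) {
    if (is.null(x) || is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(r) as.data.frame(r)))
  }
  if (!is.null(raw$tavr_volumes)) out$tavr_volumes <- deser(raw$tavr_volumes)
  if (!is.null(raw$savr_volumes)) out$savr_volumes <- deser(raw$savr_volumes)
  if (!is.null(raw$risk_mix)) out$risk_mix <- deser(raw$risk_mix)
  if (!is.null(raw$redo_series)) out$redo_series <- deser(raw$redo_series)
  if (!is.null(raw$age_model)) {
    am <- raw$age_model
    if (!is.null(am$family)) {
      support <- 60:95
      w <- switch(am$family,
        discretized_normal = stats::dnorm(support, am$mean, am$sd),
        uniform = rep(1, length(support)),
        stop("configuration error: unknown age_model family '", am$family, "'"))
      out$age_model <- list(support = support, weights = w / sum(w))
    } else {
      out$age_model <- list(support = as.integer(am$support),
                            weights = as.numeric(am$weights))
    }
  }
  if (!is.null(raw$durability_models)) {
    out$durability_models <- lapply(raw$durability_models, function(m) {
      comp <- if (is.data.frame(m$components)) m$components else deser(m$components)
      list(components = comp)
    })
  }
  if (!is.null(raw$penetration)) {
    out$penetration <- lapply(raw$penetration, function(pa) {
      if (is.data.frame(pa)) return(pa)
      anchors <- if (!is.null(pa$anchors)) pa$anchors else pa
      deser(anchors)
    })
  }
  out
}

#' @export
print.viv_config <- function(x, ...) {
  cat("<viv_config>\n")
  cat("  horizon:      ", x$start_year, "-", x$end_year, "\n", sep = "")
  cat("  replicates:   ", x$n_replicates, " (master seed ", x$master_seed,
      ")\n", sep = "")
  cat("  TAVR volumes: ", min(x$tavr_volumes$year), "-",
      max(x$tavr_volumes$year), ", ",
      format(sum(x$tavr_volumes$count), big.mark = ","),
      " implants total\n", sep = "")
  cat("  SAVR volumes: ", min(x$savr_volumes$year), "-",
      max(x$savr_volumes$year), ", ",
      format(sum(x$savr_volumes$count), big.mark = ","),
      " implants total\n", sep = "")
  invisible(x)
}

# ---- schedule lookups ------------------------------------------------------

#' Fraction of low-risk patients for a procedure class and year
#'
#' Risk-class eras are half-open `[from, to_excl)`; an uncovered year is an
#' error.
#'
#' @param mix the `risk_mix` table of a configuration.
#' @param proc `"TAVR"` or `"SAVR"`.
#' @param year calendar year (scalar).
#' @return the era's `fraction_low_risk`.
#' @export
risk_fraction_low <- function(mix, proc, year) {
  e <- mix[mix$proc == proc & mix$from <= year & year < mix$to_excl, ]
  if (nrow(e) != 1L) {
    stop("risk mix does not cover year ", year, " for ", proc)
  }
  e$fraction_low_risk
}

#' Evaluate a penetration schedule
#'
#' Linear interpolation between anchors, constant at the first anchor's
#' value before it and at the last anchor's value after it ("progressive
#' increase" read as piecewise-linear).
#'
#' @param schedule the `penetration` list of a configuration.
#' @param failure_type `"TAVR"` or `"SAVR"` (type of the failed valve).
#' @param years calendar years (vectorised).
#' @return fractions in `[0, 1]`.
#' @export
penetration_at <- function(schedule, failure_type, years) {
  pa <- schedule[[failure_type]]
  if (is.null(pa)) stop("no penetration schedule for ", failure_type,
                        " failures")
  if (nrow(pa) == 1L) return(rep(pa$fraction, length(years)))
  stats::approx(pa$year, pa$fraction, xout = years, rule = 2)$y
}
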