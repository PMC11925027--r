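#' Sample patient ages at the index procedure
#'
#' Draws integer ages from the configured discrete distribution on 60-95.
#' All samplers in the package consume R's global random stream; callers
#' (the engine) position that stream with [set.seed()] per work unit, so a
#' given stream position and parameter set always reproduce the same draws.
#'
#' @param n number of patients.
#' @param dist an age distribution, `list(support, weights)`.
#' @return integer vector of ages in `[60, 95]`.
#' @export
sample_age <- function(n, dist) {
  if (n == 0L) return(integer(0))
  dist$support[sample.int(length(dist$support), n, replace = TRUE,
                          prob = dist$weights)]
}

#' Assign surgical-risk classes for one seeding cohort
#'
#' Bernoulli draws with the era's low-risk fraction for the cohort's
#' procedure class and index year.
#'
#' @param n number of patients.
#' @param year index (seeding) calendar year.
#' @param proc `"TAVR"` or `"SAVR"`.
#' @param mix the configuration's `risk_mix` table.
#' @return character vector, `"low"` or `"intermediate_high"`.
#' @export
assign_risk_class <- function(n, year, proc, mix) {
  f <- risk_fraction_low(mix, proc, year)
  if (n == 0L) return(character(0))
  ifelse(stats::runif(n) < f, "low", "intermediate_high")
}

#' Sample valve durability (time to structural degeneration)
#'
#' Durability follows a mixture of normals truncated to strictly positive
#' values: a component is chosen by weight, a normal variate drawn, and the
#' whole pair redrawn while non-positive, i.e. the *mixture* is truncated,
#' so the sampled law has CDF `(G(x) - G(0)) / (1 - G(0))` with `G` the
#' untruncated mixture CDF. TAVR uses one mixture for all ages; SAVR is
#' age-stratified at `age_split` (strictly below vs. at-or-above).
#'
#' @param n number of patients.
#' @param proc `"TAVR"` or `"SAVR"`.
#' @param age integer ages (length `n` or 1); only used for SAVR strata.
#' @param models the configuration's `durability_models` list.
#' @param age_split SAVR age threshold (default 70).
#' @param details if `TRUE`, also return the accepted mixture component per
#'   draw.
#' @return numeric vector of strictly positive years, or (with
#'   `details = TRUE`) `list(years, component)`.
#' @export
sample_durability <- function(n, proc, age, models, age_split = 70L,
                              details = FALSE) {
  if (n == 0L) {
    return(if (details) list(years = numeric(0), component = integer(0))
           else numeric(0))
  }
  age <- rep_len(as.integer(age), n)
  if (proc == "TAVR") {
    key <- rep("TAVR", n)
  } else {
    key <- ifelse(age < age_split, "SAVR_lt70", "SAVR_ge70")
  }
  missing <- setdiff(unique(key), names(models))
  if (length(missing)) {
    stop("no durability model for stratum ", missing[1L])
  }
  years <- numeric(n)
  comp_out <- integer(n)
  for (k in unique(key)) {
    idx <- which(key == k)
    d <- draw_truncated_mixture(length(idx), models[[k]]$components)
    years[idx] <- d$years
    comp_out[idx] <- d$component
  }
  if (details) list(years = years, component = comp_out) else years
}

draw_truncated_mixture <- function(n, comp) {
  years <- numeric(n)
  component <- integer(n)
  todo <- seq_len(n)
  k <- nrow(comp)
  while (length(todo)) {
    ci <- if (k == 1L) rep(1L, length(todo)) else {
      sample.int(k, length(todo), replace = TRUE, prob = comp$weight)
    }
    x <- stats::rnorm(length(todo), comp$mean_years[ci], comp$sd_years[ci])
    ok <- x > 0
    years[todo[ok]] <- x[ok]
    component[todo[ok]] <- ci[ok]
    todo <- todo[!ok]
  }
  list(years = years, component = component)
}

#' Sample post-procedure survival times
#'
#' Survival for each risk class is a normal distribution parameterised by
#' its median (= mean, symmetric family) and SD, truncated to strictly
#' positive values by rejection, then capped so that no patient exceeds the
#' configured attained age (`age + survival <= cap`, default 100).
#'
#' @param n number of patients.
#' @param risk character vector (length `n` or 1), `"low"` or
#'   `"intermediate_high"`.
#' @param age integer ages at the index procedure (length `n` or 1).
#' @param models the configuration's `survival_models` list.
#' @param cap attained-age cap in years (default 100).
#' @return numeric vector of strictly positive years.
#' @export
sample_survival <- function(n, risk, age, models, cap = 100L) {
  if (n == 0L) return(numeric(0))
  risk <- rep_len(as.character(risk), n)
  age <- rep_len(as.integer(age), n)
  out <- numeric(n)
  for (rc in unique(risk)) {
    m <- models[[rc]]
    if (is.null(m)) stop("no survival model for risk class ", rc)
    idx <- which(risk == rc)
    x <- stats::rnorm(length(idx), m$median_years, m$sd_years)
    while (any(bad <- x <= 0)) {
      x[bad] <- stats::rnorm(sum(bad), m$median_years, m$sd_years)
    }
    out[idx] <- x
  }
  pmin(out, cap - age)
}

# numeric CDF of the positive-truncated normal mixture; used by tests as an
# independent oracle and exported for diagnostics
#' CDF of a positive-truncated normal mixture
#'
#' `(G(x) - G(0)) / (1 - G(0))` with `G` the untruncated mixture CDF — the
#' law produced by [sample_durability()] (and by [sample_survival()] before
#' the age cap).
#'
#' @param x quantiles.
#' @param components data frame with `weight`, `mean_years`, `sd_years`.
#' @return CDF values in `[0, 1]`.
#' @export
ptruncmix <- function(x, components) {
  G <- function(q) {
    vapply(q, function(qq) {
      sum(components$weight *
            stats::pnorm(qq, components$mean_years, components$sd_years))
    }, numeric(1))
  }
  g0 <- G(0)
  pmax(0, (G(x) - g0) / (1 - g0))
}
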