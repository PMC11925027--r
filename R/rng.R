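#' Derive a deterministic sub-seed from a key path
#'
#' The simulation assigns an independent random stream to every unit of work
#' (one per replicate, and within a replicate one per seeding year and
#' procedure class, plus one per failure type for penetration thinning).
#' Streams are keyed, not sequential, so adding replicates or seeding years
#' never perturbs the draws of existing units.
#'
#' The mixer iterates two multiplicative congruential steps modulo
#' 2^31 - 1 per key element; all intermediates stay below 2^48 and are
#' therefore exact in double precision. The result seeds R's default
#' Mersenne-Twister generator via [set.seed()].
#'
#' @param ... integer-like key elements (seed, replicate index, year,
#'   procedure code, purpose code).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @keywords internal
mix_seed <- function(...) {
  keys <- as.numeric(c(...))
  if (any(!is.finite(keys))) {
    stop("mix_seed: keys must be finite numbers")
  }
  m <- 2147483647
  h <- 1
  for (k in keys) {
    k <- k %% m
    h <- (h * 48271 + k + 1) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h)
}

# purpose codes for stream derivation (kept distinct so the same
# (replicate, year) pair never reuses a stream across stages)
.RNG_PURPOSE <- c(cohort = 101L, penetration = 202L, replicate = 7L)

# procedure codes used in stream keys
.PROC_CODE <- c(TAVR = 1L, SAVR = 2L)
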