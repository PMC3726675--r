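#' Derive a deterministic per-stage RNG seed
#'
#' One global seed lives in the simulation config; each generator stage draws
#' from its own substream so that adding draws to one stage never perturbs
#' another. The substream seed is a deterministic hash of (seed, stage label),
#' kept below 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% (2^31 - 1))
}

assert_probabilities <- function(p, what = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must be numeric probabilities in [0, 1].", what))
  }
  invisible(p)
}

#' Round half away from zero
#'
#' Display convention for expected SNP counts: `round()` in R rounds half to
#' even, which would print 18.65 as 18.6; summaries instead round half away
#' from zero so 3725 * 0.005 = 18.625 prints as 18.6 and 139.75 as 139.8.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @keywords internal
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
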