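#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded helpers never perturb the global random stream.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-unit seed from a master seed
#'
#' Deterministic stream splitting: each unit (e.g. a site) gets its own
#' seed so results do not depend on evaluation order. Kept strictly below
#' 2^31 so the value is always a valid R integer.
#'
#' @param seed master integer seed.
#' @param index 1-based unit index.
#' @return integer seed for the unit.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index)) %% 2147483629)
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star codes.
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
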