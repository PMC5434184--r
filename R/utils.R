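#' Derive a stage seed from a master seed
#'
#' All randomness in the package flows from a single master seed; each
#' pipeline stage reseeds with a distinct offset so stages stay reproducible
#' independently of how many random draws earlier stages consumed.
#'
#' @param seed master integer seed.
#' @param stage small integer stage offset.
#' @return an integer seed < 2^31.
#' @keywords internal
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 131L + stage * 7919L) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}

# geometric mean; defined only for strictly positive values
geo_mean <- function(x) {
  if (any(x <= 0)) stopf("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}
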