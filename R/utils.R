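# Internal helpers shared across modules.

#' Truncate (not round) a percentage at a displayed precision
#'
#' Reporting convention for printed overlap percentages: values are truncated
#' toward zero at the requested number of digits, so 62.8 prints as 62 at
#' `digits = 0`. Full-precision values are always retained alongside.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Numeric vector truncated at `digits` decimals.
#' @export
#' @examples
#' truncate_pct(62.84, 0) # 62
truncate_pct <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  trunc(x * 10^digits) / 10^digits
}

# Derive a reproducible sub-stream seed from a base seed and an integer
# offset, staying inside 32-bit integer range. Adding new outputs with new
# offsets never perturbs streams already in use.
substream_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((abs(seed) %% 1000003) * 2011 + offset) %% 2147483647L
}

# Negative-binomial draw parameterised by mean and overdispersion phi
# (var = mu + phi * mu^2). phi = 0 is defined as the deterministic
# zero-noise limit: the rounded mean is returned exactly.
rnb <- function(n, mu, dispersion) {
  mu <- rep_len(mu, n)
  if (dispersion == 0) {
    return(round(mu))
  }
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

# Gaussian noise that degenerates to exactly zero at sd = 0.
rnorm0 <- function(n, sd) {
  if (sd == 0) rep(0, n) else stats::rnorm(n, 0, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_field <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}
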