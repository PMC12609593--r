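# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Truncated normal via inverse-CDF; bounds may be infinite.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate truncated normal: mean outside bounds")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi <= plo) stop("empty truncation interval")
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Beta draw parameterised by mean and concentration (shape1 + shape2).
rbeta_ms <- function(n, mean, conc) {
  stopifnot(mean > 0, mean < 1, conc > 0)
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

# Round half away from zero (reported copy numbers are integers).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Wilson score interval for a binomial proportion.
wilson_interval <- function(n_success, n, conf_level = 0.95) {
  stopifnot(n > 0, n_success >= 0, n_success <= n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- n_success / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
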