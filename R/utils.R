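## Internal numeric helpers.

## Cumulative trapezoid integral of y over x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-1L] + y[-n]) / 2))
}

## Truncated-normal sampling by rejection (bounds are a few SD wide here,
## acceptance is high; loop guards degenerate inputs).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

## Signed cube root (used by the cohort generator and transformKi).
signedCbrt <- function(x) sign(x) * abs(x)^(1 / 3)

## Sub-seed derivation that stays inside 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}
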