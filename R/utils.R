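# small internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# multiplicative lognormal measurement noise with unit mean
lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# shape-preserving monotone map through anchor points, clamped to [0, 1];
# Hyman-filtered cubic: strictly monotonicity-preserving, unlike monoH.FC
# which can overshoot by ~1e-5
mono_map <- function(f, value) {
  stopifnot(length(f) == length(value), !is.unsorted(f))
  fn <- stats::splinefun(f, value, method = "hyman")
  function(x) fn(pmin(pmax(x, 0), 1))
}

# deterministic per-chamber RNG seed derived from the master seed, so a
# chamber's stream does not depend on how many chambers are simulated
chamber_seed <- function(seed, chamber) {
  as.integer((as.numeric(seed) * 48271 + chamber * 16807) %% 2147483647L) + 1L
}

# stable short hash of a configuration (polynomial rolling hash)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
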