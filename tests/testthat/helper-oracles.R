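# Independent brute-force oracles, deliberately written as direct
# transcriptions of the definitions (double loops, no shared code with the
# package implementations).

# Sample entropy by explicit template enumeration: count pairs i < j of
# length-m (and length-(m+1)) templates with Chebyshev distance strictly
# below r, both over the same N - m start positions.
brute_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  B <- 0L
  A <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in seq(i + 1L, nt)) {
      dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dm < r) B <- B + 1L
      dm1 <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
      if (dm1 < r) A <- A + 1L
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# Permutation entropy by explicit ordinal-pattern counting with a string
# tally; ties broken earlier-index-is-smaller via order()'s stable sort.
brute_pe <- function(x, D, delay = 1L) {
  nv <- length(x) - (D - 1L) * delay
  tally <- character(0)
  for (i in seq_len(nv)) {
    v <- x[i + (0:(D - 1L)) * delay]
    tally <- c(tally, paste(order(v), collapse = "-"))
  }
  p <- table(tally) / nv
  -sum(p * log2(p))
}

# constant-frequency surrogate recording for feature tests
toy_recording <- function(n = 400, rate = 100, seed = 42) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / rate
  tug_recording(ml = sin(2 * pi * 2 * t) + 0.2 * rnorm(n),
                v  = 1.5 * sin(2 * pi * 2 * t + 1) + 0.2 * rnorm(n),
                ap = 0.8 * sin(2 * pi * 2 * t + 2) + 0.2 * rnorm(n),
                sampling_rate = rate)
}

# small planted-signal feature table: k informative features, rest noise
planted_features <- function(n = 120, informative = c("CI (ML)", "STD (V)"),
                             effect = 2, seed = 99) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * 27), n, 27, dimnames = list(NULL, feature_names()))
  for (f in informative) X[, f] <- X[, f] + effect * y
  list(x = as.data.frame(X, check.names = FALSE), y = y)
}
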