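#' Coarse-grain a time series
#'
#' Non-overlapping block averaging at scale factor `tau`: element `j` of the
#' output is the mean of input points `(j-1)*tau + 1` through `j*tau`. Trailing
#' points that do not fill a complete block are discarded, so the output has
#' length `floor(length(x)/tau)`. This is the first step of the multiscale
#' entropy (MSE) computation.
#'
#' @param x Numeric series.
#' @param tau Integer scale factor, `>= 1`.
#' @return Numeric vector of length `floor(length(x)/tau)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4, 5, 6), 2)  # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, tau) {
  stopifnot(is.numeric(x), length(tau) == 1L, tau >= 1, tau == as.integer(tau))
  n_blocks <- length(x) %/% tau
  if (n_blocks < 1L) {
    stop("scale factor tau = ", tau, " exceeds series length ", length(x),
         ": coarse-grained series would be empty")
  }
  if (tau == 1L) return(x)
  colMeans(matrix(x[seq_len(n_blocks * tau)], nrow = tau))
}

#' Sample entropy
#'
#' SampEn(m, r) of a series: the negative natural logarithm of the conditional
#' probability that two template sequences matching for `m` points (Chebyshev
#' distance strictly below the tolerance) also match for `m + 1` points.
#' Self-matches are excluded, and both template lengths range over the same
#' `N - m` start positions (Richman-Moorman convention).
#'
#' The tolerance defaults to a fraction of the standard deviation of `x`
#' (`r_mode = "sd_fraction"`); `r_mode = "absolute"` interprets `r` directly in
#' signal units, which is convenient when the tolerance must be held fixed
#' across coarse-graining scales (see [mse_profile()]).
#'
#' If no template pairs match at either length the conditional probability is
#' undefined and `NA_real_` is returned (never silently zero); a constant
#' series in `sd_fraction` mode has zero tolerance and is likewise undefined.
#'
#' @param x Numeric series, length `> m + 1`.
#' @param m Embedding (template) length, default 2.
#' @param r Tolerance, default 0.15. A fraction of `sd(x)` in `"sd_fraction"`
#'   mode, an absolute distance in `"absolute"` mode.
#' @param r_mode Tolerance interpretation, `"sd_fraction"` (default) or
#'   `"absolute"`.
#' @return A single non-negative number, or `NA_real_` when undefined.
#' @references Richman JS, Moorman JR (2000) Physiological time-series
#'   analysis using approximate entropy and sample entropy.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.15,
                           r_mode = c("sd_fraction", "absolute")) {
  r_mode <- match.arg(r_mode)
  stopifnot(is.numeric(x), all(is.finite(x)), m >= 1, r > 0)
  if (length(x) <= m + 1L) {
    stop("series of length ", length(x), " too short for m = ", m,
         ": need length > m + 1")
  }
  tol <- if (r_mode == "sd_fraction") r * sd(x) else r
  if (!is.finite(tol) || tol <= 0) return(NA_real_)  # constant series
  cnt <- sampen_counts(as.numeric(x), as.integer(m), tol)
  if (cnt$A == 0 || cnt$B == 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

#' Multiscale entropy profile
#'
#' Sample entropy of the coarse-grained series at every scale `1..tau_max`.
#' The tolerance is r times the SD of the *original* series and is held fixed
#' across scales, the convention under which white noise shows decaying
#' entropy with scale while 1/f noise stays approximately flat.
#'
#' @param x Numeric series; must satisfy `length(x) >= tau_max * (m + 2)` so
#'   every coarse-grained series supports the template length.
#' @param params An [mse_params()] object (fields `m`, `r`, `tau_max`).
#' @return Numeric vector of length `tau_max`; entries are `NA_real_` where
#'   SampEn is undefined at that scale.
#' @examples
#' set.seed(1)
#' mse_profile(rnorm(500), mse_params())
#' @export
mse_profile <- function(x, params = mse_params()) {
  stopifnot(inherits(params, "mse_params"))
  m <- params$m; r <- params$r; tau_max <- params$tau_max
  if (length(x) < tau_max * (m + 2)) {
    stop("series of length ", length(x), " too short for tau_max = ", tau_max,
         " with m = ", m, ": need at least ", tau_max * (m + 2), " points")
  }
  tol <- r * sd(x)
  vapply(seq_len(tau_max), function(tau) {
    y <- coarse_grain(x, tau)
    if (length(y) <= m + 1L) {
      stop("coarse-grained series at scale ", tau, " is too short (",
           length(y), " points) for m = ", m)
    }
    if (!is.finite(tol) || tol <= 0) return(NA_real_)
    sample_entropy(y, m = m, r = tol, r_mode = "absolute")
  }, numeric(1))
}

#' Complexity index
#'
#' Sum of the sample-entropy values of an MSE profile over all scale factors.
#' Any undefined (`NA`) entry propagates: the index is then `NA`.
#'
#' @param profile Numeric MSE profile as returned by [mse_profile()].
#' @return A single number, or `NA_real_` if any entry is undefined.
#' @export
complexity_index <- function(profile) {
  stopifnot(is.numeric(profile), length(profile) >= 1L)
  if (anyNA(profile)) return(NA_real_)
  sum(profile)
}

#' Permutation entropy
#'
#' Shannon entropy (base 2, bits) of the relative frequencies of ordinal
#' patterns among all `T - (D - 1) * delay` delay-embedded vectors of the
#' series. Each embedded vector is mapped to the permutation that sorts it;
#' ties are broken deterministically with the earlier index ranking lower.
#' Values lie in `[0, log2(factorial(D))]`: a single repeated pattern (e.g. a
#' monotone series) gives 0, and i.i.d. continuous noise approaches the upper
#' bound. PE depends only on the ordinal structure, so it is invariant under
#' any strictly increasing transform of the series.
#'
#' @param x Numeric series of length at least `(D - 1) * delay + 1`.
#' @param D Embedding dimension, `>= 2`. Default 4.
#' @param delay Embedding time delay in samples, `>= 1`. Default 1.
#' @return Permutation entropy in bits.
#' @references Bandt C, Pompe B (2002) Permutation entropy: a natural
#'   complexity measure for time series.
#' @examples
#' permutation_entropy(1:10, D = 3)              # 0
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), D = 2)  # ~0.918
#' @export
permutation_entropy <- function(x, D = 4L, delay = 1L) {
  stopifnot(is.numeric(x), all(is.finite(x)),
            D >= 2, D == as.integer(D), delay >= 1, delay == as.integer(delay))
  n_vec <- length(x) - (D - 1L) * delay
  if (n_vec < 1L) {
    stop("series of length ", length(x), " too short for D = ", D,
         ", delay = ", delay, ": need at least ", (D - 1L) * delay + 1L,
         " points")
  }
  idx <- outer(seq_len(n_vec), seq(0L, by = delay, length.out = D), `+`)
  emb <- matrix(x[idx], nrow = n_vec)
  # rank with ties.method = "first": earlier index ranks lower on ties
  codes <- apply(emb, 1L, function(v)
    paste(rank(v, ties.method = "first"), collapse = "."))
  p <- as.numeric(table(codes)) / n_vec
  -sum(p * log2(p))
}
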