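#' Profile similarity by maximal cyclic-shift correlation
#'
#' The similarity between two binary time series is measured on their
#' entropy profiles: `rho = max_k corr(S1, shift(S2, k))`, the largest
#' Pearson correlation over all cyclic shifts of the second profile. Because
#' a profile encodes the relative distances between all "1" signals, `rho`
#' is sensitive to the signal distribution, unlike the Euclidean distance
#' between the raw 0/1 vectors.
#'
#' Profiles of unequal length are linearly resampled onto a common uniform
#' grid of `resample_to` points before shifting (cyclic shifts are otherwise
#' undefined); equal-length profiles are compared as-is.
#'
#' @param profile_a,profile_b [bls_profile] objects with at least 3 values.
#' @param resample_to Grid size used when the profile lengths differ
#'   (default 512).
#' @return List with `rho` (in `[-1, 1]`), `best_shift` (offset of the
#'   second profile at the maximum, in `[0, n)`), and `resampled` (logical).
#' @examples
#' p <- entropy_profile(random_series(400, 80, seed = 1))
#' profile_rho(p, p)$rho  # 1
#' @export
profile_rho <- function(profile_a, profile_b, resample_to = 512) {
  stopifnot(inherits(profile_a, "bls_profile"),
            inherits(profile_b, "bls_profile"))
  a <- profile_a$values
  b <- profile_b$values
  if (length(a) < 3L || length(b) < 3L)
    stop("profiles must have at least 3 values")
  resampled <- length(a) != length(b)
  if (resampled) {
    resample_to <- as.integer(resample_to)
    if (is.na(resample_to) || resample_to < 3L)
      stop("resample_to must be an integer >= 3")
    a <- .resample_linear(a, resample_to)
    b <- .resample_linear(b, resample_to)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: constant profile")
  n <- length(b)
  best <- -Inf
  best_shift <- 0L
  for (k in 0:(n - 1L)) {
    bk <- if (k == 0L) b else c(b[(k + 1L):n], b[1:k])
    r <- stats::cor(a, bk)
    if (r > best) {
      best <- r
      best_shift <- k
    }
  }
  list(rho = best, best_shift = best_shift, resampled = resampled)
}

.resample_linear <- function(v, n) {
  stats::approx(seq(0, 1, length.out = length(v)), v,
                seq(0, 1, length.out = n))$y
}

#' Euclidean distance between two binary time series
#'
#' Square root of the number of time positions at which the two 0/1 vectors
#' differ. The position-wise baseline that `rho` is compared against; it
#' carries no information about how the differing signals are distributed.
#'
#' @param series_a,series_b [bls_series] objects of equal length.
#' @return Non-negative real.
#' @examples
#' a <- bls_series(4, c(1, 2))
#' b <- bls_series(4, c(3, 4))
#' euclidean_distance(a, b)  # 2
#' @export
euclidean_distance <- function(series_a, series_b) {
  stopifnot(inherits(series_a, "bls_series"),
            inherits(series_b, "bls_series"))
  if (series_a$length != series_b$length)
    stop("series must have equal length")
  # differing positions = symmetric difference of the signal-time sets
  sqrt(length(c(setdiff(series_a$times, series_b$times),
                setdiff(series_b$times, series_a$times))))
}
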