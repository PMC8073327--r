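#' Branch probabilities of a star network
#'
#' Each branch of a one-node star network is assigned the probability
#' `p_j = L_j / sum(L_k)`, the ratio of its length to the total branch
#' length. These probabilities feed the BLS entropy.
#'
#' @param lengths Numeric vector of strictly positive branch lengths,
#'   at least two.
#' @return An object of class `"bls_branches"`: list with `lengths`,
#'   `probabilities` (summing to 1) and `n` (branch count).
#' @examples
#' branch_probabilities(c(1, 1, 2))$probabilities  # 0.25 0.25 0.50
#' @export
branch_probabilities <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 2L)
    stop("degenerate star network: need at least 2 branch lengths")
  if (anyNA(lengths) || any(lengths <= 0))
    stop("branch lengths must be strictly positive")
  structure(list(lengths = lengths,
                 probabilities = lengths / sum(lengths),
                 n = length(lengths)),
            class = "bls_branches")
}

#' Branch length similarity (BLS) entropy
#'
#' The normalized Shannon entropy of the branch-length distribution,
#' `S = -sum(p_j log p_j) / log(n)`. `S = 1` exactly when all branches have
#' equal length, and approaches 0 as a single branch dominates. The value
#' does not depend on the logarithm base (numerator and denominator share
#' it) nor on a common rescaling of the lengths.
#'
#' @param x A [branch_probabilities] result, or a numeric vector of branch
#'   lengths (which is passed through [branch_probabilities]).
#' @return A single value in `[0, 1]`.
#' @examples
#' bls_entropy(c(3, 3, 3, 3))  # 1
#' bls_entropy(c(1, 1, 2))     # ~0.9464
#' @export
bls_entropy <- function(x) {
  if (!inherits(x, "bls_branches")) x <- branch_probabilities(x)
  p <- x$probabilities
  -sum(p * log(p)) / log(x$n)
}

#' Circular time distances from one focal signal
#'
#' The "1" signals of a series are placed on a circle of circumference `L`
#' at their own times. The branch lengths of the focal signal's star network
#' are its circular time distances `d(t_i, t_j) = min(|t_i - t_j|,
#' L - |t_i - t_j|)` to every other signal. Connecting the series end back
#' to its start bounds all distances by `L/2`, so distant signals cannot
#' dilute the entropy. Optionally the chord of the embedded circle,
#' `2 sin(pi d / L)` (radius dropped; BLS entropy is scale invariant), is
#' returned instead of the arc.
#'
#' @param series A [bls_series] with at least 3 signals.
#' @param focal_index Index of the focal signal in `series$times` (1-based).
#' @param distance `"arc"` (default) for circular time distance, `"chord"`
#'   for the chord length of the embedded circle.
#' @return Numeric vector of `m - 1` positive branch lengths, in the time
#'   order of the non-focal signals.
#' @export
circular_distances <- function(series, focal_index,
                               distance = c("arc", "chord")) {
  stopifnot(inherits(series, "bls_series"))
  distance <- match.arg(distance)
  m <- length(series$times)
  if (m < 3L) stop("too few signals for a profile (need at least 3)")
  focal_index <- as.integer(focal_index)
  if (is.na(focal_index) || focal_index < 1L || focal_index > m)
    stop("focal_index out of range")
  tt <- series$times
  L <- series$length
  d <- abs(tt - tt[focal_index])
  d <- pmin(d, L - d)[-focal_index]
  if (distance == "chord") d <- 2 * sin(pi * d / L)
  d
}

#' BLS entropy profile of a binary time series
#'
#' For each "1" signal in time order, the BLS entropy of the star network
#' formed by its circular distances to all other signals. The resulting
#' sequence `S(t-tilde)` is the entropy profile; it is equivariant under
#' cyclic shifts of the series and reverses under time reversal.
#'
#' @param series A [bls_series] with at least 3 signals.
#' @param distance Distance convention, see [circular_distances].
#' @return An object of class `"bls_profile"`: list with `times` (signal
#'   times), `values` (entropies in `[0, 1]`), and `source_length` (the `L`
#'   of the originating series).
#' @examples
#' q <- uniform_series(500, 5)
#' p <- entropy_profile(q)
#' range(p$values)  # constant: uniform spacing
#' @export
entropy_profile <- function(series, distance = c("arc", "chord")) {
  stopifnot(inherits(series, "bls_series"))
  distance <- match.arg(distance)
  tt <- series$times
  L <- series$length
  m <- length(tt)
  if (m < 3L) stop("too few signals for a profile (need at least 3)")
  logn <- log(m - 1)
  vals <- if (distance == "arc") {
    # arc distances are integers in [1, L/2]: precompute a log table and
    # use sum(d log d) - s log s to avoid forming p explicitly
    lt <- log(seq_len(L))
    vapply(seq_len(m), function(i) {
      d <- abs(tt - tt[i])
      d <- pmin(d, L - d)[-i]
      s <- sum(d)
      -(sum(d * lt[d]) / s - log(s)) / logn
    }, numeric(1))
  } else {
    vapply(seq_len(m), function(i) {
      d <- abs(tt - tt[i])
      d <- 2 * sin(pi * pmin(d, L - d)[-i] / L)
      p <- d / sum(d)
      -sum(p * log(p)) / logn
    }, numeric(1))
  }
  bls_profile(tt, vals, L)
}

#' Construct an entropy profile object
#'
#' Low-level constructor used by [entropy_profile] and the profile reader.
#'
#' @param times Signal times (strictly increasing integers).
#' @param values Entropy values in `[0, 1]`, one per signal.
#' @param source_length Length `L` of the originating series.
#' @return A `"bls_profile"` object.
#' @export
bls_profile <- function(times, values, source_length) {
  times <- as.integer(times)
  values <- as.numeric(values)
  source_length <- as.integer(source_length)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop("profile times must be strictly increasing")
  if (anyNA(values) || any(values < -1e-12 | values > 1 + 1e-12))
    stop("profile values must lie in [0, 1]")
  structure(list(times = times, values = values,
                 source_length = source_length),
            class = "bls_profile")
}

#' @export
print.bls_profile <- function(x, ...) {
  cat(sprintf("BLS entropy profile: %d signals, source L = %d\n",
              length(x$times), x$source_length))
  cat(sprintf("  S in [%.6f, %.6f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.bls_profile <- function(x) length(x$values)
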