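#' Displacement headings of a trajectory
#'
#' The heading of each displacement vector, measured counterclockwise from
#' the +x axis and normalized to `[0, 360)` degrees. A zero-length
#' displacement (stationary frame) inherits the previous heading; a
#' zero-length first displacement is an error because no heading exists yet.
#'
#' @param traj A [bls_trajectory] (or any two-column object coercible to
#'   one) with at least 2 points.
#' @return Numeric vector of `n_points - 1` headings in degrees.
#' @examples
#' headings(bls_trajectory(c(0, 1, 1), c(0, 0, 1)))  # 0 90
#' @export
headings <- function(traj) {
  if (!inherits(traj, "bls_trajectory"))
    traj <- bls_trajectory(traj[[1L]], traj[[2L]])
  dx <- diff(traj$x)
  dy <- diff(traj$y)
  still <- dx == 0 & dy == 0
  if (still[1L]) stop("first displacement has zero length: heading undefined")
  h <- (atan2(dy, dx) * 180 / pi) %% 360
  if (any(still)) {
    for (i in which(still)) h[i] <- h[i - 1L]
  }
  h
}

#' Eight-way 3-bit angle code
#'
#' An angle in `[0, 360)` falls into one of eight 45-degree categories,
#' `[k * 45, (k + 1) * 45)` for `k = 0..7`, and each category is emitted as
#' a 3-bit big-endian code. The default `"shifted"` map encodes category
#' `k` as the binary representation of `(k + 1) mod 8`, so the first
#' category `[0, 45)` is `001`, the second `010`, ..., and the last category
#' `[315, 360)` is `000`. The `"plain"` map encodes `k` directly
#' (`[0, 45)` is `000`, `[315, 360)` is `111`).
#'
#' @param angle Numeric vector of angles in degrees, each in `[0, 360)`.
#' @param code_map `"shifted"` (default) or `"plain"`.
#' @return Integer matrix with one row per angle and three 0/1 columns
#'   (most significant bit first).
#' @examples
#' angle_to_code(25)   # 0 0 1
#' angle_to_code(50)   # 0 1 0
#' angle_to_code(350)  # 0 0 0
#' @export
angle_to_code <- function(angle, code_map = c("shifted", "plain")) {
  code_map <- match.arg(code_map)
  angle <- as.numeric(angle)
  if (anyNA(angle) || any(angle < 0 | angle >= 360))
    stop("angles must lie in [0, 360)")
  k <- floor(angle / 45)
  code <- if (code_map == "shifted") (k + 1) %% 8 else k
  m <- cbind(code %/% 4L, (code %/% 2L) %% 2L, code %% 2L)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Binarize a movement trajectory
#'
#' Converts a planar trajectory into a binary time series by coding each
#' movement step's angle into a 3-bit word and concatenating the words in
#' time order: the series has length `3 * (n_points - 1)` and its "1"
#' signals are the positions of the 1-bits.
#'
#' In the default `"relative"` mode the coded angle is the turning angle —
#' the change of heading from the previous step, normalized to `[0, 360)` —
#' with the first step measured against a reference heading of 0 degrees
#' (so a single-step trajectory codes its absolute heading). In
#' `"absolute"` mode the compass heading itself is coded.
#'
#' @param traj A [bls_trajectory] with at least 2 points.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param code_map Passed to [angle_to_code].
#' @return A [bls_series] of length `3 * (n_points - 1)`.
#' @examples
#' # one step turning 25 degrees: code 001, signal at time 3
#' trajectory_to_series(bls_trajectory(c(0, cos(pi / 7.2)),
#'                                     c(0, sin(pi / 7.2))))$times  # 3
#' @export
trajectory_to_series <- function(traj, mode = c("relative", "absolute"),
                                 code_map = c("shifted", "plain")) {
  mode <- match.arg(mode)
  code_map <- match.arg(code_map)
  h <- headings(traj)
  a <- if (mode == "relative") (h - c(0, h[-length(h)])) %% 360 else h
  bits <- as.integer(t(angle_to_code(a, code_map)))
  bls_series(length(bits), which(bits == 1L))
}
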