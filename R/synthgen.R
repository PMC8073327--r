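# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required (no global random state)")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Uniformly spaced binary series
#'
#' Signals at `start, start + spacing, start + 2 spacing, ...` up to the
#' series length. The spacing sets the (constant) signal density; on the
#' time circle every focal signal of such a series sees the same distance
#' multiset, so its entropy profile is constant.
#'
#' @param length Series length `L`.
#' @param spacing Positive integer gap between consecutive signals.
#' @param start First signal time (default 1).
#' @return A [bls_series].
#' @examples
#' n_signals(uniform_series(500, 2))   # 250
#' n_signals(uniform_series(500, 10))  # 50
#' @export
uniform_series <- function(length, spacing, start = 1) {
  spacing <- as.integer(spacing)
  if (is.na(spacing) || spacing < 1L) stop("spacing must be >= 1")
  start <- as.integer(start)
  if (start < 1L || start > length) stop("start must lie in [1, length]")
  bls_series(length, seq.int(start, length, by = spacing))
}

#' Concatenate binary series end to end
#'
#' The lengths add and each part's signal times are offset by the summed
#' length of the preceding parts. Concatenating series of different
#' densities builds the stepped-density test series whose profile
#' inflections mark the junctions.
#'
#' @param ... [bls_series] objects, or a single list of them.
#' @return A [bls_series].
#' @examples
#' q12 <- concat_series(uniform_series(500, 2), uniform_series(500, 5))
#' q12$length      # 1000
#' n_signals(q12)  # 350
#' @export
concat_series <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1L]], "bls_series"))
    parts <- parts[[1L]]
  if (length(parts) < 1L) stop("need at least one series")
  ok <- vapply(parts, inherits, logical(1), what = "bls_series")
  if (!all(ok)) stop("all parts must be bls_series objects")
  offs <- cumsum(c(0L, vapply(parts, `[[`, integer(1), "length")))
  times <- unlist(lapply(seq_along(parts),
                         function(i) parts[[i]]$times + offs[i]))
  bls_series(offs[length(offs)], times)
}

#' Triangular-gap binary series
#'
#' Signals whose consecutive gaps grow arithmetically (1, 2, 3, ...), so the
#' signal density thins gradually: times `start, start + 1, start + 3,
#' start + 6, ...`, truncated at `start + span - 1`. With
#' `ascending = FALSE` the pattern is mirrored within the span, giving a
#' gradually densifying series.
#'
#' @param start_time First signal time.
#' @param span Number of time steps covered by the pattern.
#' @param ascending Gaps increase along time (default `TRUE`).
#' @return A [bls_series] of length `start_time + span - 1`.
#' @examples
#' head(triangular_series(1, 500)$times)    # 1 2 4 7 11 16
#' n_signals(triangular_series(1, 500))     # 32
#' head(triangular_series(500, 497)$times)  # 500 501 503 506 ...
#' @export
triangular_series <- function(start_time, span, ascending = TRUE) {
  start_time <- as.integer(start_time)
  span <- as.integer(span)
  if (is.na(span) || span < 1L) stop("span must be >= 1")
  if (is.na(start_time) || start_time < 1L) stop("start_time must be >= 1")
  last <- start_time + span - 1L
  k <- 0L
  times <- integer(0)
  repeat {
    t_k <- start_time + (k * (k + 1L)) %/% 2L
    if (t_k > last) break
    times <- c(times, t_k)
    k <- k + 1L
  }
  if (!ascending) times <- sort(start_time + last - times)
  bls_series(last, times)
}

#' Fractal-landscape binary series
#'
#' Generates a heterogeneous binary series from a two-dimensional fractal
#' surface: a fractional-Brownian field is synthesized spectrally (Fourier
#' amplitudes decaying as `f^-(H + 1)`, random phases), min–max normalized
#' to heights in `[0, 1]`, binarized at `height_threshold` (sites strictly
#' above the threshold become 1), and flattened column-major into a single
#' series of length `rows * cols`. The control variable `H` in `[0, 1]`
#' sets the smoothness: `H` near 0 gives a rough surface and a fragmented
#' series, `H` near 1 a smooth surface and long runs.
#'
#' @param H Heterogeneity/smoothness control in `[0, 1]`.
#' @param grid_shape Integer `(rows, cols)`; default `c(100, 100)`, i.e.
#'   series length 10000.
#' @param height_threshold Binarization level in (0, 1), default 0.5. Sites
#'   exactly at the threshold are assigned 0.
#' @param seed Integer seed; the same seed and parameters reproduce the
#'   identical series.
#' @param phase_seed Optional separate seed for the random phase field.
#'   Passing the same `phase_seed` with different `H` values yields series
#'   that share their large-scale structure and differ only in smoothness —
#'   the controlled comparison used when studying how profile similarity
#'   tracks `H`. Default `NULL`: phases come from `seed`.
#' @return A [bls_series] of length `prod(grid_shape)`.
#' @export
landscape_series <- function(H, grid_shape = c(100, 100),
                             height_threshold = 0.5, seed,
                             phase_seed = NULL) {
  if (!is.numeric(H) || length(H) != 1L || is.na(H) || H < 0 || H > 1)
    stop("H must lie in [0, 1]")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 2L))
    stop("grid_shape must be two integers >= 2")
  if (height_threshold <= 0 || height_threshold >= 1)
    stop("height_threshold must lie in (0, 1)")
  nr <- grid_shape[1L]; nc <- grid_shape[2L]
  ph <- .with_seed(if (is.null(phase_seed)) seed else phase_seed,
                   matrix(stats::runif(nr * nc, 0, 2 * pi), nr, nc))
  fy <- c(0:(nr %/% 2L), -((nr - 1L) %/% 2L):-1L) / nr
  fx <- c(0:(nc %/% 2L), -((nc - 1L) %/% 2L):-1L) / nc
  f <- sqrt(outer(fy^2, fx^2, "+"))
  amp <- matrix(0, nr, nc)
  amp[f > 0] <- f[f > 0]^(-(H + 1))
  z <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE))
  z <- (z - min(z)) / (max(z) - min(z))
  v <- as.integer(as.vector(z > height_threshold))  # column-major flatten
  bls_series(nr * nc, which(v == 1L))
}

#' Random binary series
#'
#' `n_signals` distinct signal times drawn uniformly from `1..length`.
#'
#' @param length Series length `L`.
#' @param n_signals Number of "1" signals (at most `length`).
#' @param seed Integer seed.
#' @return A [bls_series].
#' @export
random_series <- function(length, n_signals, seed) {
  length <- as.integer(length)
  n_signals <- as.integer(n_signals)
  if (n_signals > length) stop("n_signals must not exceed length")
  if (n_signals < 1L) stop("n_signals must be >= 1")
  times <- .with_seed(seed, sample.int(length, n_signals))
  bls_series(length, times)
}

#' Correlated random-walk trajectory
#'
#' A planar walk with constant step length whose per-step heading change is
#' drawn from a centered normal with standard deviation `turning_spread`
#' (degrees). Small spreads give nearly straight, persistent paths (the
#' "simple movement" regime); large spreads give tortuous, frequently
#' re-oriented paths (the "complex" regime). A synthetic stand-in for
#' recorded crawling trajectories.
#'
#' @param n_steps Number of trajectory points (>= 2); the walk makes
#'   `n_steps - 1` displacements.
#' @param turning_spread Non-negative heading-change standard deviation in
#'   degrees; 0 gives a straight line.
#' @param step_length Positive displacement per step (default 1).
#' @param seed Integer seed.
#' @return A `"bls_trajectory"`: data.frame with columns `x`, `y`.
#' @export
random_walk_trajectory <- function(n_steps, turning_spread,
                                   step_length = 1, seed) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 2L) stop("n_steps must be >= 2")
  if (turning_spread < 0) stop("turning_spread must be non-negative")
  if (step_length <= 0) stop("step_length must be positive")
  turns <- if (n_steps > 2L)
    .with_seed(seed, stats::rnorm(n_steps - 2L, 0, turning_spread))
  else numeric(0)
  theta <- cumsum(c(0, turns)) * pi / 180
  bls_trajectory(cumsum(c(0, step_length * cos(theta))),
                 cumsum(c(0, step_length * sin(theta))))
}

#' Planar trajectory
#'
#' Ordered planar coordinates sampled at uniform frame intervals. The frame
#' period is irrelevant to the angle coding, so it is not stored.
#'
#' @param x,y Numeric coordinate vectors of equal length (>= 2 points).
#' @return A `"bls_trajectory"` data.frame with columns `x`, `y`.
#' @export
bls_trajectory <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("a trajectory needs at least 2 points")
  if (anyNA(x) || anyNA(y)) stop("coordinates contain NA")
  structure(data.frame(x = x, y = y),
            class = c("bls_trajectory", "data.frame"))
}
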