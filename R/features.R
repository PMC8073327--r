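# Peak finding with topographic prominence.
#
# Returns the leftmost sample of each peak plateau together with its
# prominence: the peak height minus the higher of the two base levels, where
# each base is the minimum encountered while walking away from the peak
# until a strictly higher sample (or the boundary / a full circle) is met.
# Circular sequences are scanned via triplication so that the first and last
# samples are interior points.
.find_peaks <- function(x, circular = TRUE) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(0), prominence = numeric(0)))
  if (circular) {
    ext <- c(x, x, x); lo <- n + 1L; hi <- 2L * n; span <- n
  } else {
    ext <- x; lo <- 2L; hi <- n - 1L; span <- n
  }
  N <- length(ext)
  idx <- integer(0); prom <- numeric(0)
  i <- lo
  while (i <= hi) {
    if (ext[i] > ext[i - 1L]) {
      j <- i
      while (j < N && ext[j + 1L] == ext[j]) j <- j + 1L
      if (j < N && ext[j + 1L] < ext[j]) {
        peak <- ext[i]
        lmin <- peak; k <- i - 1L
        while (k >= 1L && k >= i - span && ext[k] <= peak) {
          if (ext[k] < lmin) lmin <- ext[k]
          k <- k - 1L
        }
        rmin <- peak; k <- j + 1L
        while (k <= N && k <= j + span && ext[k] <= peak) {
          if (ext[k] < rmin) rmin <- ext[k]
          k <- k + 1L
        }
        idx <- c(idx, if (circular) i - n else i)
        prom <- c(prom, peak - max(lmin, rmin))
        i <- j + 1L
      } else i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(index = idx, prominence = prom)
}

# Centered moving average; `circular` wraps, otherwise the window shrinks
# symmetrically at the ends.
.smooth_ma <- function(x, window, circular) {
  if (window <= 1L) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  if (circular) {
    as.numeric(stats::filter(x, rep(1 / window, window), circular = TRUE))
  } else {
    vapply(seq_len(n), function(i) {
      k <- min(h, i - 1L, n - i)
      mean(x[(i - k):(i + k)])
    }, numeric(1))
  }
}

#' Slope of an entropy profile
#'
#' First differences of the entropy values with respect to signal index:
#' central differences at interior signals, one-sided at the two ends. The
#' slope measures the degree of change in the signal density along the
#' series.
#'
#' @param profile A [bls_profile] with at least 2 values.
#' @return Numeric vector of the same length as the profile.
#' @export
profile_slope <- function(profile) {
  stopifnot(inherits(profile, "bls_profile"))
  S <- profile$values
  m <- length(S)
  if (m < 2L) stop("profile must have at least 2 values")
  if (m == 2L) return(rep(S[2L] - S[1L], 2L))
  c(S[2L] - S[1L],
    (S[3:m] - S[1:(m - 2L)]) / 2,
    S[m] - S[m - 1L])
}

#' Local extrema of an entropy profile
#'
#' Local maxima and minima of the profile, filtered either by topographic
#' prominence (default) or by a plain height threshold. Prominence — the
#' height of a peak above the higher of its two flanking valleys — is robust
#' to baseline drift and matches the observation that an unfiltered search
#' returns a forest of micro-oscillations. The `"height"` mode reproduces a
#' plain MinPeakHeight filter: maxima are kept when their entropy value is
#' at least `height_threshold`; minima are kept when they lie at least
#' `height_threshold` below the profile maximum.
#'
#' @param profile A [bls_profile] with at least 3 values.
#' @param height_threshold Non-negative filter threshold (default 0.01).
#' @param mode `"prominence"` (default) or `"height"`.
#' @param circular Treat the profile as circular so the first/last samples
#'   are interior points (default `TRUE`, consistent with the time circle).
#' @return List with `maxima` and `minima`, each a data.frame with columns
#'   `index` (signal index), `time`, `value`, `prominence`.
#' @export
local_extrema <- function(profile, height_threshold = 0.01,
                          mode = c("prominence", "height"),
                          circular = TRUE) {
  stopifnot(inherits(profile, "bls_profile"))
  mode <- match.arg(mode)
  if (!is.numeric(height_threshold) || height_threshold < 0)
    stop("height_threshold must be non-negative")
  S <- profile$values
  if (length(S) < 3L) stop("profile must have at least 3 values")
  mk <- function(pk, values) {
    data.frame(index = pk$index,
               time = profile$times[pk$index],
               value = values[pk$index],
               prominence = pk$prominence)
  }
  maxima <- mk(.find_peaks(S, circular), S)
  minima <- mk(.find_peaks(-S, circular), S)
  if (mode == "prominence") {
    maxima <- maxima[maxima$prominence >= height_threshold, , drop = FALSE]
    minima <- minima[minima$prominence >= height_threshold, , drop = FALSE]
  } else {
    maxima <- maxima[maxima$value >= height_threshold, , drop = FALSE]
    minima <- minima[max(S) - minima$value >= height_threshold, , drop = FALSE]
  }
  rownames(maxima) <- rownames(minima) <- NULL
  list(maxima = maxima, minima = minima)
}

#' Count profile peaks
#'
#' Number of local maxima passing [local_extrema]'s filter; the per-series
#' statistic used to compare groups of movement trajectories.
#'
#' @inheritParams local_extrema
#' @return Non-negative integer.
#' @export
count_peaks <- function(profile, height_threshold = 0.01,
                        mode = c("prominence", "height"),
                        circular = TRUE) {
  nrow(local_extrema(profile, height_threshold, mode, circular)$maxima)
}

#' Inflection points of an entropy profile
#'
#' An inflection of the profile is a sign change of its discrete second
#' difference, equivalently a local extremum of the per-interval slope
#' `(S[i+1] - S[i]) / (t[i+1] - t[i])`. Each detected inflection is located
#' at the midpoint of the bracketing signal times (linear interpolation at
#' the crossing, rounded to the nearest integer) and carries a strength: the
#' topographic prominence of the slope extremum. The inflection time `tau`
#' marks the moment at which the signal-density regime of the series
#' changes.
#'
#' By default crossings whose strength is below `0.1 * max(strength)` are
#' discarded as sampling noise (the genuine regime changes of the worked
#' examples exceed the background by 2–3 orders of magnitude); pass
#' `min_strength = 0` to obtain every crossing, or an absolute value to set
#' the cut directly.
#'
#' @param profile A [bls_profile] with at least 4 values.
#' @param smoothing_window Odd integer; width of a centered moving average
#'   applied to the entropy values before differencing. Default 1 (none).
#'   Noisy profiles (e.g. from fractal-landscape series) need a window wider
#'   than 1.
#' @param min_strength `NULL` (default, relative 0.1 dominance filter) or a
#'   non-negative absolute strength threshold.
#' @param circular If `TRUE`, the wrap-around interval from the last signal
#'   back to the first is included, so a regime change across the circle
#'   seam is reported as an inflection. Default `FALSE`: the profile is
#'   treated as a curve over the observed window and the seam, an artifact
#'   of the circular embedding, is not reported.
#' @return data.frame with columns `time` (tau, integer), `strength`,
#'   `kind` (`"fall"` for a slope maximum: density starts decreasing;
#'   `"rise"` for a slope minimum), `index_left`, `index_right` (bracketing
#'   signal indices), sorted by `time`.
#' @export
inflection_points <- function(profile, smoothing_window = 1,
                              min_strength = NULL, circular = FALSE) {
  stopifnot(inherits(profile, "bls_profile"))
  m <- length(profile$values)
  if (m < 4L) stop("profile must have at least 4 values")
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be a positive odd integer")
  if (!is.null(min_strength) &&
      (!is.numeric(min_strength) || min_strength < 0))
    stop("min_strength must be non-negative")
  S <- .smooth_ma(profile$values, smoothing_window, circular)
  tt <- profile$times
  L <- profile$source_length
  if (circular) {
    tw <- c(tt, tt[1L] + L)
    Sw <- c(S, S[1L])
    left <- seq_len(m)                      # interval j: signals j -> j+1 (wrap)
  } else {
    tw <- tt
    Sw <- S
    left <- seq_len(m - 1L)
  }
  g <- diff(Sw) / diff(tw)
  mid <- (tw[-length(tw)] + tw[-1L]) / 2
  collect <- function(pk, kind) {
    if (nrow(pk) == 0L)
      return(data.frame(time = integer(0), strength = numeric(0),
                        kind = character(0), index_left = integer(0),
                        index_right = integer(0)))
    j <- left[pk$index]
    tau <- floor(mid[pk$index] + 0.5)  # half-up: keeps shift equivariance
    tau <- ((tau - 1L) %% L) + 1L           # wrap midpoint onto [1, L]
    data.frame(time = as.integer(tau), strength = pk$prominence,
               kind = kind, index_left = j,
               index_right = ifelse(j == m, 1L, j + 1L))
  }
  out <- rbind(collect(.find_peaks(g, circular), "fall"),
               collect(.find_peaks(-g, circular), "rise"))
  if (nrow(out)) {
    cut <- if (is.null(min_strength)) 0.1 * max(out$strength) else min_strength
    out <- out[out$strength >= cut, , drop = FALSE]
    out <- out[order(out$time), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Characteristic feature set of an entropy profile
#'
#' Convenience wrapper bundling [local_extrema] and [inflection_points]
#' into one table, the form written by the command-line interface.
#'
#' @inheritParams local_extrema
#' @param smoothing_window Passed to [inflection_points].
#' @return data.frame with columns `kind` (`max`, `min`, `inflection`),
#'   `time`, `entropy` (`NA` for inflections), `index`.
#' @export
extract_features <- function(profile, height_threshold = 0.01,
                             smoothing_window = 1,
                             mode = c("prominence", "height"),
                             circular = TRUE) {
  ex <- local_extrema(profile, height_threshold, mode, circular)
  infl <- inflection_points(profile, smoothing_window,
                            circular = FALSE)
  rbind(
    if (nrow(ex$maxima)) data.frame(kind = "max", time = ex$maxima$time,
                                    entropy = ex$maxima$value,
                                    index = ex$maxima$index),
    if (nrow(ex$minima)) data.frame(kind = "min", time = ex$minima$time,
                                    entropy = ex$minima$value,
                                    index = ex$minima$index),
    if (nrow(infl)) data.frame(kind = "inflection", time = infl$time,
                               entropy = NA_real_,
                               index = infl$index_left)
  )
}
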