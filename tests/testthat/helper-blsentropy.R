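# Shared fixtures and independent oracles, built in code.

# Stepped-density worked examples: dense / medium / sparse uniform parts.
make_q12 <- function() {
  concat_series(uniform_series(500, 2), uniform_series(500, 5))
}
make_q123 <- function() {
  concat_series(uniform_series(500, 2), uniform_series(500, 5),
                uniform_series(500, 10))
}

# Gradually thinning then re-densifying series: two triangular-gap parts,
# the second restarting at t = 500 (union of signal sets on one axis).
make_thinning_series <- function() {
  a <- triangular_series(1, 500)
  b <- triangular_series(500, 497)
  bls_series(1000, union(a$times, b$times))
}

# Independent oracle: literal two-loop evaluation of the branch
# probabilities and normalized entropy, no shared code with the package
# implementation.
naive_entropy_profile <- function(series) {
  tt <- series$times
  L <- series$length
  m <- length(tt)
  vals <- numeric(m)
  for (i in seq_len(m)) {
    d <- numeric(0)
    for (j in seq_len(m)) {
      if (j != i) {
        dd <- abs(tt[i] - tt[j])
        d <- c(d, min(dd, L - dd))
      }
    }
    p <- d / sum(d)
    vals[i] <- -sum(p * log(p)) / log(length(d))
  }
  vals
}

# Independent Pearson correlation (textbook formula).
naive_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Brute-force maximal cyclic-shift correlation.
naive_rho <- function(a, b) {
  n <- length(b)
  best <- -Inf
  for (k in 0:(n - 1)) {
    bk <- if (k == 0) b else c(b[(k + 1):n], b[1:k])
    best <- max(best, naive_pearson(a, bk))
  }
  best
}

# Hand-built profile from explicit values (times 1..m on an axis of the
# same length unless given).
profile_from_values <- function(values, L = length(values)) {
  bls_profile(seq_along(values), values, L)
}

# Scratch file path inside the session temp directory.
temp_path <- function(name) file.path(tempdir(), name)
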