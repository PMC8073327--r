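test_that("branch probabilities are proportional to lengths and sum to 1", {
  expect_equal(branch_probabilities(c(2, 2))$probabilities, c(0.5, 0.5))
  expect_equal(branch_probabilities(c(1, 1, 2))$probabilities,
               c(0.25, 0.25, 0.5))
  set.seed(42)
  for (i in 1:20) {
    len <- runif(sample(2:30, 1), min = 0.01, max = 100)
    b <- branch_probabilities(len)
    expect_equal(sum(b$probabilities), 1, tolerance = 1e-12)
    expect_equal(b$probabilities, len / sum(len))
    # scale invariance of the probabilities
    c_ <- runif(1, 0.1, 50)
    expect_equal(branch_probabilities(c_ * len)$probabilities,
                 b$probabilities, tolerance = 1e-12)
  }
})

test_that("degenerate or invalid star networks are rejected", {
  expect_error(branch_probabilities(numeric(0)), "degenerate")
  expect_error(branch_probabilities(5), "degenerate")
  expect_error(branch_probabilities(c(1, 0)), "positive")
  expect_error(branch_probabilities(c(1, -2, 3)), "positive")
  expect_error(bls_entropy(3), "degenerate")
})

test_that("BLS entropy is 1 exactly for equal branches and only then", {
  for (n in c(2, 3, 4, 7, 50)) {
    expect_equal(bls_entropy(rep(3, n)), 1, tolerance = 1e-12)
    expect_equal(bls_entropy(rep(pi, n)), 1, tolerance = 1e-12)
  }
  set.seed(7)
  for (i in 1:25) {
    len <- runif(sample(2:40, 1), 0.1, 10)
    s <- bls_entropy(len)
    expect_gte(s, 0)
    expect_lte(s, 1 + 1e-12)
    if (max(len) - min(len) > 1e-6) expect_lt(s, 1)
    # scale invariance
    expect_equal(bls_entropy(runif(1, 0.1, 20) * len), s,
                 tolerance = 1e-12)
  }
})

test_that("BLS entropy matches hand evaluation and dominance limit", {
  # -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)) / log(3)
  expect_equal(bls_entropy(c(1, 1, 2)),
               -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)) / log(3),
               tolerance = 1e-12)
  expect_equal(bls_entropy(c(1, 1, 2)), 0.9463946, tolerance = 1e-7)
  expect_lt(bls_entropy(c(1, 1e6)), 1e-4)
})

test_that("circular distances wrap around the time circle", {
  s <- bls_series(10, c(1, 2, 9))
  expect_equal(sort(circular_distances(s, 1)), c(1, 2))
  u <- bls_series(8, c(1, 3, 5, 7))
  for (i in 1:4)
    expect_equal(sort(circular_distances(u, i)), c(2, 2, 4))
  expect_error(circular_distances(bls_series(10, c(1, 5)), 1), "too few")
  expect_error(circular_distances(s, 4), "out of range")
})

test_that("circular distance multisets are rotation invariant", {
  s <- random_series(400, 60, seed = 11)
  for (k in c(1, 37, 399)) {
    sh <- shift_series(s, k)
    d0 <- sort(unlist(lapply(1:60, function(i) circular_distances(s, i))))
    dk <- sort(unlist(lapply(1:60, function(i) circular_distances(sh, i))))
    expect_equal(dk, d0)
  }
})

test_that("uniform series have constant entropy profiles", {
  p <- entropy_profile(uniform_series(500, 5))
  expect_lt(max(p$values) - min(p$values), 1e-12)
  expect_equal(length(p), 100L)
})

test_that("entropy profile is equivariant under cyclic shift", {
  s <- random_series(300, 40, seed = 3)
  p <- entropy_profile(s)
  for (k in c(1, 13, 250)) {
    ps <- entropy_profile(shift_series(s, k))
    # values follow their signals: match by (shifted) time
    shifted_times <- ((s$times - 1 + k) %% s$length) + 1
    expect_equal(ps$values[order(order(shifted_times))], p$values,
                 tolerance = 1e-12)
  }
})

test_that("time reversal reverses the entropy profile", {
  s <- random_series(250, 35, seed = 9)
  p <- entropy_profile(s)
  pr <- entropy_profile(reverse_series(s))
  expect_equal(pr$values, rev(p$values), tolerance = 1e-12)
})

test_that("profile equals the naive two-loop oracle on random series", {
  for (seed in 1:4) {
    m <- c(10, 50, 120, 200)[seed]
    s <- random_series(5 * m, m, seed = seed)
    p <- entropy_profile(s)
    expect_equal(p$values, naive_entropy_profile(s), tolerance = 1e-12)
    expect_true(all(p$values >= 0 & p$values <= 1))
  }
})

test_that("chord distance option is a monotone transform of the arc", {
  s <- bls_series(100, c(10, 30, 80))
  arc <- circular_distances(s, 1, "arc")
  chord <- circular_distances(s, 1, "chord")
  expect_equal(chord, 2 * sin(pi * arc / 100))
  # profiles under both conventions stay in [0, 1]
  r <- random_series(200, 30, seed = 5)
  pc <- entropy_profile(r, distance = "chord")
  expect_true(all(pc$values >= 0 & pc$values <= 1))
})

test_that("series constructor enforces its invariants", {
  expect_error(bls_series(10, c(3, 3)), "unique")
  expect_error(bls_series(10, c(0, 4)), "\\[1, length\\]")
  expect_error(bls_series(10, c(4, 11)), "\\[1, length\\]")
  expect_error(bls_series(10, c(1.5, 3)), "integers")
  expect_error(entropy_profile(bls_series(10, c(1, 5))), "too few")
})
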