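test_that("uniform series place signals at fixed spacing", {
  q1 <- uniform_series(500, 2)
  expect_equal(n_signals(q1), 250L)
  expect_equal(q1$times[1:3], c(1L, 3L, 5L))
  expect_equal(q1$times[250], 499L)
  expect_equal(n_signals(uniform_series(500, 10)), 50L)
  expect_equal(uniform_series(5, 10)$times, 1L)
  expect_error(uniform_series(500, 0), "spacing")
})

test_that("concatenation adds lengths and offsets signal times", {
  q12 <- make_q12()
  expect_equal(q12$length, 1000L)
  expect_equal(n_signals(q12), 350L)
  expect_equal(q12$times[251], 501L)  # first signal of the second part
  expect_equal(make_q123()$length, 1500L)
  one <- uniform_series(100, 3)
  expect_equal(concat_series(one), one)
  expect_equal(concat_series(list(one, one))$length, 200L)
})

test_that("triangular series follow the arithmetic gap sequence", {
  tri <- triangular_series(1, 500)
  expect_equal(utils::head(tri$times, 4), c(1L, 2L, 4L, 7L))
  expect_equal(tri$times[5], 11L)  # 1 + 4*5/2
  expect_equal(n_signals(tri), 32L)
  expect_equal(max(tri$times), 497L)
  tri2 <- triangular_series(500, 497)
  expect_equal(utils::head(tri2$times, 4), c(500L, 501L, 503L, 506L))
  expect_equal(max(tri2$times), 996L)
  # descending: mirrored within the span
  d <- triangular_series(1, 500, ascending = FALSE)
  expect_equal(n_signals(d), 32L)
  expect_equal(rev(500 + 1 - d$times), tri$times)
})

test_that("landscape series: length, binarity, determinism, H domain", {
  s <- landscape_series(0.3, seed = 42)
  expect_equal(s$length, 10000L)
  expect_true(all(as_binary_vector(s) %in% c(0L, 1L)))
  expect_identical(landscape_series(0.3, seed = 42)$times, s$times)
  expect_false(identical(landscape_series(0.3, seed = 43)$times, s$times))
  small <- landscape_series(0.9, grid_shape = c(20, 30), seed = 1)
  expect_equal(small$length, 600L)
  expect_error(landscape_series(1.5, seed = 1), "H must")
  expect_error(landscape_series(-0.1, seed = 1), "H must")
})

test_that("landscape smoothness increases with H", {
  # rough landscapes fragment into many runs, smooth ones into few
  runs <- vapply(c(0.1, 0.9), function(H) {
    mean(vapply(1:5, function(s) {
      r <- rle(as_binary_vector(landscape_series(H, grid_shape = c(50, 50),
                                                 seed = s)))
      length(r$lengths)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(runs[1], runs[2])
})

test_that("landscape signal density averages near the threshold level", {
  dens <- vapply(1:10, function(s) {
    n_signals(landscape_series(0.5, grid_shape = c(50, 50), seed = s)) / 2500
  }, numeric(1))
  expect_gt(mean(dens), 0.3)
  expect_lt(mean(dens), 0.7)
})

test_that("windowed signal density and entropy are anticorrelated", {
  # high entropy marks locally sparse stretches: Spearman correlation
  # between per-signal windowed density and profile value is negative
  neg <- vapply(1:10, function(s) {
    ser <- landscape_series(0.3, grid_shape = c(50, 50), seed = 100 + s)
    v <- as_binary_vector(ser)
    L <- ser$length
    S <- entropy_profile(ser)$values
    w <- 125L
    dens <- vapply(ser$times, function(t0) {
      idx <- (((t0 - w):(t0 + w) - 1L) %% L) + 1L
      mean(v[idx])
    }, numeric(1))
    stats::cor(dens, S, method = "spearman")
  }, numeric(1))
  expect_true(all(neg < 0))
})

test_that("random series obey their contract and determinism", {
  r <- random_series(400, 100, seed = 1)
  expect_equal(n_signals(r), 100L)
  expect_true(all(r$times >= 1 & r$times <= 400))
  expect_identical(random_series(400, 100, seed = 1)$times, r$times)
  expect_false(identical(random_series(400, 100, seed = 2)$times, r$times))
  expect_equal(n_signals(random_series(400, 400, seed = 3)), 400L)
  expect_error(random_series(400, 401, seed = 1), "exceed")
})

test_that("random walks: straight line at zero spread, determinism", {
  w0 <- random_walk_trajectory(50, 0, seed = 1)
  expect_equal(w0$y, rep(0, 50), tolerance = 1e-12)
  expect_equal(w0$x, 0:49, tolerance = 1e-12)
  two <- random_walk_trajectory(2, 45, seed = 1)
  expect_equal(nrow(two), 2L)
  wa <- random_walk_trajectory(100, 30, seed = 5)
  expect_identical(random_walk_trajectory(100, 30, seed = 5), wa)
  expect_false(identical(random_walk_trajectory(100, 30, seed = 6), wa))
  # constant step length
  expect_equal(sqrt(diff(wa$x)^2 + diff(wa$y)^2), rep(1, 99),
               tolerance = 1e-12)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(random_series(100, 10, seed = 99))
  invisible(landscape_series(0.4, grid_shape = c(10, 10), seed = 99))
  invisible(random_walk_trajectory(10, 20, seed = 99))
  expect_identical(.Random.seed, before)
})
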