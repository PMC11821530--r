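# Molecular-orbital degeneracy metric.

test_that("exact degeneracy limits are reproduced", {
  expect_equal(sDelta(c(1, 1), delta = 0, dMax = 2L), 1)
  expect_equal(sDelta(c(0, 1), delta = 0, dMax = 2L), 0)
})

test_that("the metric is bounded in [0, 1] for random spectra", {
  set.seed(12)
  for (i in 1:8) {
    mu <- sort(stats::rnorm(6))
    for (d in c(0, 0.01, 0.1, 1)) {
      s <- sDelta(mu, delta = d)
      expect_gte(s, 0)
      expect_lte(s, 1 + 1e-12)
    }
  }
})

test_that("the metric is monotone in the filtering parameter", {
  set.seed(13)
  for (i in 1:6) {
    mu <- sort(stats::rnorm(5))
    deltas <- c(0, 0.005, 0.02, 0.1, 0.5)
    vals <- vapply(deltas, function(d) sDelta(mu, delta = d), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("deepening the truncation never loses exact-degeneracy signal", {
  mu <- c(0, 0, 1, 2.5)
  counts <- vapply(2:4, function(d) {
    # unnormalized count of zero arguments at delta = 0
    total <- 0
    for (i in 2:d) {
      combos <- utils::combn(4, i)
      x <- mu[combos[i, ]] - colSums(matrix(mu[combos[-i, , drop = FALSE]],
                                            nrow = i - 1))
      total <- total + sum(abs(x) < 1e-12)
    }
    total
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the pairwise depth is permutation invariant", {
  set.seed(14)
  mu <- stats::rnorm(5)
  s1 <- sDelta(mu, delta = 0.05, dMax = 2L)
  s2 <- sDelta(sample(mu), delta = 0.05, dMax = 2L)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("a synthetic two-level crossing yields a single interior peak", {
  rs <- seq(0, 1, by = 0.05)
  muList <- lapply(rs, function(r) c(-1, r - 0.5, 0.5 - r, 1))
  names(muList) <- rs
  scan <- degeneracyScan(muList, delta = 0.02)
  peaks <- scan$r[scan$isPeak]
  expect_equal(length(peaks), 1L)
  expect_equal(peaks, 0.5, tolerance = 0.051)
})

test_that("parameter validation rejects bad depths", {
  expect_error(sDelta(c(0, 1), dMax = 1L), "dMax")
  expect_error(sDelta(c(0, 1), dMax = 3L), "dMax")
  expect_error(sDelta(c(0, 1), delta = -0.1), "delta")
})
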