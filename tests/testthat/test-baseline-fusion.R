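test_that("concatenation z-scores each modality and joins columns", {
  set.seed(1)
  I1 <- matrix(rnorm(40, 5, 2), 20, 2)
  I2 <- matrix(rnorm(60, -1, 3), 20, 3)
  O <- concat_fuse(I1, I2)
  expect_equal(ncol(O), 5)
  expect_equal(colMeans(O), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(O, 2, var), rep(1, 5), tolerance = 1e-12)
  # training-split statistics are reusable on held-out rows: shifting the
  # input by +1 shifts each z-scored column mean by 1/sd
  O2 <- concat_fuse(I1 + 1, I2, stats = attr(O, "stats"))
  expect_equal(colMeans(O2[, 1:2]), 1 / attr(O, "stats")$sd1,
               tolerance = 1e-9)
})

test_that("zero-variance columns are dropped with a warning", {
  I1 <- cbind(rnorm(10), rep(2, 10))
  I2 <- matrix(rnorm(10), 10, 1)
  expect_warning(O <- concat_fuse(I1, I2), "zero-variance")
  expect_equal(ncol(O), 2)
})

test_that("concatenating with an empty block returns the normalised rest", {
  I1 <- matrix(rnorm(20), 10, 2)
  O <- concat_fuse(I1, matrix(numeric(0), 10, 0))
  expect_equal(ncol(O), 2)
  expect_equal(colMeans(O), rep(0, 2), tolerance = 1e-12)
})

test_that("kernel combination is convex and preserves PSD", {
  set.seed(2)
  A <- tcrossprod(matrix(rnorm(30), 10, 3))
  B <- tcrossprod(matrix(rnorm(40), 10, 4))
  K1 <- matrix(rnorm(100), 10) ; K1 <- crossprod(K1) / 10
  expect_equal(combine_kernels(list(K1), 1), K1)
  expect_equal(combine_kernels(list(K1, K1), c(0.5, 0.5)), K1)
  Kc <- combine_kernels(list(A, B), c(0.3, 0.7))
  expect_equal(Kc, t(Kc))
  expect_gt(min(eigen(Kc, symmetric = TRUE)$values), -1e-10)
  expect_error(combine_kernels(list(A, B), c(0.5, 0.6)),
               class = "emofuse_range")
})

test_that("the max rule matches an exhaustive double loop", {
  set.seed(3)
  for (rep in 1:20) {
    U <- sample(1:4, 1); V <- sample(2:4, 1); n <- 5
    probs <- array(runif(n * V * U), c(n, V, U))
    for (t in 1:n) for (j in 1:U) {
      probs[t, , j] <- probs[t, , j] / sum(probs[t, , j])
    }
    got <- max_fuse(probs)
    for (t in 1:n) {
      best_c <- 1; best_v <- -Inf
      for (i in 1:V) for (j in 1:U) {
        if (probs[t, i, j] > best_v) { best_v <- probs[t, i, j]; best_c <- i }
      }
      expect_equal(got[t], best_c)
    }
  }
})

test_that("max-rule examples and tie-breaking follow the contract", {
  p <- list(matrix(c(0.6, 0.3, 0.1), 1), matrix(c(0.2, 0.7, 0.1), 1))
  expect_equal(max_fuse(p), 2L)
  expect_equal(max_fuse(list(matrix(c(0.2, 0.5, 0.3), 1))), 2L)  # U = 1
  u <- matrix(rep(1 / 3, 3), 1)
  expect_equal(max_fuse(list(u, u)), 1L)   # ties break to the first class
})

test_that("the Sugeno lambda solves the defining product identity", {
  m <- sugeno_lambda_measure(c(0.2, 0.3))
  # bisection oracle on f(l) = (1+0.2 l)(1+0.3 l) - (1+l)
  f <- function(l) (1 + 0.2 * l) * (1 + 0.3 * l) - (1 + l)
  lo <- 1e-9; hi <- 100
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(m$lambda, (lo + hi) / 2, tolerance = 1e-10)
  expect_equal(unname(emofuse:::measure_value(m, 1:2)), 1, tolerance = 1e-10)
  # densities summing to one give the additive measure
  m0 <- sugeno_lambda_measure(c(0.5, 0.5))
  expect_equal(m0$lambda, 0)
  expect_equal(unname(emofuse:::measure_value(m0, 1)), 0.5)
  expect_error(sugeno_lambda_measure(c(0.5, 1.2)), class = "emofuse_range")
  expect_error(sugeno_lambda_measure(0.4), class = "emofuse_range")
})

test_that("the lambda-measure is monotone over random densities", {
  set.seed(4)
  for (rep in 1:5) {
    g <- runif(3, 0.1, 0.9)
    m <- sugeno_lambda_measure(g)
    subsets <- list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), 1:3)
    for (A in subsets) for (B in subsets) {
      if (all(A %in% B)) {
        expect_lte(emofuse:::measure_value(m, A),
                   emofuse:::measure_value(m, B) + 1e-12)
      }
    }
    expect_equal(unname(emofuse:::measure_value(m, 1:3)), 1,
                 tolerance = 1e-10)
  }
})

test_that("the Choquet integral reduces to the weighted mean when additive", {
  m0 <- sugeno_lambda_measure(c(0.5, 0.5))
  h <- c(0.3, 0.9)
  expect_equal(choquet_fuse(h, m0), sum(0.5 * h), tolerance = 1e-10)
  # a constant score integrates to itself
  m <- sugeno_lambda_measure(c(0.2, 0.3, 0.4))
  expect_equal(choquet_fuse(rep(0.7, 3), m), 0.7, tolerance = 1e-10)
})

test_that("the Choquet integral matches a brute-force sorted evaluation", {
  set.seed(5)
  for (rep in 1:10) {
    g <- runif(3, 0.1, 0.8)
    m <- sugeno_lambda_measure(g)
    h <- runif(3)
    ord <- order(h)
    hh <- c(0, h[ord])
    acc <- 0
    for (i in 1:3) {
      A <- ord[i:3]
      acc <- acc + (hh[i + 1] - hh[i]) * emofuse:::measure_value(m, A)
    }
    got <- choquet_fuse(h, m)
    expect_equal(got, acc, tolerance = 1e-12)
    expect_gte(got, min(h) - 1e-12)
    expect_lte(got, max(h) + 1e-12)
  }
})

test_that("Choquet decision fusion labels by the largest integral", {
  m <- sugeno_lambda_measure(c(0.6, 0.7))
  p1 <- matrix(c(0.8, 0.1, 0.1,
                 0.2, 0.2, 0.6), 2, 3, byrow = TRUE)
  p2 <- matrix(c(0.7, 0.2, 0.1,
                 0.1, 0.3, 0.6), 2, 3, byrow = TRUE)
  expect_equal(choquet_label(list(p1, p2), m), c(1L, 3L))
})

test_that("the adaptive rule is continuous at the threshold and monotone", {
  yF <- 0.37
  lo <- adaptive_fuse(0.4, yF)
  hi <- adaptive_fuse(0.4 + 1e-9, yF)
  expect_lt(abs(hi - lo), 1e-6)
  expect_equal(adaptive_fuse(0.4, yF), (yF + 0.4) / 2)
  expect_equal(adaptive_fuse(0.2, 0.6), 0.4)
  grid <- seq(0, 1, by = 0.01)
  for (yf in c(0, 0.5, 1)) {
    vals <- adaptive_fuse(grid, yf)
    expect_true(all(diff(vals) >= -1e-12))
  }
  expect_error(adaptive_fuse(1.2, 0.5), class = "emofuse_range")
})

test_that("fusion rules are pure functions", {
  set.seed(6)
  probs <- array(runif(24), c(4, 3, 2))
  for (t in 1:4) for (j in 1:2) {
    probs[t, , j] <- probs[t, , j] / sum(probs[t, , j])
  }
  expect_identical(max_fuse(probs), max_fuse(probs))
  m <- sugeno_lambda_measure(c(0.4, 0.7))
  expect_identical(choquet_label(probs, m), choquet_label(probs, m))
  expect_identical(adaptive_fuse(0.55, 0.3), adaptive_fuse(0.55, 0.3))
})
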