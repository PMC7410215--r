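test_that("kNN estimator coefficient matches its gamma-function closed form", {
  # Gamma(k)^2 / (Gamma(k - a + 1) Gamma(k + a - 1))
  expect_equal(knn_coefficient(3, 1), 1.0)
  expect_equal(knn_coefficient(1, 0.5), 2 / pi)
  expect_equal(knn_coefficient(5, 0.5), 576 / (gamma(5.5) * gamma(4.5)))
  expect_equal(round(knn_coefficient(5, 0.5), 4), 0.9461)
  expect_error(knn_coefficient(0, 0.5), "positive integer")
  expect_error(knn_coefficient(2.5, 0.5), "positive integer")
  expect_error(knn_coefficient(3, 1.5), "scalar in")
})

test_that("k-th nearest neighbour distances agree with exhaustive enumeration", {
  x <- col1(c(0, 1, 3))
  d <- kth_nearest_distances(x, k = 1, exclude_self = TRUE)
  expect_equal(d, c(1, 1, 2))
  d2 <- kth_nearest_distances(x, k = 2, exclude_self = TRUE)
  expect_equal(d2, c(3, 2, 3))
  # without self-exclusion the nearest neighbour of a duplicated point is itself
  expect_equal(kth_nearest_distances(x, x, k = 1, exclude_self = FALSE),
               c(0, 0, 0))
  expect_error(kth_nearest_distances(x, k = 3, exclude_self = TRUE),
               "available neighbours")
  expect_error(kth_nearest_distances(x, matrix(1, 1, 2), k = 1),
               "dimensionality")
  # random 2-D case against a brute-force distance matrix
  with_seed(4, {
    a <- matrix(rnorm(60), ncol = 2)
    b <- matrix(rnorm(40), ncol = 2)
    got <- kth_nearest_distances(b, a, k = 3)
    dm <- as.matrix(dist(rbind(a, b)))[seq_len(30), 30 + seq_len(20)]
    want <- apply(dm, 1, function(r) sort(r)[3])
    expect_equal(got, unname(want))
  })
})

test_that("hand-enumerated micro-oracle X={0,2}, Y={1,3} is exact", {
  # rho = 2 for both points, nu = 1 for both, so every term is
  # ((N-1)*2 / (N*1))^(1/2) = 1 and D_hat = B_{1,1/2} = 2/pi
  est <- knn_alpha_divergence(col1(c(0, 2)), col1(c(1, 3)), k = 1, order = 0.5)
  expect_equal(est$value, 2 / pi)
  h <- hellinger_estimate(col1(c(0, 2)), col1(c(1, 3)), k = 1)
  expect_equal(h$value, 1 - 2 / pi)
  expect_false(h$clipped)
})

test_that("estimate is invariant under permutation and translation, not order", {
  with_seed(11, {
    x <- matrix(rnorm(400), ncol = 2)
    y <- matrix(rnorm(360, 1), ncol = 2)
    base <- hellinger_estimate(x, y)$value
    expect_equal(hellinger_estimate(x[sample(200), ], y[sample(180), ])$value,
                 base)
    shift <- c(3.7, -1.2)
    expect_equal(
      hellinger_estimate(sweep(x, 2, shift, "+"), sweep(y, 2, shift, "+"))$value,
      base)
    # the estimator (unlike the Hellinger distance itself) is not symmetric
    expect_false(isTRUE(all.equal(knn_alpha_divergence(x, y)$value,
                                  knn_alpha_divergence(y, x)$value)))
  })
})

test_that("raw estimates above one are clipped into [0, 1]", {
  # a tight cluster next to a broad one inflates rho/nu ratios so the raw
  # D_hat exceeds 1
  x <- col1(c(0, 1, 2, 3))
  y <- col1(c(0.01, 1.01, 2.01, 3.01))
  raw <- knn_alpha_divergence(x, y, k = 1, order = 0.5)
  expect_gt(raw$value, 1)
  h <- hellinger_estimate(x, y, k = 1)
  expect_identical(h$value, 0)
  expect_true(h$clipped)
})

test_that("same-distribution estimates concentrate near zero", {
  for (d in 1:2) {
    vals <- vapply(1:20, function(s) {
      with_seed(100 + s, {
        x <- matrix(rnorm(2000 * d), ncol = d)
        y <- matrix(rnorm(2000 * d), ncol = d)
        hellinger_estimate(x, y, k = 5)$value
      })
    }, numeric(1))
    expect_lt(abs(mean(vals)), 0.08)
  }
})

test_that("estimator tracks the Gaussian closed form across separations", {
  for (mu in c(0.5, 1, 2)) {
    truth <- gaussian_hellinger_closed_form(0, 1, mu, 1)
    vals <- vapply(1:20, function(s) {
      with_seed(200 + s, {
        x <- col1(rnorm(4000))
        y <- col1(rnorm(4000, mu))
        hellinger_estimate(x, y, k = 5)$value
      })
    }, numeric(1))
    expect_lt(abs(mean(vals) - truth), 0.06)
  }
})

test_that("directional asymmetry of the estimator shrinks with sample size", {
  gaps <- vapply(c(250, 1000, 4000), function(n) {
    diffs <- vapply(1:10, function(s) {
      with_seed(300 + s, {
        x <- col1(rnorm(n))
        y <- col1(rnorm(n, 1))
        abs(knn_alpha_divergence(x, y)$value - knn_alpha_divergence(y, x)$value)
      })
    }, numeric(1))
    mean(diffs)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("Gaussian Hellinger closed form behaves as an oracle should", {
  expect_equal(gaussian_hellinger_closed_form(3, 2, 3, 2), 0)
  expect_equal(gaussian_hellinger_closed_form(0, 1, 2, 1), 1 - exp(-0.5))
  expect_equal(gaussian_hellinger_closed_form(0, 1, 2, 3),
               gaussian_hellinger_closed_form(2, 3, 0, 1))
  expect_error(gaussian_hellinger_closed_form(0, 0, 1, 1), "positive")
})
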