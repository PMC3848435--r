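test_that("KL divergence matches hand evaluations and its conventions", {
  u <- rep(0.25, 4)
  expect_equal(kl_divergence(u, u), 0)
  expect_equal(kl_divergence(c(0.5, 0.5, 0, 0), u), log(2))
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "infinite divergence")
  # 0 log 0 contributes nothing
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  expect_error(kl_divergence(c(0.5, 0.5), c(0.3, 0.3, 0.4)), "dimension mismatch")
})

test_that("KL divergence is non-negative, zero only at equality", {
  withr::with_seed(21, {
    for (rep in 1:50) {
      p <- runif_simplex(8)
      q <- runif_simplex(8)
      expect_gte(kl_divergence(p, q), 0)
      expect_equal(kl_divergence(p, p), 0)
      if (max(abs(p - q)) > 1e-3) expect_gt(kl_divergence(p, q), 0)
    }
  })
})

test_that("symmetrized KL matches hand values and equals the sum of both KLs", {
  expect_equal(sym_kl_distance(c(0.75, 0.25), c(0.25, 0.75)), log(3))
  expect_error(sym_kl_distance(c(0.5, 0.5, 0), c(0.5, 0, 0.5)), "one-sided")
  withr::with_seed(22, {
    for (rep in 1:20) {
      p <- runif_simplex(6)
      q <- runif_simplex(6)
      expect_equal(sym_kl_distance(p, q), sym_kl_distance(q, p))
      expect_equal(sym_kl_distance(p, q), kl_divergence(p, q) + kl_divergence(q, p))
    }
  })
})

test_that("L2 and d2 distances behave as Euclidean and cosine geometry", {
  expect_equal(l2_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), sqrt(2))
  expect_equal(l2_distance(c(0.6, 0.8), c(0, 0)), 1)
  expect_equal(d2_distance(c(1, 2, 3), 5 * c(1, 2, 3)), 0)
  expect_equal(d2_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(d2_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2))
  expect_error(d2_distance(c(0, 0), c(1, 0)), "zero-norm")
})

test_that("zero-order Markov expectations are products of base frequencies", {
  expect_equal(unname(zero_order_expected_frequencies(rep(0.25, 4), 2)),
               rep(1 / 16, 16))
  q <- zero_order_expected_frequencies(c(0.5, 0.5, 0, 0), 2)
  expect_equal(unname(q[c("AA", "AC", "CA", "CC")]), rep(0.25, 4))
  expect_equal(sum(q), 1)
  expect_equal(unname(zero_order_expected_frequencies(c(0.7, 0.1, 0.1, 0.1), 2)["AA"]),
               0.49)
  expect_error(zero_order_expected_frequencies(c(-0.1, 0.5, 0.3, 0.3), 1),
               "non-negative")
})

test_that("standardization centers counts at their expectation", {
  expect_equal(standardize(c(6, 2), c(0.5, 0.5)), c(1, -1))
  # perfectly expected counts standardize to zero for any simplex Q
  withr::with_seed(23, {
    for (rep in 1:10) {
      Q <- runif_simplex(8)
      S <- sample(50:500, 1)
      expect_equal(standardize(Q * S, Q), rep(0, 8))
    }
  })
  # doubling counts is not a linear rescaling of the standardized vector
  x <- c(7, 1, 4, 0)
  Q <- c(0.4, 0.3, 0.2, 0.1)
  direct <- (2 * x - Q * sum(2 * x)) / sqrt(Q * sum(2 * x))
  expect_equal(standardize(2 * x, Q), direct)
  expect_false(isTRUE(all.equal(standardize(2 * x, Q), 2 * standardize(x, Q))))
  expect_error(standardize(c(1, 1), c(1, 0)), "zero at word index")
})

test_that("d2* is the half-cosine dissimilarity of standardized vectors", {
  expect_equal(d2star_distance(c(6, 2), c(6, 2), c(0.5, 0.5)), 0)
  expect_equal(d2star_distance(c(6, 2), c(2, 6), c(0.5, 0.5)), 1)
  expect_error(d2star_distance(c(4, 4), c(2, 6), c(0.5, 0.5)), "degenerate standardization")
  withr::with_seed(24, {
    for (rep in 1:20) {
      Q <- runif_simplex(8)
      c0 <- rpois(8, 10) + 1
      x0 <- rpois(8, 40) + 1
      d <- d2star_distance(c0, x0, Q)
      expect_gte(d, 0)
      expect_lte(d, 1)
    }
  })
})

test_that("chi-squared distance matches Pearson arithmetic and scales with depth", {
  expect_equal(chi2_distance(c(3, 1), c(0.5, 0.5)), 1)
  expect_equal(chi2_distance(c(2, 3, 5), c(0.2, 0.3, 0.5)), 0)
  expect_error(chi2_distance(c(0, 0), c(0.5, 0.5)), "all-zero")
  # same composition at k-fold depth scales the statistic by k
  c0 <- c(8, 2, 4, 6)
  Q <- c(0.3, 0.3, 0.2, 0.2)
  for (k in c(2, 5, 10)) {
    expect_equal(chi2_distance(k * c0, Q), k * chi2_distance(c0, Q))
  }
})

test_that("the Gaussian limit agrees with the scaled KL divergence near q", {
  expect_equal(gaussian_limit_neg_log_likelihood(c(3, 1), c(0.5, 0.5)), 0.5)
  expect_equal(gaussian_limit_neg_log_likelihood(c(2, 3, 5), c(0.2, 0.3, 0.5)), 0)
  withr::with_seed(25, {
    for (rep in 1:50) {
      q <- runif_simplex(6) * 0.8 + 0.2 / 6 # bounded away from zero
      q <- q / sum(q)
      p <- q * (1 + runif(6, -0.01, 0.01))
      p <- p / sum(p)
      L <- 1000
      klv <- L * kl_divergence(p, q)
      gauss <- gaussian_limit_neg_log_likelihood(L * p, q)
      expect_lt(abs(klv - gauss) / gauss, 0.05)
    }
  })
})
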