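test_that("the mean-versus-3-SD rule selects the printed families", {
  expect_equal(dist_from_moments(100, 400)$family, "normal")  # 3*20 < 100
  d <- dist_from_moments(10, 25)                              # 3*5 > 10
  expect_equal(d$family, "negative-binomial")
  expect_equal(d$size, 100 / 15)
  expect_equal(d$p, 10 / 25)
  # low-mean states at or below the Poisson boundary C = mu
  expect_equal(dist_from_moments(6, 6)$family, "poisson")
  expect_equal(dist_from_moments(6, 5)$family, "poisson")
  expect_equal(dist_from_moments(0, 0)$family, "point")
  expect_error(dist_from_moments(-1, 4), "invalid moments")
  expect_error(dist_from_moments(5, -2), "invalid moments")
})

test_that("the moment-matched negative binomial recovers mean and variance", {
  d <- dist_from_moments(10, 25)
  k <- 0:500
  p <- dnbinom(k, size = d$size, mu = d$mu)
  expect_equal(sum(k * p), 10, tolerance = 1e-9)
  expect_equal(sum((k - 10)^2 * p), 25, tolerance = 1e-9)
})

test_that("discretized mass functions are normalized and moment-faithful", {
  for (d in list(dist_from_moments(10, 25), dist_from_moments(100, 400),
                 dist_from_moments(6, 6))) {
    pm <- dist_pmf(d)
    expect_equal(sum(pm$p), 1, tolerance = 1e-9)
    expect_equal(sum(pm$support * pm$p), d$mu, tolerance = 1e-4)
  }
  pt <- dist_pmf(dist_from_moments(5, 0))
  expect_equal(pt$p, 1)
  expect_equal(pt$support, 5)
})

test_that("the discretized normal reproduces the Gaussian entropy", {
  pm <- dist_pmf(dist_from_moments(100, 400))
  h <- -sum(pm$p * log2(pm$p)) + log2(pm$dx)   # differential entropy
  expect_equal(h, 0.5 * log2(2 * pi * exp(1) * 400), tolerance = 0.01)
})

test_that("the family switch is mild at the regime boundary", {
  # At the boundary mu = 3 sd the moment-matched NB keeps a skewness
  # near 2/3 (its shape parameter tends to 9 there), so the two laws
  # differ in shape by a bounded, scale-free amount: the max-normalized
  # sup distance stays near 0.13-0.16 at every scale, while both laws
  # carry identical first two moments.
  for (mu in c(20, 36, 60, 90)) {
    C <- (mu / 3)^2
    nb <- dist_from_moments(mu * 0.999, C)    # just inside NB regime
    no <- dist_from_moments(mu * 1.001, C)    # just inside normal regime
    expect_equal(nb$family, "negative-binomial")
    expect_equal(no$family, "normal")
    k <- 0:ceiling(mu + 10 * sqrt(C))
    pnb <- stochmi:::dist_density(nb, k)
    pno <- stochmi:::dist_density(no, k)
    expect_lt(max(abs(pnb / max(pnb) - pno / max(pno))), 0.17)
    expect_equal(sum(k * pnb / sum(pnb)), nb$mu, tolerance = 1e-6)
  }
})

test_that("bivariate normal conditionals match brute-force integration", {
  d <- joint_normal(c(40, 70), matrix(c(25, 15, 15, 36), 2))
  y1 <- 44
  cond <- conditional_normal(d, y1, var_floor = 0)
  # brute force on a fine 1-D grid of the second coordinate
  y2 <- seq(70 - 8 * 6, 70 + 8 * 6, by = 0.01)
  w <- dnorm(y1, 40, 5) * dnorm(y2, 70 + 15 / 25 * (y1 - 40),
                                sqrt(36 - 15^2 / 25))
  w <- w / sum(w)
  expect_equal(cond$mean, 70 + 15 / 25 * (y1 - 40))
  expect_equal(sum(y2 * w), cond$mean, tolerance = 1e-4)
  expect_equal(sum((y2 - sum(y2 * w))^2 * w), cond$var, tolerance = 1e-4)
})

test_that("degenerate joint normals are guarded", {
  expect_error(joint_normal(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
  # perfect correlation: conditional variance is floored, not zero
  d <- joint_normal(c(10, 10), matrix(c(4, 4, 4, 4), 2))
  expect_gte(conditional_normal(d, 11)$var, 0.25)
  # zero cross-covariance: conditional equals the marginal
  ind <- joint_normal(c(10, 20), diag(c(4, 9)))
  cc <- conditional_normal(ind, c(5, 10, 15), var_floor = 0)
  expect_equal(cc$mean, rep(20, 3))
  expect_equal(cc$var, 9)
})
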