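test_that("analytic propensity gradients match finite differences", {
  set.seed(12)
  nets <- list(
    build_simple_cascade(),
    attach_global_variable(build_simple_cascade(), global_spec(50, 3e-8)),
    build_synthetic_circuit()
  )
  for (net in nets) {
    for (i in 1:5) {
      z <- setNames(runif(length(net$species), 1, 500), net$species)
      x <- runif(1, 0, 100)
      lin <- linearize_propensities(net, z, x)
      jnum <- numeric_propensity_jacobian(net, z, x)
      expect_lt(max(abs(lin$jac - jnum) / (abs(jnum) + 1e-6)), 1e-5)
      expect_equal(unname(lin$a), unname(propensities(net, z, x)))
    }
  }
})

test_that("bilinear G-coupled translation linearizes exactly", {
  net <- attach_global_variable(build_simple_cascade(),
                                global_spec(50, 3e-8))
  z <- c(Y1s = 10, Y1 = 5, My2 = 200, Y2 = 100, G = 50)
  lin <- linearize_propensities(net, z)
  j <- match("tl_y2", rownames(net$nu))
  expect_equal(unname(lin$a[["tl_y2"]]), 0.0014 * 200)
  expect_equal(unname(lin$jac[j, "My2"]), 0.0014)
  expect_equal(unname(lin$jac[j, "G"]), 0.0014 * 200 / 50)
})

test_that("birth/death moments follow the Poisson transient closed form", {
  bd <- birth_death_network(beta = 0.5, gamma = 0.01)
  times <- c(0, 0.5, 1, 2, 5, 20)
  tr <- integrate_moments(bd, moment_state(c(X = 0)), times,
                          rtol = 1e-10, atol = 1e-12)
  zt <- 50 * (1 - exp(-0.01 * times * 60))
  expect_lt(max(abs(tr$mean[, 1] - zt) / (zt + 1)), 1e-8)
  expect_lt(max(abs(tr$cov[1, 1, ] - zt) / (zt + 1)), 1e-8)
})

test_that("cascade stationary state reproduces the printed copy numbers", {
  net <- build_simple_cascade()
  st <- stationary_moments(net, x = 0)
  # total Y1 = beta_y1s / gamma_y1s
  expect_equal(st$mean[["Y1s"]] + st$mean[["Y1"]], 0.01 / 0.0000067,
               tolerance = 1e-9)
  expect_equal(st$mean[["My2"]], 0.0083 / 0.00083, tolerance = 1e-6)
  expect_equal(st$mean[["Y2"]], 10 * 0.0014 / 0.00014, tolerance = 1e-6)
  # residual of the stationary point is tiny
  rhs <- stochmi:::moment_rhs(0, stochmi:::pack_moments(st$mean, st$cov),
                              list(net = net, x = 0))[[1]]
  expect_lt(max(abs(rhs[1:4])), 1e-9)
})

test_that("all-zero synthesis rates give the zero stationary state", {
  net <- build_simple_cascade(cascade_params(beta_y1s = 0, beta_m2s = 0,
                                             beta_m2 = 0))
  st <- stationary_moments(net, x = 0)
  expect_equal(unname(st$mean), rep(0, 4))
})

test_that("the global variable reaches its Poisson stationary law", {
  g <- birth_death_network(1.5e-6, 3e-8, name = "G")
  st <- stationary_moments(g)
  expect_equal(unname(st$mean), 50)
  expect_equal(unname(drop(st$cov)), 50)
})

test_that("zero-covariance mean flow equals the deterministic rates", {
  net <- build_simple_cascade()
  z <- c(Y1s = 800, Y1 = 120, My2 = 40, Y2 = 400)
  rhs <- stochmi:::moment_rhs(
    0, stochmi:::pack_moments(z, matrix(0, 4, 4)),
    list(net = net, x = 30))[[1]][1:4]
  p <- cascade_params()
  hand <- c(
    p$beta_y1s - p$gamma_y1s * 800 - p$theta_x * 30 * 800 +
      p$theta_y1 * 120,
    p$theta_x * 30 * 800 - (p$theta_y1 + p$gamma_y1) * 120,
    hill_activation(120, p) - p$gamma_m2 * 40,
    p$beta_y2 * 40 - p$gamma_y2 * 400
  )
  expect_equal(unname(rhs), hand, tolerance = 1e-12)
})

test_that("expected propensities carry the exact bilinear correction", {
  net <- attach_global_variable(build_simple_cascade(),
                                global_spec(50, 3e-8))
  z <- setNames(c(100, 10, 200, 500, 50), net$species)
  C <- matrix(0, 5, 5, dimnames = list(net$species, net$species))
  C["My2", "G"] <- C["G", "My2"] <- 120
  a <- expected_propensities(net, z, C)
  # E[c * My2 * G] = c * (z_My2 z_G + C_My2G)
  expect_equal(unname(a[["tl_y2"]]),
               0.0014 / 50 * (200 * 50 + 120))
})

test_that("covariance stays symmetric positive semi-definite in the SGF run", {
  sgf <- build_synthetic_circuit()
  het <- make_initial("heterogeneous", sgf)
  tr <- integrate_moments(sgf, het, c(0, 65, 330, 580), x = 44.4)
  for (i in 1:4) {
    C <- tr$cov[, , i]
    expect_equal(C, t(C))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(diag(C)))
  }
})

test_that("trajectories are tidy and anchored at the initial condition", {
  bd <- birth_death_network(0.5, 0.01)
  init <- moment_state(c(X = 20))
  tr <- integrate_moments(bd, init, c(0, 1, 5))
  expect_equal(unname(tr$mean[1, "X"]), 20)
  df <- as.data.frame(tr)
  expect_named(df, c("time_min", "species", "mean", "variance"))
  expect_equal(nrow(df), 3)
  expect_error(integrate_moments(bd, init, c(5, 1)), "is.unsorted")
})
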