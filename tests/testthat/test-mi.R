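test_that("surfaces are dose-independent at t = 0 and interpolate linearly", {
  net <- build_simple_cascade()
  init <- make_initial("heterogeneous", net)
  surf <- build_surface(net, c(0, 50, 150, 250), c(0, 75), init)
  # the step has not acted yet at t = 0
  for (d in 2:4) expect_equal(surf$mu[d, 1, ], surf$mu[1, 1, ])
  # exact at a grid dose
  q <- interpolate_surface(surf, 150, 75)
  expect_equal(unname(q$mu["Y2"]), unname(surf$mu[3, 2, "Y2"]))
  # midpoint query is the arithmetic mean of the neighbors
  q2 <- interpolate_surface(surf, 100, 75)
  expect_equal(unname(q2$mu["Y2"]),
               unname((surf$mu[2, 2, "Y2"] + surf$mu[3, 2, "Y2"]) / 2))
  expect_equal(q2$C["Y2", "Y2"],
               (surf$cov[2, 2, "Y2", "Y2"] + surf$cov[3, 2, "Y2", "Y2"]) / 2)
  expect_error(interpolate_surface(surf, 300, 75), "outside")
  expect_error(mutual_information(surf, 99, "Y2"), "not on the surface")
})

test_that("dose-response ordering matches the transient response", {
  net <- build_simple_cascade()
  init <- moment_state(stationary_moments(net, 0)$mean)
  surf <- build_surface(net, c(0, 125, 250), c(0, 75, 750), init)
  expect_gt(surf$mu[3, 3, "Y2"], surf$mu[3, 2, "Y2"])  # 750 > 75 min
  expect_gt(surf$mu[3, 3, "Y2"], surf$mu[1, 3, "Y2"])  # dose response
})

test_that("mutual information matches a brute-force Gaussian oracle", {
  # channel with normal conditionals whose means ramp linearly in the
  # dose; oracle integrates the continuous MI integral over a dense
  # mixture representation of the same channel
  mus <- c(20, 26); sig <- 2
  surf <- manual_surface(c(0, 1), 10, mu1 = mus, mu2 = c(1, 1),
                         v1 = c(sig^2, sig^2), v2 = c(1, 1), c12 = c(0, 0))
  got <- mutual_information(surf, 10, "Y1r", n_grid = 501)
  ref <- gaussian_channel_mi_oracle(seq(mus[1], mus[2], length.out = 501),
                                    rep(sig, 501))
  expect_equal(got, ref, tolerance = 1e-3)
})

test_that("degenerate channels give zero bits and perfect ones saturate", {
  # identical output laws at every dose carry no information
  surf <- manual_surface(c(0, 1, 2), 5, mu1 = c(30, 30, 30),
                         mu2 = c(5, 5, 5), v1 = c(9, 9, 9),
                         v2 = c(2, 2, 2), c12 = c(0, 0, 0))
  expect_equal(mutual_information(surf, 5, "Y1r"), 0, tolerance = 1e-9)
  # four equiprobable doses with disjoint supports resolve fully
  mu <- c(50, 200, 800, 3200)
  bits <- stochmi:::mi_from_moment_sets(mu, (mu / 50)^2)
  expect_equal(bits, 2, tolerance = 1e-6)
})

test_that("MI is bounded and vanishes at time zero on a model surface", {
  net <- build_simple_cascade()
  init <- make_initial("heterogeneous", net)
  surf <- build_surface(net, log_step_protocol(250, 7)$amplitudes,
                        c(0, 75, 750), init)
  mi <- mutual_information(surf, c(0, 75, 750), "Y2", n_grid = 201)
  expect_equal(mi[1], 0, tolerance = 1e-9)
  expect_true(all(mi >= 0))
  expect_true(all(mi <= log2(201)))
  expect_gt(mi[3], mi[2])   # information accumulates along the transient
})

test_that("refining the interpolation grid leaves MI unchanged", {
  net <- build_simple_cascade()
  init <- moment_state(stationary_moments(net, 0)$mean)
  surf <- build_surface(net, log_step_protocol(250, 13)$amplitudes,
                        c(0, 750), init)
  a <- mutual_information(surf, 750, "Y2", n_grid = 501)
  b <- mutual_information(surf, 750, "Y2", n_grid = 1001)
  expect_lt(abs(a - b) / a, 0.001)
})

test_that("the geometric extrapolation selects N on synthetic sequences", {
  cand <- 4:20
  mi_n <- 3 - 2 * 0.5^cand
  sel <- stochmi:::select_converged_n(cand, mi_n)
  expect_equal(sel$mi_inf, 3, tolerance = 1e-9)
  # the gap to the bound is 2 * 0.5^N; accepted once within 1 percent
  expect_equal(sel$N, cand[which(2 * 0.5^cand <= 0.01 * 3)[1]])
  # constant sequence converges immediately
  selc <- stochmi:::select_converged_n(4:8, rep(1.7, 5))
  expect_true(selc$converged)
  expect_equal(selc$N, 6)
  # non-contracting sequence defers and warns through choose_N
  seld <- stochmi:::select_converged_n(4:8, c(1, 2, 4, 8, 16))
  expect_false(seld$converged)
})

test_that("joint MI equals its chain-rule decomposition", {
  rho_cov <- c(12, 15, 18)
  surf <- manual_surface(c(0, 1, 2), 5,
                         mu1 = c(50, 55, 60), mu2 = c(20, 40, 60),
                         v1 = c(25, 25, 25), v2 = c(16, 16, 16),
                         c12 = rho_cov)
  jm <- joint_mi(surf, 5, c("Y1r", "Y2"), n_grid = 201)
  expect_equal(jm$bits, jm$chain, tolerance = 1e-3)
  expect_gte(jm$bits, jm$marginal1)
})

test_that("an uninformative independent reporter leaves joint MI unchanged", {
  surf <- manual_surface(c(0, 1, 2), 5,
                         mu1 = c(50, 50, 50), mu2 = c(20, 40, 60),
                         v1 = c(25, 25, 25), v2 = c(16, 16, 16),
                         c12 = c(0, 0, 0))
  jm <- joint_mi(surf, 5, c("Y1r", "Y2"), n_grid = 201)
  m2 <- mutual_information(surf, 5, "Y2", n_grid = 201)
  expect_equal(jm$marginal1, 0, tolerance = 1e-6)
  expect_equal(jm$bits, m2, tolerance = 5e-3)
})

test_that("mean equalization removes reporter information, nothing else", {
  surf <- manual_surface(c(0, 1, 2), 5,
                         mu1 = c(50, 45, 40), mu2 = c(20, 40, 60),
                         v1 = c(25, 20, 16), v2 = c(16, 16, 16),
                         c12 = c(10, 9, 8))
  eq <- equalize_reporter_means(surf, "Y1r")
  expect_equal(eq$mu[, 1, "Y1r"], rep(50, 3))
  # per-dose noise (SD over mean) of the reporter is preserved
  expect_equal(sqrt(eq$cov[, 1, "Y1r", "Y1r"]) / eq$mu[, 1, "Y1r"],
               sqrt(surf$cov[, 1, "Y1r", "Y1r"]) / surf$mu[, 1, "Y1r"],
               tolerance = 1e-12)
  # correlation with the output is preserved
  r0 <- surf$cov[, 1, "Y1r", "Y2"] /
    sqrt(surf$cov[, 1, "Y1r", "Y1r"] * surf$cov[, 1, "Y2", "Y2"])
  r1 <- eq$cov[, 1, "Y1r", "Y2"] /
    sqrt(eq$cov[, 1, "Y1r", "Y1r"] * eq$cov[, 1, "Y2", "Y2"])
  expect_equal(r1, r0, tolerance = 1e-12)
  # reporter-alone information is (essentially) erased
  expect_lt(joint_mi(eq, 5, c("Y1r", "Y2"), n_grid = 201)$marginal1, 1e-3)
  bad <- manual_surface(c(1, 2), 5, mu1 = c(45, 40), mu2 = c(40, 60),
                        v1 = c(20, 16), v2 = c(16, 16), c12 = c(9, 8))
  expect_error(equalize_reporter_means(bad, "Y1r"), "zero-dose")
})

test_that("a single-node grid reduces conditional MI to the pinned case", {
  net <- attach_global_variable(build_simple_cascade(),
                                global_spec(50, 3e-8))
  doses <- c(0, 100, 250)
  one <- g_grid(net$gspec, n_nodes = 1)
  ec <- expected_conditional_mi(net, doses, 300, grid = one, n_grid = 101)
  pinned <- pin_global(net, one$g)
  surf <- build_surface(pinned, doses, c(0, 300),
                        conditional_initial(net, one$g))
  direct <- mutual_information(surf, 300, "Y2", n_grid = 101)
  expect_equal(ec$bits, direct, tolerance = 1e-9)
})
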