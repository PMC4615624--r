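test_that("Hill transcription propensity has the printed limits", {
  p <- cascade_params()
  # half-saturation at y1 = y1_0
  expect_equal(hill_activation(85, p), 0.0083 + 0.1583 / 2)
  expect_equal(hill_activation(0, p), p$beta_m2s)
  expect_lt(abs(hill_activation(1e9, p) - (p$beta_m2s + p$beta_m2)), 1e-9)
})

test_that("cascade propensities follow the printed mass-action forms", {
  net <- build_simple_cascade()
  a <- propensities(net, c(Y1s = 1500, Y1 = 0, My2 = 10, Y2 = 100),
                    x = 250)
  expect_equal(unname(a[["act"]]), 0.001 * 250 * 1500)
  expect_equal(unname(a[["syn_y1s"]]), 0.01)
  expect_equal(unname(a[["deg_my2"]]), 0.00083 * 10)
  # zero state: only synthesis propensities survive
  a0 <- propensities(net, c(Y1s = 0, Y1 = 0, My2 = 0, Y2 = 0), x = 250)
  expect_equal(unname(a0[c("deg_y1s", "act", "deact", "deg_y1",
                           "deg_my2", "tl_y2", "deg_y2")]),
               rep(0, 7))
  expect_equal(unname(a0[["syn_y1s"]]), 0.01)
  expect_equal(unname(a0[["tx_my2"]]), 0.0083)
  # propensities are non-negative at random non-negative states
  set.seed(4)
  for (i in 1:20) {
    y <- runif(4, 0, 3000)
    expect_true(all(propensities(net, setNames(y, net$species),
                                 x = runif(1, 0, 250)) >= 0))
  }
})

test_that("estradiol-repressed ADH1 rate matches its limiting values", {
  p <- circuit_params()
  expect_equal(adh1_rate(0, p), p$beta_m1)
  # half-saturation of the repression at x = x_e = 45 nM
  expect_equal(adh1_rate(45, p), p$beta_m1 * (1 - p$alpha_x / 2))
  expect_equal(adh1_rate(45, p), p$beta_m1 * 0.825)
  expect_lt(abs(adh1_rate(1e9, p) - p$beta_m1 * (1 - p$alpha_x)), 1e-9)
})

test_that("global variable spec encodes the birth/death mean and noise", {
  gs <- global_spec(gbar = 50, gamma_g = 3e-8)
  expect_equal(gs$beta_g, 1.5e-6)
  expect_equal(gs$gbar, 50)
  expect_equal(gs$eta_g * sqrt(gs$gbar), 1)
  # beta_g = 3e-6 with gbar 50 implies gamma_g = 6e-8
  gs2 <- global_spec(gbar = 50, gamma_g = 6e-8, beta_g = 3e-6)
  expect_equal(gs2$gbar, 50)
})

test_that("pinning G at its mean recovers the nominal cascade", {
  casc <- build_simple_cascade()
  net <- attach_global_variable(casc, global_spec(50, 3e-8))
  pinned <- pin_global(net, 50)
  expect_setequal(pinned$species, casc$species)
  set.seed(7)
  for (i in 1:10) {
    y <- setNames(runif(4, 0, 2000), casc$species)
    x <- runif(1, 0, 250)
    expect_equal(propensities(pinned, y, x)[rownames(casc$nu)],
                 propensities(casc, y, x))
  }
})

test_that("G coupling scales protein synthesis linearly in G", {
  net <- attach_global_variable(build_simple_cascade(),
                                global_spec(50, 3e-8))
  y <- c(Y1s = 100, Y1 = 50, My2 = 200, Y2 = 500, G = 75)
  a <- propensities(net, y, x = 10)
  expect_equal(unname(a[["tl_y2"]]), 0.0014 * 200 * 75 / 50)
  expect_equal(unname(a[["syn_y1s"]]), 0.01 * 75 / 50)
  # uncoupled transcription unchanged
  expect_equal(unname(a[["tx_my2"]]), hill_activation(50))
})

test_that("synthetic circuit variants carry the printed structure", {
  sgf <- build_synthetic_circuit()
  expect_true(all(c("M1", "Y1s", "Y1", "Y1r", "My2", "Y2", "G") %in%
                    sgf$species))
  expect_equal(sgf$gspec$gbar, 42)
  expect_equal(sgf$gspec$gamma_g, 3e-6)
  intr <- build_synthetic_circuit(variant = "intrinsic")
  expect_false("G" %in% intr$species)
  expect_equal(intr$params$beta_y1s, 0.0000019)
  # reporter and TF translated from the same mRNA at the same rate
  a <- propensities(intr, setNames(c(100, 0, 0, 0, 0, 0), intr$species))
  expect_equal(unname(a[["tl_y1s"]]), unname(a[["tl_y1r"]]))
  # ADH1 repression flag off: transcription constant in x
  flat <- build_synthetic_circuit(variant = "intrinsic",
                                  adh1_estradiol = FALSE)
  y0 <- setNames(numeric(6), flat$species)
  expect_equal(propensities(flat, y0, x = 0)[["tx_m1"]],
               propensities(flat, y0, x = 100)[["tx_m1"]])
})

test_that("step protocols reproduce the experimental dose series", {
  ep <- estradiol_protocol()
  expect_length(ep$amplitudes, 12)
  expect_equal(max(ep$amplitudes), 100)   # column c = 1
  expect_equal(min(ep$amplitudes), 0)     # the zero-estradiol well
  nz <- sort(ep$amplitudes[ep$amplitudes > 0], decreasing = TRUE)
  expect_equal(nz, 100 * (2 / 3)^(0:10))
  expect_equal(sum(ep$p), 1)
  lp <- log_step_protocol(250, 13)
  expect_length(lp$amplitudes, 13)
  expect_true(all(lp$amplitudes <= 250) && all(lp$amplitudes >= 0))
})

test_that("constructors reject invalid input by name", {
  expect_error(cascade_params(nonsense = 1), "unknown parameter")
  p <- cascade_params()
  p$beta_y1s <- NULL
  expect_error(build_simple_cascade(p), "beta_y1s")
  expect_error(
    attach_global_variable(build_simple_cascade(),
                           global_spec(coupled = "no_such_reaction")),
    "no_such_reaction")
  expect_error(build_synthetic_circuit(variant = "intrinsic",
                                       gspec = global_spec()),
               "no global")
})
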