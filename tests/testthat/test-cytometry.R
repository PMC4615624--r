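test_that("cell tables are reproducible and carry the protocol columns", {
  cells <- generate_cells("intrinsic", n_cells = 150, seed = 31,
                          doses = c(0, 29.6, 100), times_min = c(0, 580))
  again <- generate_cells("intrinsic", n_cells = 150, seed = 31,
                          doses = c(0, 29.6, 100), times_min = c(0, 580))
  expect_identical(cells, again)
  expect_equal(nrow(cells), 150 * 3 * 2)
  expect_named(cells, c("well", "dose_nM", "time_min", "y1r", "y2", "g",
                        "seed"))
  expect_true(all(cells$y1r >= 0) && all(cells$y2 >= 0))
  expect_true(all(is.na(cells$g)))   # no global variable in this variant
  other <- generate_cells("intrinsic", n_cells = 150, seed = 32,
                          doses = c(0, 29.6, 100), times_min = c(0, 580))
  expect_false(identical(cells$y2, other$y2))
})

test_that("the SGF reporter reproduces the measured noise level", {
  cells <- generate_cells("SGF", n_cells = 3000, seed = 11,
                          doses = c(0, 100), times_min = c(0, 580))
  s <- summarize_cells(cells)
  noise <- s$noise[s$channel == "y1r" & s$dose_nM == 0 &
                     s$time_min == 580]
  expect_equal(noise, 0.155, tolerance = 0.01 / 0.155)
  expect_true(all(!is.na(cells$g)))
})

test_that("sample moments converge on the model moments", {
  n <- 20000
  cells <- generate_cells("intrinsic", n_cells = n, seed = 77,
                          doses = c(0, 100), times_min = c(0, 580),
                          background = NULL)
  net <- build_synthetic_circuit(variant = "intrinsic")
  tr <- integrate_moments(net, stationary_moments(net, 0), c(0, 580),
                          x = 100)
  sub <- cells[cells$dose_nM == 100 & cells$time_min == 580, ]
  se_mean <- sd(sub$y2) / sqrt(n)
  expect_lt(abs(mean(sub$y2) - tr$mean[2, "Y2"]), 3 * se_mean)
  se_var <- var(sub$y2) * sqrt(2 / (n - 1))
  expect_lt(abs(var(sub$y2) - tr$cov["Y2", "Y2", 2]), 3 * se_var)
})

test_that("summaries encode the noise, normalization and ratio statistics", {
  df <- data.frame(
    well = 1, dose_nM = rep(c(1, 10), each = 40),
    time_min = rep(rep(c(165, 580), each = 20), 2),
    y1r = 50, y2 = rep(c(4, 2, 8, 4, 40, 20, 80, 40), each = 10))
  s <- summarize_cells(df)
  y2 <- s[s$channel == "y2", ]
  expect_equal(y2$mean[y2$dose_nM == 1 & y2$time_min == 165], 3)
  # constant channel: zero noise, flat normalized curve
  y1r <- s[s$channel == "y1r", ]
  expect_true(all(y1r$noise == 0))
  expect_true(all(y1r$norm_mean == 1))
  # noise ratio of the later reference time is 1 by construction
  expect_true(all(y2$noise_ratio[y2$time_min == 580] == 1))
  r <- y2$noise_ratio[y2$dose_nM == 10 & y2$time_min == 165]
  expect_equal(r, y2$noise[y2$dose_nM == 10 & y2$time_min == 165] /
                 y2$noise[y2$dose_nM == 10 & y2$time_min == 580])
  dfz <- df; dfz$y2 <- 0
  expect_warning(summarize_cells(dfz), "zero-mean")
})

test_that("surfaces built from cells agree with the generating model", {
  cells <- generate_cells("intrinsic", n_cells = 8000, seed = 19,
                          doses = c(0, 44.4, 100),
                          times_min = c(0, 330, 580), background = NULL)
  surf <- surface_from_cells(cells)
  net <- build_synthetic_circuit(variant = "intrinsic")
  model <- build_surface(net, c(0, 44.4, 100), c(0, 330, 580),
                         stationary_moments(net, 0))
  for (d in 2:3) {
    for (t in 2:3) {
      se <- sqrt(model$cov[d, t, "Y2", "Y2"] / 8000)
      expect_lt(abs(surf$mu[d, t, "Y2"] - model$mu[d, t, "Y2"]), 3.5 * se)
    }
  }
  # background subtraction recovers the un-shifted moments
  cells_bg <- generate_cells("intrinsic", n_cells = 8000, seed = 19,
                             doses = c(0, 44.4, 100),
                             times_min = c(0, 330, 580))
  raw <- surface_from_cells(cells_bg)
  corr <- surface_from_cells(cells_bg,
                             background = stochmi:::default_background())
  expect_gt(raw$mu[3, 3, "Y2"], corr$mu[3, 3, "Y2"])
  se <- sqrt(model$cov[3, 3, "Y2", "Y2"] / 8000)
  expect_lt(abs(corr$mu[3, 3, "Y2"] - model$mu[3, 3, "Y2"]), 4 * se)
})
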