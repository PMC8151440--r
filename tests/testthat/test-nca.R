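test_that("trapezoidal AUC handles triangles, plateaus and smooth decay", {
  tri <- concentration_profile(c(0, 1, 2), c(0, 10, 0))
  expect_equal(auc_trapezoid(tri), 10)
  flat <- concentration_profile(c(0, 2, 5, 12), rep(3, 4))
  expect_equal(auc_trapezoid(flat), 36)
  expect_equal(auc_trapezoid(flat, t_end = 7), 21)  # interpolated end point

  t <- seq(0, 24, by = 0.05)
  dec <- concentration_profile(t, 100 * exp(-0.3 * t))
  expect_equal(auc_trapezoid(dec), 100 / 0.3 * (1 - exp(-0.3 * 24)),
               tolerance = 5e-3)
  expect_error(auc_trapezoid(tri, t_end = 30), "beyond")
})

test_that("AUC is additive and invariant to collinear points", {
  t <- c(0, 1, 2.5, 4, 7, 12)
  y <- c(0, 8, 6, 5, 3, 1)
  p <- concentration_profile(t, y)
  expect_equal(auc_trapezoid(p, 4) +
                 (auc_trapezoid(p) - auc_trapezoid(p, 4)),
               auc_trapezoid(p))
  # insert a collinear midpoint on the [2.5, 4] segment
  t2 <- sort(c(t, 3.25)); y2 <- stats::approx(t, y, xout = t2)$y
  expect_equal(auc_trapezoid(concentration_profile(t2, y2)),
               auc_trapezoid(p), tolerance = 1e-12)
})

test_that("terminal slope estimation finds the elimination constant", {
  t <- seq(0, 24, by = 1)
  mono <- concentration_profile(t, 50 * exp(-0.24 * t))
  est <- terminal_K(mono)
  expect_equal(est$K, 0.24, tolerance = 1e-10)

  # two-compartment tail approaches the slow hybrid constant
  micro <- ref_micro()
  prof <- simulate_iv_bolus(micro, 7e6, c(0.25, 0.5, 1, 2, 4, 8, 12, 16,
                                          20, 24))
  expect_equal(terminal_K(prof)$K, macro_from_micro(micro)$beta,
               tolerance = 0.02)

  rising <- concentration_profile(c(0, 1, 2, 3, 4, 5), c(5, 1, 2, 3, 4, 5))
  expect_error(terminal_K(rising), "no terminal phase")
})

test_that("NCA composes AUC, extrapolation and observed Cmax/Tmax", {
  tri <- concentration_profile(c(0, 1, 2, 3, 4), c(0, 10, 5, 2.5, 1.25))
  res <- nca(tri)
  expect_equal(res$cmax, 10)
  expect_equal(res$tmax, 1)
  expect_gte(res$auc_inf, res$auc_0_t)

  t <- seq(0, 24, by = 0.1)
  mono <- concentration_profile(t, 80 * exp(-0.3 * t))
  res <- nca(mono)
  expect_equal(res$auc_inf, 80 / 0.3, tolerance = 0.01)

  expect_error(nca(concentration_profile(c(0, 1, 2, 3), rep(0, 4))))
})

test_that("grid interpolation is exact at nodes and refuses extrapolation", {
  p <- concentration_profile(c(0, 1, 2, 4), c(0, 10, 20, 5))
  expect_equal(interpolate_to_grid(p, p$times)$concentrations,
               p$concentrations)
  expect_equal(interpolate_to_grid(p, 1.5)$concentrations, 15)
  expect_error(interpolate_to_grid(p, c(2, 5)), "extrapolation")
})

test_that("cross-study normalization removes a known study effect", {
  micro <- ref_micro()
  sched1 <- c(0, 0.5, 1, 2, 3, 4, 6, 8, 12, 24)
  sched2 <- c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 12, 24)
  ref2 <- gen_first_order_oral(1.2, 0.9, micro, 1e7, sched2, "Ref")
  test_true <- gen_first_order_oral(0.8, 1.0, micro, 1e7, sched1, "T1")
  gamma <- 1.27  # multiplicative between-study bias
  ref1 <- concentration_profile(sched1,
    gamma * gen_first_order_oral(1.2, 0.9, micro, 1e7, sched1)$concentrations,
    product = "Ref")
  obs1 <- concentration_profile(sched1, gamma * test_true$concentrations,
                                product = "T1")

  out <- normalize_cross_study(list(obs1), ref1, ref2)
  # at study-1 sampling times the correction is exact
  at1 <- match(sched1, out$grid)
  expect_equal(out$profiles[[1L]]$concentrations[at1],
               test_true$concentrations, tolerance = 1e-10)

  # identical references leave profiles unchanged (idempotence)
  again <- normalize_cross_study(out$profiles,
                                 out$profiles[[1L]], out$profiles[[1L]])
  expect_equal(again$profiles[[1L]]$concentrations,
               rep(1, length(out$grid)) * out$profiles[[1L]]$concentrations)

  # doubling reference doubles the test profiles
  twice <- normalize_cross_study(list(obs1), ref1,
    concentration_profile(sched1, 2 * ref1$concentrations, product = "Ref"))
  expect_equal(twice$profiles[[1L]]$concentrations[match(sched1, twice$grid)],
               2 * obs1$concentrations)

  # Ref1 = 0 where Ref2 > 0 is undefined
  bad1 <- concentration_profile(c(0, 1, 2, 3), c(0, 0, 5, 4), product = "Ref")
  bad2 <- concentration_profile(c(0, 1, 2, 3), c(0, 2, 5, 4), product = "Ref")
  expect_error(normalize_cross_study(list(bad1), bad1, bad2), "undefined")
})
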