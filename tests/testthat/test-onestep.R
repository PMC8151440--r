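test_that("the logistic cut-off has the right midpoint and asymptotes", {
  expect_equal(cutoff_phi(9.585, 3.623, 9.585), 0.5)
  expect_equal(cutoff_phi(5, 2, 5), 0.5)
  expect_equal(cutoff_phi(0, 3.623, 9.585), 1, tolerance = 1e-10)
  expect_equal(cutoff_phi(1e4, 3.623, 9.585), 0, tolerance = 1e-10)
  t <- seq(0, 24, by = 0.1)
  phi <- cutoff_phi(t, 3.623, 9.585)
  expect_true(all(diff(phi) < 0))
  expect_true(all(phi > 0 & phi < 1))
})

test_that("extent scaling is a power law in Fmax", {
  expect_equal(extent_scale(1, 2.5e-5, 1.4), 2.5e-5)
  expect_equal(extent_scale(0.7, 3, 0), 3)
  f <- seq(0.4, 1.2, by = 0.1)
  sc <- extent_scale(f, 1.55e-5, 1.402)
  slope <- stats::coef(stats::lm(log(sc) ~ log(f)))[2L]
  expect_equal(unname(slope), 1.402, tolerance = 1e-10)
})

test_that("time scaling is monotone with the documented unit behaviour", {
  expect_equal(timescale_vivo_to_vitro(1, 1.069, 0.967), 1.069)
  expect_equal(timescale_vivo_to_vitro(c(0, 2, 5), 1, 1), c(0, 2, 5))
  t <- seq(0, 24, by = 0.5)
  expect_true(all(diff(timescale_vivo_to_vitro(t, 0.8, 1.2)) > 0))
  expect_error(timescale_vivo_to_vitro(-1, 1, 1), "negative")
})

test_that("the Weibull parameter map is recovered from constructed pairs", {
  vitro <- lapply(c("Reference", "Test1", "Test3"), product_weibull)
  idmap <- fit_weibull_map(vitro, vitro)
  same <- map_weibull_vivo(vitro[[1L]], idmap)
  expect_equal(same$alpha_w, vitro[[1L]]$alpha_w, tolerance = 1e-9)
  expect_equal(same$fmax, vitro[[1L]]$fmax, tolerance = 1e-9)

  truth <- list(alpha = c(a = -0.5, m = 1.3), beta = c(a = 0.2, m = 0.9),
                fmax = c(a = -0.1, m = 1.05))
  vivo <- lapply(vitro, function(w) weibull_params(
    truth$alpha["a"] + truth$alpha["m"] * w$alpha_w,
    truth$beta["a"] + truth$beta["m"] * w$beta_w,
    truth$fmax["a"] + truth$fmax["m"] * w$fmax, flavor = "vivo"))
  map <- fit_weibull_map(vitro, vivo)
  expect_equal(unname(map$alpha_w[c("a", "m")]), unname(truth$alpha),
               tolerance = 1e-9)
  expect_equal(unname(map$beta_w[c("a", "m")]), unname(truth$beta),
               tolerance = 1e-9)
  expect_equal(unname(map$fmax[c("a", "m")]), unname(truth$fmax),
               tolerance = 1e-9)
  expect_equal(unname(map$alpha_w["r2"]), 1, tolerance = 1e-9)

  # a map pushing the shape negative must refuse
  bad <- map
  bad$beta_w <- c(a = -10, m = 0.1, r2 = 1)
  expect_error(map_weibull_vivo(vitro[[1L]], bad))
})

test_that("the one-step simulation keeps mass bookkeeping and positivity", {
  micro <- ref_micro()
  p <- ref_onestep()
  wb <- product_weibull("Reference")
  sched <- clinical_schedule()
  dose <- 1e7

  expect_equal(simulate_onestep(p, wb, micro, 0, sched)$concentrations,
               rep(0, length(sched)))

  out <- simulate_onestep(p, wb, micro, dose, c(sched, 48, 72),
                          return_amounts = TRUE)
  sc <- extent_scale(wb$fmax, p$SC1, p$B)
  expected_in <- dose * sc * stats::integrate(function(t)
    cutoff_phi(t, p$eta, p$tcut) *
      weibull_rate(timescale_vivo_to_vitro(t, p$s0, p$s1), wb),
    0, 72, rel.tol = 1e-10)$value
  qin <- out$amounts$Qin[nrow(out$amounts)]
  expect_equal(qin, expected_in, tolerance = 1e-3)

  # solver tolerance governs grid-independence
  dense <- simulate_onestep(p, wb, micro, dose,
                            sort(unique(c(sched, seq(0, 24, 0.1)))))
  at <- match(sched, dense$times)
  coarse <- simulate_onestep(p, wb, micro, dose, sched)
  expect_equal(coarse$concentrations, dense$concentrations[at],
               tolerance = 1e-6)

  set.seed(14)
  for (i in 1:5) {
    pr <- one_step_params(stats::runif(1, 0.5, 2), stats::runif(1, 0.7, 1.3),
                          10^stats::runif(1, -6, -4), stats::runif(1, 0.5, 2),
                          stats::runif(1, 0.5, 8), stats::runif(1, 4, 20))
    sim <- simulate_onestep(pr, wb, micro, dose, sched)
    expect_true(all(sim$concentrations >= 0))
  }
})

test_that("with the cut-off disabled the one-step input matches convolution", {
  micro <- ref_micro()
  wb <- product_weibull("Reference")
  dose <- 1e7
  # phi ~ 1 over the horizon, identity time scale, SC = 1: cumulative input
  # is dose * Fdiss(t), the same input the convolution reconstructs
  p <- one_step_params(1, 1, 1, 1e-12, 1, 1e4)
  grid <- seq(0, 24, by = 0.02)
  one <- simulate_onestep(p, wb, micro, dose, grid)
  mac <- macro_from_micro(micro)

  aucmax <- dose / (micro$Vc * micro$k10)
  fa <- absorption_profile(grid, weibull_cdf(grid, wb))
  conv <- inverse_loo_riegelman(fa, micro, aucmax)
  # compare central amounts (the two report different volume conventions)
  qc_one <- one$concentrations * mac$Vss
  qc_conv <- conv$concentrations * micro$Vc
  expect_lt(max(abs(qc_one - qc_conv)) / max(qc_conv), 0.01)
})

test_that("simultaneous fitting recovers the generating link parameters", {
  micro <- ref_micro()
  truth <- ref_onestep()
  sched <- clinical_schedule()
  dose <- 1e7
  wbs <- lapply(c("Reference", "Test1", "Test3"), product_weibull)
  plasma <- lapply(wbs, function(w)
    simulate_onestep(truth, w, micro, dose, sched))

  fit <- fit_onestep(plasma, wbs, micro, dose)
  expect_equal(fit$estimates[["SC1"]], truth$SC1, tolerance = 0.05)
  expect_equal(fit$estimates[["s0"]], truth$s0, tolerance = 0.05)
  expect_equal(fit$estimates[["s1"]], truth$s1, tolerance = 0.05)
  expect_equal(fit$estimates[["B"]], truth$B, tolerance = 0.05)

  # with the poorly identified steepness pinned, the midpoint is recovered
  fit_fix <- fit_onestep(plasma, wbs, micro, dose, fixed = c(eta = 3.623))
  expect_true(is.na(fit_fix$se[["eta"]]))
  expect_equal(fit_fix$estimates[["tcut"]], truth$tcut, tolerance = 0.10)
})

test_that("noisy plasma data are recovered within 3 SE", {
  micro <- ref_micro()
  truth <- ref_onestep()
  sched <- clinical_schedule()
  dose <- 1e7
  wbs <- lapply(c("Reference", "Test1", "Test3"), product_weibull)
  set.seed(15)
  plasma <- lapply(wbs, function(w) {
    clean <- simulate_onestep(truth, w, micro, dose, sched)
    concentration_profile(sched, pmax(
      clean$concentrations * (1 + stats::rnorm(length(sched), 0, 0.05)), 0))
  })
  # the cut-off steepness is weakly identified under noise (it runs to its
  # bound, with CV% far above 100), so it is pinned at truth and the
  # remaining five parameters are checked jointly at the Wald level
  fit <- fit_onestep(plasma, wbs, micro, dose, fixed = c(eta = truth$eta))
  free <- c("s0", "s1", "SC1", "B", "tcut")
  d <- fit$estimates[free] - unlist(truth[free])
  t2 <- drop(t(d) %*% solve(fit$cov[free, free]) %*% d)
  expect_lt(t2, stats::qchisq(0.999, df = length(free)))
})
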