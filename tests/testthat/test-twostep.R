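test_that("Levy plot recovers identity and pure time-scaling", {
  p <- product_weibull("Reference")
  levy <- build_levy(p, p)
  expect_equal(levy$slope, 1, tolerance = 1e-9)
  expect_equal(levy$intercept, 0, tolerance = 1e-9)
  expect_equal(levy$r2, 1, tolerance = 1e-12)

  # doubling all in vitro times (alpha scaled by 2^beta) halves the slope
  p2 <- weibull_params(p$alpha_w * 2^p$beta_w, p$beta_w, p$fmax)
  levy2 <- build_levy(p, p2, t_limit = 100)
  expect_equal(levy2$slope, 0.5, tolerance = 1e-9)
  expect_equal(levy2$intercept, 0, tolerance = 1e-9)

  # fractions above the smaller asymptote are excluded and counted
  lo <- weibull_params(3, 1.5, 0.60)
  levy3 <- build_levy(lo, p, fractions = seq(0.05, 0.95, by = 0.05),
                      t_limit = 100)
  expect_equal(levy3$n_excluded, sum(seq(0.05, 0.95, by = 0.05) >= 0.60))

  expect_error(build_levy(p, p, t_limit = 0.01), "fewer than 3")
})

test_that("time-rescaled dissolution refits the in vivo generator", {
  w <- product_weibull("Test3")
  t <- seq(0.25, 8, by = 0.25)
  prof <- dissolution_profile(t, weibull_cdf(t, w), product = "Test3")

  identity_levy <- build_levy(w, w)
  same <- rescale_dissolution(prof, identity_levy)
  expect_equal(unname(same$fit$estimates), c(7.000, 1.656, 0.753),
               tolerance = 1e-5)

  # a pure slow-down by factor b: refit equals the time-scaled generator
  b <- 1.4
  wv <- weibull_params(w$alpha_w * b^w$beta_w, w$beta_w, w$fmax)
  levy <- build_levy(wv, w, t_limit = 100)
  scaled <- rescale_dissolution(prof, levy)
  expect_equal(unname(scaled$fit$estimates),
               c(wv$alpha_w, wv$beta_w, wv$fmax), tolerance = 1e-6)
})

test_that("level-A regression recovers a constructed linear relation", {
  sched <- clinical_schedule()
  prods <- c("Reference", "Test1", "Test3")
  vitro <- lapply(prods, product_weibull)
  vivo <- lapply(seq_along(prods), function(j) {
    fd <- weibull_cdf(sched, vitro[[j]])
    absorption_profile(sched, pmin(0.05 + 0.9 * fd, 1), product = prods[j])
  })
  fit <- fit_levelA(vitro, vivo, t_limit = 3.5)
  expect_equal(fit$intercept_a, 0.05, tolerance = 1e-10)
  expect_equal(fit$slope_b, 0.9, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # near-constant dissolved fractions cannot support a regression
  flat <- weibull_params(1e9, 1, 0.9)
  fa <- absorption_profile(sched, seq(0, 0.5, length.out = length(sched)))
  expect_error(fit_levelA(list(flat), list(fa)), "degenerate")
})

test_that("percent prediction error keeps its sign convention", {
  expect_equal(percent_pe(100, 100), 0)
  expect_equal(percent_pe(100, 90), 10)
  expect_equal(percent_pe(90, 100), -100 / 9, tolerance = 1e-12)
  expect_error(percent_pe(0, 5), "non-zero")
})

test_that("FDA validation applies the threshold per product and metric", {
  reports <- rbind(
    pe_report("Reference", 2, -3, "internal"),
    pe_report("Test1", -9.9, 4, "internal"),
    pe_report("Test2", 12, 5, "external"))
  v <- validate_ivivc(reports)
  expect_true(v$pass_internal)
  expect_false(v$pass_external)
  # a wider threshold lets the same errors pass
  v15 <- validate_ivivc(reports, threshold = 15)
  expect_true(v15$pass_external)
  expect_error(validate_ivivc(reports, threshold = 0), "positive")

  zero <- validate_ivivc(pe_report("X", 0, 0, "internal"))
  expect_true(zero$pass_internal)
  expect_true(is.na(zero$pass_external))
})

test_that("the full two-step loop closes on self-consistent data", {
  dat <- closed_loop_dataset()
  cfg <- run_config(dat$plasma, dat$dissolution, dat$micro, dose_mg = 10)
  rep <- suppressWarnings(run_two_step(cfg))
  expect_lt(max(abs(rep$pe$pe_cmax)), 1)
  expect_lt(max(abs(rep$pe$pe_auc)), 1)
  expect_true(rep$validation$pass_internal)
  expect_equal(rep$levy$slope, dat$levy_slope, tolerance = 0.01)
})

test_that("omitting time scaling degrades the correlation and predictions", {
  dat <- closed_loop_dataset(levy_slope = 1.5)
  micro <- dat$micro
  aucmax_est <- max(vapply(split(dat$plasma, dat$plasma$product), function(d)
    nca(concentration_profile(d$time_h, d$conc_ng_ml))$auc_inf, 0))
  fabs <- lapply(split(dat$plasma, dat$plasma$product), function(d)
    loo_riegelman(concentration_profile(d$time_h, d$conc_ng_ml,
                                        product = d$product[1L]),
                  micro, aucmax_est))
  vivo_fits <- lapply(fabs, function(f) fit_weibull(f)$params)
  vitro_fits <- lapply(split(dat$dissolution, dat$dissolution$product),
                       function(d) fit_weibull(dissolution_profile(
                         unique(d$time_h),
                         d$fraction[order(d$time_h)],
                         product = d$product[1L]))$params)
  ord <- names(vivo_fits)
  vitro_fits <- vitro_fits[ord]

  levy <- build_levy(vivo_fits, vitro_fits)
  scaled <- lapply(vitro_fits, function(w)
    rescale_dissolution(w, levy)$fit$params)
  with_scaling <- fit_levelA(scaled, fabs)
  without_scaling <- fit_levelA(vitro_fits, fabs)
  expect_gt(with_scaling$r2, without_scaling$r2)

  # prediction error inflates without the time scaling
  idmap <- build_levy(vitro_fits[[1L]], vitro_fits[[1L]])
  pe_of <- function(levy_used, levelA_used) {
    max(vapply(ord, function(nm) {
      d <- dat$plasma[dat$plasma$product == nm, ]
      obs <- concentration_profile(d$time_h, d$conc_ng_ml, product = nm)
      vit <- dissolution_profile(
        dat$dissolution$time_h[dat$dissolution$product == nm],
        dat$dissolution$fraction[dat$dissolution$product == nm], product = nm)
      pred <- predict_plasma_twostep(vit, levy_used, levelA_used, micro,
                                     aucmax_est, obs$times)
      abs(percent_pe(max(obs$concentrations), max(pred$concentrations)))
    }, 0))
  }
  expect_gt(pe_of(idmap, without_scaling), pe_of(levy, with_scaling))
  expect_gt(pe_of(idmap, without_scaling), 1)
})

test_that("predicted Cmax responds monotonically to the level-A slope", {
  dat <- closed_loop_dataset()
  cfg <- run_config(dat$plasma, dat$dissolution, dat$micro)
  rep <- suppressWarnings(run_two_step(cfg))
  lA <- rep$levelA
  lA_half <- lA
  lA_half$slope_b <- lA$slope_b / 2
  vit <- dissolution_profile(
    dat$dissolution$time_h[dat$dissolution$product == "Reference"],
    dat$dissolution$fraction[dat$dissolution$product == "Reference"],
    product = "Reference")
  full <- predict_plasma_twostep(vit, rep$levy, lA, dat$micro,
                                 rep$inputs$auc_inf_max, dat$sched)
  half <- predict_plasma_twostep(vit, rep$levy, lA_half, dat$micro,
                                 rep$inputs$auc_inf_max, dat$sched)
  expect_lt(max(half$concentrations), max(full$concentrations))

  # zero dissolution predicts zero plasma
  zero <- dissolution_profile(seq(0.5, 8, 0.5), rep(0, 16), product = "none")
  none <- predict_plasma_twostep(zero, rep$levy, lA, dat$micro,
                                 rep$inputs$auc_inf_max, dat$sched)
  expect_lt(max(none$concentrations), 1e-5 * max(full$concentrations))
})
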