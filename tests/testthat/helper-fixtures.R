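# Shared fixtures: the published two-compartment disposition constants, the
# time-corrected Weibull parameter sets of the four study products, the
# one-step link-parameter set, and the clinical sampling schedule.

ref_micro <- function() pk_micro_params(k10 = 0.65, k12 = 1.15, k21 = 0.90,
                                         Vc = 2754.74)

product_weibull <- function(product = c("Reference", "Test1", "Test2", "Test3")) {
  product <- match.arg(product)
  switch(product,
    Reference = weibull_params(2.916, 1.545, 0.863),
    Test1     = weibull_params(4.180, 2.163, 1.023),
    Test2     = weibull_params(5.395, 2.108, 0.930),
    Test3     = weibull_params(7.000, 1.656, 0.753))
}

ref_onestep <- function() one_step_params(s0 = 1.069, s1 = 0.967,
                                           SC1 = 1.55e-5, B = 1.402,
                                           eta = 3.623, tcut = 9.585)

clinical_schedule <- function() c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.25, 3.5, 3.75,
                                  4, 4.25, 4.5, 5, 6, 8, 12, 16, 20, 24)

# numeric ODE oracle: two-compartment disposition driven by an arbitrary
# input rate (ng/h), returning concentration Qc/Vc at `times`
ode_conc_oracle <- function(rate_fn, micro, times, rtol = 1e-10, atol = 1e-12) {
  deriv <- function(t, y, parms) {
    list(c(rate_fn(t) - (micro$k10 + micro$k12) * y[1L] + micro$k21 * y[2L],
           micro$k12 * y[1L] - micro$k21 * y[2L]))
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::ode(c(0, 0), tt, deriv, NULL, rtol = rtol, atol = atol)
  sol[match(times, tt), 2L] / micro$Vc
}

# Self-consistent two-step dataset: observed plasma is produced by the
# package's own discrete convolution on a grid with hourly late sampling, so
# the deconvolution/correlation/reconvolution chain can close exactly. The
# in vivo clock runs `levy_slope` times slower than the in vitro one and the
# largest asymptote is 1 (the normalization convention: the best product
# defines auc_inf_max).
closed_loop_dataset <- function(levy_slope = 1.2, aucmax = 2000,
                                fmax = c(Reference = 0.91, Test1 = 1.00,
                                         Test3 = 0.79)) {
  micro <- ref_micro()
  sched <- c(seq(0, 5, by = 0.25), seq(6, 24, by = 1))
  shapes <- list(Reference = c(2.916, 1.545), Test1 = c(4.180, 2.163),
                 Test3 = c(7.000, 1.656))
  dt <- seq(0.25, 8, by = 0.25)
  plasma <- NULL; diss <- NULL; vitro <- list(); vivo <- list()
  for (nm in names(fmax)) {
    w <- weibull_params(shapes[[nm]][1L], shapes[[nm]][2L], fmax[[nm]])
    wv <- weibull_params(w$alpha_w * levy_slope^w$beta_w, w$beta_w, w$fmax)
    fa <- absorption_profile(sched, weibull_cdf(sched, wv), product = nm)
    cp <- inverse_loo_riegelman(fa, micro, aucmax, product = nm)
    plasma <- rbind(plasma, data.frame(product = nm, subject = "mean",
                                       time_h = sched,
                                       conc_ng_ml = cp$concentrations))
    diss <- rbind(diss, data.frame(product = nm, replicate = 1L, time_h = dt,
                                   fraction = weibull_cdf(dt, w)))
    vitro[[nm]] <- w; vivo[[nm]] <- wv
  }
  list(plasma = plasma, dissolution = diss, micro = micro, sched = sched,
       aucmax = aucmax, levy_slope = levy_slope, vitro = vitro, vivo = vivo)
}
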