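#' Three-parameter Weibull release parameters
#'
#' Parameters of the cumulative release model
#' \deqn{F(t) = F_{max}\,(1 - e^{-t^{\beta}/\alpha})}
#' with scale `alpha_w` (units h^beta_w), shape `beta_w` (dimensionless) and
#' asymptotic released fraction `Fmax`. `Fmax` may exceed 1 slightly (up to
#' 1.25) because dissolved fractions are expressed against the label dose.
#'
#' @param alpha_w Scale, > 0.
#' @param beta_w Shape, > 0.
#' @param fmax Asymptotic fraction, in (0, 1.25].
#' @param flavor `"vitro"` or `"vivo"`, a bookkeeping label.
#'
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(alpha_w, beta_w, fmax, flavor = "vitro") {
  if (!is.numeric(alpha_w) || alpha_w <= 0) stop("alpha_w must be > 0")
  if (!is.numeric(beta_w) || beta_w <= 0) stop("beta_w must be > 0")
  if (!is.numeric(fmax) || fmax <= 0 || fmax > 1.25)
    stop("Fmax must lie in (0, 1.25]")
  structure(list(alpha_w = alpha_w, beta_w = beta_w, fmax = fmax,
                 flavor = flavor),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("<weibull_params %s> alpha=%.4g h^beta, beta=%.4g, Fmax=%.4g\n",
              x$flavor, x$alpha_w, x$beta_w, x$fmax))
  invisible(x)
}

#' Weibull cumulative release
#'
#' @param t Times (h), >= 0; vectorized.
#' @param p A [weibull_params()] object.
#' @return Dissolved fractions `fmax * (1 - exp(-t^beta_w / alpha_w))`.
#' @export
weibull_cdf <- function(t, p) {
  stopifnot(inherits(p, "weibull_params"))
  if (any(t < 0)) stop("negative times not allowed")
  p$fmax * (1 - exp(-(t^p$beta_w) / p$alpha_w))
}

#' Weibull inverse: time to reach a fraction
#'
#' Algebraic inverse of [weibull_cdf()]:
#' \deqn{t(f) = \left(-\alpha \ln\frac{F_{max}-f}{F_{max}}\right)^{1/\beta}}
#' so that `weibull_cdf(weibull_inverse(f, p), p) == f`.
#'
#' @param f Fractions, `0 <= f < fmax`; vectorized.
#' @param p A [weibull_params()] object.
#' @return Times (h).
#' @export
weibull_inverse <- function(f, p) {
  stopifnot(inherits(p, "weibull_params"))
  if (any(f < 0)) stop("fractions must be >= 0")
  if (any(f >= p$fmax)) stop("fraction at or above Fmax is never reached")
  (-p$alpha_w * log((p$fmax - f) / p$fmax))^(1 / p$beta_w)
}

#' Weibull release rate
#'
#' Exact time-derivative of [weibull_cdf()]:
#' \deqn{r(t) = F_{max}\frac{\beta}{\alpha} t^{\beta-1} e^{-t^\beta/\alpha}}
#' so that the rate integrates to `Fmax` over \[0, Inf). `t = 0` is only
#' admissible for `beta_w >= 1` (the rate is singular below).
#'
#' @param t Times (h); vectorized.
#' @param p A [weibull_params()] object.
#' @return Release rates (fraction/h), non-negative.
#' @export
weibull_rate <- function(t, p) {
  stopifnot(inherits(p, "weibull_params"))
  if (any(t < 0)) stop("negative times not allowed")
  if (p$beta_w < 1 && any(t == 0))
    stop("rate is singular at t = 0 for shape < 1")
  out <- p$fmax * (p$beta_w / p$alpha_w) * t^(p$beta_w - 1) *
    exp(-(t^p$beta_w) / p$alpha_w)
  # beta_w == 1 gives t^0 = 1 even at t = 0; beta_w > 1 gives 0 * finite
  out[t == 0 & p$beta_w > 1] <- 0
  out
}

#' Fit the three-parameter Weibull model
#'
#' Bounded Levenberg-Marquardt least squares of the mean release profile.
#' Starting values are deterministic: `Fmax0` is the largest observed
#' fraction, `beta0 = 1`, and `alpha0` makes the one-shape model pass through
#' the half-maximal observation. Bounds keep `alpha_w, beta_w > 0` and
#' `0 < Fmax <= 1.25`.
#'
#' @param profile A [dissolution_profile()] or [absorption_profile()]
#'   (fractions absorbed are modelled with the same equation), >= 4 time
#'   points with at least one positive fraction.
#' @param start Optional named vector `c(alpha_w=, beta_w=, fmax=)`
#'   overriding the default initialization.
#'
#' @return A list of class `weibull_fit` with `params`
#'   ([weibull_params()]), `se`, `cov` (parameter covariance), `cv_pct`,
#'   `rss`, `r2`, `fitted`.
#' @export
fit_weibull <- function(profile, start = NULL) {
  if (inherits(profile, "dissolution_profile")) {
    t <- profile$times; f <- profile$fractions; flavor <- "vitro"
  } else if (inherits(profile, "absorption_profile")) {
    t <- profile$times; f <- profile$fabs; flavor <- "vivo"
  } else stop("profile must be a dissolution_profile or absorption_profile")
  keep <- t >= 0
  t <- t[keep]; f <- f[keep]
  if (length(t) < 4L) stop("need at least 4 time points")
  if (all(f <= 0)) stop("all fractions are zero; nothing to fit")

  if (is.null(start)) {
    fmax0 <- min(max(f), 1.249)
    beta0 <- 1
    # time at which the profile crosses half of Fmax0, by interpolation
    above <- which(f >= fmax0 / 2)
    t_half <- if (length(above)) t[above[1L]] else stats::median(t[t > 0])
    alpha0 <- max(t_half, 1e-3) / log(2)
    start <- c(alpha_w = alpha0, beta_w = beta0, fmax = fmax0)
  }
  start <- pmin(pmax(start, c(1e-6, 1e-6, 1e-6)), c(Inf, Inf, 1.25))

  residfun <- function(par) {
    p <- weibull_params(par[1L], par[2L], par[3L], flavor = flavor)
    f - weibull_cdf(t, p)
  }
  fit <- minpack.lm::nls.lm(par = start, fn = residfun,
                            lower = c(1e-9, 1e-9, 1e-9),
                            upper = c(Inf, 20, 1.25),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  if (fit$info %in% c(0L, 9L))
    stop(sprintf("Weibull fit did not converge (objective %.6g)", fit$deviance))
  est <- fit$par
  names(est) <- c("alpha_w", "beta_w", "fmax")
  dof <- length(t) - 3L
  sigma2 <- if (dof > 0) fit$deviance / dof else NA_real_
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(covm)) rep(NA_real_, 3L) else sqrt(pmax(diag(covm), 0))
  names(se) <- names(est)
  if (!is.null(covm)) dimnames(covm) <- list(names(est), names(est))
  params <- weibull_params(est[["alpha_w"]], est[["beta_w"]], est[["fmax"]],
                           flavor = flavor)
  fitted <- weibull_cdf(t, params)
  structure(list(params = params, estimates = est, se = se, cov = covm,
                 cv_pct = 100 * se / abs(est), rss = fit$deviance,
                 r2 = 1 - fit$deviance / max(sum((f - mean(f))^2), 1e-300),
                 times = t, observed = f, fitted = fitted,
                 convergence = fit$info),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (%s): alpha=%.4g beta=%.4g Fmax=%.4g, RSS=%.3g, R2=%.4f\n",
              x$params$flavor, x$estimates[1L], x$estimates[2L],
              x$estimates[3L], x$rss, x$r2))
  invisible(x)
}

#' f2 dissolution similarity factor
#'
#' \deqn{f_2 = 50 \log_{10}\left(100\left[1 + \tfrac{1}{n}\sum (R_t - T_t)^2
#' \right]^{-1/2}\right)}
#' with reference and test expressed in percent dissolved. Identical profiles
#' give 100; 50 is the conventional similarity boundary. By default all
#' common time points enter the sum; `guard_85 = TRUE` applies the usual
#' regulatory truncation keeping at most one point after the reference
#' exceeds 85% dissolved.
#'
#' @param ref,test [dissolution_profile()]s on identical time grids with at
#'   least 3 points.
#' @param guard_85 Apply the 85%-dissolved truncation guard (default FALSE).
#'
#' @return The f2 score (<= 100).
#' @export
f2_similarity <- function(ref, test, guard_85 = FALSE) {
  stopifnot(inherits(ref, "dissolution_profile"),
            inherits(test, "dissolution_profile"))
  if (length(ref$times) != length(test$times) ||
      any(abs(ref$times - test$times) > 1e-9))
    stop("profiles must share an identical time grid")
  Rt <- 100 * ref$fractions
  Tt <- 100 * test$fractions
  keep <- ref$times > 0 | Rt > 0 | Tt > 0   # drop a shared t=0 zero point
  Rt <- Rt[keep]; Tt <- Tt[keep]
  if (guard_85) {
    over <- which(Rt > 85)
    if (length(over) > 1L) {
      last <- over[1L]
      Rt <- Rt[seq_len(last)]; Tt <- Tt[seq_len(last)]
    }
  }
  n <- length(Rt)
  if (n < 3L) stop("need at least 3 time points for f2")
  50 * log10(100 / sqrt(1 + sum((Rt - Tt)^2) / n))
}
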