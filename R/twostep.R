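#' Levy plot time-scaling fit
#'
#' Builds the Levy plot relating in vivo to in vitro times: for each fraction
#' on `fractions`, the time needed to absorb it in vivo and to dissolve it in
#' vitro are obtained from the respective fitted Weibull models via
#' [weibull_inverse()], and a straight line `t_vivo = intercept + slope *
#' t_vitro` is fitted over the pairs with `t_vivo <= t_limit`. Fractions at or
#' above either model's asymptote are excluded (their time is undefined);
#' the number excluded is recorded.
#'
#' Several products can be pooled into one shared mapping by passing lists
#' of parameter objects (paired by position).
#'
#' @param vivo A [weibull_params()] fitted to fractions absorbed, or a list
#'   of them (one per product).
#' @param vitro A [weibull_params()] fitted to the dissolution profile, or a
#'   list matching `vivo`.
#' @param fractions Fraction grid probed (default 0.05 to 0.95 by 0.05).
#' @param t_limit In vivo time cut-off (h) for pair inclusion; default 3.5 h,
#'   beyond which the in vitro/in vivo relation is no longer a single
#'   function for slowly absorbed drugs.
#' @param through_origin Force a zero intercept (default FALSE).
#'
#' @return An object of class `levy_mapping` with `pairs`, `slope`,
#'   `intercept`, `r2`, `t_limit`, `n_excluded`.
#' @export
build_levy <- function(vivo, vitro, fractions = seq(0.05, 0.95, by = 0.05),
                       t_limit = 3.5, through_origin = FALSE) {
  if (inherits(vivo, "weibull_params")) vivo <- list(vivo)
  if (inherits(vitro, "weibull_params")) vitro <- list(vitro)
  stopifnot(length(vivo) == length(vitro))
  pairs <- NULL
  n_excluded <- 0L
  for (j in seq_along(vivo)) {
    fmax_min <- min(vivo[[j]]$fmax, vitro[[j]]$fmax)
    ok <- fractions < fmax_min
    n_excluded <- n_excluded + sum(!ok)
    f <- fractions[ok]
    if (!length(f)) next
    pairs <- rbind(pairs, data.frame(
      product = j, fraction = f,
      t_vivo = weibull_inverse(f, vivo[[j]]),
      t_vitro = weibull_inverse(f, vitro[[j]])))
  }
  if (is.null(pairs)) stop("no admissible fraction pairs")
  keep <- pairs$t_vivo <= t_limit
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 3L)
    stop("fewer than 3 admissible (t_vivo, t_vitro) pairs below t_limit")
  fit <- if (through_origin) stats::lm(t_vivo ~ t_vitro - 1, data = pairs)
         else stats::lm(t_vivo ~ t_vitro, data = pairs)
  cf <- stats::coef(fit)
  slope <- unname(cf[["t_vitro"]])
  intercept <- if (through_origin) 0 else unname(cf[["(Intercept)"]])
  if (slope <= 0) stop("Levy slope must be positive")
  structure(list(pairs = pairs, slope = slope, intercept = intercept,
                 r2 = suppressWarnings(summary(fit)$r.squared), t_limit = t_limit,
                 n_excluded = n_excluded, through_origin = through_origin),
            class = "levy_mapping")
}

#' @export
print.levy_mapping <- function(x, ...) {
  cat(sprintf("<levy_mapping> t_vivo = %.4g + %.4g * t_vitro (r2=%.4f, %d pairs <= %g h, %d fractions excluded)\n",
              x$intercept, x$slope, x$r2, nrow(x$pairs), x$t_limit,
              x$n_excluded))
  invisible(x)
}

#' Time-scale a dissolution profile to the in vivo clock
#'
#' Transforms in vitro times to their in vivo equivalents through a Levy
#' mapping (`t_scaled = intercept + slope * t_vitro`) and refits the Weibull
#' model on the scaled clock, giving "time-corrected" release parameters.
#' Negative scaled times (possible with a negative intercept) are clamped to
#' zero with a warning.
#'
#' @param vitro A [dissolution_profile()], or a [weibull_params()] object
#'   (in which case a noise-free profile is generated on `grid` first).
#' @param levy A [levy_mapping()].
#' @param grid Evaluation grid used when `vitro` is a parameter object.
#'
#' @return A list with `profile` (the time-scaled [dissolution_profile()])
#'   and `fit` (the refitted [fit_weibull()] result); `fit$params` are the
#'   time-corrected Weibull parameters.
#' @export
rescale_dissolution <- function(vitro, levy, grid = seq(0.25, 12, by = 0.25)) {
  stopifnot(inherits(levy, "levy_mapping"))
  if (inherits(vitro, "weibull_params")) {
    vitro <- dissolution_profile(grid, weibull_cdf(grid, vitro),
                                 product = "weibull")
  }
  stopifnot(inherits(vitro, "dissolution_profile"))
  t_scaled <- levy$intercept + levy$slope * vitro$times
  if (any(t_scaled < 0)) {
    warning("negative scaled times clamped to 0")
    t_scaled <- pmax(t_scaled, 0)
  }
  keep <- !duplicated(t_scaled)
  prof <- dissolution_profile(t_scaled[keep], vitro$fractions[keep],
                              sd = vitro$sd[keep], product = vitro$product,
                              n_units = vitro$n_units)
  list(profile = prof, fit = fit_weibull(prof))
}

#' Level-A in vitro-in vivo correlation
#'
#' Ordinary least squares of fractions absorbed on fractions dissolved at
#' matched (in vivo) times, pooled across products:
#' `fabs = intercept_a + slope_b * fdiss`. Fractions dissolved are evaluated
#' from the time-corrected Weibull parameters at each product's in vivo
#' sampling times up to `t_limit`.
#'
#' @param scaled_vitro List of time-corrected [weibull_params()] per product.
#' @param vivo List of [absorption_profile()]s per product (same order).
#' @param t_limit Time cut-off (h), default 3.5.
#'
#' @return An object of class `levelA_correlation` with `intercept_a`,
#'   `slope_b`, `r2`, `t_limit`, `n_points`, `data`, and `per_product`
#'   diagnostic fits.
#' @export
fit_levelA <- function(scaled_vitro, vivo, t_limit = 3.5) {
  if (inherits(scaled_vitro, "weibull_params")) scaled_vitro <- list(scaled_vitro)
  if (inherits(vivo, "absorption_profile")) vivo <- list(vivo)
  stopifnot(length(scaled_vitro) == length(vivo))
  dat <- NULL
  for (j in seq_along(vivo)) {
    keep <- vivo[[j]]$times <= t_limit
    tt <- vivo[[j]]$times[keep]
    dat <- rbind(dat, data.frame(
      product = vivo[[j]]$product,
      time_h = tt,
      fdiss = weibull_cdf(tt, scaled_vitro[[j]]),
      fabs = vivo[[j]]$fabs[keep]))
  }
  if (is.null(dat) || nrow(dat) < 4L)
    stop("need at least 4 pooled (fdiss, fabs) points below t_limit")
  if (stats::var(dat$fdiss) < 1e-12)
    stop("degenerate level-A regression: fractions dissolved have no variance")
  fit <- stats::lm(fabs ~ fdiss, data = dat)
  per_product <- lapply(split(dat, dat$product), function(d) {
    if (nrow(d) >= 3L && stats::var(d$fdiss) > 1e-12) {
      f <- stats::lm(fabs ~ fdiss, data = d)
      c(intercept_a = unname(stats::coef(f)[1L]),
        slope_b = unname(stats::coef(f)[2L]),
        r2 = suppressWarnings(summary(f)$r.squared))
    } else c(intercept_a = NA_real_, slope_b = NA_real_, r2 = NA_real_)
  })
  structure(list(intercept_a = unname(stats::coef(fit)[1L]),
                 slope_b = unname(stats::coef(fit)[2L]),
                 r2 = suppressWarnings(summary(fit)$r.squared), t_limit = t_limit,
                 n_points = nrow(dat), data = dat,
                 per_product = per_product),
            class = "levelA_correlation")
}

#' @export
print.levelA_correlation <- function(x, ...) {
  cat(sprintf("<levelA_correlation> fabs = %.4g + %.4g * fdiss (r2=%.4f, %d points <= %g h)\n",
              x$intercept_a, x$slope_b, x$r2, x$n_points, x$t_limit))
  invisible(x)
}

#' Predict plasma levels through the two-step IVIVC
#'
#' Chains the full forward path: fractions dissolved from the time-corrected
#' Weibull model at the requested in vivo times, mapped to predicted
#' fractions absorbed by the level-A line (clipped to \[0, 1\] and forced
#' non-decreasing by a running maximum), then convoluted with
#' [inverse_loo_riegelman()].
#'
#' @param vitro [dissolution_profile()] or [weibull_params()] of the product.
#' @param levy A [levy_mapping()].
#' @param levelA A `levelA_correlation`.
#' @param micro A [pk_micro_params()].
#' @param auc_inf_max Normalizing AUC0-inf (ng h/mL).
#' @param times In vivo sampling times (h) for the prediction.
#' @param product Label for the output profile.
#'
#' @return A [concentration_profile()] of predicted plasma levels.
#' @export
predict_plasma_twostep <- function(vitro, levy, levelA, micro, auc_inf_max,
                                   times, product = "predicted") {
  stopifnot(inherits(levelA, "levelA_correlation"))
  if (inherits(vitro, "dissolution_profile") && all(vitro$fractions == 0)) {
    fdiss <- rep(0, length(times))   # nothing dissolves, nothing to absorb
  } else {
    scaled <- rescale_dissolution(vitro, levy)
    fdiss <- weibull_cdf(times, scaled$fit$params)
  }
  fabs <- levelA$intercept_a + levelA$slope_b * fdiss
  fabs <- cummax(pmin(pmax(fabs, 0), 1))
  fa <- absorption_profile(times, fabs, product = product)
  inverse_loo_riegelman(fa, micro, auc_inf_max, product = product)
}

#' Signed percent prediction error
#'
#' `%PE = (observed - predicted) / observed * 100`; the sign is retained, so
#' over-prediction gives a negative value.
#'
#' @param observed Observed value (non-zero).
#' @param predicted Predicted value.
#' @return Signed percent error.
#' @export
percent_pe <- function(observed, predicted) {
  if (any(observed == 0)) stop("observed value must be non-zero")
  (observed - predicted) / observed * 100
}

#' Prediction-error report row
#'
#' @param product Product label.
#' @param pe_cmax,pe_auc Signed percent prediction errors for Cmax and AUC.
#' @param scope `"internal"` (product used to build the correlation) or
#'   `"external"` (held-out validation product).
#' @return A one-row data.frame of class `pe_report`.
#' @export
pe_report <- function(product, pe_cmax, pe_auc,
                      scope = c("internal", "external")) {
  scope <- match.arg(scope)
  if (!is.finite(pe_cmax) || !is.finite(pe_auc))
    stop("prediction errors must be finite")
  structure(data.frame(product = product, scope = scope,
                       pe_cmax = pe_cmax, pe_auc = pe_auc),
            class = c("pe_report", "data.frame"))
}

#' Validate an IVIVC by the FDA percent-prediction-error criterion
#'
#' Each product/metric passes when `|%PE|` is below `threshold` (10% by
#' default, the FDA level-A acceptance limit). Internal and external
#' products are summarized separately.
#'
#' @param reports A data.frame with columns `product`, `scope`, `pe_cmax`,
#'   `pe_auc` (e.g. stacked [pe_report()] rows), or a list of such rows.
#' @param threshold Acceptance limit in percent (> 0), default 10.
#'
#' @return A list of class `ivivc_validation` with the per-product `table`
#'   (logical pass columns added), `pass_internal`, `pass_external` (NA when
#'   no external product), and `threshold`.
#' @export
validate_ivivc <- function(reports, threshold = 10) {
  if (threshold <= 0) stop("threshold must be positive")
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  stopifnot(all(c("product", "scope", "pe_cmax", "pe_auc") %in% names(reports)))
  tab <- as.data.frame(reports)
  tab$pass_cmax <- abs(tab$pe_cmax) < threshold
  tab$pass_auc <- abs(tab$pe_auc) < threshold
  internal <- tab$scope == "internal"
  external <- tab$scope == "external"
  structure(list(
    table = tab,
    pass_internal = all(tab$pass_cmax[internal]) && all(tab$pass_auc[internal]),
    pass_external = if (any(external))
      all(tab$pass_cmax[external]) && all(tab$pass_auc[external]) else NA,
    threshold = threshold),
    class = "ivivc_validation")
}

#' @export
print.ivivc_validation <- function(x, ...) {
  cat(sprintf("IVIVC validation at |%%PE| < %g%%\n", x$threshold))
  print(x$table, row.names = FALSE)
  cat(sprintf("internal: %s; external: %s\n",
              if (x$pass_internal) "PASS" else "FAIL",
              if (is.na(x$pass_external)) "none"
              else if (x$pass_external) "PASS" else "FAIL"))
  invisible(x)
}
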