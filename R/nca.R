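#' Linear trapezoidal AUC
#'
#' Area under a plasma concentration-time curve on \[0, t_end\] by the linear
#' trapezoidal rule. If `t_end` falls between samples the profile is linearly
#' interpolated at `t_end`.
#'
#' @param profile A [concentration_profile()].
#' @param t_end Upper integration limit (h), defaults to the last sample
#'   time; must not exceed it.
#'
#' @return Area (ng h/mL).
#' @export
auc_trapezoid <- function(profile, t_end = NULL) {
  stopifnot(inherits(profile, "concentration_profile"))
  t <- profile$times; y <- profile$concentrations
  if (is.null(t_end)) t_end <- t[length(t)]
  if (t_end > t[length(t)]) stop("t_end beyond the last sample time")
  if (t_end < t[2L]) stop("t_end must not precede the second sample")
  keep <- t <= t_end
  tt <- t[keep]; yy <- y[keep]
  if (tt[length(tt)] < t_end) {
    tt <- c(tt, t_end)
    yy <- c(yy, stats::approx(t, y, xout = t_end)$y)
  }
  sum(diff(tt) * (yy[-1L] + yy[-length(yy)]) / 2)
}

#' Terminal elimination rate constant
#'
#' Slope of the log-linear terminal phase. Candidate windows are all
#' contiguous runs of at least `min_points` positive-concentration samples
#' strictly after Tmax and extending to the last positive sample; the window
#' with the best adjusted R-squared of the `ln(C)` vs `t` regression is
#' selected, ties broken in favour of the longest window.
#'
#' @param profile A [concentration_profile()].
#' @param min_points Minimum window size (default 3).
#'
#' @return List with `K` (1/h, positive), `n_points`, `r2_adj`, `intercept`
#'   (on the log scale) and the selected `window` times.
#' @export
terminal_K <- function(profile, min_points = 3L) {
  stopifnot(inherits(profile, "concentration_profile"))
  t <- profile$times; y <- profile$concentrations
  i_max <- which.max(y)
  post <- which(seq_along(t) > i_max & y > 0)
  if (length(post) < min_points)
    stop("need at least 3 positive post-peak samples for the terminal phase")
  best <- NULL
  # suffix windows of the positive post-peak samples
  for (start in seq_len(length(post) - min_points + 1L)) {
    idx <- post[start:length(post)]
    fit <- stats::lm(log(y[idx]) ~ t[idx])
    slope <- stats::coef(fit)[2L]
    if (slope >= 0) next
    # noise-free profiles fit perfectly; the lm warning is expected there
    r2a <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || r2a > best$r2_adj + 1e-12)
      best <- list(K = -unname(slope), n_points = length(idx), r2_adj = r2a,
                   intercept = unname(stats::coef(fit)[1L]), window = t[idx])
  }
  if (is.null(best))
    stop("no terminal phase: log-linear slope non-negative in every window")
  best
}

#' Non-compartmental analysis of a plasma profile
#'
#' AUC to the last sample by trapezoids, extrapolated area `C_last/K`, their
#' sum `auc_inf`, observed Cmax/Tmax and the terminal rate constant K.
#'
#' @param profile A [concentration_profile()].
#' @param t_end Upper limit of the observed AUC (defaults to last sample).
#'
#' @return A list of class `nca_result` with `auc_0_t`, `auc_extra`,
#'   `auc_inf`, `cmax`, `tmax`, `K`, `K_n_points`.
#' @export
nca <- function(profile, t_end = NULL) {
  stopifnot(inherits(profile, "concentration_profile"))
  term <- terminal_K(profile)
  auc_0_t <- auc_trapezoid(profile, t_end)
  c_last <- profile$concentrations[length(profile$concentrations)]
  auc_extra <- c_last / term$K
  i <- which.max(profile$concentrations)
  structure(list(
    auc_0_t = auc_0_t, auc_extra = auc_extra, auc_inf = auc_0_t + auc_extra,
    cmax = profile$concentrations[i], tmax = profile$times[i],
    K = term$K, K_n_points = term$n_points, product = profile$product),
    class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s: Cmax=%.4g ng/mL at %g h, AUC0-t=%.5g, AUCinf=%.5g ng*h/mL, K=%.4g 1/h (%d pts)\n",
              x$product, x$cmax, x$tmax, x$auc_0_t, x$auc_inf, x$K,
              x$K_n_points))
  invisible(x)
}

#' Interpolate a profile onto a time grid
#'
#' Linear interpolation on the linear concentration scale; exact at original
#' sampling times. Extrapolation outside the sampled range is refused.
#'
#' @param profile A [concentration_profile()].
#' @param grid Target times (h) within the sampled range.
#'
#' @return A [concentration_profile()] on `grid`.
#' @export
interpolate_to_grid <- function(profile, grid) {
  stopifnot(inherits(profile, "concentration_profile"))
  t <- profile$times
  if (any(grid < t[1L]) || any(grid > t[length(t)]))
    stop("interpolation grid outside the sampled range (extrapolation refused)")
  conc <- stats::approx(t, profile$concentrations, xout = grid)$y
  concentration_profile(grid, conc, product = profile$product,
                        subject = profile$subject)
}

#' Cross-study normalization by reference concentration ratios
#'
#' Makes the plasma profiles of one study comparable with a second study that
#' shared the same reference product: both reference mean profiles are
#' interpolated to the combined grid (sorted union of both studies' sampling
#' times restricted to their common range) and each study-1 concentration is
#' multiplied by the pointwise `Ref2/Ref1` ratio
#' (`Cp_corrected = Cp_observed * Ref2/Ref1`). Where both references are zero
#' (the pre-dose sample) the factor is taken as 1.
#'
#' @param study1_profiles A list of [concentration_profile()]s from study 1.
#' @param ref_study1,ref_study2 Reference-product mean profiles observed in
#'   study 1 and study 2.
#'
#' @return A list with `profiles` (corrected study-1 profiles on the combined
#'   grid), `grid`, and `factor` (the pointwise correction).
#' @export
normalize_cross_study <- function(study1_profiles, ref_study1, ref_study2) {
  if (inherits(study1_profiles, "concentration_profile"))
    study1_profiles <- list(study1_profiles)
  stopifnot(inherits(ref_study1, "concentration_profile"),
            inherits(ref_study2, "concentration_profile"))
  lo <- max(ref_study1$times[1L], ref_study2$times[1L],
            vapply(study1_profiles, function(p) p$times[1L], 0))
  hi <- min(max(ref_study1$times), max(ref_study2$times),
            vapply(study1_profiles, function(p) max(p$times), 0))
  grid <- sort(unique(c(ref_study1$times, ref_study2$times)))
  grid <- grid[grid >= lo & grid <= hi]
  r1 <- interpolate_to_grid(ref_study1, grid)$concentrations
  r2 <- interpolate_to_grid(ref_study2, grid)$concentrations
  factor <- rep(1, length(grid))
  both_pos <- r1 > 0
  factor[both_pos] <- r2[both_pos] / r1[both_pos]
  bad <- r1 == 0 & r2 > 0 & grid > 0
  if (any(bad))
    stop("undefined normalization factor: Ref1 = 0 with Ref2 > 0 at t > 0")
  corrected <- lapply(study1_profiles, function(p) {
    ip <- interpolate_to_grid(p, grid)
    concentration_profile(grid, ip$concentrations * factor,
                          product = p$product, subject = p$subject)
  })
  list(profiles = corrected, grid = grid, factor = factor)
}
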