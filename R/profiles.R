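#' Plasma concentration-time profile
#'
#' Container for a single plasma concentration-time course, either an
#' individual subject or a study mean. Times are hours, concentrations ng/mL.
#'
#' @param times Numeric vector of sampling times (h), strictly increasing,
#'   first value >= 0.
#' @param concentrations Numeric vector of plasma concentrations (ng/mL),
#'   non-negative, same length as `times`.
#' @param product Product label.
#' @param subject Subject label, or `"mean"` for an average profile.
#'
#' @return An object of class `concentration_profile`.
#' @export
concentration_profile <- function(times, concentrations, product = "product",
                                  subject = "mean") {
  stopifnot(is.numeric(times), is.numeric(concentrations))
  if (length(times) != length(concentrations))
    stop("`times` and `concentrations` must have equal length")
  if (length(times) == 0L) stop("empty profile")
  if (anyNA(times) || anyNA(concentrations))
    stop("missing values in profile")
  if (times[1L] < 0) stop("first sampling time must be >= 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concentrations < 0)) stop("negative concentrations not allowed")
  structure(
    list(times = as.numeric(times),
         concentrations = as.numeric(concentrations),
         product = as.character(product), subject = as.character(subject)),
    class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("<concentration_profile> product=%s subject=%s, %d samples over [%g, %g] h, Cmax=%.4g ng/mL\n",
              x$product, x$subject, length(x$times), min(x$times),
              max(x$times), max(x$concentrations)))
  invisible(x)
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(product = x$product, subject = x$subject,
             time_h = x$times, conc_ng_ml = x$concentrations)
}

#' Dissolution profile
#'
#' Mean dissolved fraction versus time for one product, optionally with the
#' per-time standard deviation across dissolution units.
#'
#' @param times Sampling times (h), strictly increasing, >= 0.
#' @param fractions Mean dissolved fraction of label dose at each time
#'   (0-1 scale; values slightly above 1 are tolerated up to 1.25 because
#'   assay/label variability can push asymptotes past unity).
#' @param sd Optional per-time standard deviation across units.
#' @param product Product label.
#' @param n_units Number of dissolution units averaged (default 6).
#'
#' @return An object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(times, fractions, sd = NULL,
                                product = "product", n_units = 6L) {
  stopifnot(is.numeric(times), is.numeric(fractions))
  if (length(times) != length(fractions))
    stop("`times` and `fractions` must have equal length")
  if (length(times) == 0L) stop("empty profile")
  if (times[1L] < 0) stop("times must be >= 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(fractions < 0)) stop("negative dissolved fractions not allowed")
  if (any(fractions > 1.3)) stop("dissolved fractions above 1.3 look like percent, expected fraction scale")
  if (!is.null(sd)) {
    stopifnot(is.numeric(sd), length(sd) == length(times), all(sd >= 0))
  }
  structure(
    list(times = as.numeric(times), fractions = as.numeric(fractions),
         sd = if (is.null(sd)) NULL else as.numeric(sd),
         product = as.character(product), n_units = as.integer(n_units)),
    class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf("<dissolution_profile> product=%s, %d times over [%g, %g] h, final fraction %.3f (n=%d units)\n",
              x$product, length(x$times), min(x$times), max(x$times),
              x$fractions[length(x$fractions)], x$n_units))
  invisible(x)
}

#' @export
as.data.frame.dissolution_profile <- function(x, ...) {
  out <- data.frame(product = x$product, time_h = x$times,
                    fraction = x$fractions)
  if (!is.null(x$sd)) out$sd <- x$sd
  out
}

#' Cumulative absorption profile
#'
#' Fractions absorbed over time from deconvolution, normalized to the largest
#' AUC0-inf across the products of a study so that asymptotes express
#' relative bioavailability.
#'
#' @param times Times (h), strictly increasing.
#' @param fabs Cumulative fractions absorbed, non-decreasing, in \[0, 1\].
#' @param product Product label.
#'
#' @return An object of class `absorption_profile`.
#' @export
absorption_profile <- function(times, fabs, product = "product") {
  stopifnot(is.numeric(times), is.numeric(fabs))
  if (length(times) != length(fabs))
    stop("`times` and `fabs` must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(fabs < -1e-9) || any(fabs > 1 + 1e-9))
    stop("fractions absorbed must lie in [0, 1]")
  if (any(diff(fabs) < -1e-9))
    stop("fractions absorbed must be non-decreasing")
  # snap tiny numerical violations
  fabs <- pmin(pmax(cummax(fabs), 0), 1)
  structure(
    list(times = as.numeric(times), fabs = as.numeric(fabs),
         product = as.character(product)),
    class = "absorption_profile")
}

#' @export
print.absorption_profile <- function(x, ...) {
  cat(sprintf("<absorption_profile> product=%s, %d times, plateau %.3f\n",
              x$product, length(x$times), x$fabs[length(x$fabs)]))
  invisible(x)
}

#' @export
as.data.frame.absorption_profile <- function(x, ...) {
  data.frame(product = x$product, time_h = x$times, fabs = x$fabs)
}
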