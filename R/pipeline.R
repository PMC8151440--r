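#' Run configuration for the IVIVC pipelines
#'
#' Bundles everything a full analysis needs. Plasma and dissolution inputs
#' may be file paths (CSV, see [read_plasma_csv()] / [read_dissolution_csv()])
#' or in-memory data.frames in the same schema; the disposition may be a
#' [pk_micro_params()] object or a YAML/JSON path.
#'
#' @param plasma Plasma data (path or data.frame with
#'   `product,subject,time_h,conc_ng_ml` and optional `study`).
#' @param dissolution Dissolution data (path or data.frame with
#'   `product,replicate,time_h,fraction`).
#' @param disposition [pk_micro_params()] or config path.
#' @param dose_mg Administered dose (mg); converted to ng internally.
#' @param t_limit Level-A / Levy inclusion cut-off (h), default 3.5.
#' @param pe_threshold FDA percent-prediction-error limit, default 10.
#' @param exclude_product Product held out of correlation development and
#'   used for external validation (NULL to use all products internally).
#' @param ref_product Reference product label shared by both studies
#'   (default `"Reference"`), used for cross-study normalization.
#' @param seed Integer seed for any stochastic step (none in the core path;
#'   kept for reproducibility contracts).
#' @param out_dir Optional directory; when given, reports and intermediate
#'   artifacts are written there as JSON/CSV.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(plasma, dissolution, disposition, dose_mg = 10,
                       t_limit = 3.5, pe_threshold = 10,
                       exclude_product = NULL, ref_product = "Reference",
                       seed = 1L, out_dir = NULL) {
  if (is.character(plasma)) plasma <- read_plasma_csv(plasma)
  if (is.character(dissolution)) dissolution <- read_dissolution_csv(dissolution)
  if (is.character(disposition)) disposition <- read_disposition_config(disposition)
  stopifnot(inherits(disposition, "pk_micro_params"))
  if (pe_threshold <= 0) stop("pe_threshold must be positive")
  if (t_limit <= 0) stop("t_limit must be positive")
  structure(list(plasma = plasma, dissolution = dissolution,
                 disposition = disposition, dose_mg = dose_mg,
                 t_limit = t_limit, pe_threshold = pe_threshold,
                 exclude_product = exclude_product,
                 ref_product = ref_product, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

# stage-tagged error propagation for pipeline steps
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

# shared front end: normalize across studies (if needed), average, NCA,
# deconvolve, and fit Weibull models to dissolution and absorption
prepare_ivivc_inputs <- function(config) {
  micro <- config$disposition
  plasma <- config$plasma

  means <- run_stage("normalize", {
    if ("study" %in% names(plasma) && length(unique(plasma$study)) > 1L) {
      m <- mean_profiles_from_data(plasma)
      studies <- vapply(m, function(p) attr(p, "study"), 0)
      refs <- m[vapply(m, function(p) p$product == config$ref_product, TRUE)]
      if (length(refs) != 2L)
        stop(sprintf("need the reference product '%s' in both studies",
                     config$ref_product))
      ref1 <- refs[[which(vapply(refs, function(p) attr(p, "study"), 0) == 1)]]
      ref2 <- refs[[which(vapply(refs, function(p) attr(p, "study"), 0) == 2)]]
      s1 <- m[studies == 1 & vapply(m, function(p) p$product, "") != config$ref_product]
      s2 <- m[studies == 2 & vapply(m, function(p) p$product, "") != config$ref_product]
      norm <- normalize_cross_study(s1, ref1, ref2)
      grid <- norm$grid
      corrected <- c(norm$profiles,
                     lapply(c(s2, list(ref2)), interpolate_to_grid, grid = grid))
      names(corrected) <- vapply(corrected, function(p) p$product, "")
      corrected
    } else {
      m <- mean_profiles_from_data(plasma)
      names(m) <- vapply(m, function(p) p$product, "")
      m
    }
  })

  nca_res <- run_stage("nca", lapply(means, nca))
  auc_inf_max <- max(vapply(nca_res, `[[`, 0, "auc_inf"))

  fabs <- run_stage("deconvolve",
                    lapply(means, loo_riegelman, micro = micro,
                           auc_inf_max = auc_inf_max))

  vivo_fits <- run_stage("fit-weibull-vivo", lapply(fabs, fit_weibull))

  diss <- config$dissolution
  vitro_profiles <- run_stage("dissolution-mean", {
    lapply(split(diss, diss$product), function(g) {
      agg_m <- stats::aggregate(fraction ~ time_h, data = g, FUN = mean)
      agg_s <- stats::aggregate(fraction ~ time_h, data = g, FUN = stats::sd)
      o <- order(agg_m$time_h)
      dissolution_profile(agg_m$time_h[o], agg_m$fraction[o],
                          sd = if (all(is.finite(agg_s$fraction)))
                            agg_s$fraction[o] else NULL,
                          product = g$product[1L],
                          n_units = length(unique(g$replicate)))
    })
  })
  vitro_fits <- run_stage("fit-weibull-vitro", lapply(vitro_profiles, fit_weibull))

  products <- intersect(names(means), names(vitro_fits))
  if (length(products) < 2L)
    stop("[stage match] need at least 2 products present in both plasma and dissolution data")
  included <- setdiff(products, config$exclude_product)
  if (!is.null(config$exclude_product) &&
      !config$exclude_product %in% products)
    warning(sprintf("exclude_product '%s' not found among products",
                    config$exclude_product))

  list(micro = micro, means = means[products], nca = nca_res[products],
       auc_inf_max = auc_inf_max, fabs = fabs[products],
       vivo_fits = vivo_fits[products],
       vitro_profiles = vitro_profiles[products],
       vitro_fits = vitro_fits[products],
       products = products, included = included)
}

pe_for_product <- function(observed, predicted, product, scope) {
  obs <- nca(observed)
  cmax_pred <- max(predicted$concentrations)
  auc_pred <- auc_trapezoid(predicted)
  pe_report(product,
            pe_cmax = percent_pe(obs$cmax, cmax_pred),
            pe_auc = percent_pe(obs$auc_0_t, auc_pred),
            scope = scope)
}

#' Run the two-step IVIVC analysis
#'
#' Executes the full classical pipeline: cross-study normalization, NCA,
#' Loo-Riegelman deconvolution, Weibull fits in vitro and in vivo, pooled
#' Levy time-scaling, pooled level-A regression, reconvolution of predicted
#' plasma levels, and FDA %PE validation. Products named in
#' `exclude_product` do not enter the Levy or level-A fits and are scored as
#' external validation.
#'
#' @param config A [run_config()].
#' @return A list of class `twostep_report` carrying every intermediate
#'   artifact (mean profiles, NCA, absorption profiles, Weibull fits, Levy
#'   mapping, level-A correlation, predicted profiles, %PE table,
#'   validation verdict).
#' @export
run_two_step <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  inp <- prepare_ivivc_inputs(config)

  levy <- run_stage("levy", build_levy(
    lapply(inp$vivo_fits[inp$included], `[[`, "params"),
    lapply(inp$vitro_fits[inp$included], `[[`, "params"),
    t_limit = config$t_limit))

  scaled <- run_stage("rescale", lapply(inp$vitro_profiles, function(pr)
    rescale_dissolution(pr, levy)))
  scaled_params <- lapply(scaled, function(s) s$fit$params)

  levelA <- run_stage("levelA", fit_levelA(
    scaled_params[inp$included], inp$fabs[inp$included],
    t_limit = config$t_limit))

  predicted <- run_stage("predict", {
    out <- lapply(inp$products, function(nm)
      predict_plasma_twostep(inp$vitro_profiles[[nm]], levy, levelA,
                             inp$micro, inp$auc_inf_max,
                             times = inp$means[[nm]]$times, product = nm))
    stats::setNames(out, inp$products)
  })

  pe_tab <- run_stage("pe", do.call(rbind, lapply(inp$products, function(nm)
    pe_for_product(inp$means[[nm]], predicted[[nm]], nm,
                   scope = if (nm %in% inp$included) "internal" else "external"))))

  validation <- validate_ivivc(pe_tab, threshold = config$pe_threshold)

  report <- structure(list(
    config = config, inputs = inp, levy = levy,
    scaled_weibull = scaled_params, levelA = levelA,
    predicted = predicted, pe = pe_tab, validation = validation),
    class = "twostep_report")
  if (!is.null(config$out_dir)) persist_report(report, config$out_dir, "two_step")
  report
}

#' Run the one-step IVIVC analysis
#'
#' Executes the differential-equation pipeline: the shared front end
#' (normalization, NCA, deconvolution, Weibull fits), then the linear
#' in vitro to in vivo Weibull parameter map, simultaneous fitting of the six
#' link parameters over the included products' plasma profiles, prediction
#' for every product (including the held-out one through its mapped
#' parameters), and %PE validation.
#'
#' @param config A [run_config()].
#' @return A list of class `onestep_report` with the fitted
#'   `one_step_fit`, the `weibull_map`, predicted profiles, the %PE table
#'   and validation verdict, plus all shared intermediates.
#' @export
run_one_step <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  inp <- prepare_ivivc_inputs(config)
  dose <- config$dose_mg * 1e6   # mg -> ng

  wmap <- run_stage("weibull-map", fit_weibull_map(
    lapply(inp$vitro_fits[inp$included], `[[`, "params"),
    lapply(inp$vivo_fits[inp$included], `[[`, "params")))

  vivo_mapped <- run_stage("map-vivo", lapply(
    inp$vitro_fits, function(f) map_weibull_vivo(f$params, wmap)))

  fit <- run_stage("fit-onestep", fit_onestep(
    plasma = inp$means[inp$included],
    vivo_weibull = vivo_mapped[inp$included],
    micro = inp$micro, dose = dose))

  predicted <- run_stage("predict", {
    out <- lapply(inp$products, function(nm)
      simulate_onestep(fit$params, vivo_mapped[[nm]], inp$micro, dose,
                       inp$means[[nm]]$times, product = nm))
    stats::setNames(out, inp$products)
  })

  pe_tab <- run_stage("pe", do.call(rbind, lapply(inp$products, function(nm)
    pe_for_product(inp$means[[nm]], predicted[[nm]], nm,
                   scope = if (nm %in% inp$included) "internal" else "external"))))

  validation <- validate_ivivc(pe_tab, threshold = config$pe_threshold)

  report <- structure(list(
    config = config, inputs = inp, weibull_map = wmap, fit = fit,
    predicted = predicted, pe = pe_tab, validation = validation),
    class = "onestep_report")
  if (!is.null(config$out_dir)) persist_report(report, config$out_dir, "one_step")
  report
}

# write the machine-readable pieces of a report bundle (JSON + CSV)
persist_report <- function(report, out_dir, prefix) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_plasma_csv(report$predicted,
                   file.path(out_dir, paste0(prefix, "_predicted_plasma.csv")))
  fabs_df <- do.call(rbind, lapply(report$inputs$fabs, as.data.frame))
  utils::write.csv(fabs_df, file.path(out_dir, paste0(prefix, "_fabs.csv")),
                   row.names = FALSE, quote = FALSE)
  summary <- list(
    pe = report$pe,
    validation = list(pass_internal = report$validation$pass_internal,
                      pass_external = report$validation$pass_external,
                      threshold = report$validation$threshold))
  if (!is.null(report$levy))
    summary$levy <- list(slope = report$levy$slope,
                         intercept = report$levy$intercept, r2 = report$levy$r2)
  if (!is.null(report$levelA))
    summary$levelA <- list(intercept_a = report$levelA$intercept_a,
                           slope_b = report$levelA$slope_b,
                           r2 = report$levelA$r2)
  if (!is.null(report$fit))
    summary$onestep <- list(estimates = as.list(report$fit$estimates),
                            se = as.list(report$fit$se),
                            cv_pct = as.list(report$fit$cv_pct))
  jsonlite::write_json(summary, file.path(out_dir, paste0(prefix, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.twostep_report <- function(x, ...) {
  cat("Two-step level-A IVIVC report\n")
  print(x$levy); print(x$levelA); print(x$validation)
  invisible(x)
}

#' @export
print.onestep_report <- function(x, ...) {
  cat("One-step IVIVC report\n")
  print(x$fit); print(x$validation)
  invisible(x)
}
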