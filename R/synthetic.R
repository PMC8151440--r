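#' Synthetic study design
#'
#' Describes the simulated setting the generators emulate: four film-coated
#' tablet products (one reference, three tests) with Weibull release, two
#' cross-over bioequivalence studies sharing the reference product, the
#' dense early sampling schedule of a single-dose trial, replicated
#' dissolution runs, and the nuisance structure the analysis must undo
#' (between-study bias, between-subject variability, dissolution noise).
#'
#' Defaults: 10 mg dose; study 2 uses the full 19-sample schedule
#' (0.5-24 h plus pre-dose), study 1 a slightly sparser one (without the
#' 3.25/3.75/4.25 h draws) so the two trials genuinely need a combined grid;
#' 36 and 24 subjects; 25% log-normal between-subject CV on exposure; a
#' 15% multiplicative study effect on study-1 concentrations; 6 dissolution
#' units with additive noise sd 0.02.
#'
#' @param products Named list of per-product settings; each element needs a
#'   `weibull` ([weibull_params()]) and a `study` (1 or 2; the reference
#'   belongs to both and is marked 0).
#' @param schedule_study1,schedule_study2 Sampling times (h), strictly
#'   increasing, starting at 0.
#' @param n_subjects Integer vector c(study1, study2).
#' @param inter_subject_cv Log-normal CV of the subject-level exposure
#'   multiplier.
#' @param study_effect Multiplicative bias applied to study-1 concentrations.
#' @param noise_sd Additive dissolution noise sd (fraction units).
#' @param n_units Dissolution replicates per product.
#' @param dose_mg Dose (mg).
#' @param seed Integer seed; all generators are pure functions of the design.
#'
#' @return A list of class `study_design`.
#' @export
study_design <- function(
    products = list(
      Reference = list(weibull = weibull_params(2.916, 1.545, 0.863), study = 0L),
      Test1     = list(weibull = weibull_params(4.180, 2.163, 1.023), study = 1L),
      Test2     = list(weibull = weibull_params(5.395, 2.108, 0.930), study = 2L),
      Test3     = list(weibull = weibull_params(7.000, 1.656, 0.753), study = 2L)),
    schedule_study1 = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5, 6, 8, 12, 16, 20, 24),
    schedule_study2 = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.25, 3.5, 3.75, 4, 4.25,
                        4.5, 5, 6, 8, 12, 16, 20, 24),
    n_subjects = c(36L, 24L), inter_subject_cv = 0.25, study_effect = 1.15,
    noise_sd = 0.02, n_units = 6L, dose_mg = 10, seed = 42L) {
  stopifnot(length(products) >= 1L, !is.null(names(products)))
  for (p in products) stopifnot(inherits(p$weibull, "weibull_params"))
  stopifnot(all(diff(schedule_study1) > 0), all(diff(schedule_study2) > 0))
  if (inter_subject_cv < 0 || noise_sd < 0) stop("variabilities must be >= 0")
  if (study_effect <= 0) stop("study_effect must be positive")
  structure(list(products = products,
                 schedule_study1 = schedule_study1,
                 schedule_study2 = schedule_study2,
                 n_subjects = as.integer(n_subjects),
                 inter_subject_cv = inter_subject_cv,
                 study_effect = study_effect, noise_sd = noise_sd,
                 n_units = as.integer(n_units), dose_mg = dose_mg,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Generate replicated dissolution profiles
#'
#' For each product, `n_units` replicate curves are drawn as the Weibull
#' release curve plus additive Gaussian noise truncated at zero; the mean
#' and per-time sd across units are recorded in the returned
#' [dissolution_profile()]s. Output is a deterministic function of the
#' design (its seed included).
#'
#' @param design A [study_design()].
#' @param times Dissolution sampling times (h); default 0.25 to 8 h every
#'   15 min, the span of a pH-transition flow-through run.
#'
#' @return A list with `profiles` (named list of mean
#'   [dissolution_profile()]s) and `replicates` (long data.frame
#'   `product,replicate,time_h,fraction`).
#' @export
gen_dissolution <- function(design, times = seq(0.25, 8, by = 0.25)) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  reps <- NULL
  profiles <- list()
  for (nm in names(design$products)) {
    wb <- design$products[[nm]]$weibull
    truth <- weibull_cdf(times, wb)
    mat <- matrix(NA_real_, nrow = length(times), ncol = design$n_units)
    for (u in seq_len(design$n_units)) {
      mat[, u] <- pmax(truth + stats::rnorm(length(times), 0, design$noise_sd), 0)
      reps <- rbind(reps, data.frame(product = nm, replicate = u,
                                     time_h = times, fraction = mat[, u]))
    }
    profiles[[nm]] <- dissolution_profile(
      times, rowMeans(mat),
      sd = apply(mat, 1L, stats::sd),
      product = nm, n_units = design$n_units)
  }
  list(profiles = profiles, replicates = reps)
}

#' Generate plasma profiles under the one-step model
#'
#' Mean plasma profiles per product are simulated with [simulate_onestep()]
#' on each study's schedule; study-1 profiles (including that study's copy
#' of the reference) are multiplied by the design's study effect, emulating
#' the between-trial exposure bias that cross-study normalization must
#' remove. Optionally, per-subject profiles are produced as the mean profile
#' times a log-normal subject factor (CV `inter_subject_cv`).
#'
#' @param design A [study_design()].
#' @param p A [one_step_params()] truth.
#' @param micro A [pk_micro_params()] disposition truth.
#' @param dose Dose (ng); defaults to `design$dose_mg * 1e6`.
#' @param subjects Also draw per-subject profiles (default FALSE).
#'
#' @return A list with `mean_profiles` (named list; the reference appears as
#'   `Reference.study1` and `Reference.study2`), `data` (long data.frame of
#'   the mean profiles with a `study` column) and, when requested,
#'   `subject_data`.
#' @export
gen_plasma_onestep <- function(design, p, micro, dose = NULL,
                               subjects = FALSE) {
  stopifnot(inherits(design, "study_design"), inherits(p, "one_step_params"),
            inherits(micro, "pk_micro_params"))
  if (is.null(dose)) dose <- design$dose_mg * 1e6
  set.seed(design$seed + 1L)
  schedules <- list(`1` = design$schedule_study1, `2` = design$schedule_study2)
  out <- list()
  long <- NULL
  subj <- NULL
  for (nm in names(design$products)) {
    in_studies <- design$products[[nm]]$study
    in_studies <- if (in_studies == 0L) c(1L, 2L) else in_studies
    for (s in in_studies) {
      sched <- schedules[[as.character(s)]]
      prof <- simulate_onestep(p, design$products[[nm]]$weibull, micro, dose,
                               sched, product = nm)
      conc <- prof$concentrations
      if (s == 1L) conc <- conc * design$study_effect
      key <- if (length(in_studies) > 1L) sprintf("%s.study%d", nm, s) else nm
      out[[key]] <- concentration_profile(sched, conc, product = nm)
      long <- rbind(long, data.frame(product = nm, study = s, subject = "mean",
                                     time_h = sched, conc_ng_ml = conc))
      if (subjects) {
        ns <- design$n_subjects[s]
        sdlog <- sqrt(log(1 + design$inter_subject_cv^2))
        fac <- if (design$inter_subject_cv > 0)
          stats::rlnorm(ns, -sdlog^2 / 2, sdlog) else rep(1, ns)
        for (k in seq_len(ns)) {
          subj <- rbind(subj, data.frame(
            product = nm, study = s, subject = sprintf("S%d_%02d", s, k),
            time_h = sched, conc_ng_ml = conc * fac[k]))
        }
      }
    }
  }
  res <- list(mean_profiles = out, data = long)
  if (subjects) res$subject_data <- subj
  res
}

#' Closed-form first-order oral absorption profile
#'
#' Analytic three-exponential solution of first-order input (rate `ka`,
#' bioavailable fraction `F`) into the two-compartment disposition model, the
#' standard oracle for testing deconvolution:
#' \deqn{C(t) = \frac{k_a F D}{V_c}\left[
#'   \frac{k_{21}-\alpha}{(k_a-\alpha)(\beta-\alpha)} e^{-\alpha t} +
#'   \frac{k_{21}-\beta}{(k_a-\beta)(\alpha-\beta)} e^{-\beta t} +
#'   \frac{k_{21}-k_a}{(\alpha-k_a)(\beta-k_a)} e^{-k_a t}\right].}
#'
#' @param ka First-order absorption rate constant (1/h), distinct from both
#'   hybrid constants.
#' @param F Bioavailable fraction.
#' @param micro A [pk_micro_params()] object.
#' @param dose Dose (ng).
#' @param times Sampling times (h).
#' @param product Label.
#'
#' @return A [concentration_profile()].
#' @export
gen_first_order_oral <- function(ka, F, micro, dose, times,
                                 product = "oral") {
  stopifnot(inherits(micro, "pk_micro_params"))
  mac <- macro_from_micro(micro)
  a <- mac$alpha; b <- mac$beta; k21 <- micro$k21
  if (min(abs(ka - a), abs(ka - b)) < 1e-8 * ka)
    stop("ka equal to a hybrid constant: closed form degenerate")
  coef <- ka * F * dose / micro$Vc
  conc <- coef * (
    (k21 - a) / ((ka - a) * (b - a)) * exp(-a * times) +
    (k21 - b) / ((ka - b) * (a - b)) * exp(-b * times) +
    (k21 - ka) / ((a - ka) * (b - ka)) * exp(-ka * times))
  conc[conc < 0 & conc > -1e-9] <- 0
  concentration_profile(times, conc, product = product)
}
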