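#' Read a plasma concentration CSV
#'
#' Expected columns: `product,subject,time_h,conc_ng_ml`, header required,
#' decimal point `.`. An optional `study` column (1/2) is carried through
#' for cross-study normalization.
#'
#' @param path CSV file path.
#' @return A data.frame with validated columns.
#' @export
read_plasma_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("plasma file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("product", "subject", "time_h", "conc_ng_ml")
  if (!all(need %in% names(d)))
    stop(sprintf("plasma CSV must have columns %s", paste(need, collapse = ",")))
  if (any(d$conc_ng_ml < 0)) stop("negative concentrations in plasma CSV")
  d
}

#' Write a plasma concentration CSV
#'
#' @param data A data.frame with plasma columns, or a list of
#'   [concentration_profile()]s.
#' @param path Output path.
#' @export
write_plasma_csv <- function(data, path) {
  if (is.list(data) && !is.data.frame(data))
    data <- do.call(rbind, lapply(data, as.data.frame))
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dissolution CSV
#'
#' Expected columns: `product,replicate,time_h,fraction` (fractions on the
#' 0-1 scale).
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_dissolution_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("dissolution file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("product", "replicate", "time_h", "fraction")
  if (!all(need %in% names(d)))
    stop(sprintf("dissolution CSV must have columns %s",
                 paste(need, collapse = ",")))
  if (any(d$fraction < 0)) stop("negative dissolved fractions in CSV")
  d
}

#' Write a dissolution CSV
#' @param data Long data.frame `product,replicate,time_h,fraction`.
#' @param path Output path.
#' @export
write_dissolution_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a disposition configuration
#'
#' Reads YAML or JSON carrying a `disposition:` block with `k10`, `k12`,
#' `k21` (1/h) and `Vc` (mL).
#'
#' @param path `.yml`/`.yaml` or `.json` file.
#' @return A [pk_micro_params()] object.
#' @export
read_disposition_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  d <- if (!is.null(cfg$disposition)) cfg$disposition else cfg
  need <- c("k10", "k12", "k21", "Vc")
  if (!all(need %in% names(d)))
    stop("disposition config must provide k10, k12, k21, Vc")
  pk_micro_params(d$k10, d$k12, d$k21, d$Vc)
}

# mean profile per product (and study, if present) from long plasma data
mean_profiles_from_data <- function(d) {
  has_study <- "study" %in% names(d)
  keyvars <- if (has_study) c("product", "study") else "product"
  split_key <- interaction(d[keyvars], drop = TRUE)
  lapply(split(d, split_key), function(g) {
    agg <- stats::aggregate(conc_ng_ml ~ time_h, data = g, FUN = mean)
    agg <- agg[order(agg$time_h), ]
    prof <- concentration_profile(agg$time_h, agg$conc_ng_ml,
                                  product = g$product[1L], subject = "mean")
    if (has_study) attr(prof, "study") <- g$study[1L]
    prof
  })
}
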