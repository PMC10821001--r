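#' Effective dose from DLP and a conversion factor
#'
#' The ED is the product of the scanner-reported dose-length product and
#' an age- and region-specific conversion factor.
#'
#' @param dlp dose-length product(s), mGy.cm, non-negative.
#' @param factor conversion factor(s), mSv/mGy/cm, positive.
#' @return Effective dose(s) in mSv.
#' @examples
#' estimate_ed(500, 0.0040)  # 2 mSv
#' @export
estimate_ed <- function(dlp, factor) {
  if (anyNA(dlp) || any(dlp < 0))
    stop("`dlp` must be non-negative", call. = FALSE)
  if (any(!is.finite(factor)) || any(factor <= 0))
    stop("`factor` must be positive", call. = FALSE)
  dlp * factor
}

#' ED/DLP ratio
#'
#' @param ed effective dose(s), mSv.
#' @param dlp dose-length product(s), mGy.cm, strictly positive.
#' @return Ratio(s) in mSv/mGy/cm.
#' @export
ed_dlp_ratio <- function(ed, dlp) {
  if (anyNA(dlp) || any(dlp <= 0))
    stop("`dlp` must be strictly positive", call. = FALSE)
  ed / dlp
}

#' Convert dose records to per-method effective doses
#'
#' Applies the requested conversion-factor methods to each record of a
#' dose table. The primary analysis evaluates the curve and linear
#' methods at the floored integer age (a child of 2.5 years counts as
#' 2 years); set `continuous_age = TRUE` to evaluate the curve and linear
#' methods at the actual decimal age instead. The simple method is always
#' evaluated at integer age. The `device` method passes through the
#' dose-management system's own ED (`ed_device_msv`); records without a
#' device ED get `NA` in the device columns rather than an error.
#'
#' @param records data frame with columns `exam_id`, `age_years`,
#'   `dlp_mgycm` and optionally `ed_device_msv` and `sex` (see
#'   [read_dose_records()]).
#' @param model fitted `kcurve`; required for the `curve` method.
#' @param anchors [anchor_table] for the linear/simple methods.
#' @param bins [phantom_bin_table] for the `phantom_bin` method.
#' @param methods subset of `c("curve", "linear", "simple",
#'   "phantom_bin", "device")`.
#' @param continuous_age evaluate curve/linear factors at decimal age.
#' @return The input data frame plus `integer_age` and, per method `m`,
#'   columns `factor_m` and `ed_m` (for `device`, `ed_device` and
#'   `factor_device` = device ED / DLP). Row order is preserved.
#' @examples
#' rec <- data.frame(exam_id = "e1", age_years = 2.5, dlp_mgycm = 600)
#' fit <- fit_kcurve(brain_anchors())
#' convert_records(rec, model = fit, methods = c("curve", "simple"))
#' @export
convert_records <- function(records, model = NULL,
                            anchors = brain_anchors(),
                            bins = default_phantom_bins(),
                            methods = c("curve", "linear", "simple"),
                            continuous_age = FALSE) {
  methods <- match.arg(methods,
                       c("curve", "linear", "simple", "phantom_bin", "device"),
                       several.ok = TRUE)
  required <- c("exam_id", "age_years", "dlp_mgycm")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("records lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyNA(records$age_years) || any(records$age_years < 0))
    stop("`age_years` must be non-negative", call. = FALSE)
  if (anyNA(records$dlp_mgycm) || any(records$dlp_mgycm < 0))
    stop("`dlp_mgycm` must be non-negative", call. = FALSE)

  out <- records
  out$integer_age <- integer_age(records$age_years)
  eval_age <- if (continuous_age) records$age_years else out$integer_age

  for (m in methods) {
    f <- switch(m,
      curve = {
        if (is.null(model))
          stop("curve method requested but no `model` supplied",
               call. = FALSE)
        curve_factor(model, eval_age, warn_infant = FALSE)
      },
      linear = linear_factor(anchors, eval_age),
      simple = simple_factor(anchors, out$integer_age),
      phantom_bin = phantom_bin_factor(bins, records$age_years),
      device = NULL
    )
    if (m == "device") {
      if (is.null(records$ed_device_msv)) {
        out$ed_device <- NA_real_
        out$factor_device <- NA_real_
      } else {
        out$ed_device <- records$ed_device_msv
        out$factor_device <- ifelse(
          !is.na(records$ed_device_msv) & records$dlp_mgycm > 0,
          records$ed_device_msv / records$dlp_mgycm, NA_real_)
      }
    } else {
      out[[paste0("factor_", m)]] <- f
      out[[paste0("ed_", m)]] <- records$dlp_mgycm * f
    }
  }
  out
}

#' Read a dose-record CSV
#'
#' Expected columns: `exam_id`, `dlp_mgycm`, and either `age_years`
#' (decimal years) or both `birth_date` and `scan_date` (ISO-8601 dates;
#' age is computed as elapsed days / 365.2425). Optional: `ed_device_msv`,
#' `sex`. Rows whose age cannot be parsed are dropped with a warning
#' naming the row.
#'
#' @param path path to a CSV file (comma-separated, header row, `.`
#'   decimal separator, UTF-8).
#' @return A data frame of dose records with a computed `age_years`
#'   column.
#' @export
read_dose_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$dlp_mgycm))
    stop("dose-record file '", path, "' lacks required column `dlp_mgycm`",
         call. = FALSE)
  if (is.null(df$exam_id))
    stop("dose-record file '", path, "' lacks required column `exam_id`",
         call. = FALSE)
  if (is.null(df$age_years)) {
    if (is.null(df$birth_date) || is.null(df$scan_date))
      stop("dose-record file '", path, "' needs `age_years` or both ",
           "`birth_date` and `scan_date`", call. = FALSE)
    bd <- as.Date(df$birth_date)
    sd_ <- as.Date(df$scan_date)
    df$age_years <- as.numeric(sd_ - bd) / 365.2425
  } else {
    df$age_years <- suppressWarnings(as.numeric(df$age_years))
  }
  bad <- which(!is.finite(df$age_years) | df$age_years < 0)
  if (length(bad)) {
    warning("dropping ", length(bad), " record(s) with unparseable or ",
            "negative age (row ", paste(bad, collapse = ", "), ")",
            call. = FALSE)
    df <- df[-bad, , drop = FALSE]
  }
  df
}
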