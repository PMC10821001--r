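#' Workflow entry points
#'
#' Four high-level runners tie the package together and back the
#' command-line script shipped in `inst/cli/kcurve-cli.R`:
#' `run_fit()` fits the curve and tabulates every method,
#' `run_convert()` converts a dose-record CSV to per-method EDs,
#' `run_summarize()` produces per-bin cohort summaries, and
#' `run_simulate()` writes a synthetic cohort. All file outputs are
#' deterministic given config and seed; progress messages go to stderr.
#'
#' @param anchors an [anchor_table] or path to an anchor JSON file.
#' @param bins a [phantom_bin_table] or path to a phantom-bin JSON file.
#' @param out optional output path; reports/tables are also returned
#'   invisibly (fit report printed when `out` is `NULL`).
#' @name workflows
NULL

resolve_anchors <- function(anchors) {
  if (is.character(anchors)) read_anchor_table(anchors) else anchors
}

resolve_bins <- function(bins) {
  if (is.character(bins)) read_phantom_bins(bins) else bins
}

#' @rdname workflows
#' @return `run_fit()`: a list with the `kcurve` fit and the
#'   [factor_table()] over ages 0-14 (written as CSV when `out` is
#'   given).
#' @export
run_fit <- function(anchors = brain_anchors(), bins = default_phantom_bins(),
                    out = NULL) {
  anchors <- resolve_anchors(anchors)
  bins <- resolve_bins(bins)
  fit <- fit_kcurve(anchors)
  tab <- factor_table(fit, anchors, bins)
  if (is.null(out)) {
    print(summary(fit))
    cat("\nConversion factors at integer ages (mSv/mGy/cm):\n")
    disp <- tab
    disp$rel_linear <- round(disp$rel_linear, 2)
    disp$rel_simple <- round(disp$rel_simple, 2)
    num <- vapply(disp, is.numeric, logical(1L))
    disp[num] <- lapply(disp[num], signif, digits = 4)
    print(disp, row.names = FALSE)
  } else {
    utils::write.csv(tab, out, row.names = FALSE)
    message("factor table written to ", out)
  }
  invisible(list(fit = fit, table = tab))
}

#' @rdname workflows
#' @param input path to a dose-record CSV ([read_dose_records()]) or a
#'   dose-record data frame.
#' @param methods conversion methods to apply.
#' @param continuous_age evaluate curve/linear at decimal age.
#' @return `run_convert()`: the converted data frame (written as CSV
#'   when `out` is given).
#' @export
run_convert <- function(input, out = NULL,
                        methods = c("curve", "linear", "simple"),
                        anchors = brain_anchors(),
                        bins = default_phantom_bins(),
                        continuous_age = FALSE) {
  records <- if (is.character(input)) read_dose_records(input) else input
  anchors <- resolve_anchors(anchors)
  bins <- resolve_bins(bins)
  model <- if ("curve" %in% methods) fit_kcurve(anchors) else NULL
  conv <- convert_records(records, model = model, anchors = anchors,
                          bins = bins, methods = methods,
                          continuous_age = continuous_age)
  if ("device" %in% methods) {
    n_miss <- sum(is.na(conv$ed_device))
    if (n_miss > 0)
      message(n_miss, " record(s) lack a device ED")
  }
  if (!is.null(out)) {
    utils::write.csv(conv, out, row.names = FALSE)
    message(nrow(conv), " converted record(s) written to ", out)
  }
  invisible(conv)
}

#' @rdname workflows
#' @param scheme an [age_scheme()] or its kind label.
#' @param with_ratio also compute the device ED/DLP ratio profile over
#'   the phantom bins when device EDs are present.
#' @return `run_summarize()`: a list with the long summary table and,
#'   when available, the `ratio_profile`.
#' @export
run_summarize <- function(input, out = NULL,
                          scheme = age_scheme("integer_year"),
                          methods = c("curve", "linear", "simple", "device"),
                          anchors = brain_anchors(),
                          bins = default_phantom_bins(),
                          with_ratio = TRUE) {
  if (is.character(scheme)) scheme <- age_scheme(scheme)
  records <- if (is.character(input)) read_dose_records(input) else input
  has_device <- !is.null(records$ed_device_msv) &&
    any(!is.na(records$ed_device_msv))
  if ("device" %in% methods && !has_device) {
    warning("device summaries requested but no device EDs present; ",
            "device channel omitted", call. = FALSE)
    methods <- setdiff(methods, "device")
  }
  conv <- run_convert(records, methods = methods, anchors = anchors,
                      bins = bins)
  summ <- summarize_records(conv, scheme)
  rp <- if (with_ratio && has_device)
    ratio_profile(records, age_scheme("phantom_bin")) else NULL
  if (!is.null(out)) {
    utils::write.csv(summ, out, row.names = FALSE)
    message("summary written to ", out)
    if (!is.null(rp)) {
      ratio_out <- sub("(\\.csv)?$", "_ratio.csv", out)[1L]
      utils::write.csv(rp, ratio_out, row.names = FALSE)
      message("ratio profile written to ", ratio_out)
    }
  }
  invisible(list(summary = summ, ratio_profile = rp))
}

#' @rdname workflows
#' @param config a [cohort_config()] or path to a JSON file of config
#'   overrides (fields as in `cohort_config()`; `device_bins` given as a
#'   `bins` array).
#' @param seed optional seed overriding the config's.
#' @return `run_simulate()`: the generated cohort (written as CSV when
#'   `out` is given, with a `<out>.manifest.json` sidecar recording the
#'   config, seed and package version).
#' @export
run_simulate <- function(config = cohort_config(), out = NULL, seed = NULL) {
  if (is.character(config)) config <- read_cohort_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  if (!is.null(out)) {
    utils::write.csv(cohort, out, row.names = FALSE)
    manifest <- list(
      config = list(
        counts_per_age = config$counts_per_age,
        dlp_d0 = config$dlp_d0, dlp_dinf = config$dlp_dinf,
        dlp_k = config$dlp_k, dlp_noise_cv = config$dlp_noise_cv,
        device_bins = as.data.frame(unclass(config$device_bins)),
        device_noise_cv = config$device_noise_cv
      ),
      seed = config$seed,
      n_records = nrow(cohort),
      package_version = as.character(utils::packageVersion("kcurve"))
    )
    jsonlite::write_json(manifest, paste0(out, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(nrow(cohort), " synthetic record(s) written to ", out,
            " (seed ", config$seed, ")")
  }
  invisible(cohort)
}

#' @rdname workflows
#' @param path JSON file of [cohort_config()] overrides.
#' @export
read_cohort_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- cfg[intersect(names(cfg),
                        c("counts_per_age", "dlp_d0", "dlp_dinf", "dlp_k",
                          "dlp_noise_cv", "device_noise_cv", "seed"))]
  if (!is.null(cfg$device_bins))
    args$device_bins <- phantom_bin_table(cfg$device_bins$lower,
                                          cfg$device_bins$upper,
                                          cfg$device_bins$ratio)
  do.call(cohort_config, args)
}
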