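#' Integer age convention
#'
#' Decimal ages are floored to whole years: a child of 2 years and
#' 6 months counts as 2 years.
#'
#' @param age_years non-negative decimal age(s).
#' @return Integer age(s) in whole years.
#' @examples
#' integer_age(2.5)  # 2
#' @export
integer_age <- function(age_years) {
  age_years <- as.numeric(age_years)
  if (anyNA(age_years) || any(age_years < 0))
    stop("`age_years` must be non-negative", call. = FALSE)
  as.integer(floor(age_years))
}

#' Age-binning schemes for cohort summaries
#'
#' Three standard schemes over 0-15 years, all half-open `[lower, upper)`
#' with the last bin closed at 15:
#' \describe{
#'   \item{integer_year}{one bin per integer age 0..14.}
#'   \item{drl_group}{the diagnostic-reference-level groups 0, 1-4, 5-9,
#'     10-14 years (assignment uses the floored integer age).}
#'   \item{phantom_bin}{0-0.5, 0.5-2.5, 2.5-7.5, 7.5-12.5, 12.5-15 years,
#'     the bins over which a dose-management phantom is constant.}
#' }
#' A `custom` scheme takes explicit contiguous bins.
#'
#' @param kind one of `"integer_year"`, `"drl_group"`, `"phantom_bin"`,
#'   `"custom"`.
#' @param bins for `kind = "custom"`: data frame with columns `label`,
#'   `lower`, `upper`, contiguous and covering an interval.
#' @return An object of class `age_scheme`: data frame with columns
#'   `label`, `lower`, `upper` and attribute `kind`.
#' @export
age_scheme <- function(kind = c("integer_year", "drl_group", "phantom_bin",
                                "custom"),
                       bins = NULL) {
  kind <- match.arg(kind)
  sch <- switch(kind,
    integer_year = data.frame(label = as.character(0:14),
                              lower = 0:14, upper = 1:15),
    drl_group = data.frame(label = c("0", "1-4", "5-9", "10-14"),
                           lower = c(0, 1, 5, 10),
                           upper = c(1, 5, 10, 15)),
    phantom_bin = data.frame(label = c("0-0.5", "0.5-2.5", "2.5-7.5",
                                       "7.5-12.5", "12.5-15"),
                             lower = c(0, 0.5, 2.5, 7.5, 12.5),
                             upper = c(0.5, 2.5, 7.5, 12.5, 15)),
    custom = {
      if (is.null(bins) || !all(c("label", "lower", "upper") %in% names(bins)))
        stop("custom scheme needs `bins` with label/lower/upper",
             call. = FALSE)
      data.frame(label = as.character(bins$label),
                 lower = as.numeric(bins$lower),
                 upper = as.numeric(bins$upper))
    }
  )
  if (any(sch$upper <= sch$lower) ||
      (nrow(sch) > 1L &&
       any(abs(sch$lower[-1L] - sch$upper[-nrow(sch)]) > 1e-12)))
    stop("scheme bins must be contiguous with lower < upper", call. = FALSE)
  attr(sch, "kind") <- kind
  class(sch) <- c("age_scheme", "data.frame")
  sch
}

#' Assign ages to scheme bins
#'
#' Integer-year and DRL-group schemes bin on the floored integer age;
#' other schemes bin the decimal age directly. Bins are half-open
#' `[lower, upper)` with the last bin top-closed.
#'
#' @param age_years decimal age(s) within the scheme's coverage.
#' @param scheme an [age_scheme()].
#' @return Factor of bin labels, with levels in scheme order.
#' @examples
#' assign_bin(4.9, age_scheme("drl_group"))  # "1-4"
#' @export
assign_bin <- function(age_years, scheme) {
  stopifnot(inherits(scheme, "age_scheme"))
  age_years <- as.numeric(age_years)
  if (anyNA(age_years) || any(age_years < 0))
    stop("`age_years` must be non-negative", call. = FALSE)
  n <- nrow(scheme)
  lo <- scheme$lower[1L]; hi <- scheme$upper[n]
  if (any(age_years < lo | age_years > hi))
    stop("age outside scheme coverage [", lo, ", ", hi, "]", call. = FALSE)
  a <- if (attr(scheme, "kind") %in% c("integer_year", "drl_group"))
    as.numeric(integer_age(age_years)) else age_years
  if (any(a < lo | a > hi))
    stop("age outside scheme coverage [", lo, ", ", hi, "]", call. = FALSE)
  idx <- findInterval(a, c(scheme$lower, hi), rightmost.closed = TRUE)
  factor(scheme$label[idx], levels = scheme$label)
}

#' Per-bin summary statistics
#'
#' Summarizes one quantity over scheme bins: count, median (even counts
#' average the two central order statistics), mean, SD (n-1 divisor) and
#' the coefficient of variation `100 * sd / mean` in percent. Empty bins
#' are reported with `n = 0` and `NA` statistics so per-age profiles stay
#' complete; single-record bins report `NA` SD and CV 0.
#'
#' @param values numeric vector to summarize.
#' @param age_years ages (same length) used for bin assignment.
#' @param scheme an [age_scheme()].
#' @return A `cohort_summary` data frame: `label`, `n`, `median`, `mean`,
#'   `sd`, `cv_percent`.
#' @export
summarize_cohort <- function(values, age_years, scheme) {
  stopifnot(length(values) == length(age_years))
  bin <- assign_bin(age_years, scheme)
  stats_one <- function(v) {
    n <- length(v)
    if (n == 0L)
      return(c(n = 0, median = NA, mean = NA, sd = NA, cv_percent = NA))
    m <- mean(v)
    s <- if (n > 1L) stats::sd(v) else NA_real_
    cv <- if (n > 1L) 100 * s / m else 0
    c(n = n, median = stats::median(v), mean = m, sd = s, cv_percent = cv)
  }
  rows <- t(vapply(scheme$label,
                   function(lb) stats_one(values[bin == lb]),
                   numeric(5L)))
  out <- data.frame(label = scheme$label, rows, row.names = NULL)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, digits = 4, ...) {
  y <- x
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], signif, digits = digits)
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}

#' Per-bin ED/DLP ratio profile of the device channel
#'
#' Summarizes the device-reported ED divided by the DLP over scheme bins.
#' Only records with a present device ED and a positive DLP contribute;
#' if the device truly applies one conversion factor per phantom bin, the
#' per-bin mean recovers that factor and the CV reflects only the
#' device's residual variation.
#'
#' @param records dose-record data frame with `age_years`, `dlp_mgycm`
#'   and `ed_device_msv`.
#' @param scheme an [age_scheme()]; defaults to the phantom bins.
#' @return A `cohort_summary` of per-bin ratio statistics.
#' @export
ratio_profile <- function(records, scheme = age_scheme("phantom_bin")) {
  if (is.null(records$ed_device_msv))
    records$ed_device_msv <- NA_real_
  keep <- !is.na(records$ed_device_msv) & records$dlp_mgycm > 0
  rec <- records[keep, , drop = FALSE]
  summarize_cohort(ed_dlp_ratio(rec$ed_device_msv, rec$dlp_mgycm),
                   rec$age_years, scheme)
}

#' Summarize DLP and per-method EDs over an age scheme
#'
#' Applies [summarize_cohort()] to the DLP column and every `ed_*` column
#' of a converted record table, stacking the results in long form.
#' Records with a missing value in a channel (e.g. absent device ED) are
#' excluded from that channel only.
#'
#' @param converted output of [convert_records()].
#' @param scheme an [age_scheme()].
#' @return A data frame with a `quantity` column (`dlp`, `ed_curve`, ...)
#'   followed by the per-bin summary columns.
#' @export
summarize_records <- function(converted, scheme = age_scheme("integer_year")) {
  ed_cols <- setdiff(grep("^ed_", names(converted), value = TRUE),
                     "ed_device_msv")
  cols <- c(dlp = "dlp_mgycm", stats::setNames(ed_cols, ed_cols))
  out <- do.call(rbind, lapply(names(cols), function(qn) {
    v <- converted[[cols[[qn]]]]
    keep <- !is.na(v)
    s <- summarize_cohort(v[keep], converted$age_years[keep], scheme)
    cbind(quantity = qn, as.data.frame(s))
  }))
  rownames(out) <- NULL
  out
}

#' Plot per-bin median profiles
#'
#' Draws the per-bin medians of each quantity in a [summarize_records()]
#' table against bin midpoints, one line per quantity.
#'
#' @param summary_long output of [summarize_records()].
#' @param scheme the [age_scheme()] used to build it.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_median_profile <- function(summary_long, scheme, ...) {
  qs <- unique(summary_long$quantity)
  mid <- (scheme$lower + scheme$upper) / 2
  m <- sapply(qs, function(q)
    summary_long$median[summary_long$quantity == q])
  graphics::matplot(mid, m, type = "b", pch = 19, xlab = "age (years)",
                    ylab = "median", ...)
  graphics::legend("topright", legend = qs, col = seq_along(qs),
                   lty = seq_along(qs), bty = "n")
  invisible(NULL)
}
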