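#' Conversion-factor anchor tables
#'
#' An anchor table holds the published DLP-to-ED conversion factors
#' (mSv/mGy/cm) for one body region at a set of reference ages. The ICRP
#' provides pediatric anchors at 0, 1, 5 and 10 years; [brain_anchors()]
#' bundles the brain-CT values. All factor methods in this package
#' ([fit_kcurve()], [linear_factor()], [simple_factor()]) consume an
#' `anchor_table`.
#'
#' @param ages numeric vector of anchor ages in years; non-negative,
#'   strictly increasing.
#' @param factors numeric vector of conversion factors (mSv/mGy/cm),
#'   positive, same length as `ages`.
#' @param region single string labelling the body region.
#' @return An object of class `anchor_table`: a data frame with columns
#'   `age` and `factor` and attribute `region`.
#' @examples
#' anchor_table(c(0, 1, 5, 10), c(0.011, 0.0067, 0.0040, 0.0032), "brain")
#' brain_anchors()
#' @export
anchor_table <- function(ages, factors, region = "unspecified") {
  ages <- as.numeric(ages)
  factors <- as.numeric(factors)
  if (length(ages) != length(factors))
    stop("`ages` and `factors` must have the same length", call. = FALSE)
  if (length(ages) < 2L)
    stop("an anchor table needs at least 2 entries", call. = FALSE)
  if (anyNA(ages) || anyNA(factors))
    stop("anchor ages and factors must not contain NA", call. = FALSE)
  if (any(ages < 0))
    stop("anchor ages must be non-negative", call. = FALSE)
  if (any(diff(ages) <= 0))
    stop("anchor ages must be strictly increasing", call. = FALSE)
  if (any(factors <= 0))
    stop("anchor factors must be positive", call. = FALSE)
  out <- data.frame(age = ages, factor = factors)
  attr(out, "region") <- as.character(region)[1L]
  class(out) <- c("anchor_table", "data.frame")
  out
}

#' @rdname anchor_table
#' @details `brain_anchors()` returns the ICRP brain-CT anchors:
#'   0.011, 0.0067, 0.0040 and 0.0032 mSv/mGy/cm at 0, 1, 5 and 10 years.
#' @export
brain_anchors <- function() {
  anchor_table(c(0, 1, 5, 10), c(0.011, 0.0067, 0.0040, 0.0032), "brain")
}

#' @export
print.anchor_table <- function(x, ...) {
  cat("Conversion-factor anchors (", attr(x, "region"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Phantom-bin conversion tables
#'
#' Radiation dose management systems that estimate ED by Monte Carlo
#' simulation select a computational phantom by patient age, so their
#' implied ED/DLP ratio is piecewise constant in age. A `phantom_bin_table`
#' records those age bins and the per-bin ratio. Bins are half-open
#' `[lower, upper)` except the last, which is closed at its upper edge.
#'
#' @param lower,upper numeric vectors of bin edges in years; bins must be
#'   contiguous (`upper[i] == lower[i + 1]`) and non-overlapping.
#' @param ratios positive per-bin ED/DLP ratios (mSv/mGy/cm).
#' @return An object of class `phantom_bin_table`: a data frame with
#'   columns `lower`, `upper`, `ratio`.
#' @examples
#' default_phantom_bins()
#' @export
phantom_bin_table <- function(lower, upper, ratios) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  ratios <- as.numeric(ratios)
  n <- length(lower)
  if (length(upper) != n || length(ratios) != n || n < 1L)
    stop("`lower`, `upper` and `ratios` must have equal positive length",
         call. = FALSE)
  if (any(upper <= lower))
    stop("each bin must have lower < upper", call. = FALSE)
  if (n > 1L && any(abs(lower[-1L] - upper[-n]) > 1e-12))
    stop("phantom bins must be contiguous and non-overlapping", call. = FALSE)
  if (any(ratios <= 0))
    stop("phantom-bin ratios must be positive", call. = FALSE)
  out <- data.frame(lower = lower, upper = upper, ratio = ratios)
  class(out) <- c("phantom_bin_table", "data.frame")
  out
}

#' @rdname phantom_bin_table
#' @details `default_phantom_bins()` returns the brain-CT defaults:
#'   ratios 0.0115, 0.0076, 0.0047, 0.0036 and 0.0028 mSv/mGy/cm over the
#'   age bins 0-0.5, 0.5-2.5, 2.5-7.5, 7.5-12.5 and 12.5-15 years.
#' @export
default_phantom_bins <- function() {
  phantom_bin_table(
    lower  = c(0, 0.5, 2.5, 7.5, 12.5),
    upper  = c(0.5, 2.5, 7.5, 12.5, 15),
    ratios = c(0.0115, 0.0076, 0.0047, 0.0036, 0.0028)
  )
}

#' @export
print.phantom_bin_table <- function(x, ...) {
  cat("Phantom-bin ED/DLP ratios (mSv/mGy/cm)\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Read anchor or phantom-bin tables from a JSON config file
#'
#' Anchor files hold `region` and an `anchors` array of `{age, factor}`
#' objects; phantom-bin files hold a `bins` array of
#' `{lower, upper, ratio}` objects. Malformed rows are reported by
#' position.
#'
#' @param path path to a JSON file.
#' @return [read_anchor_table()] returns an `anchor_table`;
#'   [read_phantom_bins()] a `phantom_bin_table`.
#' @export
read_anchor_table <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$anchors))
    stop("anchor file '", path, "' has no `anchors` entry", call. = FALSE)
  a <- as.data.frame(cfg$anchors)
  for (col in c("age", "factor")) {
    if (is.null(a[[col]]))
      stop("anchor file '", path, "' lacks column `", col, "`", call. = FALSE)
    bad <- which(!is.finite(suppressWarnings(as.numeric(a[[col]]))))
    if (length(bad))
      stop("anchor file '", path, "': non-numeric `", col, "` in row ",
           bad[1L], call. = FALSE)
  }
  anchor_table(a$age, a$factor,
               region = if (is.null(cfg$region)) "unspecified" else cfg$region)
}

#' @rdname read_anchor_table
#' @export
read_phantom_bins <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$bins))
    stop("phantom-bin file '", path, "' has no `bins` entry", call. = FALSE)
  b <- as.data.frame(cfg$bins)
  for (col in c("lower", "upper", "ratio")) {
    if (is.null(b[[col]]))
      stop("phantom-bin file '", path, "' lacks column `", col, "`",
           call. = FALSE)
  }
  phantom_bin_table(b$lower, b$upper, b$ratio)
}
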