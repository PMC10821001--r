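#' Conversion factors by the curve, linear, simple and phantom-bin methods
#'
#' Four ways to obtain a DLP-to-ED conversion factor at an arbitrary
#' pediatric age from the published anchors:
#' \describe{
#'   \item{curve}{evaluate a fitted power law `a(age + b)^c`
#'     ([fit_kcurve()]) at any real age.}
#'   \item{linear}{piecewise-linear interpolation between bracketing
#'     anchors; beyond the oldest anchor, linear extrapolation from the
#'     last two.}
#'   \item{simple}{assign the anchor factor of the nearest anchor age
#'     (integer ages only; ties go to the older anchor), which maps
#'     0 -> 0 y, 1-2 -> 1 y, 3-7 -> 5 y, 8-14 -> 10 y for the brain
#'     anchors.}
#'   \item{phantom_bin}{look up the piecewise-constant ED/DLP ratio of the
#'     age bin a dose-management phantom covers.}
#' }
#' All functions are vectorized over `age`.
#'
#' @param model a fitted `kcurve` object (or any list with elements
#'   `a`, `b`, `c`).
#' @param anchors an [anchor_table].
#' @param bins a [phantom_bin_table].
#' @param age age in years; `simple_factor()` requires whole years
#'   (floor decimal ages first, see [integer_age()]).
#' @param warn_infant warn when the curve is evaluated below 1 year of
#'   age, where the fitted curve changes steeply and conversion-factor
#'   anchors give it little support.
#' @return Conversion factor(s) in mSv/mGy/cm.
#' @examples
#' fit <- fit_kcurve(brain_anchors())
#' curve_factor(fit, 2)
#' linear_factor(brain_anchors(), 3)     # 0.00535
#' simple_factor(brain_anchors(), 2)     # 0.0067
#' phantom_bin_factor(default_phantom_bins(), 3) # 0.0047
#' @name conversion-factors
NULL

#' @rdname conversion-factors
#' @export
curve_factor <- function(model, age, warn_infant = TRUE) {
  age <- as.numeric(age)
  if (anyNA(age) || any(age < 0))
    stop("`age` must be non-negative", call. = FALSE)
  if (any(age + model$b <= 0))
    stop("model not evaluable: age + b must be positive", call. = FALSE)
  if (warn_infant && any(age < 1))
    warning("curve factors below 1 year of age are steeply varying and ",
            "weakly supported by the anchors; interpret with caution",
            call. = FALSE)
  model$a * (age + model$b)^model$c
}

#' @rdname conversion-factors
#' @export
linear_factor <- function(anchors, age) {
  stopifnot(inherits(anchors, "anchor_table"))
  age <- as.numeric(age)
  if (anyNA(age) || any(age < 0))
    stop("`age` must be non-negative", call. = FALSE)
  x <- anchors$age
  y <- anchors$factor
  if (any(age < x[1L]))
    stop("age below the first anchor (", x[1L], " y); cannot interpolate",
         call. = FALSE)
  n <- length(x)
  out <- numeric(length(age))
  inside <- age <= x[n]
  if (any(inside))
    out[inside] <- stats::approx(x, y, xout = age[inside],
                                 method = "linear", ties = "ordered")$y
  if (any(!inside)) {
    slope <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    out[!inside] <- y[n] + slope * (age[!inside] - x[n])
  }
  out
}

#' @rdname conversion-factors
#' @export
simple_factor <- function(anchors, age) {
  stopifnot(inherits(anchors, "anchor_table"))
  age <- as.numeric(age)
  if (anyNA(age) || any(age < 0))
    stop("`age` must be non-negative", call. = FALSE)
  if (any(age != floor(age)))
    stop("simple method is defined on integer ages only; ",
         "floor decimal ages first (see integer_age())", call. = FALSE)
  vapply(age, function(a) {
    d <- abs(anchors$age - a)
    # ties break toward the older anchor
    anchors$factor[max(which(d == min(d)))]
  }, numeric(1L))
}

#' @rdname conversion-factors
#' @export
phantom_bin_factor <- function(bins, age) {
  stopifnot(inherits(bins, "phantom_bin_table"))
  age <- as.numeric(age)
  if (anyNA(age))
    stop("`age` must not contain NA", call. = FALSE)
  n <- nrow(bins)
  lo <- bins$lower[1L]; hi <- bins$upper[n]
  if (any(age < lo | age > hi))
    stop("age outside phantom-bin coverage [", lo, ", ", hi, "]",
         call. = FALSE)
  idx <- findInterval(age, c(bins$lower, hi), rightmost.closed = TRUE)
  bins$ratio[idx]
}

#' Relative conversion factor of a method against the curve method
#'
#' The ratio of a method's conversion factor to the curve method's at the
#' same age; 1 means agreement, values above 1 mean the method
#' over-estimates relative to the curve.
#'
#' @param method_value conversion factor(s) from the method under
#'   comparison.
#' @param curve_value positive curve-method factor(s) at the same ages.
#' @return Dimensionless ratio(s), full precision (round to 2 decimals
#'   for display).
#' @export
relative_factor <- function(method_value, curve_value) {
  if (any(!is.finite(curve_value)) || any(curve_value <= 0))
    stop("`curve_value` must be positive", call. = FALSE)
  method_value / curve_value
}

#' Tabulate all conversion-factor methods over integer ages
#'
#' Evaluates the curve, linear and simple methods (and optionally the
#' phantom-bin method) at integer ages, together with the relative
#' factors of the linear and simple methods against the curve.
#'
#' @param model a fitted `kcurve`.
#' @param anchors the [anchor_table] backing the linear and simple
#'   methods.
#' @param bins optional [phantom_bin_table]; adds a `phantom_bin` column.
#' @param ages integer ages to tabulate (default 0 to 14).
#' @return A data frame with one row per age: per-method factors and
#'   `rel_linear`, `rel_simple` ratios.
#' @export
factor_table <- function(model, anchors = brain_anchors(), bins = NULL,
                         ages = 0:14) {
  if (any(ages != floor(ages)))
    stop("`ages` must be integers", call. = FALSE)
  cv <- curve_factor(model, ages, warn_infant = FALSE)
  out <- data.frame(
    age = ages,
    curve = cv,
    linear = linear_factor(anchors, ages),
    simple = simple_factor(anchors, ages)
  )
  if (!is.null(bins)) out$phantom_bin <- phantom_bin_factor(bins, ages)
  out$rel_linear <- relative_factor(out$linear, cv)
  out$rel_simple <- relative_factor(out$simple, cv)
  out
}
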