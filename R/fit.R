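#' Fit the age-dependent conversion-factor curve
#'
#' Fits the three-parameter power law
#' \deqn{y = a (x + b)^c}
#' to an anchor table by unweighted nonlinear least squares, where `x` is
#' age in years and `y` the DLP-to-ED conversion factor (mSv/mGy/cm).
#' The offset `b` is kept positive so the model is evaluable at age 0, and
#' for decreasing anchors the exponent `c` is negative.
#'
#' The objective \eqn{\sum_i (a(x_i+b)^c - y_i)^2} has a narrow curved
#' valley for four-point anchor sets, so a single local search from an
#' arbitrary start is unreliable. The fitter therefore (1) scans a
#' `(b, c)` grid, solving the conditionally-linear scale in closed form
#' (for fixed `b`, `c` the optimal `a` is
#' \eqn{\sum y_i g_i / \sum g_i^2} with \eqn{g_i = (x_i+b)^c}), and
#' (2) refines the best grid cells by damped Gauss-Newton until the
#' relative change in the residual sum of squares falls below `tol`.
#' The best refined solution across starts is returned, which in practice
#' makes the result independent of initialization.
#'
#' @param anchors an [anchor_table] with at least 4 entries (a 3-parameter
#'   fit to fewer points is not overdetermined).
#' @param init optional numeric `c(a, b, c)` used as an additional start.
#' @param tol convergence tolerance on the relative change in the residual
#'   sum of squares between Gauss-Newton iterations.
#' @param max_iter maximum Gauss-Newton iterations per start.
#' @return An object of class `kcurve` with components
#'   \describe{
#'     \item{a, b, c}{fitted constants (`b > 0`).}
#'     \item{residuals}{model minus anchor, one per anchor.}
#'     \item{residual_sd}{`sqrt(SSR / (n_points - n_params))`.}
#'     \item{converged}{logical, Gauss-Newton met `tol` for the returned
#'       start.}
#'     \item{n_points, n_params}{bookkeeping (`n_params` is 3).}
#'     \item{anchors}{the input table.}
#'   }
#' @examples
#' fit <- fit_kcurve(brain_anchors())
#' coef(fit)
#' predict(fit, age = 0:14)
#' @seealso [predict.kcurve()], [curve_factor()], [factor_table()]
#' @export
fit_kcurve <- function(anchors, init = NULL, tol = 1e-10, max_iter = 200L) {
  if (!inherits(anchors, "anchor_table"))
    anchors <- anchor_table(anchors$age, anchors$factor)
  x <- anchors$age
  y <- anchors$factor
  n <- length(x)
  p <- 3L
  if (n < 4L)
    stop("power-law fit is under-determined: need at least 4 anchors, got ",
         n, call. = FALSE)

  ssr <- function(par) {
    g <- (x + par[2L])^par[3L]
    sum((par[1L] * g - y)^2)
  }

  # coarse profile grid: a solved in closed form per (b, c) cell
  b_grid <- seq(0.05, 5, by = 0.05)
  c_grid <- seq(-2, -0.01, by = 0.05)
  starts <- profile_grid_starts(x, y, b_grid, c_grid, n_keep = 5L)
  if (!is.null(init)) {
    if (length(init) != 3L || init[2L] <= 0)
      stop("`init` must be c(a, b, c) with b > 0", call. = FALSE)
    starts <- rbind(starts, init)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- gauss_newton_power(x, y, starts[i, ], tol = tol,
                              max_iter = max_iter)
    if (is.null(best) || fit$ssr < best$ssr) best <- fit
  }
  if (is.null(best))
    stop("power-law fit failed from every start", call. = FALSE)
  if (!best$converged)
    warning("power-law fit did not meet tolerance; last iterate returned ",
            sprintf("(a=%.6g, b=%.6g, c=%.6g)", best$par[1L], best$par[2L],
                    best$par[3L]), call. = FALSE)

  par <- unname(best$par)
  res <- par[1L] * (x + par[2L])^par[3L] - y
  structure(
    list(
      a = par[1L], b = par[2L], c = par[3L],
      residuals = res,
      ssr = best$ssr,
      residual_sd = sqrt(best$ssr / (n - p)),
      converged = best$converged,
      n_points = n, n_params = p,
      iterations = best$iterations,
      tol = tol,
      anchors = anchors
    ),
    class = "kcurve"
  )
}

# best (a, b, c) triples over a (b, c) grid with a profiled out
profile_grid_starts <- function(x, y, b_grid, c_grid, n_keep = 5L) {
  grid <- expand.grid(b = b_grid, c = c_grid)
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    g <- (x + grid$b[i])^grid$c[i]
    a <- sum(y * g) / sum(g * g)
    sum((a * g - y)^2)
  }, numeric(1L))
  keep <- order(sse)[seq_len(min(n_keep, nrow(grid)))]
  t(vapply(keep, function(i) {
    g <- (x + grid$b[i])^grid$c[i]
    c(sum(y * g) / sum(g * g), grid$b[i], grid$c[i])
  }, numeric(3L)))
}

# damped Gauss-Newton on (a, b, c); steps that leave the admissible
# region (x + b <= 0) or increase the SSR are halved
gauss_newton_power <- function(x, y, par, tol, max_iter) {
  ssr_at <- function(p) {
    if (min(x) + p[2L] <= 0) return(Inf)
    sum((p[1L] * (x + p[2L])^p[3L] - y)^2)
  }
  cur <- ssr_at(par)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    a <- par[1L]; b <- par[2L]; cc <- par[3L]
    xb <- x + b
    g <- xb^cc
    r <- a * g - y
    J <- cbind(g, a * cc * xb^(cc - 1), a * g * log(xb))
    step <- tryCatch(qr.solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    step <- drop(step)
    lambda <- 1
    new <- ssr_at(par + lambda * step)
    while (!is.finite(new) || new > cur) {
      lambda <- lambda / 2
      if (lambda < 1e-12) break
      new <- ssr_at(par + lambda * step)
    }
    if (!is.finite(new) || new > cur) break
    improved <- (cur - new) <= tol * max(cur, .Machine$double.xmin)
    par <- par + lambda * step
    cur <- new
    if (improved) { converged <- TRUE; break }
  }
  list(par = par, ssr = cur, converged = converged, iterations = iter)
}

#' @export
print.kcurve <- function(x, digits = 6, ...) {
  cat("Power-law conversion-factor curve: y = a(x + b)^c\n")
  cat(sprintf("  a = %.*g, b = %.*g, c = %.*g\n",
              digits, x$a, digits, x$b, digits, x$c))
  cat(sprintf("  fitted to %d anchors (%s); residual SD %.2g mSv/mGy/cm\n",
              x$n_points, attr(x$anchors, "region"), x$residual_sd))
  invisible(x)
}

#' @export
coef.kcurve <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
residuals.kcurve <- function(object, ...) object$residuals

#' @export
fitted.kcurve <- function(object, ...) {
  object$a * (object$anchors$age + object$b)^object$c
}

#' Evaluate a fitted conversion-factor curve at given ages
#'
#' @param object a fitted `kcurve`.
#' @param age ages in years (non-negative; vectorized).
#' @param ... unused.
#' @return Conversion factors in mSv/mGy/cm.
#' @export
predict.kcurve <- function(object, age, ...) {
  curve_factor(object, age)
}

#' @export
summary.kcurve <- function(object, ...) {
  structure(list(fit = object), class = "summary.kcurve")
}

#' @export
print.summary.kcurve <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  converged: %s after %d iterations (tol %.1g on relative SSR change)\n",
              f$converged, f$iterations, f$tol))
  tab <- data.frame(
    age = f$anchors$age,
    anchor = f$anchors$factor,
    fitted = fitted(f),
    residual = f$residuals
  )
  print(tab, row.names = FALSE)
  cat(sprintf("  residual SD = sqrt(SSR / (n - p)) = sqrt(%.3g / %d) = %.3g\n",
              f$ssr, f$n_points - f$n_params, f$residual_sd))
  invisible(x)
}

#' @export
plot.kcurve <- function(x, ages = seq(0, 15, by = 0.05), ...) {
  graphics::plot(ages, curve_factor(x, ages, warn_infant = FALSE),
                 type = "l", xlab = "age (years)",
                 ylab = "conversion factor (mSv/mGy/cm)", ...)
  graphics::points(x$anchors$age, x$anchors$factor, pch = 19)
  invisible(x)
}
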