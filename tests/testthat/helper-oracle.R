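# Brute-force reference fitter, independent of the package's Gauss-Newton
# path: profile grid over (b, c) with the conditionally-linear scale a
# solved in closed form per cell (a = sum(y*g)/sum(g^2), g = (x+b)^c),
# followed by Nelder-Mead refinement of the profiled 2-parameter
# objective.
oracle_power_law <- function(x, y,
                             b_grid = seq(0.02, 5, by = 0.02),
                             c_grid = seq(-2, -0.01, by = 0.02)) {
  prof <- function(b, cc) {
    g <- (x + b)^cc
    a <- sum(y * g) / sum(g * g)
    c(sse = sum((a * g - y)^2), a = a)
  }
  best <- c(Inf, NA, NA, NA)  # sse, a, b, c
  for (b in b_grid) for (cc in c_grid) {
    p <- prof(b, cc)
    if (p[["sse"]] < best[1L]) best <- c(p[["sse"]], p[["a"]], b, cc)
  }
  obj <- function(par) {
    if (par[1L] <= 0 || min(x) + par[1L] <= 0) return(Inf)
    prof(par[1L], par[2L])[["sse"]]
  }
  opt <- stats::optim(best[3:4], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  p <- prof(opt$par[1L], opt$par[2L])
  c(a = unname(p[["a"]]), b = unname(opt$par[1L]), c = unname(opt$par[2L]))
}

# random decreasing 4-point anchor sets from a known power law with
# small multiplicative perturbation
random_anchor_set <- function(a = stats::runif(1, 0.005, 0.02),
                              b = stats::runif(1, 0.2, 2),
                              cc = stats::runif(1, -0.8, -0.2),
                              noise = 0.02) {
  x <- c(0, 1, 5, 10)
  y <- a * (x + b)^cc * exp(stats::rnorm(4, 0, noise))
  list(x = x, y = y, truth = c(a = a, b = b, c = cc))
}
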