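# Independent brute-force oracle for the efficiency integrals: zero-extended
# linear interpolation built directly on approxfun, products taken on the
# shared integer grid, and integration by a dense midpoint Riemann sum at
# 0.01 nm on the piecewise-linear function (exact for integer-knot
# piecewise-linear integrands, unlike the engine's trapezoid this never
# touches the package's resample/area code path).

# zero-extended piecewise-linear evaluator over raw data points
oracle_interp <- function(wl, v) {
  if (length(wl) == 1L) {
    force(wl); force(v)
    return(function(x) ifelse(x == wl, v, 0))
  }
  f <- stats::approxfun(wl, v, method = "linear", yleft = 0, yright = 0)
  function(x) f(x)
}

# dense midpoint Riemann sum of f over [lo, hi] at 0.01 nm
oracle_dense_area <- function(f, lo, hi, step = 0.01) {
  x <- seq(lo + step / 2, hi - step / 2, by = step)
  sum(f(x)) * step
}

# effective spectrum evaluator of a filter placement: transmission in T mode,
# 1 - transmission in R mode inside the measured range, zero outside
oracle_effective <- function(filter, mode) {
  tr <- filter$transmission
  f <- oracle_interp(tr$wavelength, tr$value)
  lo <- min(tr$wavelength); hi <- max(tr$wavelength)
  if (mode == "T") f
  else function(x) ifelse(x >= lo & x <= hi, 1 - f(x), 0)
}

# product-at-integer-grid evaluator: samples every operand evaluator at the
# integer grid, multiplies, then linearly interpolates the sampled product
oracle_grid_product <- function(evals, lo, hi) {
  grid <- seq(lo, hi)
  vals <- Reduce(`*`, lapply(evals, function(f) f(grid)))
  oracle_interp(grid, vals)
}

oracle_support <- function(s) c(min(s$wavelength), max(s$wavelength))

# union grid over component supports, clamped like the engine's working grid
oracle_grid <- function(supports) {
  lo <- max(200, floor(min(vapply(supports, `[`, 0, 1))))
  hi <- min(1000, ceiling(max(vapply(supports, `[`, 0, 2))))
  c(lo, hi)
}

# full efficiency oracle for a setup built from raw components
oracle_efficiencies <- function(setup) {
  src <- setup$excitation$intensity
  ex_stack <- purrr::map2(setup$ex_path$filters, setup$ex_path$modes,
                          oracle_effective)
  em_stack <- purrr::map2(setup$em_path$filters, setup$em_path$modes,
                          oracle_effective)
  stack_support <- function(stack) {
    if (length(stack$filters) == 0L) list(c(200, 1000))
    else purrr::map(stack$filters, function(f) oracle_support(f$transmission))
  }

  g <- oracle_grid(c(list(oracle_support(src),
                          oracle_support(setup$dye$absorption)),
                     stack_support(setup$ex_path)))
  absorbed <- oracle_grid_product(
    c(list(oracle_interp(src$wavelength, src$value)), ex_stack,
      list(oracle_interp(setup$dye$absorption$wavelength,
                         setup$dye$absorption$value))),
    g[1], g[2])
  src_on_grid <- oracle_grid_product(
    list(oracle_interp(src$wavelength, src$value)), g[1], g[2])
  ex <- oracle_dense_area(absorbed, g[1], g[2]) /
    oracle_dense_area(src_on_grid, g[1], g[2])

  em_sp <- setup$dye$emission
  qe <- if (is.null(setup$detector)) {
    list(f = function(x) rep(1, length(x)), support = c(200, 1000))
  } else {
    list(f = oracle_interp(setup$detector$qe$wavelength,
                           setup$detector$qe$value),
         support = oracle_support(setup$detector$qe))
  }
  g2 <- oracle_grid(c(list(oracle_support(em_sp), qe$support),
                      stack_support(setup$em_path)))
  transmitted <- oracle_grid_product(
    c(list(oracle_interp(em_sp$wavelength, em_sp$value)), em_stack,
      list(qe$f)),
    g2[1], g2[2])
  em_on_grid <- oracle_grid_product(
    list(oracle_interp(em_sp$wavelength, em_sp$value)), g2[1], g2[2])
  em <- oracle_dense_area(transmitted, g2[1], g2[2]) /
    oracle_dense_area(em_on_grid, g2[1], g2[2])

  list(ex = min(1, ex), em = min(1, em))
}

# deterministic randomized synthetic setup used by the property suites
random_setup <- function(i) {
  set.seed(1000 + i)
  sigma <- runif(1, 10, 30)
  mu_abs <- round(runif(1, 420, 640))
  mu_em <- mu_abs + round(runif(1, 20, 60))
  d <- gaussian_dye(mu_abs, mu_em, round(sigma),
                    ext_coeff = round(runif(1, 20000, 150000)),
                    q_yield = round(runif(1, 0.1, 1), 2))
  src <- if (runif(1) < 0.5) {
    laser_line(mu_abs + sample(-20:20, 1))
  } else {
    flat_lamp(mu_abs - 80, mu_abs + 40, level = runif(1, 0.5, 3))
  }
  ex_path <- if (runif(1) < 0.5) {
    filter_stack(list(edge_dichroic(mu_abs + round(runif(1, 5, 25)),
                                    width = runif(1, 2, 8))), "R")
  } else {
    filter_stack()
  }
  em_filters <- list(box_filter(mu_em - round(runif(1, 5, 20)),
                                mu_em + round(runif(1, 10, 40)),
                                t_pass = runif(1, 0.8, 1)))
  em_modes <- "T"
  if (runif(1) < 0.5) {
    em_filters <- c(em_filters,
                    list(edge_dichroic(mu_abs + round(runif(1, 5, 25)),
                                       width = runif(1, 2, 8))))
    em_modes <- c(em_modes, "T")
  }
  det <- if (runif(1) < 0.7) flat_detector(runif(1, 0.5, 1)) else NULL
  optical_setup(src, d, det,
                ex_path = ex_path,
                em_path = filter_stack(em_filters, em_modes))
}
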