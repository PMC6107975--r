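# Core spectrum arithmetic: resampling, products, areas, complements.

test_that("resample interpolates linearly and zero-extends outside the data", {
  s <- spectrum(c(500, 502), c(0, 1))
  r <- resample(s, 499, 503)
  expect_equal(r$wavelength, 499:503)
  expect_equal(r$value, c(0, 0, 0.5, 1, 0))

  # zero at any grid wavelength beyond the measured range
  far <- resample(spectrum(c(700, 800), c(1, 1)), 850, 950)
  expect_true(all(far$value == 0))
})

test_that("resample is idempotent on grid-sampled spectra", {
  set.seed(7)
  s <- spectrum(400:450, runif(51), kind = "intensity")
  once <- resample(s, 390, 460)
  twice <- resample(once, 390, 460)
  expect_identical(once$value, twice$value)
  # already on the grid over its own support: values reproduced exactly
  expect_identical(resample(s)$value, s$value)
})

test_that("empty and degenerate spectra are rejected", {
  expect_error(spectrum(numeric(0), numeric(0)), "no data points")
  expect_error(spectrum(c(500, 500), c(1, 1)), "strictly increasing")
  expect_error(spectrum(c(500, 510), c(-0.1, 1)), "non-negative")
  expect_error(resample(spectrum(500:510, rep(1, 11)), 510, 500), "lo < hi")
})

test_that("area is the trapezoid of the 1 nm interpolant", {
  expect_equal(spc_area(spectrum(c(400, 500), c(1, 1))), 100)
  expect_equal(spc_area(spectrum(c(500, 501, 502), c(0, 1, 0))), 1)
  expect_equal(spc_area(spectrum(c(500, 600), c(0, 0))), 0)
  # a single 1 nm unit pulse has the area of its triangular interpolant
  expect_equal(spc_area(spectrum(561, 1)), 1)
})

test_that("multiply has an identity, composes pointwise, and zero-extends", {
  set.seed(11)
  s <- spectrum(500:540, runif(41), kind = "intensity")
  ones <- spectrum(c(500, 540), c(1, 1), kind = "transmission")
  expect_equal(spc_multiply(s, ones)$value, resample(s, 500, 540)$value)

  box <- function(h) spectrum(600:650, rep(h, 51), kind = "intensity")
  expect_true(all(spc_multiply(box(0.5), box(0.5))$value[1:51] == 0.25))

  disjoint <- spc_multiply(spectrum(c(400, 450), c(1, 1)),
                           spectrum(c(600, 650), c(1, 1)))
  expect_true(all(disjoint$value == 0))
})

test_that("multiply commutes and associates", {
  set.seed(3)
  a <- spectrum(480:560, runif(81), kind = "intensity")
  b <- spectrum(500:600, runif(101), kind = "transmission")
  c3 <- spectrum(450:520, runif(71), kind = "qe")
  expect_equal(spc_multiply(a, b)$value, spc_multiply(b, a)$value)
  expect_equal(spc_multiply(spc_multiply(a, b), c3)$value,
               spc_multiply(a, spc_multiply(b, c3))$value)
})

test_that("complement toggles transmission and reflection and is an involution", {
  t <- spectrum(500:520, rep(0.25, 21), kind = "transmission")
  r <- spc_complement(t)
  expect_equal(spectrum_kind(r), "reflection")
  expect_true(all(r$value == 0.75))
  expect_equal(spc_complement(spectrum(c(500, 510), c(1, 1),
                                       kind = "transmission"))$value,
               c(0, 0))

  set.seed(5)
  s <- spectrum(420:470, runif(51), kind = "transmission")
  expect_identical(spc_complement(spc_complement(s))$value, s$value)
  expect_identical(spectrum_kind(spc_complement(spc_complement(s))),
                   "transmission")

  bad <- spectrum(c(500, 510), c(1.5, 0.2), kind = "transmission")
  expect_error(spc_complement(bad), "not a unit-bounded spectrum")
})

test_that("peak normalisation rescales to unit maximum", {
  s <- spectrum(c(500, 510, 520), c(2, 4, 1), kind = "intensity")
  expect_equal(peak_normalize(s)$value, c(0.5, 1, 0.25))
  p <- peak_normalize(s)
  expect_identical(peak_normalize(p)$value, p$value)
  expect_error(peak_normalize(spectrum(c(500, 510), c(0, 0))), "all-zero")
})

test_that("percent-scale unit-bounded curves are detected and rescaled", {
  # vendor filter curve peaking at 98 (percent) comes out unit-bounded
  v <- c(2, 50, 98, 50, 2)
  f <- spectrum(500:504, v, kind = "transmission")
  expect_equal(max(f$value), 0.98)
  expect_equal(max(peak_normalize(f)$value), 1)
  # fraction-scale data is left alone
  expect_equal(max(spectrum(500:504, v / 100, kind = "transmission")$value),
               0.98)
  # intensities are arbitrary units and never rescaled
  expect_equal(max(spectrum(500:504, v, kind = "intensity")$value), 98)
})

test_that("area of a product is bounded by operand areas (random spectra)", {
  for (i in 1:20) {
    set.seed(i)
    n <- sample(20:80, 1)
    a <- spectrum(seq(400, length.out = n), runif(n, 0, 3), kind = "intensity")
    b <- spectrum(seq(sample(380:420, 1), length.out = n), runif(n),
                  kind = "transmission")
    expect_lte(spc_area(spc_multiply(a, b)),
               min(spc_area(a) * max(b$value), spc_area(b) * max(a$value)) +
                 1e-12)
  }
})

test_that("trapezoid area matches dense midpoint integration of the interpolant", {
  for (i in 1:10) {
    set.seed(100 + i)
    mu <- runif(1, 450, 650)
    sig <- runif(1, 8, 30)
    wl <- seq(round(mu - 5 * sig), round(mu + 5 * sig))
    s <- spectrum(wl, exp(-(wl - mu)^2 / (2 * sig^2)), kind = "intensity")
    f <- oracle_interp(s$wavelength, s$value)
    dense <- oracle_dense_area(f, min(wl), max(wl))
    expect_equal(spc_area(s), dense, tolerance = 1e-6)
  }
})
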