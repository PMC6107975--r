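# Efficiency integrals, brightness, ranking, bleedthrough.

test_that("transmitted spectrum is emission x emission path x detector", {
  d <- gaussian_dye(560, 590, 15, 90000, 0.7)
  # all-pass path and unit detector: transmitted equals resampled emission
  s <- optical_setup(laser_line(560), d, flat_detector(1))
  tr <- transmitted_spectrum(s)
  em <- resample(d$emission, min(tr$wavelength), max(tr$wavelength))
  expect_equal(tr$value, em$value)

  # a filter fully blocking the emission band yields an all-zero spectrum
  block <- light_filter("block", spectrum(c(200, 1000), c(0, 0),
                                          kind = "transmission"))
  s2 <- optical_setup(laser_line(560), d, flat_detector(1),
                      em_path = filter_stack(list(block), "T"))
  expect_true(all(transmitted_spectrum(s2)$value == 0))
  expect_equal(emission_efficiency(s2), 0)
})

test_that("band-limited collection efficiency matches the normal-CDF closed form", {
  # Gaussian emission (mu 610, sigma 20) through an ideal box [600, 640]
  d <- gaussian_dye(575, 610, 20, 90000, 0.7)
  s <- optical_setup(laser_line(575), d, flat_detector(1),
                     em_path = filter_stack(list(box_filter(600, 640)), "T"))
  expect_equal(emission_efficiency(s), pnorm(1.5) - pnorm(-0.5),
               tolerance = 1e-3)
  # transmitted area itself matches the Phi-difference closed form
  expect_equal(spc_area(transmitted_spectrum(s)),
               20 * sqrt(2 * pi) * (pnorm(1.5) - pnorm(-0.5)),
               tolerance = 1e-3)
})

test_that("laser excitation hits the closed forms at and off the peak", {
  d <- gaussian_dye(590, 620, 15, 90000, 0.7)
  expect_identical(
    excitation_efficiency(optical_setup(laser_line(590), d)), 1)
  expect_equal(
    excitation_efficiency(optical_setup(laser_line(605), d)),
    exp(-1 / 2), tolerance = 1e-3)
  # laser outside the absorption band excites nothing
  expect_equal(
    excitation_efficiency(optical_setup(laser_line(800), d)), 0)
})

test_that("flat lamp through an ideal box excites in proportion to bandwidth", {
  # absorption flat over the lamp range would be ideal; use a box on the lamp
  d <- gaussian_dye(560, 590, 15, 90000, 0.7)
  lamp <- flat_lamp(460, 660, level = 2)
  pass <- box_filter(520, 600)
  s <- optical_setup(lamp, d, ex_path = filter_stack(list(pass), "T"))
  got <- excitation_efficiency(s)
  want <- oracle_efficiencies(s)$ex
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("brightness normalises to 10 for the reference constants and is linear in EC and QY", {
  d <- gaussian_dye(560, 590, 15, ext_coeff = 73000, q_yield = 0.92)
  ideal <- optical_setup(laser_line(560), d, flat_detector(1))
  expect_equal(brightness(ideal), 10)

  half_qy <- swap_dye(ideal, gaussian_dye(560, 590, 15, 73000, 0.46))
  expect_equal(brightness(half_qy), brightness(ideal) / 2)
  double_ec <- swap_dye(ideal, gaussian_dye(560, 590, 15, 146000, 0.92))
  expect_equal(brightness(double_ec), brightness(ideal) * 2)

  # zero excitation -> zero brightness
  dark <- swap_excitation(ideal, laser_line(900))
  expect_equal(brightness(dark), 0)

  # missing constants: brightness errors, the report still carries efficiencies
  anon <- swap_dye(ideal, gaussian_dye(560, 590, 15))
  expect_error(brightness(anon), "brightness unavailable")
  rep <- light_report(anon)
  expect_true(is.na(rep$brightness))
  expect_equal(rep$ex_eff, 1)
})

test_that("optimise_dyes recovers an engineered ordering and flags incomplete dyes", {
  # three dyes whose emission overlap with the passband is ordered by
  # construction; identical EC*QY so brightness order follows the overlap
  channel <- filter_stack(list(box_filter(580, 640)), "T")
  dyes <- list(
    gaussian_dye(560, 600, 15, 90000, 0.8, id = "in-band"),
    gaussian_dye(560, 630, 15, 90000, 0.8, id = "edge"),
    gaussian_dye(560, 680, 15, 90000, 0.8, id = "far-red"),
    gaussian_dye(560, 600, 15, id = "no-constants"))
  setup <- optical_setup(laser_line(560), dyes[[1]], flat_detector(1),
                         em_path = channel)
  tbl <- optimise_dyes(setup, dyes)
  expect_equal(tbl$dye, c("in-band", "edge", "far-red", "no-constants"))
  expect_true(tbl$missing_constants[4])
  expect_false(any(tbl$missing_constants[1:3]))
  # flagged dye keeps its efficiencies
  expect_equal(tbl$ex_eff[4], tbl$ex_eff[1])
  expect_true(is.na(tbl$brightness[4]))
  # output is a permutation of the collection
  expect_setequal(tbl$dye, purrr::map_chr(dyes, "id"))

  # the engineered order agrees with the independent oracle's em ordering
  oracle_em <- purrr::map_dbl(dyes[1:3], function(dd) {
    oracle_efficiencies(swap_dye(setup, dd))$em
  })
  expect_equal(order(-oracle_em), 1:3)

  # alternative sort keys
  tbl_em <- optimise_dyes(setup, dyes, sort_by = "em")
  expect_equal(tbl_em$dye[1], "in-band")
  expect_true(all(diff(tbl_em$em_eff) <= 1e-12))
})

test_that("optimise_dyes is deterministic with ties broken by id", {
  dyes <- list(gaussian_dye(560, 600, 15, 90000, 0.8, id = "b-dye"),
               gaussian_dye(560, 600, 15, 90000, 0.8, id = "a-dye"))
  setup <- optical_setup(laser_line(560), dyes[[1]], flat_detector(1))
  tbl <- optimise_dyes(setup, dyes)
  expect_equal(tbl$dye, c("a-dye", "b-dye"))
})

test_that("bleedthrough is a brightness ratio with the expected limits", {
  channel <- optical_setup(
    laser_line(560), gaussian_dye(560, 600, 15, 90000, 0.8),
    flat_detector(1), em_path = filter_stack(list(box_filter(585, 625)), "T"))
  on_dye <- gaussian_dye(560, 600, 15, 90000, 0.8, id = "on")
  expect_equal(bleedthrough(channel, on_dye, on_dye), 1)

  # emission disjoint from the passband: nothing bleeds through
  far <- gaussian_dye(560, 800, 15, 90000, 0.8, id = "far")
  expect_equal(bleedthrough(channel, on_dye, far), 0)

  # two Gaussian dyes 40 nm apart: ratio matches the independent oracle
  off_dye <- gaussian_dye(580, 640, 15, 90000, 0.8, id = "off")
  got <- bleedthrough(channel, on_dye, off_dye)
  o_on <- oracle_efficiencies(swap_dye(channel, on_dye))
  o_off <- oracle_efficiencies(swap_dye(channel, off_dye))
  want <- (o_off$ex * o_off$em) / (o_on$ex * o_on$em)
  expect_equal(got, want, tolerance = 1e-3)
  expect_gt(got, 0)
  expect_lt(got, 1)

  # a channel blind to its own dye is an error
  blind <- swap_excitation(channel, laser_line(900))
  expect_error(bleedthrough(blind, on_dye, off_dye), "does not detect")
})

test_that("efficiencies stay in [0,1] and shrink when filters are appended", {
  for (i in 1:12) {
    s <- random_setup(i)
    ex <- excitation_efficiency(s)
    em <- emission_efficiency(s)
    expect_gte(ex, 0); expect_lte(ex, 1)
    expect_gte(em, 0); expect_lte(em, 1)
    extra <- box_filter(500 + 10 * i, 620 + 5 * i, t_pass = 0.9)
    s_ex <- s; s_ex$ex_path <- stack_append(s$ex_path, extra, "T")
    s_em <- s; s_em$em_path <- stack_append(s$em_path, extra, "T")
    expect_lte(excitation_efficiency(s_ex), ex + 1e-12)
    expect_lte(emission_efficiency(s_em), em + 1e-12)
  }
})

test_that("repeated evaluation of an immutable setup is bit-stable", {
  s <- random_setup(1)
  r1 <- glance(light_report(s))
  r2 <- glance(light_report(s))
  expect_identical(r1, r2)
})
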