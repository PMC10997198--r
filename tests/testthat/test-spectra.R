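# Vibronic lineshapes, mirror-image emission, and overlap integrals.

test_that("evaluate gives a normalized, non-negative profile with the Gaussian peak value", {
  sh <- lineshape("ABSORPTION", 15000,
                  data.frame(offset = 0, weight = 1, sigma = 100))
  ev <- evaluate(sh)
  expect_true(all(ev$density >= 0))
  area <- sum(diff(ev$nu) * (ev$density[-1] + ev$density[-length(ev$density)])) / 2
  expect_equal(area, 1, tolerance = 1e-6)
  # peak value 1/(sigma sqrt(2 pi)) ~ 3.989e-3 at the 0-0 energy
  expect_equal(max(ev$density), 1 / (100 * sqrt(2 * pi)), tolerance = 1e-4)
  expect_equal(ev$nu[which.max(ev$density)], 15000)

  # random valid shapes stay normalized and place components on the right side
  set.seed(51)
  for (rep in 1:5) {
    comp <- data.frame(offset = sort(runif(3, 0, 2500)),
                       weight = runif(3, 0.2, 1), sigma = runif(3, 300, 800))
    for (kind in c("ABSORPTION", "EMISSION")) {
      ev <- evaluate(lineshape(kind, 15000, comp))
      a <- sum(diff(ev$nu) * (ev$density[-1] + ev$density[-length(ev$density)])) / 2
      expect_equal(a, 1, tolerance = 1e-6)
      com <- sum(ev$nu * ev$density) / sum(ev$density)
      if (kind == "ABSORPTION") expect_gt(com, 15000) else expect_lt(com, 15000)
    }
  }
  expect_error(lineshape("ABSORPTION", 15000,
                         data.frame(offset = 0, weight = 1, sigma = 100),
                         grid = c(14900, 15100, 1)),
               "5 sigma")
})

test_that("mirror_emission reflects vibronic components about the 0-0 line", {
  ab <- lineshape("ABSORPTION", 16000,
                  data.frame(offset = c(0, 1200), weight = c(1, 0.6),
                             sigma = c(80, 80)))
  em <- mirror_emission(ab)
  expect_equal(em$kind, "EMISSION")
  expect_equal(em$e00, ab$e00)
  ev <- evaluate(em)
  # the satellite sits at e00 - 1200
  locmax <- ev$nu[which(diff(sign(diff(ev$density))) == -2) + 1]
  expect_true(any(abs(locmax - (16000 - 1200)) < 2))
  # a symmetric (offset-0) shape maps to itself on the shared grid
  sym <- lineshape("ABSORPTION", 15000,
                   data.frame(offset = 0, weight = 1, sigma = 150))
  evs <- evaluate(sym); evm <- evaluate(mirror_emission(sym))
  expect_equal(evm$density[match(evs$nu, evm$nu)], evs$density,
               tolerance = 1e-12)
  expect_error(mirror_emission(em), "ABSORPTION")
})

test_that("spectral_overlap matches the Gaussian-product closed form", {
  mk <- function(kind, e00) lineshape(kind, e00,
                                      data.frame(offset = 0, weight = 1,
                                                 sigma = 100))
  # identical aligned Gaussians: J = 1/(2 sigma sqrt(pi))
  j0 <- spectral_overlap(mk("EMISSION", 15000), mk("ABSORPTION", 15000))
  expect_equal(j0, 1 / (2 * 100 * sqrt(pi)), tolerance = 1e-4)
  expect_equal(j0, 2.8209e-3, tolerance = 1e-4)
  # centres 200 cm^-1 apart: J = exp(-200^2/(4 sigma^2)) * j0 = e^-1 j0
  j200 <- spectral_overlap(mk("EMISSION", 15200), mk("ABSORPTION", 15000))
  expect_equal(j200, exp(-1) * 1 / (200 * sqrt(pi)), tolerance = 1e-4)
  expect_equal(j200, 1.0377e-3, tolerance = 1e-4)
  # 10 sigma apart: vanishing but computed on a shared grid
  expect_lt(spectral_overlap(mk("EMISSION", 16000), mk("ABSORPTION", 15000)),
            1e-10)
  # fully disjoint grids are an error, distinct from J ~ 0
  expect_error(spectral_overlap(mk("EMISSION", 30000), mk("ABSORPTION", 15000)),
               "disjoint")
})

test_that("overlap is shift-invariant, monotone in width, and accurate on fine grids", {
  comp_d <- data.frame(offset = c(0, 1300), weight = c(1, 0.5),
                       sigma = c(500, 500))
  comp_a <- data.frame(offset = c(0, 1400), weight = c(1, 0.7),
                       sigma = c(600, 600))
  j <- function(ed, ea) spectral_overlap(
    mirror_emission(lineshape("ABSORPTION", ed, comp_d)),
    lineshape("ABSORPTION", ea, comp_a))
  # shifting both spectra by the same amount leaves J unchanged
  expect_equal(j(15152, 14731), j(15152 + 500, 14731 + 500),
               tolerance = 1e-10)
  # narrowing both identical aligned Gaussians increases J
  js <- vapply(c(400, 200, 100, 50), function(s) {
    sh <- data.frame(offset = 0, weight = 1, sigma = s)
    spectral_overlap(lineshape("EMISSION", 15000, sh),
                     lineshape("ABSORPTION", 15000, sh))
  }, 0)
  expect_true(all(diff(js) > 0))
  # trapezoid vs closed form within 0.1% for step <= sigma/10
  sh <- data.frame(offset = 0, weight = 1, sigma = 100)
  jt <- spectral_overlap(
    lineshape("EMISSION", 15000, sh, grid = c(14000, 16000, 10)),
    lineshape("ABSORPTION", 15000, sh, grid = c(14000, 16000, 10)))
  expect_equal(jt, 1 / (2 * 100 * sqrt(pi)), tolerance = 1e-3)
})

test_that("unit conversions are exact and mutually inverse", {
  expect_equal(ev_to_cm1(1), 8065.544, tolerance = 1e-6)
  expect_equal(nm_to_cm1(660), 1e7 / 660)
  expect_equal(cm1_to_ev(ev_to_cm1(2)), 2, tolerance = 1e-12)
  expect_equal(cm1_to_nm(nm_to_cm1(620)), 620, tolerance = 1e-12)
})

test_that("tabulated spectra import normalized", {
  f <- withr::local_tempfile(fileext = ".txt")
  nu <- seq(14000, 16000, 5)
  writeLines(paste(nu, dnorm(nu, 15000, 200) * 7), f)
  sp <- read_tabulated_spectrum(f)
  area <- sum(diff(sp$nu) * (sp$density[-1] + sp$density[-length(sp$density)])) / 2
  expect_equal(area, 1, tolerance = 1e-9)
})
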