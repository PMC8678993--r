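wn_default <- seq(900, 4000, by = 4)

test_that("a linear spectrum integrates to zero (baseline absorbs it)", {
  band <- band_definition("b", 1600, 1720)
  for (co in list(c(0, 0), c(2, 0), c(1, -0.003), c(-5, 0.01))) {
    s <- co[1] + co[2] * wn_default
    expect_lt(abs(integrate_band(s, wn_default, band)), 1e-9)
  }
})

test_that("unit Gaussian of width 10 integrates to sigma*sqrt(2*pi)", {
  center <- 1660  # on the 4 cm-1 grid
  s <- exp(-(wn_default - center)^2 / (2 * 10^2))
  band <- band_definition("g", center - 60, center + 60)
  area <- integrate_band(s, wn_default, band)
  expect_equal(area, 10 * sqrt(2 * pi), tolerance = 1e-4)
  expect_equal(round(area, 3), 25.066)
  h <- band_definition("g", center - 60, center + 60, mode = "height")
  expect_equal(integrate_band(s, wn_default, h), 1.0, tolerance = 1e-4)
})

test_that("band integration is linear in the spectrum", {
  set.seed(11)
  band <- band_definition("b", 1300, 1500)
  for (i in 1:20) {
    s1 <- rnorm(length(wn_default))
    s2 <- rnorm(length(wn_default))
    a <- runif(1, -3, 3); b <- runif(1, -3, 3)
    lhs <- integrate_band(a * s1 + b * s2, wn_default, band)
    rhs <- a * integrate_band(s1, wn_default, band) +
      b * integrate_band(s2, wn_default, band)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("area is invariant under adding an affine function of wavenumber", {
  set.seed(12)
  band <- band_definition("b", 2800, 3000)
  for (i in 1:20) {
    s <- rnorm(length(wn_default))
    off <- runif(1, -2, 2) + runif(1, -0.01, 0.01) * wn_default
    expect_equal(integrate_band(s + off, wn_default, band),
                 integrate_band(s, wn_default, band), tolerance = 1e-8)
  }
})

test_that("trapezoid result converges to the quadrature oracle with step", {
  f <- function(x) 0.8 * exp(-(x - 1650)^2 / (2 * 6^2))
  band <- band_definition("g", 1590, 1710)
  ref <- oracle_band_area(f, band$lo, band$hi, band$anchor_hw, step = 0.1)
  errs <- vapply(c(8, 4, 2), function(step) {
    wn <- seq(900, 4000, by = step)
    abs(integrate_band(f(wn), wn, band) - ref)
  }, 0)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 1e-6)
})

test_that("window and resolution preconditions are enforced", {
  expect_error(band_definition("b", 1700, 1600), "lo < hi")
  expect_error(band_definition("b", 1600, 1700, anchor_hw = -1), ">= 0")
  band <- band_definition("b", 100, 200)
  expect_error(integrate_band(rnorm(776), wn_default, band), "outside")
  wn_coarse <- seq(900, 4000, by = 200)
  narrow <- band_definition("b", 1580, 1620)
  expect_error(integrate_band(rnorm(length(wn_coarse)), wn_coarse, narrow),
               "fewer than 2")
})

test_that("default registry reproduces the standard parameter panel", {
  reg <- parameter_registry()
  absolute <- Filter(function(p) is.null(p$denominator), reg)
  ratio <- Filter(function(p) !is.null(p$denominator), reg)
  expect_length(reg, 17)
  expect_length(absolute, 6)
  expect_length(ratio, 11)
  expect_setequal(
    names(reg),
    c("1658", "1635/1658", "2800-3000", "2924/2955", "1080", "1240",
      "1360-1480", "1740",
      "2800-3000/1658", "1080/1658", "1240/1658", "1740/1658",
      "1360-1480/1658", "1080/2800-3000", "1240/2800-3000",
      "1740/2800-3000", "1360-1480/2800-3000"))
  # massifs integrate over their printed ranges
  expect_equal(c(reg[["2800-3000"]]$numerator$lo,
                 reg[["2800-3000"]]$numerator$hi), c(2800, 3000))
  expect_equal(c(reg[["1360-1480"]]$numerator$lo,
                 reg[["1360-1480"]]$numerator$hi), c(1360, 1480))
  # single bands use +/-24 cm-1 windows around the nominal centre
  expect_equal(c(reg[["1740"]]$numerator$lo, reg[["1740"]]$numerator$hi),
               c(1716, 1764))
  # amide I sub-components stay disjoint
  expect_lt(reg[["1635/1658"]]$numerator$hi,
            reg[["1635/1658"]]$denominator$lo)
  for (p in reg) {
    expect_lt(p$numerator$lo, p$numerator$hi)
    expect_gte(p$numerator$lo, 900)
    expect_lte(p$numerator$hi, 4000)
  }
})

test_that("registry JSON round-trips", {
  reg <- parameter_registry()
  path <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(names(back), names(reg))
  for (nm in names(reg)) {
    expect_equal(back[[nm]]$numerator, reg[[nm]]$numerator)
    expect_equal(back[[nm]]$denominator, reg[[nm]]$denominator)
  }
})

test_that("self-ratio parameter maps to 1 on valid pixels", {
  ph <- make_phantom(tiny_config(), group = "N")
  b <- default_bands()[["1658"]]
  spec <- parameter_spec("self", b, b)
  cm <- compute_parameter(ph$map, spec)
  tissue <- ph$mask$labels > 0
  expect_true(all(abs(cm$values[tissue & cm$valid] - 1) < 1e-12))
})

test_that("zero denominators yield invalid pixels, never NaN or Inf", {
  cube <- array(0, c(3, 3, length(wn_default)))
  m <- spectral_map(cube, wn_default)
  cm <- compute_parameter(m, "1635/1658")
  expect_false(any(cm$valid))
  expect_true(all(is.na(cm$values)))
  expect_false(any(is.nan(cm$values)) || any(is.infinite(cm$values)))
})

test_that("unknown parameter names are a lookup error", {
  ph <- make_phantom(tiny_config(), group = "N")
  expect_error(compute_parameter(ph$map, "amide-Z"), "unknown parameter")
})

test_that("tissue mask thresholds amide I area", {
  ph <- make_phantom(tiny_config(), group = "N")
  footprint <- ph$mask$labels > 0
  expect_true(all(tissue_mask(ph$map, 0)))
  expect_identical(tissue_mask(ph$map, 1), footprint)
  expect_warning(tm <- tissue_mask(ph$map, 1e6), "empty")
  expect_false(any(tm))
})
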