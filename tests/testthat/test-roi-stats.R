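test_that("erosion matches the brute-force neighborhood oracle", {
  set.seed(21)
  # random rectangles and blobs at radii 1-3
  for (i in 1:60) {
    nr <- sample(4:9, 1); nc <- sample(4:9, 1)
    region <- matrix(runif(nr * nc) < 0.6, nr, nc)
    r <- sample(1:3, 1)
    expect_identical(hippospec:::erode_region(region, r),
                     erode_bf(region, r))
  }
  # exhaustive check at radius 1 over every 4x4 binary mask
  fails <- 0
  for (code in 0:65535) {
    region <- matrix(bitwAnd(code, 2^(0:15)) > 0, 4, 4)
    if (!identical(hippospec:::erode_region(region, 1),
                   erode_bf(region, 1)))
      fails <- fails + 1
  }
  expect_equal(fails, 0)
  # erosion 1 of a 3-pixel-wide stripe keeps only interior pixels
  stripe <- matrix(FALSE, 7, 9)
  stripe[3:5, ] <- TRUE
  got <- hippospec:::erode_region(stripe, 1)
  expect_identical(got, erode_bf(stripe, 1))
  expect_equal(sum(got), 1 * 7)   # middle row, side columns eroded
})

test_that("layer extraction returns valid in-layer pixels after erosion", {
  labels <- matrix(0L, 10, 22)
  labels[3:7, 2:21] <- 1L          # 100-pixel layer... make it 200
  labels[3:7, ] <- 1L
  labels[1, ] <- 0L
  mask <- layer_mask(labels, c(GR = 1))
  vals <- matrix(2.5, 10, 22)
  cm <- chemical_map(vals, matrix(TRUE, 10, 22), "p")
  got <- extract_layer_pixels(cm, mask, "GR", erosion = 0)
  expect_equal(got$n, sum(labels == 1))
  expect_true(all(got$values == 2.5))

  got1 <- extract_layer_pixels(cm, mask, "GR", erosion = 1)
  expect_equal(got1$n, sum(erode_bf(labels == 1, 1)))

  # all layer pixels invalid -> empty extraction, QC failure downstream
  cm_invalid <- chemical_map(vals, matrix(FALSE, 10, 22), "p")
  got0 <- extract_layer_pixels(cm_invalid, mask, "GR")
  expect_equal(got0$n, 0)
  s <- summarize_animal(got0$values, min_count = 120)
  expect_false(s$qc_pass)

  expect_error(extract_layer_pixels(cm, mask, "MO"), "MO")
})

test_that("per-animal summaries are arithmetic means with QC", {
  expect_equal(summarize_animal(c(1, 2, 3))$mean, 2.0)
  expect_equal(summarize_animal(rep(7.7, 50))$mean, 7.7)
  expect_true(summarize_animal(rnorm(200), min_count = 150)$qc_pass)
  expect_false(summarize_animal(rnorm(100), min_count = 150)$qc_pass)
  expect_false(summarize_animal(numeric(0))$qc_pass)
})

test_that("noiseless phantom layer means equal the layer spectrum's value", {
  cfg <- tiny_config(wn_step = 2, layer_bands = narrow_layer_bands())
  ph <- make_phantom(cfg, group = "N")
  cm <- compute_parameter(ph$map, "1740")
  got <- extract_layer_pixels(cm, ph$mask, "MO", erosion = 0)
  # every MO pixel shares the same noiseless spectrum
  expect_equal(sd(got$values), 0)
  rc <- which(ph$mask$labels == ph$mask$legend[["MO"]], arr.ind = TRUE)[1, ]
  single <- integrate_band(ph$map$absorbance[rc[1], rc[2], ],
                           ph$map$wavenumbers, default_bands()[["1740"]])
  expect_equal(mean(got$values), single, tolerance = 1e-12)
})

test_that("Mann-Whitney matches the stated example and handles degeneracy", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$direction, "down")
  expect_equal(r$method, "exact")

  same <- mann_whitney(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")
  expect_false(same$significant)

  expect_error(mann_whitney(numeric(0), 1:3), "at least one")
})

test_that("U statistics satisfy the rank-sum identity U1 + U2 = n1*n2", {
  set.seed(31)
  for (i in 1:200) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    # mixed continuous and tied data
    x <- if (i %% 2) rnorm(n1) else sample(1:4, n1, replace = TRUE)
    y <- if (i %% 2) rnorm(n2) else sample(1:4, n2, replace = TRUE)
    u1 <- mann_whitney(x, y)$U
    u2 <- mann_whitney(y, x)$U
    expect_equal(u1 + u2, n1 * n2)
  }
})

test_that("exact p equals complete enumeration for small tie-free samples", {
  # spot patterns here; the exhaustive sweep lives in the acceptance suite
  set.seed(32)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(mann_whitney(x, y)$p, mw_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("group comparison tables have the documented shape and QC", {
  summ <- expand.grid(animal_id = sprintf("A%d", 1:6),
                      layer = "GR", parameter = "1740",
                      stringsAsFactors = FALSE)
  summ$group <- rep(c("K", "N"), each = 3)
  summ$mean <- c(5, 6, 7, 1, 2, 3)
  summ$n_pixels <- 200L
  summ$qc_pass <- TRUE
  out <- run_comparisons(summ, "group")
  expect_equal(nrow(out), 1)
  expect_equal(out$direction, "up")
  expect_equal(out$n1, 3)
  expect_true(all(c("p", "p_bh", "U", "significant") %in% names(out)))

  expect_error(run_comparisons(summ, list(c("K", "Z"))), "Z")

  # QC-failing animals are excluded from the test
  summ2 <- summ
  summ2$qc_pass[1] <- FALSE
  out2 <- run_comparisons(summ2, "group")
  expect_equal(out2$n1, 2)

  # clonic scheme compares severe/light subgroups and controls only;
  # intermediate animals never enter a pair
  prs <- hippospec:::grouping_pairs("clonic")
  expect_false("ICS" %in% unlist(prs))
  expect_setequal(unlist(prs), c("CS", "LCS", "N"))
})

test_that("direction labels are based on group medians", {
  summ <- data.frame(animal_id = sprintf("A%d", 1:8),
                     group = rep(c("K", "N"), each = 4),
                     layer = "MO", parameter = "x",
                     mean = c(1, 2, 3, 10, 4, 5, 6, 7),
                     n_pixels = 500L, qc_pass = TRUE)
  out <- run_comparisons(summ, "group")
  # median(K) = 2.5 < median(N) = 5.5 even though mean(K) = 4 > ...
  expect_equal(out$direction, "down")
})
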