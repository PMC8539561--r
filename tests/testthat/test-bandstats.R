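test_that("band RMS matches hand-computed values", {
  s <- spectrum(c(500, 501, 502), c(3, 4, 9))
  b <- band("two", 500, 501, "other")
  expect_equal(band_rms(s, b), sqrt((9 + 16) / 2))
  # zero spectrum and constant spectrum
  z <- spectrum(c(500, 501, 502), c(0, 0, 0))
  expect_equal(band_rms(z, b), 0)
  cc <- spectrum(c(500, 501, 502), c(7, 7, 7))
  expect_equal(band_rms(cc, band("all", 499, 503, "other")), 7)
  # empty band errors, naming band and axis extent
  expect_error(band_rms(s, band("off", 900, 950, "other")),
               "off.*no axis samples")
})

test_that("normalization is a ratio with missing on zero noise", {
  s <- spectrum(c(500, 501, 600, 601), c(3, 4, 3, 4))
  b <- band("sig", 600, 601, "DNA")
  nz <- band("noise", 500, 501, "noise")
  expect_equal(normalized_band_rms(s, b, nz), 1.0)
  s2 <- spectrum(c(500, 501, 600, 601), c(0.5, 0.5, 3, 4))
  expect_equal(normalized_band_rms(s2, b, nz), sqrt(12.5) / 0.5)
  s3 <- spectrum(c(500, 501, 600, 601), c(0, 0, 3, 4))
  expect_true(is.na(normalized_band_rms(s3, b, nz)))
})

test_that("normalized band RMS is scale invariant", {
  set.seed(9)
  ax <- ax_default()
  s <- spectrum(ax, abs(rnorm(length(ax))) + 0.1)
  b <- band("sig", 655, 680, "DNA")
  nz <- band("noise", 500, 520, "noise")
  ref <- normalized_band_rms(s, b, nz)
  for (k in -3:3) {
    sk <- spectrum(ax, s$intensities * 10^k)
    expect_equal(normalized_band_rms(sk, b, nz), ref, tolerance = 1e-12)
  }
})

test_that("band_rms equals the naive loop oracle on random spectra", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(50:200, 1)
    ax <- sort(runif(n, 400, 1800))
    while (any(diff(ax) <= 0)) ax <- sort(runif(n, 400, 1800))
    y <- rnorm(n, sd = runif(1, 0.1, 50))
    lo <- runif(1, 400, 1500); hi <- lo + runif(1, 30, 300)
    s <- spectrum(ax, y)
    b <- band("r", lo, hi, "other")
    if (!any(ax >= lo & ax <= hi)) next
    expect_equal(band_rms(s, b), naive_band_rms(ax, y, lo, hi),
                 tolerance = 1e-12)
  }
})

test_that("adding in-band signal never decreases the normalized RMS", {
  set.seed(21)
  ax <- ax_default()
  b <- band("sig", 655, 680, "DNA")
  nz <- band("noise", 500, 520, "noise")
  for (i in 1:25) {
    y <- rnorm(length(ax))
    s <- spectrum(ax, y)
    base <- normalized_band_rms(s, b, nz)
    add <- abs(rnorm(1, sd = 3)) * (ax >= 660 & ax <= 670)
    # non-negative addition inside the band, same sign as residuals? the
    # guarantee holds for |x| -> RMS of x + a when a has the sign of x;
    # use magnitudes to state the property cleanly
    s2 <- spectrum(ax, y + sign(y) * add)
    expect_gte(normalized_band_rms(s2, b, nz) + 1e-12, base)
  }
})

test_that("pure noise normalizes to ~1 in any equal-width band", {
  set.seed(33)
  ax <- ax_default()
  b <- band("probe", 655, 675, "other")   # same width as the noise window
  nz <- band("noise", 500, 520, "noise")
  vals <- replicate(200, {
    s <- spectrum(ax, rnorm(length(ax)))
    normalized_band_rms(s, b, nz)
  })
  expect_gt(mean(vals), 0.9)
  expect_lt(mean(vals), 1.1)
})

test_that("compute_map reproduces a per-pixel brute-force oracle", {
  set.seed(14)
  ax <- c(500, 510, 520, 660, 670, 680)
  cube <- array(rnorm(2 * 2 * 6, sd = 2), c(2, 2, 6))
  img <- hyper_image(ax, cube)
  b <- band("sig", 655, 680, "DNA")
  nz <- band("noise", 500, 520, "noise")
  m <- compute_map(img, b, nz)
  for (i in 1:2) for (j in 1:2) {
    num <- naive_band_rms(ax, cube[i, j, ], 655, 680)
    den <- naive_band_rms(ax, cube[i, j, ], 500, 520)
    expect_equal(m[i, j], num / den, tolerance = 1e-12)
  }
  expect_s3_class(m, "band_stat_map")
  expect_equal(attr(m, "band")$name, "sig")
  expect_true(attr(m, "normalized"))
  # uniform cube -> constant map
  ucube <- array(rep(rnorm(6), each = 4), c(2, 2, 6))
  um <- compute_map(hyper_image(ax, ucube), b, nz)
  expect_equal(max(um) - min(um), 0)
  # band off the axis errors with context
  expect_error(compute_map(img, band("off", 900, 950, "other"), nz),
               "compute_map")
})

test_that("the phantom DNA map is maximal inside nucleus-on-hotspot", {
  ph <- small_phantom()
  sub <- subtract_baseline_image(
    ph$cube, baseline_recipe("poly-anchors",
                             anchors = default_anchor_points(), degree = 5))
  maps <- compute_maps(sub)
  nuc <- compartment_mask(ph, "nucleus")
  expect_gt(mean(maps$DNA[nuc]), 2 * mean(maps$DNA[!nuc]))
  # map CSV export round-trips values
  p <- withr::local_tempfile(fileext = ".csv")
  write_map_csv(maps$DNA, p)
  back <- as.matrix(utils::read.csv(p, header = FALSE))
  expect_equal(unname(back), unclass(maps$DNA), tolerance = 1e-6,
               ignore_attr = TRUE)
})
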