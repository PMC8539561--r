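test_that("recipe construction validates parameter sets", {
  r <- baseline_recipe()
  expect_equal(r$method, "als")
  expect_equal(r$smoothness, 1e5)
  expect_equal(r$asymmetry, 0.01)
  expect_equal(r$iterations, 10L)
  expect_error(baseline_recipe(smoothness = -1), "positive")
  expect_error(baseline_recipe(asymmetry = 1), "0, 1")
  expect_error(baseline_recipe(iterations = 0), ">= 1")
  expect_error(baseline_recipe("poly-anchors", degree = -1), ">= 0")
  p <- withr::local_tempfile(fileext = ".json")
  r2 <- baseline_recipe("poly-anchors", anchors = c(500, 900, 1700),
                        degree = 2)
  write_recipe(r2, p)
  expect_equal(read_recipe(p), r2)
})

test_that("a featureless spectrum is its own ALS baseline", {
  ax <- ax_default()
  s <- spectrum(ax, 5 + 0.01 * ax)
  b <- fit_baseline(s, baseline_recipe())
  expect_lt(max(abs(b$intensities - s$intensities) / s$intensities), 0.01)
  z <- spectrum(ax, rep(0, length(ax)))
  expect_equal(fit_baseline(z, baseline_recipe())$intensities,
               rep(0, length(ax)))
})

test_that("baseline subtraction recovers an injected Lorentzian", {
  ax <- ax_default()
  bg <- 1e-8 * (ax - 1100)^3 + 20 + 0.005 * ax
  peak <- lorentzian(ax, 1000, 12, 100)
  s <- spectrum(ax, bg + peak)
  r <- subtract_baseline(s, baseline_recipe())
  expect_lt(abs(r$intensities[ax == 1000] - 100) / 100, 0.05)
})

test_that("anchored polynomial removes a polynomial background exactly", {
  ax <- ax_default()
  bg <- 3 + 0.02 * (ax - 1000) + 1e-5 * (ax - 1000)^2
  # Gaussian peak: negligible tails at the anchors, so the fit is exact
  peak <- 50 * exp(-4 * log(2) * (ax - 1000)^2 / 12^2)
  rec <- baseline_recipe("poly-anchors", anchors = default_anchor_points(),
                         degree = 2)
  r <- subtract_baseline(spectrum(ax, bg + peak), rec)
  expect_lt(abs(r$intensities[ax == 1000] - 50) / 50, 1e-6)
  expect_error(
    fit_baseline(spectrum(c(500, 501, 502), c(1, 2, 3)),
                 baseline_recipe("poly-anchors", degree = 3)),
    "too short")
})

test_that("image-wide subtraction shares one recipe over all pixels", {
  ax <- seq(500, 700, by = 2)
  one <- 10 + 0.01 * ax + lorentzian(ax, 600, 10, 20)
  cube <- array(rep(one, each = 6), c(2, 3, length(ax)))
  img <- hyper_image(ax, cube)
  out <- subtract_baseline_image(img, baseline_recipe())
  # uniform input -> uniform output
  expect_equal(out$cube[1, 1, ], out$cube[2, 3, ])
  expect_identical(out$axis, img$axis)
  # 1x1 image reduces to the single-spectrum operation
  img1 <- hyper_image(ax, array(one, c(1, 1, length(ax))))
  out1 <- subtract_baseline_image(img1, baseline_recipe())
  ref <- subtract_baseline(spectrum(ax, one), baseline_recipe())
  expect_equal(out1$cube[1, 1, ], ref$intensities)
})

test_that("pixel errors carry coordinates", {
  img <- hyper_image(c(500, 501, 502), array(1, c(2, 2, 3)))
  rec <- baseline_recipe("poly-anchors", degree = 3)
  expect_error(subtract_baseline_image(img, rec), "pixel \\(1,1\\)")
})

test_that("processing commutes with pixel permutation (shared recipe)", {
  ph <- small_phantom()
  img <- ph$cube
  sl <- hyper_image(img$axis, img$cube[1:4, 1:4, , drop = FALSE])
  rec <- baseline_recipe()
  out <- subtract_baseline_image(sl, rec)
  perm <- c(3, 1, 4, 2)
  slp <- hyper_image(img$axis, sl$cube[perm, , , drop = FALSE])
  outp <- subtract_baseline_image(slp, rec)
  expect_equal(outp$cube, out$cube[perm, , , drop = FALSE])
})

test_that("re-subtracting a subtracted featureless spectrum is ~idempotent", {
  ax <- ax_default()
  s <- spectrum(ax, 40 * exp(-(ax - 400) / 1500))
  r1 <- subtract_baseline(s, baseline_recipe())
  r2 <- subtract_baseline(r1, baseline_recipe())
  # the second pass changes almost nothing, on the scale of the spectrum
  rms <- sqrt(mean(s$intensities^2))
  expect_lt(sqrt(mean((r2$intensities - r1$intensities)^2)), 0.01 * rms)
})

test_that("suggest_recipe minimizes out-of-band residual roughness", {
  set.seed(5)
  ax <- ax_default()
  mk <- function() spectrum(ax, 60 * exp(-(ax - 400) / 1500) +
                              lorentzian(ax, 790, 10, 8) +
                              rnorm(length(ax), sd = 0.5))
  spectra <- replicate(10, mk(), simplify = FALSE)
  expect_error(suggest_recipe(spectra, list()), "empty")
  expect_error(suggest_recipe(spectra[1], list(baseline_recipe())),
               "at least 2")
  # singleton grid returns that candidate
  single <- suggest_recipe(spectra, list(baseline_recipe()))
  expect_equal(single$method, "als")
  # a flat-residual candidate beats one leaving sloped residuals
  good <- baseline_recipe("poly-anchors", anchors = default_anchor_points(),
                          degree = 4)
  bad <- baseline_recipe("poly-anchors", anchors = default_anchor_points(),
                         degree = 0)  # constant cannot follow the decay
  win <- suggest_recipe(spectra, list(bad, good))
  expect_equal(win$method, "poly-anchors")
  expect_equal(win$degree, 4L)
  # duplicated candidates tie and resolve to the first (same recipe, same
  # score as the singleton evaluation)
  a <- baseline_recipe("als", smoothness = 2e5)
  tie <- suggest_recipe(spectra, list(a, a))
  expect_equal(tie$smoothness, 2e5)
  expect_equal(attr(tie, "score"),
               attr(suggest_recipe(spectra, list(a)), "score"))
})
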