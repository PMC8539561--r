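test_that("airy_radius reproduces the stated spot figures", {
  expect_equal(airy_radius(785, 0.5, "full-width"), 1.9154)
  expect_equal(airy_radius(785, 0.5, "first-minimum"), 0.9577)
  # NA doubled halves the radius in either convention
  for (conv in c("first-minimum", "full-width"))
    expect_equal(airy_radius(785, 1.0, conv),
                 airy_radius(785, 0.5, conv) / 2)
  expect_error(airy_radius(785, 0), "aperture")
  expect_error(airy_radius(785, 1.6), "aperture")
  expect_error(airy_radius(-5, 0.5), "positive")
})

test_that("the component library carries the reported peaks", {
  lib <- default_library()
  expect_true(790 %in% lib$DNA$peaks$center)
  expect_true(all(c(750, 760) %in% lib$heme$peaks$center))
  # 790 remains the most intense DNA peak
  expect_equal(lib$DNA$peaks$center[which.max(lib$DNA$peaks$amplitude)], 790)
  # no component intrudes on the 500-520 noise window
  for (cs in lib)
    expect_false(any(cs$peaks$center >= 500 & cs$peaks$center <= 520))
  # evaluation: a single unit Lorentzian peaks at its center
  y <- eval_component(lib$protein, ax_default())
  expect_equal(which.max(y), which(ax_default() == 1000))
})

test_that("compartment profiles encode the stated biology", {
  pr <- compartment_profiles()
  expect_gt(pr$nucleolus["RNA"], pr$nucleus["RNA"])
  expect_equal(names(pr$outside), "substrate")
  expect_true(all(unlist(pr) >= 0))
})

test_that("cell geometry labels respect the priority and scale", {
  g <- cell_geometry(size = 64, seed = 2)
  labs <- g$labels
  expect_setequal(unique(as.vector(labs)),
                  c("outside", "cytoplasm", "membrane", "mitochondria",
                    "nucleus", "nucleolus"))
  # nucleus area ~ pi * 5 * 4.5 um^2 at 1 um pitch
  nuc <- sum(labs %in% c("nucleus", "nucleolus"))
  expect_gt(nuc, 50); expect_lt(nuc, 90)
  # mitochondria sit outside the nucleus, inside the cell
  mi <- which(labs == "mitochondria")
  expect_gt(length(mi), 0)
  ctr <- (64 + 1) / 2
  d <- sqrt((row(labs)[mi] - ctr)^2 + (col(labs)[mi] - ctr)^2)
  expect_true(all(d > 3))          # beyond the nucleolus, perinuclear
  expect_true(all(d < 12))
})

test_that("hotspot masks hit their coverage and stay reproducible", {
  set.seed(5)
  m <- hotspot_mask(64, 0.4)
  expect_equal(mean(m), 0.4, tolerance = 0.02)
  expect_error(hotspot_mask(64, 1.2), "coverage")
})

test_that("phantom generation is bit-exact reproducible per seed", {
  p <- phantom_params(size = 16, coverage = 0.5)
  a <- generate_phantom(p, seed = 9)
  b <- generate_phantom(p, seed = 9)
  expect_identical(a$cube$cube, b$cube$cube)
  expect_identical(a$hotspot, b$hotspot)
  c <- generate_phantom(p, seed = 10)
  expect_false(identical(a$cube$cube, c$cube$cube))
  expect_error(generate_phantom(p), "seed")
})

test_that("zero-noise full-coverage phantom equals the generative identity", {
  p <- phantom_params(size = 24, coverage = 0.99, noise_sd = 0,
                      peak_amplitude = 10, baseline_amplitude = 0,
                      psf_sigma_um = 0)
  ph <- generate_phantom(p, seed = 4)
  ctr <- 12L
  expect_equal(ph$geometry$labels[ctr, ctr], "nucleus")
  expect_true(ph$hotspot[ctr, ctr])
  lib <- p$library
  w <- compartment_profiles()$nucleus
  pred <- rep(0, length(p$axis))
  for (cp in names(w))
    pred <- pred + w[[cp]] * eval_component(lib[[cp]], p$axis) * 10
  expect_equal(ph$cube$cube[ctr, ctr, ], pred, tolerance = 1e-12)
})

test_that("all-zero profile override yields a silent phantom", {
  prof <- lapply(compartment_profiles(), function(w) w * 0)
  p <- phantom_params(size = 16, coverage = 0.5, profiles = prof,
                      baseline_amplitude = 0, noise_sd = 0,
                      peak_amplitude = 10)
  ph <- generate_phantom(p, seed = 2)
  expect_true(all(ph$cube$cube == 0))
})

test_that("an axis missing library peaks is refused", {
  p <- phantom_params(size = 16, axis = seq(400, 900, 1), coverage = 0.5)
  expect_error(generate_phantom(p, seed = 1), "too short")
})

test_that("off-hotspot pixels carry no component signal", {
  ph <- small_phantom()
  sub <- subtract_baseline_image(
    ph$cube, baseline_recipe("poly-anchors",
                             anchors = default_anchor_points(), degree = 5))
  maps <- compute_maps(sub)
  off <- !ph$hotspot
  for (nm in names(maps)) {
    expect_gt(mean(maps[[nm]][off]), 0.85)
    expect_lt(mean(maps[[nm]][off]), 1.15)
  }
})
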