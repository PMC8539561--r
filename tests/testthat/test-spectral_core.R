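test_that("spectral axis invariants are enforced at construction", {
  expect_silent(spectral_axis(c(500, 501, 502.5)))
  expect_error(spectral_axis(500), "at least 2")
  expect_error(spectral_axis(c(500, 400)), "strictly increasing")
  expect_error(spectral_axis(c(500, 500.0)), "strictly increasing")
  expect_error(spectral_axis(c(-1, 5)), "positive")
  expect_error(spectral_axis(c(500, Inf)), "finite")
  # constructors refuse to sort silently
  expect_error(spectrum(c(600, 500), c(1, 2)), "strictly increasing")
  expect_error(hyper_image(c(600, 500), array(0, c(2, 2, 2))),
               "strictly increasing")
})

test_that("spectrum and hyper_image validate their shapes", {
  s <- spectrum(c(500, 501), c(1, 2), meta = list(id = "a"))
  expect_s3_class(s, "spectrum")
  expect_length(s, 2L)
  expect_error(spectrum(c(500, 501), 1), "must match axis")
  expect_error(spectrum(c(500, 501), c(1, NA)), "finite")
  img <- hyper_image(c(500, 501, 502), array(1, c(2, 3, 3)))
  expect_equal(dim(img), c(2L, 3L, 3L))
  expect_error(hyper_image(c(500, 501), array(1, c(2, 2, 3))),
               "does not match axis length")
  expect_error(hyper_image(c(500, 501), array(1, c(2, 2, 2)),
                           pixel_pitch_um = 0), "positive")
  px <- pixel_spectrum(img, 2, 3)
  expect_equal(px$intensities, c(1, 1, 1))
  expect_error(pixel_spectrum(img, 3, 1), "outside image")
})

test_that("two-column spectrum reader parses, reorders and rejects", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# a comment", "500 1.0", "501 2.0"), p)
  s <- read_spectrum(p)
  expect_equal(s$axis, c(500, 501))
  expect_equal(s$intensities, c(1, 2))

  # descending input reorders both columns together
  writeLines(c("900 5", "800 3", "700 1"), p)
  s2 <- read_spectrum(p)
  expect_equal(s2$axis, c(700, 800, 900))
  expect_equal(s2$intensities, c(1, 3, 5))

  writeLines(c("750.0 1", "760 2", "750.0 3"), p)
  expect_error(read_spectrum(p), "750")

  writeLines(c("500 1", "oops nope", "502 2"), p)
  expect_error(read_spectrum(p), "line 2")

  expect_error(read_spectrum(file.path(tempdir(), "missing-xyz.txt")),
               "not found")
})

test_that("long-table spectrum dialect reads", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,intensity", "502,3", "500,1", "501,2"), p)
  s <- read_spectrum(p, dialect = "long-table")
  expect_equal(s$axis, c(500, 501, 502))
  expect_equal(s$intensities, c(1, 2, 3))
})

test_that("cube containers round-trip exactly in both formats", {
  set.seed(4)
  axis <- c(500, 600.25, 700.5)
  cube <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  img <- hyper_image(axis, cube, pixel_pitch_um = 1.5)
  for (fmt in c("matrix", "long")) {
    p <- withr::local_tempfile(fileext = ".txt")
    write_cube(img, p, format = fmt)
    back <- read_cube(p)
    expect_identical(back$cube, img$cube)
    expect_identical(back$axis, img$axis)
    expect_identical(back$pixel_pitch_um, img$pixel_pitch_um)
  }
  # integer-valued data stay bit-exact
  img2 <- hyper_image(axis, array(as.numeric(1:12), c(2, 2, 3)))
  p2 <- withr::local_tempfile()
  write_cube(img2, p2)
  expect_identical(read_cube(p2)$cube, img2$cube)
})

test_that("cube reader rejects malformed containers", {
  p <- withr::local_tempfile()
  writeLines(c("# sersmap-cube v1", "# dim: 1 1 3",
               "# pixel_pitch_um: 1", "# axis: 500 501",
               "1 1 1 2 3"), p)
  expect_error(read_cube(p), "axis length")
  writeLines("just text", p)
  expect_error(read_cube(p), "not a sersmap cube")
})

test_that("a phantom-authored cube survives the container", {
  ph <- small_phantom()
  sub <- ph$cube
  tiny <- hyper_image(sub$axis[1:3],
                      sub$cube[1:2, 1:2, 1:3, drop = FALSE],
                      sub$pixel_pitch_um)
  p <- withr::local_tempfile()
  write_cube(tiny, p)
  back <- read_cube(p)
  expect_equal(dim(back), c(2L, 2L, 3L))
  expect_identical(back$cube, tiny$cube)
})

test_that("default registry carries the frozen study windows", {
  reg <- default_registry()
  ib <- reg$imaging_bands
  expect_equal(c(ib$DNA$lo, ib$DNA$hi), c(655, 680))
  expect_equal(c(ib$heme$lo, ib$heme$hi), c(740, 765))
  expect_equal(c(ib$RNA$lo, ib$RNA$hi), c(825, 835))
  expect_equal(c(ib$protein$lo, ib$protein$hi), c(995, 1010))
  expect_equal(c(ib$noise$lo, ib$noise$hi), c(500, 520))
  expect_equal(ib$DNA$channel, "red")
  expect_equal(ib$RNA$channel, "green")
  expect_equal(ib$heme$channel, "blue")
  expect_equal(ib$noise$molecule_class, "noise")
  ab <- reg$assignment_bands
  expect_equal(c(ab$DNA_660_690$lo, ab$DNA_660_690$hi), c(660, 690))
  expect_equal(c(ab$DNA_790_805$lo, ab$DNA_790_805$hi), c(790, 805))
  expect_equal(c(ab$DNA_1300_1350$lo, ab$DNA_1300_1350$hi), c(1300, 1350))
  expect_equal(c(ab$RNA_805_850$lo, ab$RNA_805_850$hi), c(805, 850))
  expect_equal(c(ab$heme_730_765$lo, ab$heme_730_765$hi), c(730, 765))
  expect_equal(c(ab$lipid_1430_1470$lo, ab$lipid_1430_1470$hi), c(1430, 1470))
})

test_that("registries validate and serialize", {
  expect_error(band("x", 700, 650), "lo < hi")
  expect_error(band_registry(list(band("a", 1, 2, "DNA"))),
               "exactly one noise band")
  expect_error(
    band_registry(list(band("a", 1, 2, "noise"), band("a", 3, 4, "DNA"))),
    "duplicate")
  reg <- default_registry()
  p <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, p)
  back <- read_registry(p)
  expect_equal(back, reg)
})
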