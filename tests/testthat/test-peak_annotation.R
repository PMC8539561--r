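test_that("the built-in table answers the canonical lookups", {
  tab <- assignment_table()
  hit790 <- assign_peak(790, tab)
  expect_true(any(hit790$molecule == "DNA" & grepl("cytosine", hit790$note)))
  hit750 <- assign_peak(750, tab, tolerance = 3)
  expect_true(any(grepl("heme C", hit750$note)))
  hit760 <- assign_peak(760, tab, tolerance = 3)
  expect_true(any(grepl("heme B", hit760$note)))
  hit720 <- assign_peak(720, tab)
  expect_setequal(intersect(hit720$molecule, c("DNA", "lipid")),
                  c("DNA", "lipid"))   # ambiguity preserved, not collapsed
  expect_equal(nrow(assign_peak(9999, tab)), 0L)
  # results sorted by |delta|, stably
  expect_true(!is.unsorted(assign_peak(748, tab)$delta))
})

test_that("every table entry round-trips through its own center", {
  tab <- assignment_table()
  for (i in seq_len(nrow(tab))) {
    pos <- if (!is.na(tab$center[i])) tab$center[i]
           else (tab$lo[i] + tab$hi[i]) / 2
    hits <- assign_peak(pos, tab)
    expect_true(any(hits$molecule == tab$molecule[i] &
                      hits$note == tab$note[i]),
                info = paste("entry", i, tab$note[i]))
  }
})

test_that("the table serializes to JSON and back", {
  tab <- assignment_table()
  p <- withr::local_tempfile(fileext = ".json")
  write_assignment_table(tab, p)
  back <- read_assignment_table(p)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("peak detection finds injected peaks and honors thresholds", {
  ax <- ax_default()
  s <- spectrum(ax, lorentzian(ax, 790, 10, 50))
  pk <- detect_peaks(s, min_prominence = 5)
  expect_equal(nrow(pk), 1L)
  expect_lte(abs(pk$position - 790), 1)
  expect_gt(pk$prominence, 0)
  # flat spectrum: nothing
  expect_equal(nrow(detect_peaks(spectrum(ax, rep(3, length(ax))),
                                 min_prominence = 1)), 0L)
  # two peaks 3 apart with separation 10: only the taller survives
  s2 <- spectrum(ax, lorentzian(ax, 800, 6, 40) + lorentzian(ax, 803, 6, 30))
  pk2 <- detect_peaks(s2, min_prominence = 1, min_separation = 10)
  expect_equal(nrow(pk2), 1L)
  expect_lte(abs(pk2$position - 800), 1)
  expect_error(detect_peaks(s, min_prominence = 0), "positive")
  expect_error(detect_peaks(s, min_prominence = 1, min_separation = -1),
               "positive")
  # determinism and position ordering on a multi-peak spectrum
  s3 <- spectrum(ax, lorentzian(ax, 700, 8, 30) + lorentzian(ax, 1400, 8, 60))
  pk3 <- detect_peaks(s3, min_prominence = 5)
  expect_equal(pk3, detect_peaks(s3, min_prominence = 5))
  expect_true(!is.unsorted(pk3$position))
})

test_that("annotation joins detections with table hits", {
  ax <- ax_default()
  s <- spectrum(ax, lorentzian(ax, 790, 10, 50) + lorentzian(ax, 750, 8, 30))
  ann <- annotate_spectrum(s, min_prominence = 5)
  expect_true(any(ann$molecule == "DNA" & abs(ann$position - 790) <= 1))
  expect_true(any(grepl("heme C", ann$note) & abs(ann$position - 750) <= 1))
})

test_that("the 720 adenine/phospholipid rule follows the spectral context", {
  ax <- ax_default()
  p720 <- lorentzian(ax, 720, 10, 40)
  p1445 <- lorentzian(ax, 1445, 10, 40)
  p1078 <- lorentzian(ax, 1078, 10, 30)
  p790 <- lorentzian(ax, 790, 10, 40)
  # 720 alone: no 1445, so adenine
  expect_equal(disambiguate_adenine_lipid(spectrum(ax, p720),
                                          min_prominence = 5), "adenine")
  # 720 + 1445 + another lipid line, no DNA bands: phospholipid
  expect_equal(disambiguate_adenine_lipid(spectrum(ax, p720 + p1445 + p1078),
                                          min_prominence = 5),
               "phospholipid")
  # both lines of evidence: ambiguous
  expect_equal(disambiguate_adenine_lipid(spectrum(ax, p720 + p1445 + p790),
                                          min_prominence = 5), "ambiguous")
  # no 720 peak at all: error
  expect_error(disambiguate_adenine_lipid(spectrum(ax, p790),
                                          min_prominence = 5), "720")
})
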