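#!/usr/bin/env Rscript
# Stage 5: read the mean on-aggregate spectrum like a spectroscopist.
# Detect peaks in the baseline-subtracted average and look each one up
# in the built-in wavenumber -> biomolecule table (ambiguities kept);
# apply the contextual 720 cm^-1 adenine/phospholipid rule.

suppressPackageStartupMessages(library(sersmap))

cfg <- load_config("results/config.json")
sub <- read_cube("scratch/subtracted_cube.txt")
ph <- generate_phantom(cfg$phantom, cfg$seed)

d <- dim(sub)
acc <- rep(0, d[3])
n <- 0L
for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
  if (ph$hotspot[i, j] && ph$geometry$labels[i, j] != "outside") {
    acc <- acc + sub$cube[i, j, ]
    n <- n + 1L
  }
}
mspec <- spectrum(sub$axis, acc / n)
write_spectrum(mspec, "results/05_mean_cell_spectrum.txt")

thr <- 5 * band_rms(mspec, band("noise", 500, 520, "noise"))
ann <- annotate_spectrum(mspec, min_prominence = thr)
utils::write.csv(ann, "results/05_annotation.csv", row.names = FALSE)

cat("mean on-cell spectrum over", n, "aggregate pixels;",
    length(unique(ann$position)), "peaks above 5x noise RMS\n")
hits <- ann[!is.na(ann$molecule), ]
for (p in unique(hits$position)) {
  e <- hits[hits$position == p, ]
  cat(sprintf("  %6.0f cm-1 -> %s\n", p,
              paste(unique(paste0(e$molecule, " (", e$note, ")")),
                    collapse = " | ")))
}
if (any(abs(ann$position - 720) <= 5)) {
  call720 <- disambiguate_adenine_lipid(mspec, min_prominence = thr)
  cat("720 cm-1 context rule:", call720, "\n")
}
cat("wrote results/05_annotation.csv, results/05_mean_cell_spectrum.txt\n")
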