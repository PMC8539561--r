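#!/usr/bin/env Rscript
# Stage 6: the AFM layer-thickness procedure on a simulated scratch.
# A 6 nm polymer film (the PVPyr adhesion-layer scale) is scratched to
# the substrate; the height map gets an instrument tilt and roughness
# noise. Flatten the background (fit on unscratched pixels), histogram
# the heights around the scratch, and read the thickness as the
# separation of the two histogram peaks.

suppressPackageStartupMessages(library(sersmap))

set.seed(1)
t_true <- 6       # nm, film thickness
sigma <- 0.3      # nm, surface roughness + instrument noise
n <- 128

z <- matrix(t_true, n, n)
scratch <- matrix(FALSE, n, n)
scratch[, 40:66] <- TRUE                       # a scratch stripe
z[scratch] <- 0
z <- z + 0.01 * row(z) - 0.004 * col(z) + 2    # tilt + offset
z <- z + matrix(rnorm(n * n, sd = sigma), n, n)

h <- height_map(z, pixel_pitch_nm = 20, scratch_mask = scratch)
flat <- flatten(h, degree = 1)
res <- thickness_from_histogram(flat, bin_width = 0.1)

cat(sprintf("true thickness %.2f nm | measured %.3f nm (peaks at %.3f and %.3f nm)\n",
            t_true, res$thickness, res$peaks[1], res$peaks[2]))
cat(sprintf("error %.3f nm (%.1f%% of true)\n",
            abs(res$thickness - t_true),
            100 * abs(res$thickness - t_true) / t_true))

hist_df <- data.frame(height_nm = res$histogram$mids,
                      count = res$histogram$counts)
utils::write.csv(hist_df, "results/06_height_histogram.csv",
                 row.names = FALSE)
jsonlite::write_json(list(true_nm = t_true, measured_nm = res$thickness,
                          peaks_nm = res$peaks,
                          bin_width_nm = res$bin_width),
                     "results/06_afm_thickness.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/06_afm_thickness.json, results/06_height_histogram.csv\n")
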