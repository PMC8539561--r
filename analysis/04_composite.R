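#!/usr/bin/env Rscript
# Stage 4: render the maps. Each map becomes an 8-bit grayscale image on
# the shared 0-60 normalized-RMS display range, and DNA (red), RNA
# (green) and heme (blue) merge into one RGB composite, so compartments
# show as colors: nucleus red-dominant, perinuclear mitochondria blue,
# nucleolus/cytoplasm green.

suppressPackageStartupMessages(library(sersmap))

cfg <- load_config("results/config.json")
read_map <- function(nm) {
  v <- as.matrix(utils::read.csv(sprintf("results/03_map_%s.csv", nm),
                                 header = FALSE))
  b <- cfg$registry$imaging_bands[[nm]]
  structure(unname(v), class = c("band_stat_map", "matrix", "array"),
            band = b, normalized = TRUE)
}

for (nm in c("DNA", "heme", "RNA", "protein")) {
  g <- to_gray(read_map(nm), cfg$display)
  write_pgm(g, sprintf("results/04_map_%s.pgm", nm))
}
rgb <- merge_rgb(rgb_composite(read_map("DNA"), read_map("RNA"),
                               read_map("heme"), range = cfg$display))
write_ppm(rgb, "results/04_composite_rgb.ppm")

dom <- apply(rgb, c(1, 2), which.max)
lit <- apply(rgb, c(1, 2), max) > 13   # > ~5% of the display range
cat(sprintf("composite: %d of %d pixels above 5%% of the 0-%g scale\n",
            sum(lit), length(lit), cfg$display$hi))
cat(sprintf("dominant channel among lit pixels: red %d, green %d, blue %d\n",
            sum(dom == 1 & lit), sum(dom == 2 & lit), sum(dom == 3 & lit)))
cat("wrote results/04_map_*.pgm, results/04_composite_rgb.ppm\n")
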