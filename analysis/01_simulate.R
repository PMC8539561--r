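#!/usr/bin/env Rscript
# Stage 1: state the simulated experiment and generate the phantom.
#
# A 64 x 64 pixel map at 1 um pitch of a ~20 um cell with a ~10 um
# central nucleus sitting on a nanostar-aggregate footprint; molecule-
# specific peaks appear only over the aggregate (short-range SERS
# enhancement), on a fluorescence-like baseline with detector noise.
# The full cube goes to scratch/ (it is large); the experiment config
# and ground-truth summaries go to results/.

suppressPackageStartupMessages(library(sersmap))

seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- pipeline_config(seed = seed)
save_config(cfg, "results/config.json")

ph <- generate_phantom(cfg$phantom, seed)
write_cube(ph$cube, "scratch/phantom_cube.txt")

labs <- table(ph$geometry$labels)
cat("phantom: seed", seed, sprintf("| aggregate coverage %.1f%%", 100 * ph$coverage), "\n")
cat("compartment pixel counts:\n")
print(labs)
cat("nucleus pixels on the aggregate:",
    sum(compartment_mask(ph, "nucleus")), "of",
    sum(ph$geometry$labels == "nucleus"), "\n")

truth <- list(
  seed = seed,
  coverage = ph$coverage,
  compartment_pixels = as.list(labs),
  nucleus_on_hotspot = sum(compartment_mask(ph, "nucleus")),
  mitochondria_on_hotspot = sum(compartment_mask(ph, "mitochondria"))
)
jsonlite::write_json(truth, "results/01_truth.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

# the hotspot footprint as a small viewable raster
write_pgm(structure(ph$hotspot * 255L, class = "gray_image"),
          "results/01_hotspot.pgm")
cat("wrote scratch/phantom_cube.txt, results/config.json, results/01_truth.json\n")
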