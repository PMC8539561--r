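# sersmap

Label-free molecular mapping of living cells from hyperspectral SERS
images, for spectroscopists working with planar plasmonic substrates
(gold nanostar aggregates on a polymer-coated coverslip). Cells adhere
to the substrate, nanostar tips penetrate the membrane, and Raman
signal is enhanced only where the cell sits on an aggregate; scanning
at 1 µm steps gives a cube of per-pixel spectra from which maps of
DNA, RNA, proteins and mitochondrial hemes are computed.

The core statistic: after subtracting one shared baseline recipe from
every pixel, the score of band $[\nu_1,\nu_2]$ at a pixel is

$$S = \frac{\mathrm{RMS}\,I(\nu),\ \nu\in[\nu_1,\nu_2]}
           {\mathrm{RMS}\,I(\nu),\ \nu\in[500,520]\ \mathrm{cm^{-1}}},$$

the in-band root-mean-square of the residual intensities normalized by
the RMS of the peak-free 500–520 cm⁻¹ noise window. $S \approx 1$ means
no signal; maps for DNA (655–680), heme (740–765), RNA (825–835) and
protein (995–1010 cm⁻¹) are rendered on a shared 0–60 range and merged
RGB (DNA red, RNA green, heme blue). The package also implements peak
detection with a wavenumber→biomolecule assignment table, the AFM
scratch-thickness procedure (flatten, height histogram, peak
separation), and a ground-truthed synthetic phantom generator so the
whole pipeline is testable without instrument data.

## Worked example

The numbered scripts under `analysis/` run the full study on a
simulated cell (seed 1); each writes its tables under `results/` and
prints what it found. Running them in order:

```sh
Rscript analysis/01_simulate.R   # phantom: 64x64 cell, aggregate coverage 28.1%
Rscript analysis/02_baseline.R   # selects recipe: poly-anchors (degree 3, 25 anchors)
Rscript analysis/03_maps.R       # band-RMS maps + recovery vs ground truth
Rscript analysis/04_composite.R  # grayscale PGMs + merged RGB composite
Rscript analysis/05_annotate.R   # peak annotation of the mean on-cell spectrum
Rscript analysis/06_afm.R        # scratch-thickness on a simulated 6 nm film
```

Key lines printed by stages 2, 3 and 6:

```
selected recipe: poly-anchors (degree 3, 25 anchors) | out-of-band residual RMS 1.087
mean per-pixel noise-window RMS after subtraction: 1.032 counts

DNA      mean score on-aggregate 1.32 | off-aggregate 1.05
protein  mean score on-aggregate 2.19 | off-aggregate 1.04
recovery: DNA map ~ nucleus r = 0.872 | heme map ~ mitochondria r = 0.828

true thickness 6.00 nm | measured 6.075 nm (peaks at -6.016 and 0.059 nm)
```

Reading: the recipe chosen on 12 sample spectra leaves residuals at the
detector-noise level (RMS ≈ 1 count, the simulated noise sigma);
off-aggregate pixels score ≈ 1 in every band (no signal without
nanostructures, the hotspot-exclusivity check); the normalized DNA map
correlates 0.87 with the true nucleus-on-aggregate mask and the heme
map 0.83 with the mitochondria; and the height-histogram procedure
recovers a 6 nm film to ~1 %.

Equivalent one-call form:

```r
library(sersmap)
bundle <- run_pipeline(pipeline_config(seed = 1), outdir = "results/run")
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end computation
from scratch — seeded phantom, recipe selection, baseline subtraction,
normalized band-RMS maps, RGB composite — and writes the results
manifest:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The seed controls every source of randomness; the run log (stderr)
reports the realized aggregate coverage and the map-vs-truth recovery
correlations.

## Layout

- `R/` — spectral containers and I/O, baseline recipes, band
  statistics, composites, peak annotation, AFM thickness, phantom
  generator, pipeline driver
- `src/` — ALS baseline solver (Rcpp)
- `analysis/` — the numbered study scripts above
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/sers-cell-mapping.Rmd` — the model, its assumptions,
  parameter defaults and numerical choices
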