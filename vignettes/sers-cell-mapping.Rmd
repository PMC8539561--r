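---
title: "Band-RMS molecular mapping of living cells on nanostar SERS substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-RMS molecular mapping of living cells on nanostar SERS substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersmap)
```

## The measurement and the statistic

Living cells adhered to a planar SERS substrate — gold nanostar
aggregates anchored in a thin poly(4-vinyl pyridine) layer on glass —
are raster-scanned with a 785 nm laser at 1 µm steps. The sharp
nanostar tips (~37 nm long, against a ~10 nm plasma membrane) penetrate
the cell, so Raman signal is enhanced only within 1–2 nm of a tip:
a pixel carries molecular signal only where the cell sits on an
aggregate ("hotspot"), and pixels off the aggregate contain nothing but
fluorescence background and detector noise.

Each pixel holds a full spectrum $I(\nu)$ on a shared wavenumber axis.
After baseline subtraction, the per-pixel molecular score for a band
$[\nu_1,\nu_2]$ is the root-mean-square of the residual intensities
over the axis samples in the band,

$$\mathrm{RMS}_{[\nu_1,\nu_2]} =
  \sqrt{\tfrac1n \sum_{\nu_k \in [\nu_1,\nu_2]} I(\nu_k)^2},$$

normalized by the same statistic over the peak-free 500–520 cm⁻¹ noise
window:

$$S = \frac{\mathrm{RMS}_{[\nu_1,\nu_2]}}{\mathrm{RMS}_{[500,520]}}.$$

$S \approx 1$ for a pixel with no in-band signal, is invariant under
rescaling the spectrum, and grows with in-band signal-to-noise. The
imaging windows are DNA 655–680, heme 740–765, RNA 825–835 and protein
995–1010 cm⁻¹; maps are rendered on a shared 0–60 display range and
merged as DNA→red, RNA→green, heme→blue.

Broader *assignment* windows (DNA 660–690, 790–805, 1300–1350; RNA
805–850, 1510; heme 730–765; lipid 700–730, 1300–1330, 1430–1470;
protein 1000–1010, 1360–1370 cm⁻¹) are kept in a separate registry for
spectral interpretation; the two sets deliberately differ (e.g. DNA
655–680 vs 660–690) and are never reconciled.

## Baseline subtraction: one recipe per image

The background under cellular SERS spectra at 785 nm is a strong,
smooth fluorescence tail. The package follows the practice of choosing
*one* baseline recipe after inspecting 10–15 spectra of an image and
applying it to every pixel — no per-pixel adaptation, so processing
commutes with pixel permutation.

Two recipe families are implemented:

* **Asymmetric least squares** (default: smoothness $\lambda = 10^5$,
  asymmetry $p = 0.01$, 10 iterations), solved with an $O(n)$
  pentadiagonal LDLᵀ factorization in C++. ALS hugs the *lower
  envelope* of the spectrum: with $p = 0.01$ the converged baseline
  sits near the lower noise quantile, leaving residuals offset by about
  $+1.6\sigma$. Both the band and the noise window inherit the offset,
  so pure-noise pixels still normalize to $S \approx 1$, but at modest
  SNR the offset compresses map contrast (both RMS values grow in
  quadrature with the offset).
* **Anchored polynomial** (degree 0–5 through anchor wavenumbers), the
  classic interactive-tool recipe. The default anchors are 25 peak-free
  positions chosen in the gaps between the built-in assignment table's
  entries. Fitted by least squares through the spectrum at the anchors,
  it leaves zero-mean residuals (no envelope offset) wherever the true
  background is smooth.

`suggest_recipe()` scores each candidate by the mean residual RMS at
axis samples *outside* every registry band — outside known bands a good
baseline leaves flat, near-zero residuals — and returns the candidate
with the smallest score (ties go to the first in grid order). The
selection criterion is this package's concrete surrogate for a choice
that is made by eye in practice. On phantom data the criterion
reliably prefers the anchored polynomial over stock ALS, precisely
because of the ALS envelope offset; both remain available, and the
pipeline records which recipe was applied.

Negative residuals are kept (clipping would bias the RMS statistic
upward at zero signal).

## The synthetic phantom: a stated world

No raw imaging data are publicly deposited, so the package ships a
generator whose defaults state the emulated experiment:

* **Geometry.** 64 × 64 pixels at 1 µm pitch; an elliptical cell of
  20 µm major diameter (minor axis 0.9×) with a centered 10 µm nucleus,
  a 3 µm nucleolar disc offset inside it, ten 2 µm mitochondrial discs
  in a perinuclear annulus, and a 1-pixel membrane rim. Label priority:
  nucleolus > nucleus > mitochondria > membrane > cytoplasm > outside.
* **Component spectra.** Lorentzian peaks of 10 cm⁻¹ FWHM at the
  wavenumbers reported for each molecule class (DNA 670, 692, 720, 790,
  802, 1330 — 790 the most intense; RNA 775, 812, 822, 833, 1510;
  hemes 746, 750, 754, 760, 1206; protein 1000, 1180, 1365; lipid
  1078, 1270, 1445; carbohydrate 912, 1120; substrate 1010, 1065,
  1203). No peak lies in 500–520 cm⁻¹, by construction. Amplitudes are
  normalized so each mapped component's strongest peak *inside its
  imaging window* is 1: this makes the SNR statement below exact.
* **Composition.** Per-compartment weights: nucleus DNA-led (DNA 1.0,
  RNA 0.3, protein 0.6), nucleolus RNA-enriched above the surrounding
  nucleus (RNA 1.2), mitochondria heme 1.0 (hemes receive no
  amplification beyond the SNR floor — 785 nm is not resonant for
  them, so their maps stay far below the DNA/RNA range on the 0–60
  scale), membrane lipid-led, cytoplasm mixed, outside-cell substrate
  only. The nucleus RNA weight 0.3 keeps the rendered nucleus
  red-dominant, the qualitative picture the composites are meant to
  reproduce; 0.5 would tip the narrow RNA window (three stacked peaks)
  above DNA.
* **Hotspot.** One contiguous aggregate footprint: smoothed Gaussian
  noise (correlation length 6 px) plus a centered bias (3 sd, 12 px
  scale), thresholded at a coverage drawn uniformly from the observed
  13–70 % range. The central bias encodes the imaging protocol — scan
  regions are chosen *around* an aggregate, so the footprint overlaps
  the cell. Enhancement is a binary gate: a pixel's compartment
  contributes only on the footprint. (A continuous 1–2 nm distance
  decay is not modeled; the reported tip statistics are insufficient
  for a 3-D decay, and tip-penetration probability is folded into the
  compartment weights.)
* **Optics.** Abundance maps (not spectra) are blurred with a Gaussian
  PSF. The default sigma is 0.344 × the 1.22 λ/NA Airy figure at
  785 nm / 0.5 NA (1.9154 µm), i.e. ≈ 0.66 µm — 0.344 being the
  standard best-fit-Gaussian-to-Airy ratio.
* **Signal scale and noise.** In-band peak amplitude = 10 × the noise
  sigma (`peak_snr = 10`, `noise_sd = 1`); additive Gaussian detector
  noise, with an optional shot-noise-like variance scaling; a
  fluorescence-like baseline `exp(-(ν - 400)/1500)` scaled by ~50
  counts, stronger over the cell body. The gentle 1500 cm⁻¹ decay
  states a realistic 785 nm autofluorescence tail (a much steeper tail
  would defeat any fixed smooth-baseline recipe near the axis edge and
  is not what cell backgrounds look like).
* **Determinism.** `generate_phantom(params, seed)` is bit-exact
  reproducible; the seed is a mandatory argument.

What a green recovery test establishes: that the pipeline's statistic
separates compartments at 10σ in-band SNR under hotspot gating, optical
blur and a realistic baseline. What it does not establish: performance
on real detector artifacts (cosmic rays, drift), non-Gaussian hotspot
morphology, 3-D sectioning effects, or molecule cross-sections — the
phantom has no opinion on absolute SERS enhancement factors.

Seed-to-seed variation is real: with the default coverage draw, the
DNA-map/nucleus correlation sits around 0.80–0.88; unfavorable
low-coverage draws can graze the 0.8 criterion.

## Numerical choices

* Band membership is the closed interval `lo ≤ ν ≤ hi` on native axis
  samples; no resampling, and unequal sample counts between band and
  noise window are accepted (RMS is a per-sample mean).
* A zero noise-window RMS yields a *missing* map value, rendered as 0
  with a zero alpha mask; nothing is interpolated.
* Grayscale rendering is linear with clipping and half-up rounding;
  the only stated display convention is the shared 0–60 range.
* The ALS solver's pentadiagonal system is assembled once per spectrum;
  the weights iteration runs a fixed 10 rounds (no convergence test, so
  results are deterministic).
* The AFM height histogram anchors its bin grid at the data minimum
  (making the thickness exactly translation invariant), merges
  neighboring modes whose connecting valley is shallower than the
  3σ counting noise (shot noise cannot fake bimodality), requires modes
  to beat both a 5 %-of-tallest-bin floor and the 3σ counting floor,
  and refines the two surviving mode centers by a parabola on log
  counts (exact for Gaussian modes) with a plain-parabola fallback for
  spike histograms. Background flattening fits the polynomial surface
  on unscratched pixels only when a scratch mask is given — a scratch
  aligned with the scan direction would otherwise tilt the fit and bias
  the step.
* Peak detection uses strict local maxima with topographic prominence;
  edge samples use the one-sided base. Peaks closer than the minimum
  separation are thinned tallest-first (ties leftmost).
* The 720 cm⁻¹ rule is explicit and separate from the lookup table:
  adenine when no 1445 cm⁻¹ peak is detected; phospholipid when 1445 is
  present without co-occurring DNA-band peaks; ambiguous otherwise.

## Open choices made here

* The acquisition axis (400–1800 cm⁻¹ at 1 cm⁻¹) is a stated default —
  the source figures span roughly 600–1600 cm⁻¹ and no sampling step is
  reported.
* The appendix-level full assignment table is not available; the
  shipped table is the in-text subset, marked extensible (`rbind` rows
  with the same columns).
* The cube container is a plain-text format (header + one row per
  pixel) with a long-table CSV fallback, and rendered images are ASCII
  PGM/PPM — no binary dependencies, exact round-trips.
* `run_pipeline()` performs recipe selection by default
  (`select_from = default_recipe_grid()`); pass `select_from = NULL`
  to force the configured recipe.

## Known limitations

Cosmic-ray despiking, wavenumber calibration, proprietary instrument
formats, peak fitting/unmixing (MCR, NMF), and 3-D confocal phantoms
are out of scope. The recovery correlations compare a *blurred,
noise-normalized* map against a *binary* compartment indicator, which
caps attainable correlation below 1 even for a perfect pipeline.
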