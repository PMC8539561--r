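# The per-pixel molecular score: RMS of baseline-subtracted intensities
# over a wavenumber window, normalized by the RMS of the peak-free noise
# window (500-520 cm^-1). Bands are evaluated on native axis samples;
# unequal sample counts between band and noise window are fine because
# RMS is a per-sample mean.

.band_samples <- function(s, b) {
  stopifnot(inherits(s, "spectrum"), inherits(b, "band"))
  idx <- which(s$axis >= b$lo & s$axis <= b$hi)
  if (length(idx) == 0L)
    stop("band '", b$name, "' [", b$lo, ", ", b$hi,
         "] contains no axis samples (axis spans ",
         min(s$axis), "-", max(s$axis), " cm^-1)")
  idx
}

#' Band RMS of a spectrum
#'
#' Root-mean-square of the (baseline-subtracted) intensities at the axis
#' samples falling inside the closed band window.
#'
#' @param s a [spectrum()], already baseline-subtracted.
#' @param b a [band()] containing at least one axis sample.
#' @return non-negative scalar.
#' @export
band_rms <- function(s, b) {
  idx <- .band_samples(s, b)
  sqrt(mean(s$intensities[idx]^2))
}

#' Noise-normalized band RMS
#'
#' `band_rms(s, b) / band_rms(s, noise)`. Invariant under positive
#' rescaling of the spectrum. When the noise RMS is exactly zero the
#' result is `NA` (missing), not an error, so degenerate pixels propagate
#' as missing map values.
#'
#' @param s a [spectrum()], baseline-subtracted.
#' @param b signal [band()].
#' @param noise the peak-free noise [band()] (500-520 cm^-1 by default
#'   registry).
#' @return non-negative scalar, or `NA` when the noise RMS is zero.
#' @export
normalized_band_rms <- function(s, b, noise) {
  num <- band_rms(s, b)
  den <- band_rms(s, noise)
  if (den == 0) return(NA_real_)
  num / den
}

#' Per-pixel normalized band-RMS map
#'
#' Evaluates [normalized_band_rms()] at every pixel of a
#' baseline-subtracted image. The band, noise band and (optionally) the
#' upstream baseline recipe are recorded in the map's metadata.
#'
#' @param img a baseline-subtracted [hyper_image()].
#' @param b signal [band()].
#' @param noise noise [band()].
#' @param recipe optional [baseline_recipe()] used upstream, stored as
#'   provenance.
#' @param normalized set `FALSE` for raw band RMS (sensitivity analysis);
#'   default `TRUE`.
#' @return a `"band_stat_map"`: H x W numeric matrix with attributes
#'   `band`, `noise_band`, `normalized`, `recipe`.
#' @export
compute_map <- function(img, b, noise, recipe = NULL, normalized = TRUE) {
  stopifnot(inherits(img, "hyper_image"), inherits(b, "band"))
  if (normalized && !inherits(noise, "band"))
    stop("normalized maps need a noise band")
  d <- dim(img$cube)
  # resolve sample indices once on the shared axis
  probe <- spectrum(img$axis, rep(0, length(img$axis)))
  bi <- tryCatch(.band_samples(probe, b), error = function(e)
    stop("compute_map: ", conditionMessage(e), call. = FALSE))
  ni <- if (normalized) tryCatch(.band_samples(probe, noise),
                                 error = function(e)
    stop("compute_map: ", conditionMessage(e), call. = FALSE)) else NULL
  vals <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      y <- img$cube[i, j, ]
      num <- sqrt(mean(y[bi]^2))
      if (normalized) {
        den <- sqrt(mean(y[ni]^2))
        vals[i, j] <- if (den == 0) NA_real_ else num / den
      } else {
        vals[i, j] <- num
      }
    }
  }
  structure(vals, class = c("band_stat_map", "matrix", "array"),
            band = b, noise_band = if (normalized) noise else NULL,
            normalized = normalized, recipe = recipe,
            pixel_pitch_um = img$pixel_pitch_um)
}

#' @export
print.band_stat_map <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<band_stat_map> %s [%g, %g] cm^-1, %d x %d px, %s%s\n",
              b$name, b$lo, b$hi, nrow(x), ncol(x),
              if (attr(x, "normalized")) "noise-normalized" else "raw RMS",
              if (anyNA(x)) sprintf(", %d missing", sum(is.na(x))) else ""))
  invisible(x)
}

#' Maps for every non-noise imaging band of a registry
#'
#' @param img a baseline-subtracted [hyper_image()].
#' @param registry a [band_registry()]; its unique noise band is the
#'   normalization denominator.
#' @param recipe optional provenance, as in [compute_map()].
#' @return named list of `"band_stat_map"` objects.
#' @export
compute_maps <- function(img, registry = default_registry(), recipe = NULL) {
  stopifnot(inherits(registry, "band_registry"))
  isn <- vapply(registry$imaging_bands, function(b)
    b$molecule_class == "noise", logical(1))
  noise <- registry$imaging_bands[[which(isn)]]
  sig <- registry$imaging_bands[!isn]
  lapply(sig, compute_map, img = img, noise = noise, recipe = recipe)
}

#' Export a map as a CSV grid
#'
#' One row per image row, missing values empty.
#'
#' @param m a `"band_stat_map"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(m, path) {
  stopifnot(inherits(m, "band_stat_map"))
  utils::write.table(unclass(m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}
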