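# Baseline subtraction: one fixed recipe applied to every spectrum of an
# image, mirroring how mapping data are processed in practice (a recipe is
# chosen on a handful of spectra, then applied image-wide).

#' Define a baseline recipe
#'
#' Two methods are supported. `"als"` is asymmetric least squares
#' (Eilers-style): a smooth curve penalized by `smoothness` (lambda) with
#' asymmetric weights `asymmetry` (p) so the fit hugs the lower envelope
#' of the spectrum, the standard remover for fluorescence backgrounds in
#' 785 nm cell SERS. `"poly-anchors"` fits a polynomial of `degree`
#' through the spectrum at chosen anchor wavenumbers (all samples when
#' `anchors` is NULL), the anchor-based recipe familiar from interactive
#' spectroscopy tools.
#'
#' @param method `"als"` or `"poly-anchors"`.
#' @param smoothness ALS lambda (> 0); larger gives stiffer baselines.
#'   Default 1e5 suits ~1 cm^-1 sampling with broad fluorescence.
#' @param asymmetry ALS p in (0,1); fraction of weight given to points
#'   above the baseline. Default 0.01.
#' @param iterations reweighting iterations (>= 1), default 10.
#' @param anchors polynomial mode: wavenumbers the fit passes near.
#' @param degree polynomial mode: degree >= 0, default 3.
#' @return an object of class `"baseline_recipe"`.
#' @export
baseline_recipe <- function(method = c("als", "poly-anchors"),
                            smoothness = 1e5, asymmetry = 0.01,
                            iterations = 10L, anchors = NULL, degree = 3L) {
  method <- match.arg(method)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (method == "als") {
    if (!is.numeric(smoothness) || smoothness <= 0)
      stop("ALS smoothness (lambda) must be positive")
    if (!is.numeric(asymmetry) || asymmetry <= 0 || asymmetry >= 1)
      stop("ALS asymmetry (p) must lie in (0, 1)")
  } else {
    degree <- as.integer(degree)
    if (degree < 0L) stop("polynomial degree must be >= 0")
    if (!is.null(anchors)) anchors <- sort(as.numeric(anchors))
  }
  structure(list(method = method, smoothness = smoothness,
                 asymmetry = asymmetry, iterations = iterations,
                 anchors = anchors, degree = degree),
            class = "baseline_recipe")
}

#' @export
print.baseline_recipe <- function(x, ...) {
  if (x$method == "als")
    cat(sprintf("<baseline_recipe> ALS: lambda=%g, p=%g, %d iterations\n",
                x$smoothness, x$asymmetry, x$iterations))
  else
    cat(sprintf("<baseline_recipe> polynomial degree %d through %s anchors\n",
                x$degree,
                if (is.null(x$anchors)) "all" else length(x$anchors)))
  invisible(x)
}

#' Serialize / restore a recipe as JSON
#' @param r a [baseline_recipe()].
#' @param path file path.
#' @return `write_recipe` returns `path` invisibly; `read_recipe` the recipe.
#' @export
write_recipe <- function(r, path) {
  stopifnot(inherits(r, "baseline_recipe"))
  jsonlite::write_json(unclass(r), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_recipe
#' @export
read_recipe <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  baseline_recipe(method = x$method, smoothness = x$smoothness,
                  asymmetry = x$asymmetry, iterations = x$iterations,
                  anchors = x$anchors, degree = x$degree)
}

#' Default baseline anchor wavenumbers
#'
#' Peak-free positions spread across the 400-1800 cm^-1 axis, chosen in
#' the gaps between the built-in assignment-table entries (and inside
#' the 500-520 noise window), for the anchored-polynomial recipe.
#'
#' @return numeric vector of wavenumbers (cm^-1).
#' @export
default_anchor_points <- function() {
  c(405, 435, 465, 505, 515, 545, 575, 605, 860, 885, 940, 965,
    1045, 1100, 1160, 1240, 1400, 1420, 1480, 1545, 1610, 1650,
    1700, 1750, 1795)
}

#' Default candidate grid for recipe selection
#'
#' The candidates offered to [suggest_recipe()] when a pipeline picks
#' its recipe from sample spectra: the stock ALS recipe, two ALS
#' variants (stiffer; less asymmetric), and anchored polynomials of
#' degree 3 and 5 through [default_anchor_points()].
#'
#' @return list of [baseline_recipe()] objects.
#' @export
default_recipe_grid <- function() {
  list(
    baseline_recipe("als"),
    baseline_recipe("als", smoothness = 1e6),
    baseline_recipe("als", asymmetry = 0.05),
    baseline_recipe("poly-anchors", anchors = default_anchor_points(),
                    degree = 3),
    baseline_recipe("poly-anchors", anchors = default_anchor_points(),
                    degree = 5)
  )
}

#' Fit a baseline curve to one spectrum
#'
#' Returns the baseline evaluated at every axis sample (a spectrum on the
#' same axis); subtracting it from the input gives the peak-only signal.
#' Negative residuals are deliberately kept (no clipping) so downstream
#' RMS statistics are unbiased.
#'
#' @param s a [spectrum()] (raw intensities).
#' @param r a [baseline_recipe()].
#' @return a [spectrum()] holding the baseline curve.
#' @export
fit_baseline <- function(s, r) {
  stopifnot(inherits(s, "spectrum"), inherits(r, "baseline_recipe"))
  if (r$method == "als") {
    z <- .als_baseline_cpp(s$intensities, r$smoothness, r$asymmetry,
                           r$iterations)
  } else {
    if (length(s$axis) < r$degree + 1L)
      stop("axis too short (", length(s$axis),
           " samples) for polynomial degree ", r$degree)
    if (is.null(r$anchors)) {
      x <- s$axis; y <- s$intensities
    } else {
      idx <- unique(vapply(r$anchors, function(a)
        which.min(abs(s$axis - a)), integer(1)))
      if (length(idx) < r$degree + 1L)
        stop("need at least degree+1 = ", r$degree + 1L,
             " distinct anchors, got ", length(idx))
      x <- s$axis[idx]; y <- s$intensities[idx]
    }
    # scaled raw-power basis; degrees are <= 5 in practice so this is stable
    ctr <- mean(s$axis); scl <- max(diff(range(s$axis)) / 2, 1)
    X <- outer((x - ctr) / scl, 0:r$degree, `^`)
    beta <- qr.coef(qr(X), y)
    z <- drop(outer((s$axis - ctr) / scl, 0:r$degree, `^`) %*% beta)
  }
  spectrum(s$axis, z, meta = c(s$meta, list(baseline_method = r$method)))
}

#' Subtract the fitted baseline from a spectrum
#'
#' @inheritParams fit_baseline
#' @return a [spectrum()] of residual (baseline-subtracted) intensities.
#' @export
subtract_baseline <- function(s, r) {
  b <- fit_baseline(s, r)
  spectrum(s$axis, s$intensities - b$intensities,
           meta = c(s$meta, list(baseline_subtracted = TRUE,
                                 baseline_method = r$method)))
}

#' Subtract one shared baseline recipe from every pixel of an image
#'
#' The same recipe is applied to all pixels (no per-pixel adaptation), so
#' processing commutes with any pixel permutation. Errors from individual
#' pixels are re-raised with the pixel coordinates attached.
#'
#' @param img a [hyper_image()].
#' @param r a [baseline_recipe()].
#' @return a [hyper_image()] of baseline-subtracted intensities on the
#'   same axis.
#' @export
subtract_baseline_image <- function(img, r) {
  stopifnot(inherits(img, "hyper_image"), inherits(r, "baseline_recipe"))
  d <- dim(img$cube)
  out <- img$cube
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      y <- img$cube[i, j, ]
      res <- tryCatch({
        if (r$method == "als")
          y - .als_baseline_cpp(y, r$smoothness, r$asymmetry, r$iterations)
        else
          subtract_baseline(spectrum(img$axis, y), r)$intensities
      }, error = function(e)
        stop("baseline failed at pixel (", i, ",", j, "): ",
             conditionMessage(e), call. = FALSE))
      out[i, j, ] <- res
    }
  }
  hyper_image(img$axis, out, img$pixel_pitch_um)
}

#' Choose a recipe from a small sample of spectra
#'
#' Mimics the practice of picking one recipe after inspecting 10-15
#' spectra from an image: each candidate recipe is applied to every
#' sample spectrum and scored by the mean RMS of its residuals at axis
#' samples lying outside every band of the registry (imaging and
#' assignment windows alike). Outside known bands a good baseline leaves
#' a flat residual near zero, so the smallest score wins; ties and
#' duplicated candidates resolve to the first in grid order.
#'
#' @param spectra list of [spectrum()] objects (>= 2; typically 10-15).
#' @param grid list of candidate [baseline_recipe()] objects.
#' @param registry a [band_registry()] whose windows are excluded from
#'   the score; default [default_registry()].
#' @return the winning [baseline_recipe()], with the score attached as
#'   attribute `"score"`.
#' @export
suggest_recipe <- function(spectra, grid, registry = default_registry()) {
  if (length(grid) == 0L) stop("empty candidate grid")
  if (length(spectra) < 2L) stop("need at least 2 sample spectra")
  stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum")),
            all(vapply(grid, inherits, logical(1), "baseline_recipe")),
            inherits(registry, "band_registry"))
  bands <- c(registry$imaging_bands, registry$assignment_bands)
  out_mask <- function(axis) {
    inside <- rep(FALSE, length(axis))
    for (b in bands) inside <- inside | (axis >= b$lo & axis <= b$hi)
    !inside
  }
  scores <- vapply(grid, function(r) {
    mean(vapply(spectra, function(s) {
      resid <- subtract_baseline(s, r)$intensities
      m <- out_mask(s$axis)
      if (!any(m)) stop("registry bands cover the entire axis")
      sqrt(mean(resid[m]^2))
    }, numeric(1)))
  }, numeric(1))
  best <- which.min(scores)  # which.min returns the first minimum: tie rule
  structure(grid[[best]], score = scores[best])
}
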