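# Ground-truthed synthetic phantoms emulating live-cell SERS mapping on a
# nanostar substrate: a ~20 um cell with a ~10 um central nucleus on a
# 1 um grid, molecule-specific Lorentzian peaks, signal present only over
# nanostar-aggregate hotspots (short-range enhancement), optical blur at
# the detection-spot scale, a fluorescence-like baseline, and detector
# noise. Every realization is bit-exact reproducible from (params, seed).

#' Airy disk radius of the detection spot
#'
#' Two conventions are offered: the first-minimum radius `0.61 * lambda /
#' NA` and the "full-width" figure `1.22 * lambda / NA` often quoted as
#' the spot scale. 785 nm through a 0.5 NA objective gives 0.96 um and
#' 1.92 um respectively; the latter matches the upper end of the quoted
#' 1.4-1.9 um spot radius.
#'
#' @param wavelength_nm excitation wavelength in nm (> 0).
#' @param na numerical aperture, in (0, 1.5].
#' @param convention `"first-minimum"` (0.61 lambda/NA) or
#'   `"full-width"` (1.22 lambda/NA).
#' @return radius in micrometres.
#' @export
airy_radius <- function(wavelength_nm, na,
                        convention = c("first-minimum", "full-width")) {
  convention <- match.arg(convention)
  if (!is.numeric(wavelength_nm) || wavelength_nm <= 0)
    stop("wavelength must be positive")
  if (!is.numeric(na) || na <= 0 || na > 1.5)
    stop("numerical aperture must lie in (0, 1.5]")
  k <- if (convention == "first-minimum") 0.61 else 1.22
  k * wavelength_nm / na / 1000
}

# ---- component spectra -------------------------------------------------

#' Define a component spectrum as a list of peaks
#'
#' @param component label in DNA, RNA, heme, protein, lipid,
#'   carbohydrate, substrate.
#' @param peaks data frame with columns `center` (cm^-1), `fwhm` (cm^-1,
#'   > 0), `amplitude` (relative, >= 0), `shape` (lorentzian, gaussian,
#'   pseudo-voigt).
#' @return an object of class `"component_spectrum"`.
#' @export
component_spectrum <- function(component, peaks) {
  component <- match.arg(component, c("DNA", "RNA", "heme", "protein",
                                      "lipid", "carbohydrate", "substrate"))
  stopifnot(is.data.frame(peaks),
            all(c("center", "fwhm", "amplitude", "shape") %in% names(peaks)))
  if (any(peaks$fwhm <= 0)) stop("FWHM must be positive")
  if (any(peaks$amplitude < 0)) stop("amplitudes must be >= 0")
  if (!all(peaks$shape %in% c("lorentzian", "gaussian", "pseudo-voigt")))
    stop("unknown peak shape")
  structure(list(component = component, peaks = peaks),
            class = "component_spectrum")
}

#' Evaluate a component spectrum on an axis
#'
#' @param cs a [component_spectrum()].
#' @param axis wavenumber axis (cm^-1).
#' @return intensity vector (unit amplitude = 1 at the strongest peak
#'   center, before overlap).
#' @export
eval_component <- function(cs, axis) {
  stopifnot(inherits(cs, "component_spectrum"))
  axis <- spectral_axis(axis)
  y <- numeric(length(axis))
  for (i in seq_len(nrow(cs$peaks))) {
    p <- cs$peaks[i, ]
    d2 <- (axis - p$center)^2
    g <- p$fwhm / 2
    lor <- g^2 / (d2 + g^2)
    gau <- exp(-4 * log(2) * d2 / p$fwhm^2)
    y <- y + p$amplitude * switch(p$shape,
                                  "lorentzian" = lor,
                                  "gaussian" = gau,
                                  "pseudo-voigt" = 0.5 * lor + 0.5 * gau)
  }
  y
}

#' The built-in component spectral library
#'
#' One entry per molecule class with peaks at the wavenumbers reported
#' for live-cell SERS on this substrate class (DNA 670/692/720/790/802/
#' 1330 with cytosine 790 the most intense; RNA 775/812/822/833/1510;
#' hemes 746/750/754/760/1206, heme C 750 and heme B 760; protein
#' 1000/1180/1365; lipid 1078/1270/1445 with 1445 the most intense;
#' carbohydrate 912/1120; substrate 1010/1065/1203 seen outside cells).
#' Lorentzian shape and 10 cm^-1 FWHM by default; no component has a
#' peak inside the 500-520 cm^-1 noise window, by construction.
#'
#' @param fwhm default full width at half maximum in cm^-1.
#' @return named list of [component_spectrum()] objects.
#' @export
default_library <- function(fwhm = 10) {
  pk <- function(centers, amps)
    data.frame(center = centers, fwhm = fwhm, amplitude = amps,
               shape = "lorentzian", stringsAsFactors = FALSE)
  list(
    # amplitudes are scaled so the strongest peak inside the component's
    # imaging window equals 1 (the SNR reference); relative order within
    # a component follows the reported spectra (790 the most intense DNA
    # peak, 812 an intensive RNA peak, 750/760 the heme C/B pair)
    DNA = component_spectrum("DNA", pk(
      c(670, 692, 720, 790, 802, 1330),
      c(1.0, 0.86, 0.71, 1.43, 1.0, 1.14))),
    RNA = component_spectrum("RNA", pk(
      c(775, 812, 822, 833, 1510), c(0.71, 1.43, 1.14, 1.0, 1.29))),
    heme = component_spectrum("heme", pk(
      c(746, 750, 754, 760, 1206), c(0.7, 1.0, 0.7, 0.9, 0.5))),
    protein = component_spectrum("protein", pk(
      c(1000, 1180, 1365), c(1.0, 0.6, 0.7))),
    lipid = component_spectrum("lipid", pk(
      c(1078, 1270, 1445), c(0.6, 0.7, 1.0))),
    carbohydrate = component_spectrum("carbohydrate", pk(
      c(912, 1120), c(0.7, 1.0))),
    substrate = component_spectrum("substrate", pk(
      c(1010, 1065, 1203), c(1.0, 0.8, 0.6)))
  )
}

# ---- compartments ------------------------------------------------------

#' Default compartment composition profiles
#'
#' Non-negative component weights per compartment: the nucleus is rich in
#' DNA with RNA and protein; the nucleolus is RNA-enriched relative to
#' the rest of the nucleus (ribosomal RNA); mitochondria carry the heme
#' signal (hemes sit at the SNR floor with no extra amplification --
#' 785 nm excitation is not resonant for them, so their maps stay weak
#' relative to the published display scale); the membrane is lipid-led
#' with protein and
#' glycoprotein carbohydrate; outside the cell only the substrate peaks
#' remain. Override any entry by passing a modified copy downstream.
#'
#' @return named list (compartment) of named numeric vectors (component
#'   weights).
#' @export
compartment_profiles <- function() {
  list(
    outside      = c(substrate = 0.3),
    membrane     = c(lipid = 1.0, protein = 0.5, carbohydrate = 0.4),
    cytoplasm    = c(protein = 0.5, RNA = 0.3, lipid = 0.3,
                     carbohydrate = 0.2),
    mitochondria = c(heme = 1.0, protein = 0.6, lipid = 0.3),
    nucleus      = c(DNA = 1.0, RNA = 0.3, protein = 0.6),
    nucleolus    = c(RNA = 1.2, DNA = 0.3, protein = 0.6)
  )
}

.compartment_levels <- c("outside", "cytoplasm", "membrane",
                         "mitochondria", "nucleus", "nucleolus")

#' Generate the cell geometry label image
#'
#' An elliptical ~20 um cell with a centered ~10 um nucleus, an offset
#' nucleolar disc, mitochondrial discs scattered in a perinuclear
#' annulus, and a 1-pixel membrane rim. Labels are assigned with
#' priority nucleolus > nucleus > mitochondria > membrane > cytoplasm >
#' outside.
#'
#' @param size image side in pixels (square grid).
#' @param pixel_pitch_um scan step, default 1 um.
#' @param cell_diameter_um,nucleus_diameter_um major diameters (the
#'   minor axis is 0.9 of the major, a mild ellipticity).
#' @param nucleolus_diameter_um nucleolar disc diameter.
#' @param n_mitochondria number of mitochondrial discs.
#' @param mitochondrion_diameter_um mitochondrial disc diameter.
#' @param seed integer seed for mitochondria placement.
#' @return list of class `"cell_geometry"`: `labels` (character matrix),
#'   plus the parameters.
#' @export
cell_geometry <- function(size = 64, pixel_pitch_um = 1,
                          cell_diameter_um = 20, nucleus_diameter_um = 10,
                          nucleolus_diameter_um = 3, n_mitochondria = 10,
                          mitochondrion_diameter_um = 2, seed = 1) {
  stopifnot(size >= 8, pixel_pitch_um > 0,
            nucleus_diameter_um < cell_diameter_um)
  ctr <- (size + 1) / 2
  x <- (col(matrix(0, size, size)) - ctr) * pixel_pitch_um
  y <- (row(matrix(0, size, size)) - ctr) * pixel_pitch_um
  in_ellipse <- function(cx, cy, a, b) ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
  cellm <- in_ellipse(0, 0, cell_diameter_um / 2, 0.9 * cell_diameter_um / 2)
  nuc <- in_ellipse(0, 0, nucleus_diameter_um / 2,
                    0.9 * nucleus_diameter_um / 2)
  nucleol <- in_ellipse(nucleus_diameter_um / 5, nucleus_diameter_um / 5,
                        nucleolus_diameter_um / 2, nucleolus_diameter_um / 2)
  nucleol <- nucleol & nuc
  # membrane: cell pixels with a 4-neighbour outside the cell
  pad <- rbind(FALSE, cbind(FALSE, cellm, FALSE), FALSE)
  H <- size
  inner <- 2:(H + 1)
  memb <- cellm & !(pad[inner - 1, inner] & pad[inner + 1, inner] &
                      pad[inner, inner - 1] & pad[inner, inner + 1])
  # mitochondria: discs in the perinuclear annulus, seeded placement
  mito <- matrix(FALSE, size, size)
  rmin <- nucleus_diameter_um / 2 + mitochondrion_diameter_um / 2 + 0.2
  rmax <- min(rmin + 4, cell_diameter_um / 2 - 2)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  th <- runif(n_mitochondria, 0, 2 * pi)
  rr <- runif(n_mitochondria, rmin, rmax)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)
  for (m in seq_len(n_mitochondria)) {
    cx <- rr[m] * cos(th[m]); cy <- 0.9 * rr[m] * sin(th[m])
    mito <- mito | in_ellipse(cx, cy, mitochondrion_diameter_um / 2,
                              mitochondrion_diameter_um / 2)
  }
  mito <- mito & cellm & !nuc
  labels <- matrix("outside", size, size)
  labels[cellm] <- "cytoplasm"
  labels[memb] <- "membrane"
  labels[mito] <- "mitochondria"
  labels[nuc] <- "nucleus"
  labels[nucleol] <- "nucleolus"
  structure(list(labels = labels, size = size,
                 pixel_pitch_um = pixel_pitch_um,
                 cell_diameter_um = cell_diameter_um,
                 nucleus_diameter_um = nucleus_diameter_um,
                 nucleolus_diameter_um = nucleolus_diameter_um,
                 n_mitochondria = n_mitochondria,
                 mitochondrion_diameter_um = mitochondrion_diameter_um,
                 seed = seed),
            class = "cell_geometry")
}

# separable Gaussian blur with edge renormalization
.gauss_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - r); hi <- min(n, i + r)
      kk <- k[(lo - i + r + 1):(hi - i + r + 1)]
      out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
  }
  tmp <- apply(mat, 2, conv1)
  t(apply(tmp, 1, conv1))
}

#' Random nanostar-aggregate hotspot mask
#'
#' A blob-shaped aggregate footprint: smoothed white noise, plus a
#' centered Gaussian bias, thresholded at the requested coverage
#' quantile. The bias encodes the imaging protocol -- scan regions are
#' chosen around an aggregate, so the footprint sits near the field
#' center (over the cell) with an irregular, seed-dependent outline;
#' surface coverage varies between substrate syntheses from 13% to 70%.
#'
#' @param size image side in pixels.
#' @param coverage target area fraction in (0, 1).
#' @param blob_scale_px footprint correlation length (blur sigma),
#'   default 6 (aggregates are micron-scale black spots in brightfield).
#' @param center_bias strength of the central bias in field-sd units
#'   (default 3; 0 gives an unbiased random footprint).
#' @param bias_radius_px spatial scale of the central bias, default 12.
#' @return logical matrix; drawn from the current RNG state.
#' @export
hotspot_mask <- function(size, coverage, blob_scale_px = 6,
                         center_bias = 3, bias_radius_px = 12) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must lie in (0, 1)")
  field <- .gauss_blur(matrix(rnorm(size * size), size, size), blob_scale_px)
  field <- (field - mean(field)) / stats::sd(field)
  ctr <- (size + 1) / 2
  d2 <- (row(field) - ctr)^2 + (col(field) - ctr)^2
  field <- field + center_bias * exp(-d2 / (2 * bias_radius_px^2))
  field >= stats::quantile(field, 1 - coverage)
}

# ---- phantom -----------------------------------------------------------

#' Phantom generation parameters
#'
#' The defaults state the emulated experiment: a 64 x 64 pixel map at
#' 1 um pitch, a 400-1800 cm^-1 axis at 1 cm^-1, peak SNR 10 (in-band
#' peak amplitude of a unit-weight component = 10 x noise sigma),
#' aggregate coverage drawn uniformly from the observed 13-70% range
#' unless fixed, and a Gaussian PSF whose sigma is 0.344 x the 1.22
#' lambda/NA Airy figure at 785 nm / 0.5 NA (the best-fit Gaussian to an
#' Airy spot of that radius), ~0.66 um.
#'
#' @param size image side in pixels.
#' @param pixel_pitch_um scan step.
#' @param axis wavenumber axis.
#' @param library component library, see [default_library()].
#' @param profiles compartment weights, see [compartment_profiles()].
#' @param coverage hotspot area fraction; `NULL` draws from U(0.13, 0.70).
#' @param peak_snr in-band peak amplitude over noise sigma.
#' @param noise_sd detector noise sigma (counts).
#' @param peak_amplitude absolute in-band peak amplitude (counts);
#'   `NULL` (default) derives it as `peak_snr * noise_sd`. Set it
#'   explicitly for noise-free phantoms.
#' @param baseline_amplitude fluorescence baseline scale (counts).
#' @param poisson_like if `TRUE`, noise sigma scales like
#'   `sqrt(1 + clean / baseline_amplitude)` (shot-noise flavour).
#' @param psf_sigma_um Gaussian PSF sigma in um.
#' @param geometry_args extra arguments for [cell_geometry()].
#' @return a list of class `"phantom_params"`.
#' @export
phantom_params <- function(size = 64, pixel_pitch_um = 1,
                           axis = seq(400, 1800, by = 1),
                           library = default_library(),
                           profiles = compartment_profiles(),
                           coverage = NULL, peak_snr = 10, noise_sd = 1,
                           peak_amplitude = NULL,
                           baseline_amplitude = 50, poisson_like = FALSE,
                           psf_sigma_um = 0.344 *
                             airy_radius(785, 0.5, "full-width"),
                           geometry_args = list()) {
  structure(list(size = size, pixel_pitch_um = pixel_pitch_um,
                 axis = spectral_axis(axis), library = library,
                 profiles = profiles, coverage = coverage,
                 peak_snr = peak_snr, noise_sd = noise_sd,
                 peak_amplitude = peak_amplitude,
                 baseline_amplitude = baseline_amplitude,
                 poisson_like = poisson_like,
                 psf_sigma_um = psf_sigma_um,
                 geometry_args = geometry_args),
            class = "phantom_params")
}

#' Generate a ground-truthed phantom
#'
#' The generative model: compartment labels give per-component abundance
#' maps (compartment weight x indicator); the hotspot mask gates them
#' (short-range enhancement means a pixel contributes only over an
#' aggregate, and no component signal exists off-hotspot); the gated
#' maps are blurred by the detection-spot PSF; the cube is the abundance-
#' weighted sum of library spectra scaled so a unit-weight component's
#' tallest peak is `peak_snr` x noise sigma, plus an exponentially
#' decaying fluorescence-like baseline (stronger over the cell) and
#' additive Gaussian noise. Identical `(params, seed)` give bit-identical
#' cubes.
#'
#' @param params a [phantom_params()].
#' @param seed integer seed (mandatory).
#' @return list of class `"phantom"`: `geometry`, `hotspot`, `coverage`,
#'   `abundance` (per-component gated, unblurred maps), `cube` (a
#'   [hyper_image()]), `truth` (seed and params).
#' @export
generate_phantom <- function(params = phantom_params(), seed) {
  stopifnot(inherits(params, "phantom_params"))
  if (missing(seed)) stop("seed is a mandatory argument")
  axis <- params$axis
  for (cs in params$library) {
    bad <- cs$peaks$center < min(axis) | cs$peaks$center > max(axis)
    if (any(bad))
      stop("axis (", min(axis), "-", max(axis), " cm^-1) too short for ",
           cs$component, " peak(s) at ",
           paste(cs$peaks$center[bad], collapse = ", "))
  }
  set.seed(as.integer(seed))
  size <- params$size
  geom <- do.call(cell_geometry,
                  c(list(size = size, pixel_pitch_um = params$pixel_pitch_um,
                         seed = as.integer(seed)), params$geometry_args))
  coverage <- if (is.null(params$coverage)) runif(1, 0.13, 0.70)
              else params$coverage
  hotspot <- hotspot_mask(size, coverage)
  comps <- names(params$library)
  abundance <- lapply(comps, function(cp) {
    a <- matrix(0, size, size)
    for (comp in names(params$profiles)) {
      w <- params$profiles[[comp]][cp]
      if (!is.na(w) && w > 0) a <- a + w * (geom$labels == comp)
    }
    a * hotspot  # binary enhancement gate
  })
  names(abundance) <- comps
  sigma_px <- params$psf_sigma_um / params$pixel_pitch_um
  blurred <- lapply(abundance, .gauss_blur, sigma_px = sigma_px)
  K <- length(axis)
  scale <- if (!is.null(params$peak_amplitude)) params$peak_amplitude
           else params$peak_snr * params$noise_sd
  cube <- array(0, c(size, size, K))
  for (cp in comps) {
    spec <- eval_component(params$library[[cp]], axis)
    if (any(spec > 0) && any(blurred[[cp]] > 0))
      cube <- cube + outer(blurred[[cp]], spec) * scale
  }
  # fluorescence-like baseline, stronger over the cell body
  cellness <- .gauss_blur((geom$labels != "outside") * 1, max(sigma_px, 1))
  # gentle fluorescence tail: broad and smooth across the window, as 785 nm
  # autofluorescence backgrounds are
  bshape <- exp(-(axis - min(axis)) / 1500)
  cube <- cube + outer(params$baseline_amplitude * (0.6 + 0.8 * cellness),
                       bshape)
  if (params$poisson_like) {
    sdarr <- params$noise_sd * sqrt(1 + pmax(cube, 0) /
                                      params$baseline_amplitude)
    cube <- cube + array(rnorm(length(cube)), dim(cube)) * sdarr
  } else {
    cube <- cube + array(rnorm(length(cube), sd = params$noise_sd),
                         dim(cube))
  }
  structure(list(geometry = geom, hotspot = hotspot, coverage = coverage,
                 abundance = abundance,
                 cube = hyper_image(axis, cube, params$pixel_pitch_um),
                 truth = list(seed = as.integer(seed), params = params)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, %d samples, coverage %.2f, seed %d\n",
              x$geometry$size, x$geometry$size, length(x$cube$axis),
              x$coverage, x$truth$seed))
  invisible(x)
}

#' Indicator mask for phantom compartments
#'
#' @param ph a [generate_phantom()] result.
#' @param compartments character vector of compartment labels.
#' @param hotspot_only intersect with the hotspot mask (default `TRUE`,
#'   the region where signal can exist at all).
#' @return logical matrix.
#' @export
compartment_mask <- function(ph, compartments, hotspot_only = TRUE) {
  stopifnot(inherits(ph, "phantom"))
  m <- matrix(ph$geometry$labels %in% compartments,
              nrow(ph$geometry$labels))
  if (hotspot_only) m & ph$hotspot else m
}
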