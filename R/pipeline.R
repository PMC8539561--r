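# End-to-end driver: phantom (or cube on disk) -> shared-recipe baseline
# subtraction -> normalized band-RMS maps -> grayscale + merged RGB
# composites -> peak annotation. Stage order is fixed; every output
# carries the config hash and seed so bundles are reproducible.

#' Assemble a pipeline configuration
#'
#' @param recipe a [baseline_recipe()]: the fallback recipe, applied
#'   directly when `select_from` is `NULL`.
#' @param select_from optional list of candidate [baseline_recipe()]s;
#'   when non-NULL (the default grid), the pipeline picks the recipe by
#'   [suggest_recipe()] on 12 spectra sampled from the image, mirroring
#'   the practice of choosing one recipe after inspecting 10-15 spectra.
#' @param registry a [band_registry()]; must contain exactly one noise
#'   band (validated before any computation runs).
#' @param display a [display_range()] (default the shared 0-60 scale).
#' @param seed integer seed used for phantom generation.
#' @param input_cube optional path to a cube container; when `NULL` a
#'   phantom is generated from `phantom` instead.
#' @param phantom a [phantom_params()] (used when `input_cube` is NULL).
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(recipe = baseline_recipe(),
                            select_from = default_recipe_grid(),
                            registry = default_registry(),
                            display = display_range(),
                            seed = 1L, input_cube = NULL,
                            phantom = phantom_params()) {
  cfg <- structure(list(recipe = recipe, select_from = select_from,
                        registry = registry,
                        display = display, seed = as.integer(seed),
                        input_cube = input_cube, phantom = phantom),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks all component types and the presence of exactly one noise band
#' before any computation; errors name the offending field.
#'
#' @param cfg a [pipeline_config()].
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg$recipe, "baseline_recipe"))
    stop("config validation: recipe is not a baseline_recipe")
  if (!is.null(cfg$select_from) &&
      (!is.list(cfg$select_from) || length(cfg$select_from) == 0L ||
       !all(vapply(cfg$select_from, inherits, logical(1),
                   "baseline_recipe"))))
    stop("config validation: select_from must be NULL or a non-empty ",
         "list of baseline_recipe objects")
  if (!inherits(cfg$registry, "band_registry"))
    stop("config validation: registry is not a band_registry")
  n_noise <- sum(vapply(cfg$registry$imaging_bands, function(b)
    b$molecule_class == "noise", logical(1)))
  if (n_noise != 1L)
    stop("config validation: registry needs exactly one noise band, found ",
         n_noise)
  if (!inherits(cfg$display, "display_range"))
    stop("config validation: display is not a display_range")
  if (!is.integer(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("config validation: seed must be a single integer")
  if (is.null(cfg$input_cube) && !inherits(cfg$phantom, "phantom_params"))
    stop("config validation: need either input_cube or phantom params")
  invisible(cfg)
}

# FNV-1a 32-bit hash of a string; cheap provenance stamp without binary deps
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor and multiply on 16-bit halves so doubles never lose precision
    hi <- h %/% 65536; lo <- bitwXor(as.integer(h %% 65536), b)
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  # h < 2^32 exceeds integer range; format the hex from two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Hash of a serialized configuration
#'
#' @param cfg a [pipeline_config()].
#' @return 8-hex-digit string, stable across sessions.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  .fnv1a(paste(readLines(tmp), collapse = "\n"))
}

#' Serialize / restore a pipeline configuration as JSON
#'
#' `load_config(save_config(cfg))` reproduces `cfg` exactly (round-trip
#' identity), excluding the in-memory component library which is rebuilt
#' from its peak table.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `save_config` returns `path` invisibly; `load_config` the
#'   config.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  strip_bands <- function(bl) lapply(unname(bl), unclass)
  ph <- cfg$phantom
  obj <- list(
    recipe = unclass(cfg$recipe),
    select_from = if (is.null(cfg$select_from)) NULL
                  else lapply(cfg$select_from, unclass),
    registry = list(imaging_bands = strip_bands(cfg$registry$imaging_bands),
                    assignment_bands = strip_bands(cfg$registry$assignment_bands)),
    display = unclass(cfg$display),
    seed = cfg$seed,
    input_cube = cfg$input_cube,
    phantom = list(size = ph$size, pixel_pitch_um = ph$pixel_pitch_um,
                   axis = list(min = min(ph$axis), max = max(ph$axis),
                               step = ph$axis[2] - ph$axis[1]),
                   library = lapply(ph$library, function(cs)
                     list(component = cs$component, peaks = cs$peaks)),
                   profiles = lapply(ph$profiles, as.list),
                   coverage = ph$coverage, peak_snr = ph$peak_snr,
                   noise_sd = ph$noise_sd,
                   peak_amplitude = ph$peak_amplitude,
                   baseline_amplitude = ph$baseline_amplitude,
                   poisson_like = ph$poisson_like,
                   psf_sigma_um = ph$psf_sigma_um,
                   geometry_args = ph$geometry_args))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mkband <- function(e) band(e$name, e$lo, e$hi, e$molecule_class, e$channel)
  reg <- band_registry(lapply(x$registry$imaging_bands, mkband),
                       lapply(x$registry$assignment_bands, mkband))
  mkrec <- function(e)
    baseline_recipe(method = e$method, smoothness = e$smoothness,
                    asymmetry = e$asymmetry, iterations = e$iterations,
                    anchors = if (length(e$anchors)) unlist(e$anchors),
                    degree = if (is.null(e$degree)) 3L else e$degree)
  rec <- mkrec(x$recipe)
  sel <- if (is.null(x$select_from)) NULL else lapply(x$select_from, mkrec)
  lib <- lapply(x$phantom$library, function(e) {
    pk <- do.call(rbind, lapply(e$peaks, function(p)
      data.frame(center = p$center, fwhm = p$fwhm,
                 amplitude = p$amplitude, shape = p$shape,
                 stringsAsFactors = FALSE)))
    component_spectrum(e$component, pk)
  })
  names(lib) <- vapply(lib, `[[`, character(1), "component")
  prof <- lapply(x$phantom$profiles, unlist)
  ph <- phantom_params(size = x$phantom$size,
                       pixel_pitch_um = x$phantom$pixel_pitch_um,
                       axis = seq(x$phantom$axis$min, x$phantom$axis$max,
                                  by = x$phantom$axis$step),
                       library = lib, profiles = prof,
                       coverage = x$phantom$coverage,
                       peak_snr = x$phantom$peak_snr,
                       noise_sd = x$phantom$noise_sd,
                       peak_amplitude = x$phantom$peak_amplitude,
                       baseline_amplitude = x$phantom$baseline_amplitude,
                       poisson_like = x$phantom$poisson_like,
                       psf_sigma_um = x$phantom$psf_sigma_um,
                       geometry_args = as.list(x$phantom$geometry_args))
  pipeline_config(recipe = rec, select_from = sel, registry = reg,
                  display = display_range(x$display$lo, x$display$hi),
                  seed = x$seed, input_cube = x$input_cube, phantom = ph)
}

#' Run the full mapping pipeline
#'
#' Fixed stage order: acquire (phantom or cube from disk) -> baseline
#' subtraction with the one shared recipe -> normalized band-RMS maps
#' for every imaging band -> grayscale renderings and the merged RGB
#' composite on the shared display range -> peak annotation of the mean
#' on-cell spectrum. Any stage error aborts with the stage name (and
#' pixel coordinates where applicable). Progress goes to `message()`
#' (stderr); results only to files under `outdir`.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory, created if missing; `NULL` skips all
#'   file output.
#' @return invisibly, a bundle list: `phantom` (or NULL), `subtracted`
#'   image, `maps`, `rgb` array, `annotation` data frame, `report`.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  validate_config(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  hash <- config_hash(cfg)
  message("sersmap pipeline: config ", hash, ", seed ", cfg$seed)

  acq <- stage("acquire", {
    if (!is.null(cfg$input_cube))
      list(ph = NULL, img = read_cube(cfg$input_cube))
    else {
      p <- generate_phantom(cfg$phantom, cfg$seed)
      list(ph = p, img = p$cube)
    }
  })
  ph <- acq$ph
  img <- acq$img
  message("  acquired ", paste(dim(img$cube), collapse = " x "), " cube")

  recipe <- stage("recipe", {
    if (is.null(cfg$select_from)) cfg$recipe
    else {
      d <- dim(img$cube)
      n_sample <- min(12L, d[1] * d[2])
      # deterministic, evenly spaced pixel sample across the raster
      lin <- unique(round(seq(1, d[1] * d[2], length.out = n_sample)))
      spectra <- lapply(lin, function(ii) {
        i <- ((ii - 1) %% d[1]) + 1L
        j <- ((ii - 1) %/% d[1]) + 1L
        pixel_spectrum(img, i, j)
      })
      suggest_recipe(spectra, cfg$select_from, cfg$registry)
    }
  })
  message("  recipe: ", recipe$method,
          if (!is.null(cfg$select_from)) " (selected from grid)" else "")

  sub <- stage("baseline", subtract_baseline_image(img, recipe))
  message("  baseline subtracted (", recipe$method, ")")

  maps <- stage("maps", compute_maps(sub, cfg$registry, recipe = recipe))
  message("  computed ", length(maps), " band maps: ",
          paste(names(maps), collapse = ", "))

  rgbimg <- stage("composite", {
    bych <- function(chan) {
      hit <- vapply(cfg$registry$imaging_bands, function(b)
        b$channel == chan, logical(1))
      nm <- names(cfg$registry$imaging_bands)[hit][1]
      maps[[nm]]
    }
    merge_rgb(rgb_composite(bych("red"), bych("green"), bych("blue"),
                            range = cfg$display))
  })

  annot <- stage("annotate", {
    d <- dim(sub$cube)
    sel <- if (!is.null(ph)) ph$hotspot else matrix(TRUE, d[1], d[2])
    if (!any(sel)) sel[] <- TRUE
    msum <- rep(0, d[3])
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      if (sel[i, j]) msum <- msum + sub$cube[i, j, ]
    mspec <- spectrum(sub$axis, msum / sum(sel))
    noiseb <- cfg$registry$imaging_bands[[which(vapply(
      cfg$registry$imaging_bands, function(b) b$molecule_class == "noise",
      logical(1)))]]
    thr <- 5 * band_rms(mspec, noiseb)
    annotate_spectrum(mspec, min_prominence = max(thr, 1e-12))
  })
  message("  annotated ", length(unique(annot$position)), " peaks")

  report <- list(config_hash = hash, seed = cfg$seed,
                 recipe = list(method = recipe$method,
                               selected = !is.null(cfg$select_from)),
                 coverage = if (!is.null(ph)) ph$coverage else NA,
                 map_summary = lapply(maps, function(m)
                   list(mean = mean(m, na.rm = TRUE),
                        max = max(m, na.rm = TRUE),
                        missing = sum(is.na(m)))))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(maps)) {
      write_map_csv(maps[[nm]], file.path(outdir, paste0("map_", nm, ".csv")))
      write_pgm(to_gray(maps[[nm]], cfg$display),
                file.path(outdir, paste0("map_", nm, ".pgm")))
    }
    write_ppm(rgbimg, file.path(outdir, "composite_rgb.ppm"))
    utils::write.csv(annot, file.path(outdir, "annotation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    message("  wrote bundle to ", outdir)
  }
  invisible(list(phantom = ph, subtracted = sub, maps = maps, rgb = rgbimg,
                 annotation = annot, report = report))
}
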