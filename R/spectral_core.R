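#' @useDynLib sersmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile rnorm runif sd IQR
#' @importFrom graphics hist
#' @importFrom utils read.table write.table
NULL

# ---- wavenumber axis ---------------------------------------------------

#' Validate a Raman shift axis
#'
#' A spectral axis is a strictly increasing vector of finite, positive
#' wavenumbers (cm^-1) of length at least 2. All package containers share
#' one axis per spectrum or image; operations receiving a non-monotonic
#' axis raise an error rather than silently sorting (only file readers
#' reorder descending input).
#'
#' @param values numeric vector of wavenumbers in cm^-1.
#' @return the validated numeric vector, invisibly unchanged.
#' @export
spectral_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("spectral axis needs at least 2 samples, got ", length(values))
  if (!all(is.finite(values)) || any(values <= 0))
    stop("spectral axis values must be finite and positive")
  if (any(diff(values) <= 0))
    stop("spectral axis must be strictly increasing; refuse to sort silently")
  values
}

# ---- spectrum ----------------------------------------------------------

#' Construct a single Raman spectrum
#'
#' @param axis wavenumber axis (cm^-1), validated by [spectral_axis()].
#' @param intensities detector counts, same length as `axis`.
#' @param meta free-form provenance list (acquisition time, pixel origin, ...).
#' @return an object of class `"spectrum"`.
#' @export
spectrum <- function(axis, intensities, meta = list()) {
  axis <- spectral_axis(axis)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(axis))
    stop("intensities length (", length(intensities),
         ") must match axis length (", length(axis), ")")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  structure(list(axis = axis, intensities = intensities, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d samples, %.1f-%.1f cm^-1\n",
              length(x$axis), min(x$axis), max(x$axis)))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$axis)

# ---- hyperspectral image ----------------------------------------------

#' Construct a hyperspectral image cube
#'
#' A 2-D grid of spectra sharing one wavenumber axis. The cube is stored
#' as an H x W x K array (H rows, W columns, K axis samples), row-major
#' with origin at the top-left pixel (1-based indices in R).
#'
#' @param axis shared wavenumber axis (cm^-1).
#' @param cube numeric array of dim H x W x K.
#' @param pixel_pitch_um scan step in micrometres per pixel (default 1,
#'   the instrument's mapping step).
#' @return an object of class `"hyper_image"`.
#' @export
hyper_image <- function(axis, cube, pixel_pitch_um = 1) {
  axis <- spectral_axis(axis)
  if (!is.array(cube) || length(dim(cube)) != 3L)
    stop("cube must be a 3-D array (H x W x K)")
  if (dim(cube)[3] != length(axis))
    stop("cube spectral dimension (", dim(cube)[3],
         ") does not match axis length (", length(axis), ")")
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1L ||
      !is.finite(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("pixel_pitch_um must be a positive scalar")
  structure(list(axis = axis, cube = cube,
                 pixel_pitch_um = as.numeric(pixel_pitch_um)),
            class = "hyper_image")
}

#' @export
print.hyper_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<hyper_image> %d x %d pixels, %d samples (%.1f-%.1f cm^-1), pitch %g um\n",
              d[1], d[2], d[3], min(x$axis), max(x$axis), x$pixel_pitch_um))
  invisible(x)
}

#' @export
dim.hyper_image <- function(x) dim(x$cube)

#' Extract one pixel's spectrum from a cube
#'
#' @param img a [hyper_image()].
#' @param row,col 1-based pixel indices (row 1 = top).
#' @return a [spectrum()] carrying the pixel coordinates in `meta`.
#' @export
pixel_spectrum <- function(img, row, col) {
  stopifnot(inherits(img, "hyper_image"))
  d <- dim(img$cube)
  if (row < 1 || row > d[1] || col < 1 || col > d[2])
    stop("pixel (", row, ",", col, ") outside image ", d[1], "x", d[2])
  spectrum(img$axis, img$cube[row, col, ],
           meta = list(row = row, col = col,
                       pixel_pitch_um = img$pixel_pitch_um))
}

# ---- bands and registries ----------------------------------------------

.molecule_classes <- c("DNA", "RNA", "heme", "protein", "lipid",
                       "carbohydrate", "noise", "other")
.channels <- c("red", "green", "blue", "none")

#' Define a wavenumber band
#'
#' Band membership is the closed interval `lo <= nu <= hi` evaluated on
#' native axis samples (no resampling); ranges printed in the literature
#' ("655-680 cm^-1") are read as inclusive.
#'
#' @param name band label, unique within a registry.
#' @param lo,hi window edges in cm^-1, `lo < hi`.
#' @param molecule_class one of DNA, RNA, heme, protein, lipid,
#'   carbohydrate, noise, other.
#' @param channel display channel for composites: red, green, blue or none.
#' @return an object of class `"band"`.
#' @export
band <- function(name, lo, hi, molecule_class = "other", channel = "none") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("band name must be a non-empty string")
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("band '", name, "': need finite lo < hi, got [", lo, ", ", hi, "]")
  molecule_class <- match.arg(molecule_class, .molecule_classes)
  channel <- match.arg(channel, .channels)
  structure(list(name = name, lo = lo, hi = hi,
                 molecule_class = molecule_class, channel = channel),
            class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %s [%g, %g] cm^-1 (%s%s)\n", x$name, x$lo, x$hi,
              x$molecule_class,
              if (x$channel != "none") paste0(", ", x$channel) else ""))
  invisible(x)
}

#' Assemble a band registry
#'
#' Imaging bands (the narrow per-pixel mapping windows, exactly one of
#' which must be the peak-free noise window) are kept distinct from the
#' broader assignment windows used for spectral interpretation.
#'
#' @param imaging_bands,assignment_bands lists of [band()] objects.
#' @return an object of class `"band_registry"`.
#' @export
band_registry <- function(imaging_bands, assignment_bands = list()) {
  chk <- function(bl, what) {
    if (!all(vapply(bl, inherits, logical(1), "band")))
      stop(what, " must be a list of band objects")
    nm <- vapply(bl, `[[`, character(1), "name")
    if (anyDuplicated(nm))
      stop("duplicate band names in ", what, ": ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
    names(bl) <- nm
    bl
  }
  imaging_bands <- chk(imaging_bands, "imaging_bands")
  assignment_bands <- chk(assignment_bands, "assignment_bands")
  n_noise <- sum(vapply(imaging_bands, function(b)
    b$molecule_class == "noise", logical(1)))
  if (n_noise != 1L)
    stop("imaging_bands must contain exactly one noise band, found ", n_noise)
  structure(list(imaging_bands = imaging_bands,
                 assignment_bands = assignment_bands),
            class = "band_registry")
}

#' The study's band registry
#'
#' Imaging windows: DNA 655-680 (red), heme 740-765 (blue), RNA 825-835
#' (green), protein 995-1010, and the peak-free noise window 500-520 used
#' as the per-spectrum normalization denominator. Assignment windows are
#' the broader interpretation regions (DNA 660-690 / 790-805 / 1300-1350;
#' RNA 805-850 / 1510; heme 730-765; lipid 700-730 / 1300-1330 /
#' 1430-1470; protein 1000-1010 / 1360-1370).
#'
#' @return a [band_registry()].
#' @export
default_registry <- function() {
  band_registry(
    imaging_bands = list(
      band("DNA",     655,  680, "DNA",     "red"),
      band("heme",    740,  765, "heme",    "blue"),
      band("RNA",     825,  835, "RNA",     "green"),
      band("protein", 995, 1010, "protein", "none"),
      band("noise",   500,  520, "noise",   "none")
    ),
    assignment_bands = list(
      band("DNA_660_690",     660,  690, "DNA"),
      band("DNA_790_805",     790,  805, "DNA"),
      band("DNA_1300_1350",  1300, 1350, "DNA"),
      band("RNA_805_850",     805,  850, "RNA"),
      band("RNA_1510",       1505, 1515, "RNA"),
      band("heme_730_765",    730,  765, "heme"),
      band("lipid_700_730",   700,  730, "lipid"),
      band("lipid_1300_1330", 1300, 1330, "lipid"),
      band("lipid_1430_1470", 1430, 1470, "lipid"),
      band("protein_1000_1010", 1000, 1010, "protein"),
      band("protein_1360_1370", 1360, 1370, "protein")
    )
  )
}

#' Serialize / restore a band registry as JSON
#'
#' @param reg a [band_registry()].
#' @param path file path.
#' @return `write_registry` returns `path` invisibly; `read_registry`
#'   returns the registry.
#' @export
write_registry <- function(reg, path) {
  stopifnot(inherits(reg, "band_registry"))
  strip <- function(bl) lapply(unname(bl), unclass)
  jsonlite::write_json(list(imaging_bands = strip(reg$imaging_bands),
                            assignment_bands = strip(reg$assignment_bands)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  x <- jsonlite::read_json(path)
  mk <- function(e) band(e$name, e$lo, e$hi, e$molecule_class, e$channel)
  band_registry(lapply(x$imaging_bands, mk), lapply(x$assignment_bands, mk))
}

# ---- spectrum I/O ------------------------------------------------------

#' Read a single spectrum from a text file
#'
#' Accepts two dialects: `"two-column"` (wavenumber, intensity per line,
#' `#` comments allowed, whitespace or comma separated) and `"long-table"`
#' (CSV with `wavenumber` and `intensity` columns). Descending input axes
#' are reordered ascending (both columns together); duplicate wavenumbers
#' are an error.
#'
#' @param path file path.
#' @param dialect `"two-column"` (default) or `"long-table"`.
#' @return a [spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("two-column", "long-table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "two-column") {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    if (length(idx) == 0L) stop("no data rows in ", path)
    rows <- strsplit(trimws(lines[idx]), "[,;[:space:]]+")
    parsed <- lapply(seq_along(rows), function(i) {
      v <- suppressWarnings(as.numeric(rows[[i]]))
      if (length(v) < 2L || anyNA(v[1:2]))
        stop("parse error at line ", idx[i], " of ", path,
             ": expected two numeric columns, got '", lines[idx[i]], "'")
      v[1:2]
    })
    m <- do.call(rbind, parsed)
    wn <- m[, 1]; inten <- m[, 2]
  } else {
    df <- utils::read.csv(path, comment.char = "#")
    if (!all(c("wavenumber", "intensity") %in% names(df)))
      stop("long-table dialect needs 'wavenumber' and 'intensity' columns")
    wn <- as.numeric(df$wavenumber); inten <- as.numeric(df$intensity)
    if (anyNA(wn) || anyNA(inten))
      stop("parse error in ", path, ": non-numeric values at row(s) ",
           paste(which(is.na(wn) | is.na(inten)), collapse = ", "))
  }
  if (anyDuplicated(wn)) {
    dups <- unique(wn[duplicated(wn)])
    stop("duplicate wavenumber(s) in ", path, ": ",
         paste(format(dups), collapse = ", "))
  }
  o <- order(wn)
  spectrum(wn[o], inten[o], meta = list(path = path, dialect = dialect))
}

#' Write a spectrum as two-column text
#'
#' @param s a [spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  writeLines(c("# wavenumber_cm-1 intensity",
               sprintf("%.17g %.17g", s$axis, s$intensities)), path)
  invisible(path)
}

# ---- cube I/O ----------------------------------------------------------

#' Write a hyperspectral cube to a plain-text container
#'
#' Native `"matrix"` format: comment header carrying dimensions, pixel
#' pitch and the axis, then one line per pixel (`row col i1 ... iK`).
#' `"long"` is the long-table CSV fallback (`row,col,wavenumber,intensity`).
#' Both round-trip to full double precision (`%.17g`), bit-exact for
#' integer-valued data.
#'
#' @param img a [hyper_image()].
#' @param path output path.
#' @param format `"matrix"` (default, compact) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(img, path, format = c("matrix", "long")) {
  stopifnot(inherits(img, "hyper_image"))
  format <- match.arg(format)
  d <- dim(img$cube)
  if (format == "matrix") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# sersmap-cube v1",
                 sprintf("# dim: %d %d %d", d[1], d[2], d[3]),
                 sprintf("# pixel_pitch_um: %.17g", img$pixel_pitch_um),
                 paste0("# axis: ", paste(sprintf("%.17g", img$axis),
                                          collapse = " "))), con)
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2]))
        writeLines(paste(i, j, paste(sprintf("%.17g", img$cube[i, j, ]),
                                     collapse = " ")), con)
  } else {
    grid <- expand.grid(k = seq_len(d[3]), col = seq_len(d[2]),
                        row = seq_len(d[1]))
    df <- data.frame(row = grid$row, col = grid$col,
                     wavenumber = img$axis[grid$k],
                     intensity = img$cube[cbind(grid$row, grid$col, grid$k)])
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# sersmap-cube-long v1 pixel_pitch_um: %.17g",
                       img$pixel_pitch_um), con)
    writeLines("row,col,wavenumber,intensity", con)
    writeLines(sprintf("%d,%d,%.17g,%.17g", df$row, df$col,
                       df$wavenumber, df$intensity), con)
  }
  invisible(path)
}

#' Read a hyperspectral cube written by [write_cube()]
#'
#' Auto-detects the native matrix container and the long-table CSV
#' fallback from the header line.
#'
#' @param path file path.
#' @return a [hyper_image()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^# sersmap-cube v1", first)) {
    lines <- readLines(path, warn = FALSE)
    hdr <- lines[grepl("^#", lines)]
    dimline <- sub("^# dim:\\s*", "", grep("^# dim:", hdr, value = TRUE))
    d <- as.integer(strsplit(trimws(dimline), "\\s+")[[1]])
    pitch <- as.numeric(sub("^# pixel_pitch_um:\\s*", "",
                            grep("^# pixel_pitch_um:", hdr, value = TRUE)))
    axis <- as.numeric(strsplit(trimws(
      sub("^# axis:\\s*", "", grep("^# axis:", hdr, value = TRUE))), "\\s+")[[1]])
    if (length(axis) != d[3])
      stop("cube header inconsistent: axis length ", length(axis),
           " != K = ", d[3])
    body <- lines[!grepl("^#", lines)]
    body <- body[nzchar(trimws(body))]
    if (length(body) != d[1] * d[2])
      stop("cube body has ", length(body), " pixel rows, expected ",
           d[1] * d[2])
    cube <- array(NA_real_, dim = d)
    for (ln in body) {
      v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      if (length(v) != 2L + d[3])
        stop("cube row length mismatch: got ", length(v) - 2L,
             " samples, expected ", d[3])
      cube[v[1], v[2], ] <- v[-(1:2)]
    }
  } else if (grepl("^# sersmap-cube-long v1", first)) {
    pitch <- as.numeric(sub(".*pixel_pitch_um:\\s*", "", first))
    df <- utils::read.csv(path, comment.char = "#")
    axis <- sort(unique(df$wavenumber))
    H <- max(df$row); W <- max(df$col); K <- length(axis)
    if (nrow(df) != H * W * K)
      stop("long-table cube is ragged: ", nrow(df), " rows for ",
           H, "x", W, "x", K)
    cube <- array(NA_real_, dim = c(H, W, K))
    kk <- match(df$wavenumber, axis)
    cube[cbind(df$row, df$col, kk)] <- df$intensity
  } else {
    stop("not a sersmap cube container: ", path)
  }
  hyper_image(axis, cube, pitch)
}
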