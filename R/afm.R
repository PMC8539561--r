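# AFM scratch-thickness: flatten the height map background, histogram
# heights around the scratch, and read the layer thickness as the
# separation of the two histogram peaks (substrate floor vs film
# surface).

#' Construct an AFM height map
#'
#' @param heights numeric H x W matrix of heights in nm.
#' @param pixel_pitch_nm lateral pixel size in nm (> 0).
#' @param scratch_mask optional logical H x W matrix marking the
#'   scratched region; when present, [thickness_from_histogram()]
#'   histograms only the mask plus a dilated border so the two height
#'   populations are localized.
#' @return an object of class `"height_map"`.
#' @export
height_map <- function(heights, pixel_pitch_nm = 1, scratch_mask = NULL) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("heights must be a numeric matrix")
  if (!all(is.finite(heights))) stop("heights must be finite")
  if (!is.numeric(pixel_pitch_nm) || pixel_pitch_nm <= 0)
    stop("pixel_pitch_nm must be positive")
  if (!is.null(scratch_mask)) {
    if (!is.logical(scratch_mask) || !identical(dim(scratch_mask),
                                                dim(heights)))
      stop("scratch_mask must be a logical matrix matching heights")
  }
  structure(list(heights = heights, pixel_pitch_nm = pixel_pitch_nm,
                 scratch_mask = scratch_mask),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px, pitch %g nm, heights %.2f..%.2f nm%s\n",
              nrow(x$heights), ncol(x$heights), x$pixel_pitch_nm,
              min(x$heights), max(x$heights),
              if (!is.null(x$scratch_mask)) ", with scratch mask" else ""))
  invisible(x)
}

#' Read an ASCII matrix height map export
#'
#' Whitespace-separated values, one image row per line; `#` comment
#' lines (as in Gwyddion ASCII exports) are skipped. Values are taken as
#' nm unless a `# pixel_pitch_nm:` comment overrides the pitch.
#'
#' @param path file path.
#' @param pixel_pitch_nm pitch fallback when the file has no header.
#' @return a [height_map()].
#' @export
read_height_map <- function(path, pixel_pitch_nm = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  pl <- grep("pixel_pitch_nm:", hdr, value = TRUE)
  if (length(pl))
    pixel_pitch_nm <- as.numeric(sub(".*pixel_pitch_nm:\\s*", "", pl[1]))
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                              "[,;[:space:]]+")[[1]]))
    if (anyNA(v)) stop("non-numeric height at data row ", i, " of ", path)
    v
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged height matrix in ", path)
  height_map(do.call(rbind, rows), pixel_pitch_nm)
}

#' Remove a polynomial background surface
#'
#' Least-squares fit of a 2-D polynomial of total degree 0 (mean), 1
#' (plane) or 2 (quadric) in the pixel coordinates, subtracted from the
#' heights. When a scratch mask is present the surface is fitted on the
#' unscratched pixels only (a scratch aligned with the scan would
#' otherwise tilt the fit and bias the step), and the flattened
#' background has mean ~ 0. This is the "background subtraction" step
#' preceding the height histogram.
#'
#' @param h a [height_map()].
#' @param degree 0, 1 or 2.
#' @return a flattened [height_map()] (mask and pitch preserved).
#' @export
flatten <- function(h, degree = 1L) {
  stopifnot(inherits(h, "height_map"))
  degree <- as.integer(degree)
  if (!degree %in% 0:2) stop("degree must be 0, 1 or 2")
  z <- h$heights
  H <- nrow(z); W <- ncol(z)
  # centered, scaled pixel coordinates for conditioning
  r <- (row(z) - (H + 1) / 2) / max(H / 2, 1)
  c_ <- (col(z) - (W + 1) / 2) / max(W / 2, 1)
  X <- switch(as.character(degree),
              "0" = cbind(rep(1, H * W)),
              "1" = cbind(1, as.vector(r), as.vector(c_)),
              "2" = cbind(1, as.vector(r), as.vector(c_),
                          as.vector(r)^2, as.vector(r * c_), as.vector(c_)^2))
  if (H * W < ncol(X))
    stop("degenerate fit: ", H * W, " pixels for ", ncol(X), " coefficients")
  # fit the background on unscratched pixels only (a scratch correlated
  # with the scan direction would otherwise tilt the surface and bias the
  # step); subtract it everywhere
  keep <- if (!is.null(h$scratch_mask)) !as.vector(h$scratch_mask)
          else rep(TRUE, H * W)
  if (sum(keep) < ncol(X))
    stop("degenerate fit: ", sum(keep), " background pixels for ",
         ncol(X), " coefficients")
  beta <- qr.coef(qr(X[keep, , drop = FALSE]), as.vector(z)[keep])
  surf <- matrix(X %*% beta, H, W)
  height_map(z - surf, h$pixel_pitch_nm, h$scratch_mask)
}

# square dilation of a logical mask by `r` pixels
.dilate <- function(mask, r) {
  out <- mask
  H <- nrow(mask); W <- ncol(mask)
  for (di in -r:r) for (dj in -r:r) {
    si <- max(1, 1 - di):min(H, H - di)
    sj <- max(1, 1 - dj):min(W, W - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] | mask[si, sj]
  }
  out
}

# local maxima of histogram counts with simple topographic prominence
.hist_modes <- function(counts) {
  n <- length(counts)
  if (n < 3) return(integer(0))
  i <- which(counts[2:(n - 1)] > counts[1:(n - 2)] &
               counts[2:(n - 1)] >= counts[3:n]) + 1L
  if (counts[1] > counts[2]) i <- c(1L, i)
  if (counts[n] > counts[n - 1]) i <- c(i, n)
  i
}

#' Layer thickness from the height-distribution peaks
#'
#' Histograms the flattened heights (restricted to the scratch mask plus
#' an 8-pixel dilated neighborhood when a mask is present), locates the
#' two most prominent modes — the substrate floor exposed by the scratch
#' and the surrounding film surface — refines each mode center by
#' parabolic interpolation over its three surrounding bins (on log
#' counts, exact for Gaussian-shaped modes), and reports the absolute
#' separation as the layer thickness. The bin grid is anchored at the
#' data minimum, so the result is exactly invariant under a constant
#' height offset.
#'
#' @param h a flattened [height_map()].
#' @param bin_width histogram bin width in nm; default
#'   `max(0.1, Freedman-Diaconis estimate)`.
#' @param min_prominence_frac a mode must rise above this fraction of
#'   the tallest bin (default 0.05) and above 3 standard deviations of
#'   its counting noise to count.
#' @return list with `thickness` (nm), `peaks` (the two refined centers,
#'   ascending), `bin_width`, and the `histogram` (`mids`, `counts`).
#' @export
thickness_from_histogram <- function(h, bin_width = NULL,
                                     min_prominence_frac = 0.05) {
  stopifnot(inherits(h, "height_map"))
  z <- h$heights
  if (!is.null(h$scratch_mask)) {
    sel <- .dilate(h$scratch_mask, 8L)
    z <- z[sel]
  }
  z <- as.vector(z)
  if (is.null(bin_width)) {
    iqr <- stats::IQR(z)
    fd <- if (iqr > 0) 2 * iqr / length(z)^(1 / 3) else 0
    bin_width <- max(0.1, fd)
  }
  if (bin_width <= 0) stop("bin_width must be positive")
  # anchor the grid at the data minimum so the histogram (and therefore
  # the thickness) is exactly invariant under a constant height offset
  lo <- min(z) - bin_width
  nb <- ceiling((max(z) - lo) / bin_width) + 1L
  breaks <- lo + bin_width * (0:nb)
  hh <- graphics::hist(z, breaks = breaks, plot = FALSE)
  counts <- hh$counts; mids <- hh$mids
  modes <- .hist_modes(counts)
  # merge neighbouring local maxima whose connecting valley is shallower
  # than the counting noise: they are wiggles on one population, not two
  # populations (keeps the taller; ties keep the earlier)
  modes <- sort(modes)
  repeat {
    if (length(modes) < 2L) break
    merged <- FALSE
    for (k in seq_len(length(modes) - 1L)) {
      a <- modes[k]; b <- modes[k + 1L]
      valley <- min(counts[a:b])
      if (min(counts[a], counts[b]) - valley < 3 * sqrt(max(counts[a],
                                                            counts[b]))) {
        drop <- if (counts[a] >= counts[b]) k + 1L else k
        modes <- modes[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  if (length(modes)) {
    prom <- vapply(modes, function(i) .prominence(counts, i), numeric(1))
    # a mode must beat both the relative floor and the counting noise of
    # the tallest bin, else pure shot noise reads as bimodality
    thr <- max(min_prominence_frac * max(counts), 3 * sqrt(max(counts)))
    keep <- prom >= thr
    modes <- modes[keep]; prom <- prom[keep]
  }
  if (length(modes) < 2L)
    stop("no bimodal height distribution: found ", length(modes),
         " mode(s) above prominence; is there a scratch in the map?")
  o <- order(-prom)
  two <- sort(modes[o[1:2]])
  refine <- function(i) {
    if (i <= 1L || i >= length(counts)) return(mids[i])
    l <- counts[i - 1]; m <- counts[i]; r <- counts[i + 1]
    # Gaussian-shaped modes: a parabola on log counts is exact, so prefer
    # it; fall back to the plain parabola when a neighbour bin is empty
    if (l > 0 && r > 0 && m > 0) {
      ll <- log(l); lm <- log(m); lr <- log(r)
      den <- ll - 2 * lm + lr
      if (den < 0) return(mids[i] + 0.5 * (ll - lr) / den * bin_width)
    }
    den <- l - 2 * m + r
    if (den == 0) return(mids[i])
    mids[i] + 0.5 * (l - r) / den * bin_width
  }
  centers <- vapply(two, refine, numeric(1))
  list(thickness = abs(diff(centers)), peaks = sort(centers),
       bin_width = bin_width,
       histogram = list(mids = mids, counts = counts))
}
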