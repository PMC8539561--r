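# Rendering of band-RMS maps: linear grayscale on a shared display range
# (0-60 normalized RMS by default, the scale used for published cell
# composites) and the merged RGB overlay with DNA->red, RNA->green,
# heme->blue channel semantics.

#' Display range for map rendering
#'
#' @param lo,hi range endpoints, `lo < hi`; defaults 0 and 60 (the shared
#'   normalized-RMS scale).
#' @return an object of class `"display_range"`.
#' @export
display_range <- function(lo = 0, hi = 60) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("display range needs finite lo < hi, got [", lo, ", ", hi, "]")
  structure(list(lo = lo, hi = hi), class = "display_range")
}

# linear transfer with clip and half-up rounding to 8-bit
.gray_value <- function(v, r) {
  t <- (v - r$lo) / (r$hi - r$lo)
  floor(255 * pmin(pmax(t, 0), 1) + 0.5)
}

#' Render a map to 8-bit grayscale
#'
#' Value `v` maps to `round(255 * clip((v - lo)/(hi - lo), 0, 1))` with
#' half-up rounding. Missing pixels render as 0 and are recorded in an
#' alpha mask (255 = present, 0 = missing); nothing is interpolated.
#'
#' @param m a `"band_stat_map"` (or plain numeric matrix).
#' @param r a [display_range()].
#' @return a `"gray_image"`: integer matrix in 0..255 with attribute
#'   `alpha` (same shape, 0/255).
#' @export
to_gray <- function(m, r = display_range()) {
  stopifnot(inherits(r, "display_range"))
  v <- unclass(m)
  if (!is.matrix(v)) stop("to_gray expects a matrix-like map")
  miss <- is.na(v)
  g <- matrix(0L, nrow(v), ncol(v))
  g[!miss] <- as.integer(.gray_value(v[!miss], r))
  alpha <- matrix(255L, nrow(v), ncol(v))
  alpha[miss] <- 0L
  structure(g, class = c("gray_image", "matrix", "array"), alpha = alpha,
            range = r)
}

#' Assemble an RGB composite from three maps
#'
#' @param red,green,blue `"band_stat_map"` objects of identical shape;
#'   by default semantics DNA->red, RNA->green, heme->blue.
#' @param range shared [display_range()] applied to all three channels.
#' @param channel_semantics named character vector mapping channel to
#'   molecule label.
#' @return an object of class `"rgb_composite"`.
#' @export
rgb_composite <- function(red, green, blue, range = display_range(),
                          channel_semantics = c(red = "DNA", green = "RNA",
                                                blue = "heme")) {
  dims <- lapply(list(red, green, blue), dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("channel maps differ in shape: ",
         paste(vapply(dims, paste, character(1), collapse = "x"),
               collapse = " vs "))
  stopifnot(inherits(range, "display_range"))
  structure(list(red = red, green = green, blue = blue, range = range,
                 channel_semantics = channel_semantics),
            class = "rgb_composite")
}

#' Merge an RGB composite into an 8-bit 3-channel image
#'
#' Each channel is rendered independently through [to_gray()] with the
#' one shared display range, so relative channel ordering at a pixel is
#' preserved under any common rescaling of the maps.
#'
#' @param c an [rgb_composite()].
#' @return H x W x 3 integer array in 0..255 with attribute `alpha`
#'   (255 where any channel is present).
#' @export
merge_rgb <- function(c) {
  stopifnot(inherits(c, "rgb_composite"))
  ch <- lapply(list(c$red, c$green, c$blue), to_gray, r = c$range)
  H <- nrow(ch[[1]]); W <- ncol(ch[[1]])
  out <- array(0L, c(H, W, 3))
  for (k in 1:3) out[, , k] <- unclass(ch[[k]])
  alpha <- pmax(attr(ch[[1]], "alpha"), attr(ch[[2]], "alpha"),
                attr(ch[[3]], "alpha"))
  structure(out, alpha = alpha, range = c$range,
            channel_semantics = c$channel_semantics)
}

#' Write grayscale / RGB images as plain-text netpbm
#'
#' `write_pgm` writes an ASCII PGM (P2) file; `write_ppm` an ASCII PPM
#' (P3). Plain-text rasters keep the pipeline free of binary
#' dependencies and open in any image viewer.
#'
#' @param img a `"gray_image"` (PGM) or H x W x 3 integer array (PPM).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  g <- unclass(img)
  stopifnot(is.matrix(g))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
  writeLines(apply(g, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
write_ppm <- function(img, path) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  H <- dim(img)[1]; W <- dim(img)[2]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(W, H), "255"), con)
  rows <- vapply(seq_len(H), function(i) {
    trip <- rbind(img[i, , 1], img[i, , 2], img[i, , 3])
    paste(as.vector(trip), collapse = " ")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}
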