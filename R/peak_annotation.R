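# Peak detection in baseline-subtracted spectra and annotation against a
# curated wavenumber -> biomolecule table. Ambiguous assignments (e.g.
# 720 cm^-1: adenine in DNA or phospholipids) are preserved as multiple
# hits; contextual disambiguation is a separate, explicit rule.

#' The built-in wavenumber assignment table
#'
#' A data frame of class `"assignment_table"` seeding the in-text
#' assignments used for live-cell SERS spectra: ring and backbone
#' vibrations of DNA/RNA nucleotides, mitochondrial cytochrome hemes
#' (heme C at 750, heme B at 760 cm^-1), protein, lipid and carbohydrate
#' modes, and the small substrate peaks registered from nanostructures
#' outside a cell. Entries carry either a `center` (matched within a
#' tolerance) or a `[lo, hi]` window (matched by containment), plus a
#' molecule label, free-text note and source tag. The table is
#' extensible: `rbind` more rows with the same columns.
#'
#' @return data frame with columns `center`, `lo`, `hi`, `molecule`,
#'   `note`, `source`.
#' @export
assignment_table <- function() {
  e <- function(center, lo, hi, molecule, note)
    data.frame(center = center, lo = lo, hi = hi, molecule = molecule,
               note = note, source = "sersmap built-in v1",
               stringsAsFactors = FALSE)
  tab <- rbind(
    e(645, NA, NA, "other",   "[Fe-S] cluster, mitochondrial electron transfer chain"),
    e(670, NA, NA, "DNA",     "DNA nucleotide ring vibration"),
    e(692, NA, NA, "DNA",     "DNA nucleotide ring vibration"),
    e(720, NA, NA, "DNA",     "adenine"),
    e(720, NA, NA, "lipid",   "phospholipids"),
    e(790, NA, NA, "DNA",     "cytosine, most intensive DNA peak"),
    e(802, NA, NA, "DNA",     "DNA backbone"),
    e(1330, NA, NA, "DNA",    "DNA nucleotides"),
    e(NA, 745, 760, "heme",   "hemes in mitochondrial cytochromes"),
    e(750, NA, NA, "heme",    "heme C"),
    e(760, NA, NA, "heme",    "heme B"),
    e(1206, NA, NA, "heme",   "hemes in mitochondrial cytochromes"),
    e(775, NA, NA, "RNA",     "RNA nucleotide"),
    e(812, NA, NA, "RNA",     "RNA-specific"),
    e(822, NA, NA, "RNA",     "RNA nucleotide"),
    e(833, NA, NA, "RNA",     "RNA bond vibrations"),
    e(1510, NA, NA, "RNA",    "RNA-specific"),
    e(1000, NA, NA, "protein", "phenylalanine ring breathing region"),
    e(1141, NA, NA, "protein", "protein/lipid C-C"),
    e(1180, NA, NA, "protein", "protein mode"),
    e(1200, NA, NA, "protein", "protein mode"),
    e(1225, NA, NA, "protein", "amide III region"),
    e(1350, NA, NA, "protein", "protein/lipid CH deformation"),
    e(NA, 1360, 1370, "protein", "protein window"),
    e(1570, NA, NA, "protein", "protein mode"),
    e(1078, NA, NA, "lipid",  "alkyl C-C gauche stretch"),
    e(NA, 1260, 1280, "lipid", "lipid window, nuclear membrane"),
    e(1270, NA, NA, "lipid",  "unsaturated fatty acids"),
    e(1445, NA, NA, "lipid",  "C-H2 bend, most intensive lipid peak"),
    e(1446, NA, NA, "lipid",  "C-H2 bend, lipids and proteins"),
    e(912, NA, NA, "carbohydrate", "carbohydrate mode"),
    e(1120, NA, NA, "carbohydrate", "glycoproteins"),
    e(1010, NA, NA, "substrate", "registered from nanostructures outside a cell"),
    e(1065, NA, NA, "substrate", "registered from nanostructures outside a cell"),
    e(1203, NA, NA, "substrate", "registered from nanostructures outside a cell")
  )
  bad <- !is.na(tab$lo) & !(tab$lo < tab$hi)
  stopifnot(!any(bad))
  class(tab) <- c("assignment_table", "data.frame")
  tab
}

#' Serialize / restore an assignment table as JSON
#' @param tab an [assignment_table()].
#' @param path file path.
#' @return `write_assignment_table` returns `path` invisibly.
#' @export
write_assignment_table <- function(tab, path) {
  jsonlite::write_json(as.data.frame(tab), path, auto_unbox = FALSE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_assignment_table
#' @export
read_assignment_table <- function(path) {
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("center", "lo", "hi", "molecule", "note", "source")
                %in% names(tab)))
  class(tab) <- c("assignment_table", "data.frame")
  tab
}

# prominence of local maximum at index i: height minus the higher of the
# two valley floors between the peak and the nearest higher terrain (or
# signal edge) on each side -- the standard topographic definition
.prominence <- function(y, i) {
  h <- y[i]
  left <- if (i > 1) {
    seg <- y[(i - 1):1]
    stopi <- which(seg > h)[1]
    if (is.na(stopi)) min(seg) else min(seg[seq_len(stopi)])
  } else NA_real_
  right <- if (i < length(y)) {
    seg <- y[(i + 1):length(y)]
    stopi <- which(seg > h)[1]
    if (is.na(stopi)) min(seg) else min(seg[seq_len(stopi)])
  } else NA_real_
  base <- suppressWarnings(max(left, right, na.rm = TRUE))
  if (!is.finite(base)) return(0)  # single-sample signal
  h - base
}

#' Detect peaks in a baseline-subtracted spectrum
#'
#' Local maxima with topographic prominence of at least
#' `min_prominence`; peaks closer than `min_separation` are thinned
#' keeping the taller one. Deterministic; result ordered by position.
#'
#' @param s a [spectrum()], baseline-subtracted.
#' @param min_prominence minimum prominence (> 0) in intensity units.
#' @param min_separation minimum distance (> 0) between retained peaks,
#'   in cm^-1.
#' @return data frame with columns `position` (cm^-1), `height`,
#'   `prominence`; zero rows when nothing qualifies.
#' @export
detect_peaks <- function(s, min_prominence, min_separation = 5) {
  stopifnot(inherits(s, "spectrum"))
  if (!is.numeric(min_prominence) || min_prominence <= 0)
    stop("min_prominence must be positive")
  if (!is.numeric(min_separation) || min_separation <= 0)
    stop("min_separation must be positive")
  y <- s$intensities
  n <- length(y)
  empty <- data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  cand <- cand[y[cand] > 0]
  if (length(cand) == 0L) return(empty)
  prom <- vapply(cand, function(i) .prominence(y, i), numeric(1))
  keep <- prom >= min_prominence & prom > 0
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0L) return(empty)
  # thin by separation, tallest first (ties: leftmost first, stable)
  o <- order(-y[cand], s$axis[cand])
  sel <- logical(length(cand))
  for (k in o) {
    if (!any(sel & abs(s$axis[cand] - s$axis[cand[k]]) < min_separation))
      sel[k] <- TRUE
  }
  cand <- cand[sel]; prom <- prom[sel]
  o2 <- order(s$axis[cand])
  data.frame(position = s$axis[cand][o2], height = y[cand][o2],
             prominence = prom[o2])
}

#' Look up assignments for a detected peak
#'
#' Returns every table entry whose center lies within `tolerance` of the
#' peak position, or whose window contains it. Ambiguity is preserved:
#' multiple hits come back as multiple rows, sorted by absolute distance
#' (0 for containing windows), stably.
#'
#' @param position peak position in cm^-1 (or a one-row data frame from
#'   [detect_peaks()]).
#' @param table an [assignment_table()].
#' @param tolerance match tolerance in cm^-1 (> 0), default 5 (the same
#'   vibration is quoted several cm^-1 apart across cell spectra).
#' @return subset of `table` rows with an extra `delta` column.
#' @export
assign_peak <- function(position, table = assignment_table(), tolerance = 5) {
  if (is.data.frame(position)) position <- position$position[1]
  stopifnot(is.numeric(position), length(position) == 1L)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be positive")
  delta <- ifelse(!is.na(table$center), abs(table$center - position),
                  ifelse(position >= table$lo & position <= table$hi, 0,
                         pmin(abs(position - table$lo),
                              abs(position - table$hi))))
  hit <- (!is.na(table$center) & delta <= tolerance) |
    (is.na(table$center) & position >= table$lo & position <= table$hi)
  out <- table[hit, , drop = FALSE]
  out$delta <- delta[hit]
  out[order(out$delta), , drop = FALSE]
}

#' Annotate every detected peak of a spectrum
#'
#' @param s baseline-subtracted [spectrum()].
#' @param table an [assignment_table()].
#' @param min_prominence,min_separation passed to [detect_peaks()].
#' @param tolerance passed to [assign_peak()].
#' @return data frame: one row per (peak, assignment) pair; peaks with no
#'   match appear once with `molecule = NA`.
#' @export
annotate_spectrum <- function(s, table = assignment_table(),
                              min_prominence, min_separation = 5,
                              tolerance = 5) {
  pk <- detect_peaks(s, min_prominence, min_separation)
  if (nrow(pk) == 0L)
    return(cbind(pk, molecule = character(0), note = character(0),
                 source = character(0), delta = numeric(0)))
  rows <- lapply(seq_len(nrow(pk)), function(i) {
    hits <- assign_peak(pk$position[i], table, tolerance)
    if (nrow(hits) == 0L)
      hits <- data.frame(center = NA_real_, lo = NA_real_, hi = NA_real_,
                         molecule = NA_character_, note = NA_character_,
                         source = NA_character_, delta = NA_real_)
    cbind(pk[rep(i, nrow(hits)), , drop = FALSE],
          hits[, c("molecule", "note", "source", "delta")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Disambiguate the 720 cm^-1 adenine / phospholipid peak
#'
#' 720 cm^-1 can come from adenine in DNA or from phospholipids. The
#' contextual rule: if the most intensive lipid peak (1445 cm^-1 region)
#' is absent from the spectrum, 720 is read as adenine; if 1445 is
#' present and no DNA bands co-occur, as phospholipid; with both lines of
#' evidence present the call is ambiguous.
#'
#' @param s baseline-subtracted [spectrum()] with a detectable peak near
#'   720 cm^-1 (error otherwise).
#' @param table an [assignment_table()].
#' @param min_prominence detection prominence threshold (> 0).
#' @param min_separation,tolerance as in [detect_peaks()] /
#'   [assign_peak()].
#' @return one of `"adenine"`, `"phospholipid"`, `"ambiguous"`.
#' @export
disambiguate_adenine_lipid <- function(s, table = assignment_table(),
                                       min_prominence, min_separation = 5,
                                       tolerance = 5) {
  pk <- detect_peaks(s, min_prominence, min_separation)
  near720 <- abs(pk$position - 720) <= tolerance
  if (!any(near720))
    stop("no detected peak near 720 cm^-1; nothing to disambiguate")
  has1445 <- any(pk$position >= 1440 & pk$position <= 1450)
  if (!has1445) return("adenine")
  others <- pk$position[!near720]
  dna_cooccur <- any(vapply(others, function(p) {
    hits <- assign_peak(p, table, tolerance)
    any(hits$molecule == "DNA", na.rm = TRUE)
  }, logical(1)))
  if (!dna_cooccur) "phospholipid" else "ambiguous"
}
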