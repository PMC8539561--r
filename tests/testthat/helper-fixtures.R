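# shared fixtures built in code; no binary files

ax_default <- function() seq(400, 1800, by = 1)

lorentzian <- function(axis, center, fwhm, amp) {
  g <- fwhm / 2
  amp * g^2 / ((axis - center)^2 + g^2)
}

# a small phantom shared by several files; built once per test run
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(phantom_params(size = 32, coverage = 0.4),
                                 seed = 11)
    cache
  }
})

# naive RMS loop, the independent oracle for band_rms
naive_band_rms <- function(axis, intensities, lo, hi) {
  tot <- 0; n <- 0L
  for (k in seq_along(axis)) {
    if (axis[k] >= lo && axis[k] <= hi) {
      tot <- tot + intensities[k]^2
      n <- n + 1L
    }
  }
  sqrt(tot / n)
}
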