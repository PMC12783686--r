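# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities by brute force so they stay
# independent of the package implementation they check.

# brute-force peak prominence: base on each side = minimum between the
# peak and the nearest strictly-higher sample (profile edge if none)
oracle_prominence <- function(v, i) {
  h <- v[i]
  left_hi <- which(v[seq_len(i - 1)] > h)
  l <- if (length(left_hi)) max(left_hi) else 1L
  base_l <- if (i == 1) h else min(v[l:(i - 1)])
  right_hi <- which(v > h & seq_along(v) > i)
  r <- if (length(right_hi)) min(right_hi) else length(v)
  base_r <- if (i == length(v)) h else min(v[(i + 1):r])
  h - max(base_l, base_r)
}

# brute-force interior local maxima (plateaus -> center index)
oracle_local_maxima <- function(v) {
  n <- length(v)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (v[i] <= v[i - 1]) next
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    if (j < n && v[j + 1] < v[i]) out <- c(out, floor((i + j) / 2))
  }
  out
}

# noiseless single-Gaussian raw profile on a positive baseline
gauss_profile <- function(n, center, fwhm_nm, amp, baseline = 1,
                          pixel_size_nm = 100) {
  x <- seq_len(n) - 1
  sigma_px <- fwhm_nm / (2 * sqrt(2 * log(2))) / pixel_size_nm
  as_line_profile(baseline + amp * exp(-(x - center)^2 / (2 * sigma_px^2)),
                  pixel_size_nm = pixel_size_nm)
}

# a simple two-level disk field built directly (no synthgen), for
# cross-checking the generator and the segmenter against each other
manual_disk_field <- function(dims, centers, radius, interior, exterior,
                              pixel_size_nm = 120) {
  h <- dims[2]; w <- dims[1]
  img <- matrix(exterior, h, w)
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if ((j - 1 - centers[k, 1])^2 + (i - 1 - centers[k, 2])^2 <= radius^2)
        img[i, j] <- interior
    }
  }
  multichannel_field(list(main = img), pixel_size_nm = pixel_size_nm)
}
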