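#' Extract an averaged line profile along a polyline
#'
#' Samples the image at 1-px steps along the polyline; each sample is the
#' mean over `width` pixels perpendicular to the local direction, with
#' bilinear interpolation for off-grid coordinates. This mirrors the
#' wide-line profile readout used to trace cell-cell contacts.
#'
#' @param image numeric matrix `[row = y, col = x]`.
#' @param polyline numeric matrix/data frame with columns `x`, `y` (0-based
#'   pixel coordinates, origin top-left), at least 2 vertices.
#' @param width averaging width in pixels (default 4).
#' @param pixel_size_nm physical pixel size (nm/px).
#'
#' @return An object of class `line_profile`: `position_px`, `position_um`,
#'   `intensity`, `width_px`, `pixel_size_nm`, `polyline`.
#' @export
extract_line_profile <- function(image, polyline, width = 4,
                                 pixel_size_nm = 100) {
  polyline <- as.matrix(polyline)[, c("x", "y"), drop = FALSE]
  if (nrow(polyline) < 2) stop("polyline needs at least 2 vertices")
  if (width < 1) stop("averaging width must be >= 1 px")
  # resample the polyline at unit arclength spacing
  seg <- diff(polyline)
  seglen <- sqrt(rowSums(seg^2))
  if (sum(seglen) <= 0) stop("polyline has zero length")
  cum <- c(0, cumsum(seglen))
  s <- seq(0, cum[length(cum)], by = 1)
  interp_pt <- function(si) {
    k <- findInterval(si, cum, rightmost.closed = TRUE)
    k <- min(k, nrow(polyline) - 1)
    f <- (si - cum[k]) / seglen[k]
    polyline[k, ] + f * seg[k, ]
  }
  pts <- t(vapply(s, interp_pt, numeric(2)))
  dirs <- t(vapply(pmin(s, cum[length(cum)] - 1e-9), function(si) {
    k <- min(findInterval(si, cum, rightmost.closed = TRUE),
             nrow(polyline) - 1)
    seg[k, ] / seglen[k]
  }, numeric(2)))
  normal <- cbind(-dirs[, 2], dirs[, 1])
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = width)
  vals <- vapply(seq_along(s), function(i) {
    px <- pts[i, 1] + offsets * normal[i, 1]
    py <- pts[i, 2] + offsets * normal[i, 2]
    mean(bilinear_sample(image, px, py))
  }, numeric(1))
  structure(list(position_px = s,
                 position_um = s * pixel_size_nm / 1000,
                 intensity = vals, width_px = width,
                 pixel_size_nm = pixel_size_nm, polyline = polyline),
            class = "line_profile")
}

# bilinear interpolation at 0-based (x, y); coordinates are clamped to the
# image so a width-w line hugging the border stays defined
bilinear_sample <- function(image, x, y) {
  h <- nrow(image); w <- ncol(image)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]
  i11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Wrap an intensity vector as a line profile
#'
#' Convenience constructor for profiles that already exist as sampled
#' vectors (e.g. simulated junction traces) rather than being read from an
#' image with [extract_line_profile()].
#'
#' @param intensity raw intensity samples (a.u.), 1-px spacing.
#' @param pixel_size_nm physical sample spacing (nm/px).
#' @param width_px nominal averaging width recorded with the profile.
#' @return An object of class `line_profile`.
#' @export
as_line_profile <- function(intensity, pixel_size_nm = 100, width_px = 4) {
  if (length(intensity) < 2) stop("a profile needs >= 2 samples")
  pos <- seq_along(intensity) - 1
  structure(list(position_px = pos,
                 position_um = pos * pixel_size_nm / 1000,
                 intensity = as.numeric(intensity), width_px = width_px,
                 pixel_size_nm = pixel_size_nm, polyline = NULL),
            class = "line_profile")
}

#' Rank-based baseline normalization of a line profile
#'
#' The baseline is the mean of the 20th through 40th smallest samples
#' (1-based ranks, inclusive: 21 values). Ranks in that band skip the very
#' darkest pixels (shot-noise outliers) while staying below cluster peaks,
#' so the baseline tracks the unclustered membrane level. The profile is
#' divided by the baseline, making cluster amplitudes fold-over-baseline.
#'
#' @param profile a [extract_line_profile()] result, or any list with
#'   `intensity`, `position_px`, `position_um`, `pixel_size_nm`.
#' @return An object of class `normalized_profile` with `intensity`
#'   (unitless), `baseline` (a.u.), `baseline_ranks`, and the positional
#'   fields of the input.
#' @export
normalize_profile <- function(profile) {
  v <- profile$intensity
  if (length(v) < 40)
    stop("profile has ", length(v), " samples; >= 40 are required so the ",
         "20th-40th lowest-rank baseline is defined")
  ranks <- 20:40
  baseline <- mean(sort(v)[ranks])
  if (baseline <= 0) stop("non-positive baseline; cannot normalize")
  structure(list(intensity = v / baseline, baseline = baseline,
                 baseline_ranks = ranks,
                 position_px = profile$position_px,
                 position_um = profile$position_um,
                 pixel_size_nm = profile$pixel_size_nm),
            class = "normalized_profile")
}

# prominence of a local maximum at index i: height minus the higher of the
# two bases, each base being the minimum between the peak and the nearest
# strictly-higher sample (or the profile edge)
.peak_prominence <- function(v, i) {
  h <- v[i]
  left <- if (i == 1) h else {
    j <- i - 1; m <- v[j]
    while (j > 1 && v[j] <= h) { j <- j - 1; m <- min(m, v[j]) }
    m
  }
  right <- if (i == length(v)) h else {
    j <- i + 1; m <- v[j]
    while (j < length(v) && v[j] <= h) { j <- j + 1; m <- min(m, v[j]) }
    m
  }
  h - max(left, right)
}

# indices of local maxima; a plateau reports its center sample
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (v[i] > v[i - 1]) {
      j <- i
      while (j < n && v[j + 1] == v[i]) j <- j + 1
      if (j <= n - 1 && v[j + 1] < v[i])
        out <- c(out, as.integer(floor((i + j) / 2)))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

#' Call cluster peaks on a normalized profile
#'
#' Local maxima whose prominence is at least `min_amplitude * (max - min)`
#' of the normalized profile are called as clusters. Prominence relative to
#' the profile's dynamic range implements the "minimal peak amplitude"
#' criterion of interactive peak finders; plateau maxima report their
#' center sample. A flat profile yields zero peaks.
#'
#' @param nprofile a [normalize_profile()] result.
#' @param min_amplitude minimum amplitude as a fraction of the dynamic
#'   range, in (0, 1); 0.5 suits endogenous expression levels, 0.25
#'   brighter exogenous expression.
#' @return An object of class `peak_set`: `indices` (0-based sample
#'   positions, ascending), `amplitudes` (prominence / dynamic range),
#'   `min_amplitude`, `n_samples`.
#' @export
detect_peaks <- function(nprofile, min_amplitude = 0.5) {
  if (!(min_amplitude > 0 && min_amplitude < 1))
    stop("min_amplitude must lie in (0, 1)")
  v <- nprofile$intensity
  rng <- max(v) - min(v)
  if (rng == 0)
    return(structure(list(indices = integer(0), amplitudes = numeric(0),
                          min_amplitude = min_amplitude,
                          n_samples = length(v)),
                     class = "peak_set"))
  cand <- .local_maxima(v)
  prom <- vapply(cand, function(i) .peak_prominence(v, i), numeric(1))
  amp <- prom / rng
  keep <- amp >= min_amplitude
  structure(list(indices = cand[keep] - 1L, amplitudes = amp[keep],
                 min_amplitude = min_amplitude, n_samples = length(v)),
            class = "peak_set")
}

#' Peak density per micrometer
#'
#' @param peaks a [detect_peaks()] result (or anything with `indices`).
#' @param length_um profile length in micrometers, `> 0`.
#' @return Peaks per um.
#' @export
peak_density <- function(peaks, length_um) {
  if (length_um <= 0) stop("profile length must be > 0 um")
  length(peaks$indices) / length_um
}

#' Fraction of reference peaks with a nearby partner-channel peak
#'
#' A reference peak counts as overlapping when at least one partner peak
#' lies within `window` samples (inclusive, symmetric); one partner peak
#' may satisfy several reference peaks. With zero reference peaks the
#' fraction is undefined (division by zero peaks) and `NA` is returned.
#'
#' @param reference_peaks,partner_peaks [detect_peaks()] results from
#'   profiles with identical sampling.
#' @param window maximum index distance in px, default 3.
#' @return Fraction in `[0, 1]`, or `NA` (not applicable).
#' @export
overlap_fraction <- function(reference_peaks, partner_peaks, window = 3) {
  ref <- reference_peaks$indices
  par <- partner_peaks$indices
  if (!length(ref)) return(NA_real_)
  if (!length(par)) return(0)
  hit <- vapply(ref, function(i) any(abs(par - i) <= window), logical(1))
  mean(hit)
}

#' Squared Pearson correlation of two normalized profiles
#'
#' @param nprofileA,nprofileB profiles of equal length (>= 3 samples).
#' @return R-squared in `[0, 1]`, or `NA` when either profile is constant
#'   (correlation undefined).
#' @export
profile_correlation <- function(nprofileA, nprofileB) {
  a <- nprofileA$intensity; b <- nprofileB$intensity
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (length(a) < 3) stop("need >= 3 samples")
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Gaussian-fit cluster size (FWHM)
#'
#' Fits `offset + A * exp(-(x - mu)^2 / (2 * sigma^2))` by bounded
#' Levenberg-Marquardt least squares within a window around a called peak
#' and reports the full width at half maximum,
#' `FWHM = 2 * sqrt(2 * ln 2) * sigma`, converted to nm via the pixel size.
#'
#' @param nprofile a [normalize_profile()] result.
#' @param peak_index 0-based sample index of the peak (from
#'   [detect_peaks()]).
#' @param fit_window half-width of the fit window in px; the window must
#'   hold at least 5 samples.
#' @return An object of class `cluster_shape`: `peak_index`, `sigma_nm`,
#'   `fwhm_nm`, `center_px`, `fit_window_px`, `r_squared`, `converged`.
#' @export
cluster_fwhm <- function(nprofile, peak_index, fit_window = 10) {
  v <- nprofile$intensity
  i0 <- peak_index + 1L  # to 1-based
  if (i0 < 1 || i0 > length(v)) stop("peak index outside the profile")
  lo <- max(1, i0 - fit_window); hi <- min(length(v), i0 + fit_window)
  if (hi - lo + 1 < 5) stop("fit window must contain >= 5 samples")
  x <- (lo:hi) - 1; y <- v[lo:hi]
  start <- list(offset = min(y), A = max(y) - min(y),
                mu = peak_index, sigma = max(fit_window / 4, 1))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + A * exp(-(x - mu)^2 / (2 * sigma^2)),
      start = start,
      lower = c(offset = -Inf, A = 1e-12, mu = lo - 1, sigma = 1e-3),
      upper = c(offset = Inf, A = Inf, mu = hi - 1,
                sigma = (hi - lo + 1)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(peak_index = peak_index, sigma_nm = NA_real_,
                          fwhm_nm = NA_real_, center_px = NA_real_,
                          fit_window_px = c(lo, hi) - 1,
                          r_squared = NA_real_, converged = FALSE),
                     class = "cluster_shape"))
  }
  cf <- coef(fit)
  sigma_nm <- unname(cf["sigma"]) * nprofile$pixel_size_nm
  resid <- y - predict(fit)
  r2 <- if (sd(y) == 0) NA_real_ else 1 - sum(resid^2) / sum((y - mean(y))^2)
  structure(list(peak_index = peak_index, sigma_nm = sigma_nm,
                 fwhm_nm = FWHM_SIGMA * sigma_nm,
                 center_px = unname(cf["mu"]),
                 fit_window_px = c(lo, hi) - 1,
                 r_squared = r2, converged = TRUE),
            class = "cluster_shape")
}

#' Summarize a two-channel contact: density, overlap, correlation, sizes
#'
#' @param raw1,raw2 raw `line_profile`s of the two channels (identical
#'   sampling).
#' @param min_amplitude peak amplitude fraction for both channels.
#' @param window overlap window in px.
#' @param fit_window FWHM fit half-window in px.
#' @return A list with the two `peak_set`s, `peaks_per_um` (channel 1),
#'   `overlap_fraction`, `r_squared` and a tibble of per-cluster FWHMs.
#' @export
analyze_contact <- function(raw1, raw2, min_amplitude = 0.5, window = 3,
                            fit_window = 10) {
  n1 <- normalize_profile(raw1)
  n2 <- normalize_profile(raw2)
  p1 <- detect_peaks(n1, min_amplitude)
  p2 <- detect_peaks(n2, min_amplitude)
  len_um <- max(raw1$position_um)
  shapes <- lapply(p1$indices, function(i) cluster_fwhm(n1, i, fit_window))
  sizes <- tibble::tibble(
    peak_index = p1$indices,
    fwhm_nm = vapply(shapes, `[[`, numeric(1), "fwhm_nm"),
    converged = vapply(shapes, `[[`, logical(1), "converged"))
  list(peaks1 = p1, peaks2 = p2,
       peaks_per_um = peak_density(p1, len_um),
       overlap_fraction = overlap_fraction(p1, p2, window),
       r_squared = profile_correlation(n1, n2),
       cluster_sizes = sizes)
}
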