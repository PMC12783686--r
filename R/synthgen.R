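#' @importFrom stats rnorm runif rbinom cor sd setNames coef predict median
#' @importFrom utils head tail
NULL

# Gaussian sigma <-> FWHM conversion constant, 2*sqrt(2*ln 2)
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

#' Ground truth for a synthetic droplet field
#'
#' Describes spherical condensate droplets rendered as disks on a uniform
#' dilute phase, with channel-specific interior/exterior levels, optional
#' cross-channel bleedthrough and additive Gaussian noise. The truth object
#' is the generative record against which downstream droplet metrics are
#' validated by parameter recovery.
#'
#' @param centers numeric matrix (n x 2) of droplet centers, columns `x`, `y`
#'   in 0-based pixel coordinates (origin top-left).
#' @param radii numeric vector of droplet radii in pixels, all `> 0`.
#' @param interior named list or matrix of per-channel interior levels
#'   (a.u.); one value per channel.
#' @param exterior per-channel exterior (dilute-phase) levels (a.u.).
#'   Interior must be `>=` exterior `>= 0` for each channel.
#' @param bleedthrough square mixing matrix, `bleedthrough[s, t]` = fraction
#'   of source channel `s` observed in target channel `t`; unit diagonal,
#'   off-diagonals in `[0, 1)`. Default: identity.
#' @param noise_sd additive Gaussian noise sd (a.u.), clipped at zero.
#' @param pixel_size_nm physical pixel size (nm/px); metadata only.
#' @param seed integer RNG seed recorded with the truth.
#'
#' @return An object of class `droplet_truth`.
#' @export
droplet_truth <- function(centers, radii, interior, exterior,
                          bleedthrough = NULL, noise_sd = 0,
                          pixel_size_nm = 120, seed = 1L) {
  centers <- matrix(as.numeric(centers), ncol = 2,
                    dimnames = list(NULL, c("x", "y")))
  radii <- as.numeric(radii)
  if (nrow(centers) != length(radii))
    stop("one radius per droplet center is required")
  if (length(radii) && any(radii <= 0)) stop("droplet radii must be > 0")
  interior <- unlist(interior)
  exterior <- unlist(exterior)
  if (is.null(names(interior)))
    names(interior) <- paste0("ch", seq_along(interior))
  if (is.null(names(exterior))) names(exterior) <- names(interior)
  if (!identical(sort(names(interior)), sort(names(exterior))))
    stop("interior and exterior must name the same channels")
  exterior <- exterior[names(interior)]
  if (any(exterior < 0) || any(interior < exterior))
    stop("channel levels must satisfy interior >= exterior >= 0")
  nch <- length(interior)
  if (is.null(bleedthrough)) bleedthrough <- diag(nch)
  bleedthrough <- as.matrix(bleedthrough)
  if (!all(dim(bleedthrough) == nch))
    stop("bleedthrough matrix must be ", nch, "x", nch)
  if (any(abs(diag(bleedthrough) - 1) > 1e-12))
    stop("bleedthrough matrix must have a unit diagonal")
  off <- bleedthrough[row(bleedthrough) != col(bleedthrough)]
  if (length(off) && (any(off < 0) || any(off >= 1)))
    stop("off-diagonal bleedthrough entries must lie in [0, 1)")
  dimnames(bleedthrough) <- list(names(interior), names(interior))
  structure(list(centers = centers, radii = radii, interior = interior,
                 exterior = exterior, bleedthrough = bleedthrough,
                 noise_sd = as.numeric(noise_sd),
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 seed = as.integer(seed)),
            class = "droplet_truth")
}

#' Render a synthetic multi-channel droplet field
#'
#' Each channel starts at its exterior level, droplet disks are overwritten
#' with the interior level (optionally blurred to emulate soft droplet
#' edges), channels are then mixed by the bleedthrough matrix, and finally
#' additive Gaussian noise (clipped at zero) is applied.
#'
#' @param truth a [droplet_truth()] object.
#' @param dims integer vector `c(width, height)` in pixels.
#' @param blur_sd optional Gaussian blur sd in pixels applied to the clean
#'   per-channel images before mixing; `0` (default) keeps hard-edged disks
#'   with exact two-level ground truth.
#'
#' @return A [multichannel_field()] with attribute `truth` carrying the
#'   generative record.
#' @export
gen_droplet_field <- function(truth, dims = c(256L, 256L), blur_sd = 0) {
  stopifnot(inherits(truth, "droplet_truth"))
  w <- as.integer(dims[1]); h <- as.integer(dims[2])
  if (nrow(truth$centers)) {
    fit <- truth$centers[, "x"] - truth$radii >= -0.5 &
      truth$centers[, "x"] + truth$radii <= w - 0.5 &
      truth$centers[, "y"] - truth$radii >= -0.5 &
      truth$centers[, "y"] + truth$radii <= h - 0.5
    if (!all(fit))
      stop("droplet(s) ", paste(which(!fit), collapse = ", "),
           " extend outside the ", w, "x", h, " field")
  }
  set.seed(truth$seed)
  # pixel centers in 0-based coordinates; matrices are [row = y, col = x]
  xs <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  ys <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  inside <- matrix(FALSE, h, w)
  for (i in seq_along(truth$radii)) {
    inside <- inside |
      ((xs - truth$centers[i, "x"])^2 + (ys - truth$centers[i, "y"])^2 <=
         truth$radii[i]^2)
  }
  chs <- names(truth$interior)
  clean <- lapply(chs, function(ch) {
    img <- matrix(truth$exterior[[ch]], h, w)
    img[inside] <- truth$interior[[ch]]
    if (blur_sd > 0)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sd))
    img
  })
  names(clean) <- chs
  mixed <- lapply(chs, function(tgt) {
    out <- matrix(0, h, w)
    for (src in chs) out <- out + truth$bleedthrough[src, tgt] * clean[[src]]
    out
  })
  names(mixed) <- chs
  if (truth$noise_sd > 0)
    mixed <- lapply(mixed, function(img)
      pmax(img + matrix(rnorm(h * w, sd = truth$noise_sd), h, w), 0))
  field <- multichannel_field(mixed, pixel_size_nm = truth$pixel_size_nm)
  attr(field, "truth") <- truth
  field
}

#' Ground truth for a synthetic junction line profile
#'
#' Describes Gaussian clusters of given FWHM riding on a positive baseline
#' along a 1-D junction trace, with an optional co-occurring second channel
#' whose peaks are positionally jittered.
#'
#' @param length_px number of samples; `>= 40` so rank-based baseline
#'   normalization is defined.
#' @param pixel_size_nm physical sample spacing (nm/px).
#' @param centers_px cluster center positions (0-based px, within profile).
#' @param fwhm_nm per-cluster full widths at half maximum (nm), `> 0`.
#' @param amplitudes per-cluster amplitudes above baseline (a.u.), `> 0`.
#' @param baseline baseline intensity level (a.u.), `> 0`.
#' @param co_occur logical flag per cluster: render a matching channel-2
#'   peak at the (jittered) same position.
#' @param jitter_sd_px positional jitter sd of co-occurring channel-2 peaks
#'   (px); default 1 so a 3-px overlap window is meaningfully exercised.
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param seed integer RNG seed.
#'
#' @return An object of class `profile_truth`.
#' @export
profile_truth <- function(length_px = 100L, pixel_size_nm = 100,
                          centers_px = numeric(), fwhm_nm = numeric(),
                          amplitudes = numeric(), baseline = 100,
                          co_occur = NULL, jitter_sd_px = 1,
                          noise_sd = 0, seed = 1L) {
  length_px <- as.integer(length_px)
  if (length_px < 40L)
    stop("profile length must be >= 40 samples: the 20th-40th lowest-rank ",
         "baseline normalization is undefined below that")
  n <- length(centers_px)
  if (length(fwhm_nm) != n || length(amplitudes) != n)
    stop("centers, FWHMs and amplitudes must have equal length")
  if (n && (any(centers_px < 0) | any(centers_px > length_px - 1)))
    stop("cluster centers must lie within the profile")
  if (any(fwhm_nm <= 0)) stop("cluster FWHMs must be > 0")
  if (any(amplitudes <= 0)) stop("cluster amplitudes must be > 0")
  if (baseline <= 0) stop("baseline must be > 0")
  if (is.null(co_occur)) co_occur <- rep(FALSE, n)
  structure(list(length_px = length_px,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 centers_px = as.numeric(centers_px),
                 fwhm_nm = as.numeric(fwhm_nm),
                 amplitudes = as.numeric(amplitudes),
                 baseline = as.numeric(baseline),
                 co_occur = as.logical(co_occur),
                 jitter_sd_px = as.numeric(jitter_sd_px),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "profile_truth")
}

#' Generate a paired two-channel junction line profile
#'
#' Channel 1 is `baseline + sum of Gaussians + noise`; channel 2 contains a
#' jittered Gaussian at every cluster whose co-occurrence flag is set, on
#' the same baseline. The exact channel-2 peak positions drawn are recorded
#' in the returned truth (`centers2_px`).
#'
#' @param truth a [profile_truth()] object.
#' @return A list with `position_px`, `position_um`, `channel1`, `channel2`
#'   (raw intensities), `pixel_size_nm` and the updated `truth`.
#' @export
gen_junction_profile <- function(truth) {
  stopifnot(inherits(truth, "profile_truth"))
  set.seed(truth$seed)
  x <- seq_len(truth$length_px) - 1
  sigma_px <- truth$fwhm_nm / FWHM_SIGMA / truth$pixel_size_nm
  gauss_sum <- function(centers, sigmas, amps) {
    y <- rep(0, length(x))
    for (i in seq_along(centers))
      y <- y + amps[i] * exp(-(x - centers[i])^2 / (2 * sigmas[i]^2))
    y
  }
  ch1 <- truth$baseline + gauss_sum(truth$centers_px, sigma_px,
                                    truth$amplitudes)
  co <- which(truth$co_occur)
  centers2 <- truth$centers_px[co]
  if (length(co) && truth$jitter_sd_px > 0)
    centers2 <- centers2 + rnorm(length(co), sd = truth$jitter_sd_px)
  ch2 <- truth$baseline + gauss_sum(centers2, sigma_px[co],
                                    truth$amplitudes[co])
  if (truth$noise_sd > 0) {
    ch1 <- ch1 + rnorm(length(x), sd = truth$noise_sd)
    ch2 <- ch2 + rnorm(length(x), sd = truth$noise_sd)
  }
  truth$centers2_px <- centers2
  list(position_px = x,
       position_um = x * truth$pixel_size_nm / 1000,
       channel1 = ch1, channel2 = ch2,
       pixel_size_nm = truth$pixel_size_nm, truth = truth)
}

#' Ground truth for a synthetic FRAP trace
#'
#' Parameters of the single-exponential recovery model
#' `Y(t) = Y0 + (F_mob - Y0) * (1 - exp(-t * ln 2 / tau_half))` in
#' normalized intensity units, plus sampling design, noise and a constant
#' reference-region level.
#'
#' @param Y0 normalized intensity immediately after the bleach.
#' @param F_mob mobile fraction (recovery plateau), `Y0 <= F_mob <= 1.2`.
#' @param tau_half recovery half-time in seconds, `> 0`.
#' @param interval_s sampling interval (s), default 10.
#' @param n_prebleach number of pre-bleach frames at normalized level 1.
#' @param duration_s total post-bleach duration (s); a duration under
#'   `3 * tau_half` triggers a warning since the plateau is then poorly
#'   constrained.
#' @param noise_sd Gaussian noise sd in normalized units.
#' @param reference_level constant normalized level of the reference trace.
#' @param seed integer RNG seed.
#'
#' @return An object of class `frap_truth`.
#' @export
frap_truth <- function(Y0 = 0.1, F_mob = 0.7, tau_half = 17,
                       interval_s = 10, n_prebleach = 5L,
                       duration_s = 300, noise_sd = 0,
                       reference_level = 1, seed = 1L) {
  if (tau_half <= 0) stop("tau_half must be > 0")
  if (interval_s <= 0) stop("sampling interval must be > 0")
  if (!(Y0 >= 0 && Y0 <= F_mob && F_mob <= 1.2))
    stop("parameters must satisfy 0 <= Y0 <= F_mob <= 1.2")
  structure(list(Y0 = Y0, F_mob = F_mob, tau_half = tau_half,
                 interval_s = interval_s,
                 n_prebleach = as.integer(n_prebleach),
                 duration_s = duration_s, noise_sd = noise_sd,
                 reference_level = reference_level,
                 seed = as.integer(seed)),
            class = "frap_truth")
}

#' Evaluate the single-exponential FRAP recovery model
#'
#' @param t time since bleach (s).
#' @param Y0,F_mob,tau_half model parameters; see [frap_truth()].
#' @return Normalized intensity `Y(t)`.
#' @export
frap_model <- function(t, Y0, F_mob, tau_half) {
  Y0 + (F_mob - Y0) * (1 - exp(-t * log(2) / tau_half))
}

#' Simulate a FRAP trace from the recovery model
#'
#' Pre-bleach frames sit at normalized level 1, post-bleach frames follow
#' the single-exponential recovery model, the reference trace is constant
#' at its stated level; Gaussian noise is added to all three.
#'
#' @param truth a [frap_truth()] object.
#' @return A list of class `frap_trace_sim` with `time_s` (0 at bleach,
#'   negative pre-bleach), `roi` and `reference` normalized traces,
#'   `bleach_index` (index of the last pre-bleach frame), and `truth`.
#' @export
gen_frap_trace <- function(truth) {
  stopifnot(inherits(truth, "frap_truth"))
  if (truth$duration_s < 3 * truth$tau_half)
    warning("post-bleach duration covers < 3 half-lives; ",
            "the recovery plateau will be poorly constrained")
  set.seed(truth$seed)
  t_pre <- -rev(seq_len(truth$n_prebleach)) * truth$interval_s
  t_post <- seq(0, truth$duration_s, by = truth$interval_s)
  tt <- c(t_pre, t_post)
  roi <- c(rep(1, truth$n_prebleach),
           frap_model(t_post, truth$Y0, truth$F_mob, truth$tau_half))
  ref <- rep(truth$reference_level, length(tt))
  if (truth$noise_sd > 0) {
    roi <- roi + rnorm(length(tt), sd = truth$noise_sd)
    ref <- ref + rnorm(length(tt), sd = truth$noise_sd)
  }
  structure(list(time_s = tt, roi = roi, reference = ref,
                 bleach_index = truth$n_prebleach, truth = truth),
            class = "frap_trace_sim")
}
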