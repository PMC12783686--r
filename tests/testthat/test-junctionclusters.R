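test_that("line profiles average across the line width with interpolation", {
  # uniform image: constant profile regardless of path
  img <- matrix(7, 30, 30)
  lp <- extract_line_profile(img, cbind(x = c(3, 20), y = c(4, 18)),
                             width = 4, pixel_size_nm = 100)
  expect_true(all(abs(lp$intensity - 7) < 1e-9))

  # vertical 4-px-wide line over a column gradient: mean of spanned columns
  grad <- matrix(rep(1:30, each = 30), 30, 30)  # column j has value j
  lpv <- extract_line_profile(grad, cbind(x = c(10, 10), y = c(5, 25)),
                              width = 4, pixel_size_nm = 100)
  # 0-based x = 10 -> columns 9.5..12.5 in 1-based terms, mean = 11
  expect_true(all(abs(lpv$intensity - 11) < 1e-9))

  # width-1 on-grid horizontal line returns exact row values
  rimg <- matrix(0, 20, 20)
  rimg[6, ] <- 1:20
  lph <- extract_line_profile(rimg, cbind(x = c(2, 17), y = c(5, 5)),
                              width = 1, pixel_size_nm = 100)
  expect_equal(lph$intensity, 3:18)

  expect_error(extract_line_profile(img, cbind(x = 3, y = 4)), "2 vertices")
})

test_that("baseline normalization uses ranks 20-40 and is scale-equivariant", {
  lp <- as_line_profile(rep(5, 50))
  np <- normalize_profile(lp)
  expect_equal(np$baseline, 5)
  expect_true(all(np$intensity == 1))

  expect_error(normalize_profile(as_line_profile(rep(5, 39))), "40")

  # clusters occupying <15% of samples leave the rank baseline intact
  tr <- profile_truth(length_px = 200, centers_px = c(40, 100, 160),
                      fwhm_nm = rep(300, 3), amplitudes = rep(50, 3),
                      baseline = 100, noise_sd = 2, seed = 11)
  p <- gen_junction_profile(tr)
  npc <- normalize_profile(as_line_profile(p$channel1))
  expect_lt(abs(npc$baseline - 100) / 100, 0.02)

  # scale equivariance across random profiles
  for (s in 1:20) {
    set.seed(s)
    v <- abs(rnorm(60, 10, 2))
    n1 <- normalize_profile(as_line_profile(v))
    n2 <- normalize_profile(as_line_profile(v * (1 + s)))
    expect_equal(n2$intensity, n1$intensity)
  }
})

test_that("peak calling matches a brute-force prominence oracle", {
  # strictly monotonic ramp: no peaks
  npr <- normalize_profile(as_line_profile(seq(1, 5, length.out = 50)))
  expect_length(detect_peaks(npr, 0.5)$indices, 0)

  # flat profile: zero peaks, not an error
  npf <- normalize_profile(as_line_profile(rep(2, 50)))
  expect_length(detect_peaks(npf, 0.5)$indices, 0)

  # single Gaussian: one peak at the truth center
  tr <- profile_truth(length_px = 100, centers_px = 47, fwhm_nm = 400,
                      amplitudes = 4, baseline = 1, noise_sd = 0)
  p <- gen_junction_profile(tr)
  pk <- detect_peaks(normalize_profile(as_line_profile(p$channel1)), 0.5)
  expect_length(pk$indices, 1)
  expect_lte(abs(pk$indices - 47), 1)

  # two Gaussians, prominences ~0.9 and ~0.3 of range: one survives 0.5
  tr2 <- profile_truth(length_px = 100, centers_px = c(25, 70),
                       fwhm_nm = c(400, 400), amplitudes = c(9, 3),
                       baseline = 1, noise_sd = 0)
  p2 <- gen_junction_profile(tr2)
  np2 <- normalize_profile(as_line_profile(p2$channel1))
  expect_length(detect_peaks(np2, 0.5)$indices, 1)
  expect_length(detect_peaks(np2, 0.25)$indices, 2)

  # randomized profiles: detected set == oracle set at several thresholds
  for (s in 1:15) {
    set.seed(100 + s)
    v <- abs(rnorm(80, 10, 3))
    np <- normalize_profile(as_line_profile(v))
    u <- np$intensity
    rng <- max(u) - min(u)
    for (amp in c(0.25, 0.5, 0.75)) {
      cand <- oracle_local_maxima(u)
      proms <- vapply(cand, function(i) oracle_prominence(u, i), numeric(1))
      expected <- sort(cand[proms / rng >= amp] - 1L)
      got <- sort(detect_peaks(np, amp)$indices)
      expect_equal(got, expected)
    }
  }
})

test_that("peak count is monotone non-increasing in the amplitude setting", {
  set.seed(42)
  v <- abs(rnorm(120, 10, 3))
  np <- normalize_profile(as_line_profile(v))
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(a) length(detect_peaks(np, a)$indices),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak density divides count by contact length", {
  pk <- list(indices = c(1, 5, 9, 30, 44))
  expect_equal(peak_density(pk, 10), 0.5)
  expect_equal(peak_density(list(indices = integer(0)), 10), 0)
  expect_error(peak_density(pk, 0), "> 0")
})

test_that("overlap fraction uses an inclusive symmetric window", {
  mk <- function(idx) list(indices = as.integer(idx))
  expect_equal(overlap_fraction(mk(c(5, 20, 40)), mk(c(5, 20, 40))), 1)
  expect_equal(overlap_fraction(mk(10), mk(14), window = 3), 0)
  expect_equal(overlap_fraction(mk(10), mk(13), window = 3), 1)
  # one partner may satisfy several reference peaks
  expect_equal(overlap_fraction(mk(c(10, 12)), mk(11), window = 3), 1)
  # zero reference peaks: not applicable
  expect_true(is.na(overlap_fraction(mk(integer(0)), mk(10))))
  # zero partner peaks: plain 0
  expect_equal(overlap_fraction(mk(10), mk(integer(0))), 0)
  # window 0 with partner superset of reference
  expect_equal(overlap_fraction(mk(c(3, 8)), mk(c(3, 8, 15)), window = 0), 1)
})

test_that("overlap fraction recovers the co-occurrence probability", {
  est_overlap <- function(p_co, n = 200) {
    vals <- vapply(seq_len(n), function(s) {
      set.seed(5000 + s)
      k <- 4
      co <- runif(k) < p_co
      tr <- profile_truth(length_px = 160,
                          centers_px = c(25, 65, 105, 145) - 5,
                          fwhm_nm = rep(350, k), amplitudes = rep(5, k),
                          baseline = 1, co_occur = co, jitter_sd_px = 1,
                          noise_sd = 0, seed = 5000 + s)
      p <- gen_junction_profile(tr)
      p1 <- detect_peaks(normalize_profile(as_line_profile(p$channel1)),
                         0.25)
      p2 <- detect_peaks(normalize_profile(as_line_profile(p$channel2)),
                         0.25)
      overlap_fraction(p1, p2, window = 3)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  expect_lt(abs(est_overlap(1) - 1), 0.05)
  expect_lt(abs(est_overlap(0) - 0), 0.05)
  expect_lt(abs(est_overlap(0.5) - 0.5), 0.05)
})

test_that("profile correlation is affine-invariant and near zero under the null", {
  set.seed(9)
  v <- abs(rnorm(60, 10, 2))
  npa <- normalize_profile(as_line_profile(v))
  expect_equal(profile_correlation(npa, npa), 1)
  aff <- normalize_profile(as_line_profile(3 * v + 0.5))
  expect_equal(profile_correlation(npa, aff), 1)
  # independent noise profiles: R^2 below 0.05 at n = 500
  set.seed(10)
  a <- normalize_profile(as_line_profile(abs(rnorm(500, 10, 2))))
  b <- normalize_profile(as_line_profile(abs(rnorm(500, 10, 2))))
  expect_lt(profile_correlation(a, b), 0.05)
  # constant profile: undefined
  cflat <- normalize_profile(as_line_profile(rep(4, 60)))
  expect_true(is.na(profile_correlation(cflat, npa)))
})

test_that("Gaussian FWHM estimation is exact on noiseless clusters", {
  # closed form: sigma 100 nm -> FWHM 2*sqrt(2 ln 2)*100 = 235.48 nm
  sigma_nm <- 100
  fw <- 2 * sqrt(2 * log(2)) * sigma_nm
  lp <- gauss_profile(120, 60, fw, amp = 3, pixel_size_nm = 50)
  np <- normalize_profile(lp)
  cs <- cluster_fwhm(np, 60, fit_window = 15)
  expect_true(cs$converged)
  expect_lt(abs(cs$fwhm_nm - fw) / fw, 0.005)
  expect_equal(cs$fwhm_nm, 2 * sqrt(2 * log(2)) * cs$sigma_nm)

  # exactness across sigma >= 1.5 px
  for (sig_px in c(1.5, 2, 3, 5)) {
    fwn <- 2 * sqrt(2 * log(2)) * sig_px * 100
    lp2 <- gauss_profile(160, 80, fwn, amp = 4, pixel_size_nm = 100)
    cs2 <- cluster_fwhm(normalize_profile(lp2), 80,
                        fit_window = max(10, ceiling(4 * sig_px)))
    expect_lt(abs(cs2$fwhm_nm - fwn) / fwn, 0.005)
  }
})

test_that("FWHM estimation stays within 3% under 5% amplitude noise", {
  truth_fwhm <- 400
  ests <- vapply(1:100, function(s) {
    set.seed(700 + s)
    lp <- gauss_profile(120, 60, truth_fwhm, amp = 4, pixel_size_nm = 100)
    lp$intensity <- lp$intensity + rnorm(120, sd = 0.05 * 4)
    cs <- cluster_fwhm(normalize_profile(lp), 60, fit_window = 12)
    if (cs$converged) cs$fwhm_nm else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(ests, na.rm = TRUE) - truth_fwhm) / truth_fwhm, 0.03)
})
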