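#' Construct a raw FRAP trace
#'
#' @param time_s acquisition times (s), strictly increasing, uniform
#'   spacing assumed by downstream fitting (default design: 10-s interval).
#' @param roi mean intensity of the bleached cluster ROI per frame (a.u.).
#' @param reference mean intensity of a distal junction reference ROI
#'   (a.u.); optional.
#' @param background background intensity, a scalar or per-frame vector.
#' @param bleach_index index (1-based) of the last frame acquired before
#'   the bleach; frames `1..bleach_index` are pre-bleach.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(time_s, roi, reference = NULL, background = 0,
                       bleach_index) {
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  n <- length(time_s)
  if (length(roi) != n) stop("roi trace length must match time")
  if (!is.null(reference) && length(reference) != n)
    stop("reference trace length must match time")
  if (!length(background) %in% c(1L, n))
    stop("background must be scalar or per-frame")
  if (bleach_index < 1 || bleach_index >= n)
    stop("bleach frame must lie within the series")
  if (bleach_index < 2)
    warning("only one pre-bleach frame; pre-bleach mean is a single value")
  structure(list(time_s = time_s, roi = roi, reference = reference,
                 background = background,
                 bleach_index = as.integer(bleach_index)),
            class = "frap_trace")
}

#' Extract a FRAP trace from a time-lapse z-stack
#'
#' Per time frame, the stack is maximum-intensity projected over z and the
#' mean intensity of each ROI is taken on the projection. ROIs are
#' half-open rectangles `[x0, x1) x [y0, y1)` in 0-based pixel coordinates.
#'
#' @param stack 4-D numeric array `[y, x, z, t]` (a 3-D `[y, x, t]` array
#'   is treated as a single-slice stack).
#' @param cluster_roi,reference_roi,background_roi ROI rectangles as
#'   `c(x0, x1, y0, y1)`; `reference_roi` and `background_roi` optional.
#' @param bleach_index last pre-bleach frame (1-based).
#' @param interval_s frame interval in seconds (default 10).
#' @return A [frap_trace()].
#' @export
extract_frap_trace <- function(stack, cluster_roi, reference_roi = NULL,
                               background_roi = NULL, bleach_index,
                               interval_s = 10) {
  if (length(dim(stack)) == 3)
    dim(stack) <- c(dim(stack)[1:2], 1L, dim(stack)[3])
  if (length(dim(stack)) != 4) stop("stack must be a [y, x, z, t] array")
  d <- dim(stack)
  roi_idx <- function(r) {
    if (r[1] < 0 || r[3] < 0 || r[2] > d[2] || r[4] > d[1] ||
        r[2] <= r[1] || r[4] <= r[3])
      stop("ROI empty or outside image bounds")
    list(x = (r[1] + 1):r[2], y = (r[3] + 1):r[4])
  }
  roi_means <- function(r) {
    ix <- roi_idx(r)
    vapply(seq_len(d[4]), function(t) {
      proj <- apply(stack[, , , t, drop = FALSE], c(1, 2), max)
      mean(proj[ix$y, ix$x])
    }, numeric(1))
  }
  roi <- roi_means(cluster_roi)
  reference <- if (!is.null(reference_roi)) roi_means(reference_roi)
  bg <- if (!is.null(background_roi)) roi_means(background_roi) else 0
  frap_trace(time_s = (seq_len(d[4]) - 1) * interval_s, roi = roi,
             reference = reference, background = bg,
             bleach_index = bleach_index)
}

#' Double normalization of a FRAP trace
#'
#' Background-subtracted intensities are anchored to the pre-bleach mean
#' (maps to 1) and the immediate post-bleach value (first frame acquired
#' after the bleach; maps to 0):
#' `N(t) = (I(t) - bg - I_post') / (I_pre' - I_post')`, primes denoting
#' background-subtracted values. The reference trace is normalized to its
#' own background-subtracted pre-bleach mean. Any affine gain/offset of
#' the raw intensities cancels.
#'
#' @param trace a [frap_trace()].
#' @return A list of class `frap_normalized`: `time_s` (0 at the first
#'   post-bleach frame), `roi`, `reference` (or NULL), `bleach_index`.
#' @export
normalize_frap <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  bi <- trace$bleach_index
  bg <- trace$background
  I <- trace$roi - bg
  pre <- mean(I[seq_len(bi)])
  post <- I[bi + 1L]
  if (pre <= post)
    stop("pre-bleach mean does not exceed the immediate post-bleach ",
         "value; no bleach detected")
  roi_n <- (I - post) / (pre - post)
  ref_n <- NULL
  if (!is.null(trace$reference)) {
    R <- trace$reference - bg
    ref_pre <- mean(R[seq_len(bi)])
    if (ref_pre <= 0) stop("non-positive pre-bleach reference level")
    ref_n <- R / ref_pre
  }
  structure(list(time_s = trace$time_s - trace$time_s[bi + 1L],
                 roi = roi_n, reference = ref_n, bleach_index = bi),
            class = "frap_normalized")
}

#' Coerce to a normalized FRAP trace
#'
#' Simulated traces from [gen_frap_trace()] are already in normalized
#' units (pre-bleach 1, bleach drop to `Y0`), so coercion just relabels.
#'
#' @param x object to coerce.
#' @return A `frap_normalized` object.
#' @export
as_frap_normalized <- function(x) UseMethod("as_frap_normalized")

#' @export
as_frap_normalized.frap_normalized <- function(x) x

#' @export
as_frap_normalized.frap_trace_sim <- function(x) {
  structure(list(time_s = x$time_s, roi = x$roi, reference = x$reference,
                 bleach_index = x$bleach_index),
            class = "frap_normalized")
}

#' Fit the single-exponential recovery model
#'
#' Fits `Y(t) = Y0 + (F_mob - Y0) * (1 - exp(-t * ln 2 / tau_half))` to the
#' post-bleach portion of one or several normalized traces by bounded
#' nonlinear least squares. In `"ensemble-mean"` mode (the convention for
#' replicate-averaged recovery curves) traces are averaged pointwise before
#' a single fit; `"per-trace"` fits each trace separately.
#'
#' @param traces one `frap_normalized` or a list of them (identical time
#'   bases for ensemble mode).
#' @param mode `"ensemble-mean"` (default) or `"per-trace"`.
#' @return For ensemble mode, an object of class `frap_fit` with `Y0`,
#'   `F_mob`, `tau_half`, standard errors `se`, `fitted` curve and
#'   `time_s`; `tau_at_bound` flags an unreliable half-time at the box
#'   bound. For per-trace mode, a list of `frap_fit`s.
#' @export
fit_recovery <- function(traces, mode = c("ensemble-mean", "per-trace")) {
  mode <- match.arg(mode)
  if (inherits(traces, "frap_normalized")) traces <- list(traces)
  if (mode == "per-trace")
    return(lapply(traces, function(tr) fit_recovery_one(tr)))
  t0 <- traces[[1]]$time_s
  for (tr in traces)
    if (!isTRUE(all.equal(tr$time_s, t0)))
      stop("ensemble-mean mode needs identical time bases")
  roi <- rowMeans(vapply(traces, `[[`, numeric(length(t0)), "roi"))
  mean_tr <- structure(list(time_s = t0, roi = roi,
                            bleach_index = traces[[1]]$bleach_index),
                       class = "frap_normalized")
  fit_recovery_one(mean_tr)
}

fit_recovery_one <- function(tr) {
  post <- tr$time_s >= 0
  t <- tr$time_s[post]; y <- tr$roi[post]
  if (length(t) < 5) stop("need >= 5 post-bleach samples to fit")
  dur <- max(t)
  if (sd(y) < 1e-12) {
    # no recovery signal at all: the model degenerates to Y0 = F_mob
    return(structure(list(Y0 = y[1], F_mob = y[1], tau_half = NA_real_,
                          se = rep(NA_real_, 3), time_s = t,
                          fitted = rep(y[1], length(t)),
                          tau_at_bound = TRUE, n_traces = 1L),
                     class = "frap_fit"))
  }
  y0_init <- y[1]
  fmob_init <- mean(tail(y, max(1, floor(length(y) / 10))))
  half_level <- (y0_init + fmob_init) / 2
  i_half <- which(y >= half_level)[1]
  tau_init <- if (!is.na(i_half) && t[i_half] > 0) t[i_half] else dur / 5
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Y0 + (F_mob - Y0) * (1 - exp(-t * log(2) / tau_half)),
      start = list(Y0 = min(max(y0_init, -0.2), 0.5),
                   F_mob = min(max(fmob_init, 0), 1.5),
                   tau_half = min(max(tau_init, 1e-3), dur * 10)),
      lower = c(Y0 = -0.2, F_mob = 0, tau_half = 1e-6),
      upper = c(Y0 = 0.5, F_mob = 1.5, tau_half = dur * 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("recovery fit did not converge: ", conditionMessage(e)))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(Y0 = unname(cf["Y0"]), F_mob = unname(cf["F_mob"]),
                 tau_half = unname(cf["tau_half"]),
                 se = se, time_s = t,
                 fitted = frap_model(t, cf["Y0"], cf["F_mob"],
                                     cf["tau_half"]),
                 tau_at_bound = cf["tau_half"] >= dur * 10 * 0.999,
                 n_traces = 1L),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> Y0 = %.3f, F_mob = %.3f, tau_half = %.2f s%s\n",
    x$Y0, x$F_mob, x$tau_half,
    if (isTRUE(x$tau_at_bound)) " [tau at bound: unreliable]" else ""))
  invisible(x)
}

#' Compare the recovery plateau to the junction reference level
#'
#' The fitted mobile fraction divided by the time-averaged normalized
#' reference level: 1 means the cluster recovers all the way to the
#' surrounding junction intensity, 0 means no recovery.
#'
#' @param fit a `frap_fit`.
#' @param reference normalized reference trace (vector or the `reference`
#'   field of a `frap_normalized`).
#' @return A list with `ratio`, `F_mob`, `reference_level`.
#' @export
compare_to_reference <- function(fit, reference) {
  if (is.list(reference)) reference <- reference$reference
  if (is.null(reference)) stop("no reference trace available")
  lev <- mean(reference)
  if (lev == 0) return(list(ratio = NA_real_, F_mob = fit$F_mob,
                            reference_level = 0))
  list(ratio = fit$F_mob / lev, F_mob = fit$F_mob, reference_level = lev)
}
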