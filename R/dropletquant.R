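#' Multi-channel fluorescence field
#'
#' A set of aligned 2-D intensity grids, one per fluorophore channel, with
#' a common pixel size. Matrices are stored `[row = y, col = x]` with the
#' origin at the top-left, matching 0-based image conventions.
#'
#' @param channels named list of numeric matrices (a.u.), equal dimensions,
#'   finite and non-negative.
#' @param pixel_size_nm physical pixel size (nm/px).
#' @return An object of class `multichannel_field`.
#' @export
multichannel_field <- function(channels, pixel_size_nm) {
  if (!length(channels)) stop("at least one channel is required")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- paste0("ch", seq_along(channels))
  dims <- vapply(channels, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("all channels must share dimensions")
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (any(!is.finite(v)) || any(v < 0))
      stop("channel '", ch, "' contains non-finite or negative intensities")
  }
  structure(list(channels = channels,
                 pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "multichannel_field")
}

#' @export
print.multichannel_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<multichannel_field> ", d[2], "x", d[1], " px, ",
      length(x$channels), " channel(s): ",
      paste(names(x$channels), collapse = ", "),
      ", ", x$pixel_size_nm, " nm/px\n", sep = "")
  invisible(x)
}

# boundary-polygon perimeter of every label; pixel-count perimeters
# overestimate circularity badly on small disks
.label_perimeters <- function(labmap) {
  oc <- EBImage::ocontour(labmap)
  vapply(oc, function(p) {
    if (nrow(p) < 2) return(4)  # single pixel: unit square
    nxt <- p[c(seq_len(nrow(p))[-1], 1), , drop = FALSE]
    sum(sqrt(rowSums((p - nxt)^2)))
  }, numeric(1))
}

#' Segment condensate droplets in one channel
#'
#' Thresholds a channel, labels connected components, and retains regions
#' passing area bounds and a minimum circularity
#' (`4 * pi * area / perimeter^2`, perimeter measured on the boundary
#' polygon). Deterministic given its inputs; an empty result is returned
#' (not an error) when nothing exceeds the threshold.
#'
#' @param field a [multichannel_field()].
#' @param channel channel name to segment.
#' @param intensity_thresh `"otsu"` (default; Otsu's method on the channel
#'   histogram) or a numeric absolute threshold, or `"ksd"` for
#'   `median(bulk) + k * sd` with `k` from `ksd_k`.
#' @param min_area,max_area retained region area bounds (px).
#' @param min_circularity minimum circularity, default 0.8.
#' @param ksd_k multiplier for the `"ksd"` rule, default 3.
#'
#' @return An object of class `droplet_set`: `labels` (integer matrix,
#'   0 = bulk), a per-droplet tibble `stats` (label, area_px, perimeter_px,
#'   circularity, and per-channel `mean_<ch>` / `total_<ch>` interior
#'   intensities), the segmentation `channel` and threshold used.
#' @export
segment_droplets <- function(field, channel,
                             intensity_thresh = "otsu",
                             min_area = 10, max_area = 1e4,
                             min_circularity = 0.8,
                             ksd_k = 3) {
  stopifnot(inherits(field, "multichannel_field"))
  if (!channel %in% names(field$channels))
    stop("unknown channel '", channel, "'")
  img <- field$channels[[channel]]
  thr <- if (is.numeric(intensity_thresh)) {
    intensity_thresh
  } else if (identical(intensity_thresh, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0) rng[2] + 1  # uniform image: nothing above threshold
    else {
      sc <- (img - rng[1]) / diff(rng)
      EBImage::otsu(EBImage::Image(sc), range = c(0, 1)) * diff(rng) + rng[1]
    }
  } else if (identical(intensity_thresh, "ksd")) {
    stats::median(img) + ksd_k * sd(img)
  } else stop("unknown intensity threshold rule")
  mask <- img > thr
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                   stats = droplet_stats_tibble(field, integer(0)),
                   channel = channel, threshold = thr),
              class = "droplet_set")
  }
  if (!any(mask)) return(empty())
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- matrix(as.integer(EBImage::imageData(lab)), nrow(img), ncol(img))
  areas <- tabulate(labm[labm > 0])
  perims <- .label_perimeters(lab)
  circ <- pmin(4 * pi * areas / perims^2, 1.05)
  keep <- which(areas >= min_area & areas <= max_area &
                  circ >= min_circularity)
  if (!length(keep)) return(empty())
  # relabel retained droplets 1..k in original order
  remap <- integer(max(labm))
  remap[keep] <- seq_along(keep)
  newlab <- matrix(0L, nrow(img), ncol(img))
  pos <- labm > 0
  newlab[pos] <- remap[labm[pos]]
  st <- droplet_stats_tibble(field, seq_along(keep), newlab)
  st$area_px <- areas[keep]
  st$perimeter_px <- perims[keep]
  st$circularity <- circ[keep]
  structure(list(labels = newlab, stats = st,
                 channel = channel, threshold = thr),
            class = "droplet_set")
}

# per-label per-channel interior mean/total intensities
droplet_stats_tibble <- function(field, labels, labmap = NULL) {
  base <- tibble::tibble(label = as.integer(labels),
                         area_px = integer(length(labels)),
                         perimeter_px = numeric(length(labels)),
                         circularity = numeric(length(labels)))
  for (ch in names(field$channels)) {
    if (length(labels)) {
      img <- field$channels[[ch]]
      sums <- vapply(labels, function(l) sum(img[labmap == l]), numeric(1))
      ns <- vapply(labels, function(l) sum(labmap == l), numeric(1))
      base[[paste0("mean_", ch)]] <- sums / ns
      base[[paste0("total_", ch)]] <- sums
    } else {
      base[[paste0("mean_", ch)]] <- numeric(0)
      base[[paste0("total_", ch)]] <- numeric(0)
    }
  }
  base
}

#' @export
print.droplet_set <- function(x, ...) {
  cat("<droplet_set> ", nrow(x$stats), " droplet(s) segmented on '",
      x$channel, "' (threshold ", signif(x$threshold, 4), ")\n", sep = "")
  invisible(x)
}

#' Per-droplet partition ratios
#'
#' Partition ratio = mean droplet interior intensity (C-in) over mean bulk
#' intensity (C-out), a proxy for the concentration of the fluorescent
#' species in the condensed phase over the dilute phase. The bulk is every
#' pixel outside all droplet labels; by default a union bulk mask across
#' additional droplet sets may be supplied so the bulk is condensate-free
#' in every channel.
#'
#' @param field a [multichannel_field()].
#' @param droplets a [segment_droplets()] result.
#' @param channel channel whose intensities are evaluated.
#' @param union_with optional list of further `droplet_set`s whose labels
#'   are also excluded from the bulk.
#'
#' @return A list with `ratios` (per droplet; `NA` where C-out is 0),
#'   `mean_ratio`, `C_out`, and the per-droplet `C_in` vector.
#' @export
partition_ratio <- function(field, droplets, channel, union_with = NULL) {
  stopifnot(inherits(field, "multichannel_field"),
            inherits(droplets, "droplet_set"))
  img <- field$channels[[channel]]
  if (is.null(img)) stop("unknown channel '", channel, "'")
  bulk <- droplets$labels == 0L
  for (d in union_with) bulk <- bulk & d$labels == 0L
  C_out <- if (any(bulk)) mean(img[bulk]) else NA_real_
  C_in <- droplets$stats[[paste0("mean_", channel)]]
  ratios <- if (!is.na(C_out) && C_out > 0) C_in / C_out
            else rep(NA_real_, length(C_in))
  list(ratios = ratios,
       mean_ratio = if (length(ratios)) mean(ratios, na.rm = TRUE) else NA_real_,
       C_out = C_out, C_in = C_in)
}

#' Condensed fraction of a channel
#'
#' Total intensity inside all droplet pixels (TC-in) divided by the total
#' intensity of the whole field (TC-out): the share of the fluorescent
#' species residing in the condensed phase. Always in `[0, 1]`.
#'
#' @inheritParams partition_ratio
#' @param mask optional logical matrix overriding the droplet mask (used
#'   for scaffold-based co-condensation).
#' @return A single fraction in `[0, 1]`.
#' @export
condensed_fraction <- function(field, droplets, channel, mask = NULL) {
  stopifnot(inherits(field, "multichannel_field"))
  img <- field$channels[[channel]]
  if (is.null(img)) stop("unknown channel '", channel, "'")
  if (is.null(mask)) {
    stopifnot(inherits(droplets, "droplet_set"))
    mask <- droplets$labels > 0L
  }
  total <- sum(img)
  if (total == 0) {
    warning("channel '", channel, "' is all zero; condensed fraction is 0")
    return(0)
  }
  sum(img[mask]) / total
}

#' Co-condensed fraction against a scaffold channel's droplet mask
#'
#' The condensed fraction of a client (target) channel evaluated over the
#' droplet mask of a scaffold channel: the share of the client's total
#' signal found inside the scaffold's condensates.
#'
#' @param field a [multichannel_field()].
#' @param scaffold_droplets `droplet_set` segmented on the scaffold channel.
#' @param target_channel channel whose intensity share is measured.
#' @return A single fraction in `[0, 1]`.
#' @export
co_condensed_fraction <- function(field, scaffold_droplets, target_channel) {
  stopifnot(inherits(scaffold_droplets, "droplet_set"))
  mask <- scaffold_droplets$labels > 0L
  if (!any(mask)) {
    warning("scaffold mask is empty; co-condensed fraction is 0")
    return(0)
  }
  condensed_fraction(field, NULL, target_channel, mask = mask)
}

#' Default per-channel-class bleedthrough partition-ratio thresholds
#'
#' Red (mCherry/mScarlet) and green (mEGFP) channels use 1.1; blue
#' (mTagBFP2) uses 1.35 to correct for mEGFP bleedthrough into the blue
#' detection band.
#' @export
bleedthrough_defaults <- c(red = 1.1, green = 1.1, blue = 1.35)

#' Filter droplets by per-channel partition-ratio thresholds
#'
#' Droplets whose partition ratio in a channel falls below that channel
#' class's threshold are excluded from that channel's statistics (they stay
#' in the geometry, so scaffold masks remain intact). Default thresholds:
#' 1.1 for red/green-class channels, 1.35 for the blue class.
#'
#' @param droplets a `droplet_set`.
#' @param per_channel_ratios named list: per evaluated channel, the vector
#'   of per-droplet partition ratios (from [partition_ratio()]).
#' @param channel_class named character vector mapping each evaluated
#'   channel to a class in `names(thresholds)`.
#' @param thresholds named numeric vector of per-class minimum ratios;
#'   default [bleedthrough_defaults].
#'
#' @return The `droplet_set` with an added `retained` logical tibble
#'   (label + one column per evaluated channel) and, in `stats`,
#'   `retained_<ch>` columns.
#' @export
filter_bleedthrough <- function(droplets, per_channel_ratios, channel_class,
                                thresholds = bleedthrough_defaults) {
  stopifnot(inherits(droplets, "droplet_set"))
  ret <- tibble::tibble(label = droplets$stats$label)
  for (ch in names(per_channel_ratios)) {
    cls <- channel_class[[ch]]
    if (is.null(cls) || is.na(cls) || !cls %in% names(thresholds))
      stop("channel '", ch, "' has no known class; supply an explicit ",
           "threshold via `thresholds`")
    keep <- per_channel_ratios[[ch]] >= thresholds[[cls]]
    keep[is.na(keep)] <- FALSE
    ret[[ch]] <- keep
    droplets$stats[[paste0("retained_", ch)]] <- keep
  }
  droplets$retained <- ret
  droplets
}

#' Normalize a per-condition measurement table to a reference condition
#'
#' Each value is divided by the mean of the reference condition in the same
#' channel, so the reference condition's mean maps to 1 in every channel
#' independently.
#'
#' @param condition_table tibble with columns `condition`, `channel`,
#'   `value` (other columns pass through).
#' @param reference_condition name of the reference condition.
#' @return The table with an added `value_norm` column.
#' @export
normalize_to_reference <- function(condition_table, reference_condition) {
  stopifnot(all(c("condition", "channel", "value") %in%
                  names(condition_table)))
  ref <- dplyr::filter(condition_table,
                       .data$condition == reference_condition)
  if (!nrow(ref))
    stop("reference condition '", reference_condition, "' not present")
  ref_means <- dplyr::summarise(dplyr::group_by(ref, .data$channel),
                                .ref_mean = mean(.data$value),
                                .groups = "drop")
  if (any(ref_means$.ref_mean == 0))
    stop("reference condition has zero mean in channel(s): ",
         paste(ref_means$channel[ref_means$.ref_mean == 0], collapse = ", "))
  out <- dplyr::left_join(condition_table, ref_means, by = "channel")
  if (any(is.na(out$.ref_mean)))
    stop("channel(s) missing from the reference condition: ",
         paste(unique(out$channel[is.na(out$.ref_mean)]), collapse = ", "))
  out$value_norm <- out$value / out$.ref_mean
  out$.ref_mean <- NULL
  out
}

#' Per-field droplet metrics for every channel
#'
#' Convenience wrapper computing, per channel: bulk level C-out, per-droplet
#' partition ratios, bleedthrough-filtered mean partition ratio, condensed
#' fraction, co-condensed fraction with respect to a scaffold channel, and
#' retained droplet count.
#'
#' @param field a [multichannel_field()].
#' @param droplets segmented droplets (scaffold geometry).
#' @param channel_class named character vector of channel classes (see
#'   [filter_bleedthrough()]).
#' @param thresholds per-class bleedthrough thresholds.
#' @return A tibble with one row per channel.
#' @export
field_metrics <- function(field, droplets, channel_class,
                          thresholds = bleedthrough_defaults) {
  prs <- lapply(names(field$channels), function(ch)
    partition_ratio(field, droplets, ch))
  names(prs) <- names(field$channels)
  ratios <- lapply(prs, `[[`, "ratios")
  filt <- filter_bleedthrough(droplets, ratios, channel_class, thresholds)
  rows <- lapply(names(field$channels), function(ch) {
    keep <- filt$retained[[ch]]
    r <- ratios[[ch]][keep]
    tibble::tibble(
      channel = ch,
      C_out = prs[[ch]]$C_out,
      n_droplets = sum(keep),
      mean_partition_ratio = if (length(r)) mean(r) else NA_real_,
      condensed_fraction = condensed_fraction(field, droplets, ch),
      co_condensed_fraction =
        co_condensed_fraction(field, droplets, ch))
  })
  dplyr::bind_rows(rows)
}
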