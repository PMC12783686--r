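#' @importFrom rlang .data
NULL

#' Replicate-aware ("superplot") aggregation of a measurement table
#'
#' Summarizes a tidy long table at three levels: per-image points,
#' per-replicate means, and per-condition grand mean with sd computed
#' across replicate means — the nesting used when images are
#' pseudoreplicates within independent experiments.
#'
#' @param table tibble with columns `condition`, `replicate`, `image`,
#'   `metric`, `value`.
#' @return A list of tibbles: `images` (the finite-value rows),
#'   `replicates` (per condition x metric x replicate mean, n),
#'   `conditions` (per condition x metric mean of replicate means, sd
#'   across replicate means, n_replicates).
#' @export
aggregate_replicates <- function(table) {
  need <- c("condition", "replicate", "image", "metric", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  tbl <- dplyr::filter(table, is.finite(.data$value))
  dropped <- setdiff(unique(table$condition), unique(tbl$condition))
  if (length(dropped))
    warning("condition(s) with no finite values omitted: ",
            paste(dropped, collapse = ", "))
  tbl <- dplyr::arrange(tbl, .data$condition, .data$metric,
                        .data$replicate, .data$image)
  reps <- dplyr::summarise(
    dplyr::group_by(tbl, .data$condition, .data$metric, .data$replicate),
    mean = mean(.data$value), n_images = dplyr::n(), .groups = "drop")
  conds <- dplyr::summarise(
    dplyr::group_by(reps, .data$condition, .data$metric),
    grand_mean = mean(.data$mean),
    sd = sd(.data$mean),
    n_replicates = dplyr::n(), .groups = "drop")
  list(images = tbl, replicates = reps, conditions = conds)
}

#' Summarize manually scored de-novo contact formation
#'
#' Per condition: the fraction of contacts showing clustering, the
#' fraction establishing a linear junction, their cross-tabulation, and
#' onset delays of cortical enrichment (per-contact values plus
#' per-replicate means). Contacts whose onset never occurred within the
#' movie are right-censored: they are excluded from onset means but still
#' counted in the fractions.
#'
#' @param scores tibble with columns `condition`, `replicate`, `contact`,
#'   `clustering` (logical), `linear_junction` (logical), `onset_min`
#'   (minutes, `NA` allowed when censored), `censored` (logical).
#' @return A list of tibbles: `fractions`, `crosstab`, `onsets`,
#'   `onset_replicates`, `onset_conditions`.
#' @export
summarize_contact_scores <- function(scores) {
  need <- c("condition", "replicate", "contact", "clustering",
            "linear_junction", "onset_min", "censored")
  if (!all(need %in% names(scores)))
    stop("scores must have columns: ", paste(need, collapse = ", "))
  if (any(!scores$censored & (is.na(scores$onset_min) |
                              scores$onset_min < 0)))
    stop("uncensored contacts need a non-negative onset delay")
  scores <- dplyr::arrange(scores, .data$condition, .data$replicate,
                           .data$contact)
  fractions <- dplyr::summarise(
    dplyr::group_by(scores, .data$condition),
    n_contacts = dplyr::n(),
    fraction_clustering = mean(.data$clustering),
    fraction_linear = mean(.data$linear_junction), .groups = "drop")
  crosstab <- dplyr::summarise(
    dplyr::group_by(scores, .data$condition, .data$clustering,
                    .data$linear_junction),
    n = dplyr::n(), .groups = "drop")
  onsets <- dplyr::filter(scores, !.data$censored)
  onset_reps <- dplyr::summarise(
    dplyr::group_by(onsets, .data$condition, .data$replicate),
    mean_onset_min = mean(.data$onset_min),
    n = dplyr::n(), .groups = "drop")
  onset_conds <- dplyr::summarise(
    dplyr::group_by(onsets, .data$condition),
    mean_onset_min = mean(.data$onset_min),
    median_onset_min = stats::median(.data$onset_min),
    n = dplyr::n(), .groups = "drop")
  # conditions where every contact is censored: onset not applicable
  all_cens <- setdiff(unique(scores$condition), unique(onsets$condition))
  if (length(all_cens))
    onset_conds <- dplyr::bind_rows(
      onset_conds,
      tibble::tibble(condition = all_cens, mean_onset_min = NA_real_,
                     median_onset_min = NA_real_, n = 0L))
  list(fractions = fractions, crosstab = crosstab,
       onsets = onsets, onset_replicates = onset_reps,
       onset_conditions = onset_conds)
}

#' Write a multi-channel field as TIFF + JSON sidecar
#'
#' One 32-bit float page per channel, intensities scaled into `[0, 1]` by
#' a common factor recorded in the sidecar (and undone by
#' [read_field_tiff()]), because float TIFF pages store values in that
#' range.
#'
#' @param field a [multichannel_field()].
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @param truth optional generative truth to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path, truth = NULL) {
  mx <- max(vapply(field$channels, max, numeric(1)), 1e-12)
  pages <- lapply(field$channels, function(m) m / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  side <- list(channels = names(field$channels),
               pixel_size_nm = field$pixel_size_nm,
               intensity_scale = mx)
  if (!is.null(truth)) side$truth <- unclass(truth)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a multi-channel field written by [write_field_tiff()]
#'
#' @param path TIFF path with `<path>.json` sidecar.
#' @return A [multichannel_field()].
#' @export
read_field_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  chans <- lapply(pages, function(p) p * side$intensity_scale)
  names(chans) <- side$channels
  multichannel_field(chans, pixel_size_nm = side$pixel_size_nm)
}

#' Read polylines from a CSV or JSON sidecar
#'
#' CSV needs columns `polyline_id`, `x`, `y` (0-based pixel coordinates,
#' origin top-left); JSON is a list of objects with `x`/`y` vertex arrays.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return A named list of two-column matrices.
#' @export
read_polylines <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- lapply(raw, function(p) cbind(x = unlist(p$x), y = unlist(p$y)))
    if (is.null(names(out))) names(out) <- seq_along(out)
    return(out)
  }
  df <- utils::read.csv(path)
  if (!all(c("polyline_id", "x", "y") %in% names(df)))
    stop("polyline CSV must have columns polyline_id, x, y")
  lapply(split(df, df$polyline_id),
         function(d) cbind(x = d$x, y = d$y))
}

#' Read FRAP traces from CSV
#'
#' Expected columns: `time_s`, `roi`, and optionally `reference`,
#' `background`; a `trace_id` column splits multiple traces.
#'
#' @param path CSV path.
#' @param bleach_index last pre-bleach frame (1-based) shared by all
#'   traces.
#' @return A list of [frap_trace()]s.
#' @export
read_frap_csv <- function(path, bleach_index) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "roi") %in% names(df)))
    stop("FRAP CSV must have columns time_s, roi")
  groups <- if ("trace_id" %in% names(df)) split(df, df$trace_id)
            else list(trace = df)
  lapply(groups, function(d)
    frap_trace(time_s = d$time_s, roi = d$roi,
               reference = if ("reference" %in% names(d)) d$reference,
               background = if ("background" %in% names(d)) d$background
                            else 0,
               bleach_index = bleach_index))
}

# write a CSV with a manifest-hash header comment
write_csv_manifest <- function(df, path, manifest_hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(manifest_hash))
    writeLines(paste0("# manifest_hash: ", manifest_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# deterministic short hash of an R object (polynomial rolling hash over
# its version-2 serialization, header skipped)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2)[-(1:14)])
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Run a configured pipeline stage
#'
#' Validates a configuration list (or YAML path), dispatches to the
#' requested analysis, writes tabular outputs as CSV (with a manifest-hash
#' header comment) and a JSON run manifest recording inputs, parameters
#' and seeds so the run can be reproduced exactly.
#'
#' @param config named list or path to a YAML/JSON config file. Required
#'   keys: `kind` (one of `simulate`, `droplets`, `junction`, `frap`,
#'   `report`) and `out_dir`; per-kind keys documented in the package
#'   vignette.
#' @return Invisibly, the manifest list (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  problems <- character(0)
  if (is.null(config$kind) ||
      !config$kind %in% c("simulate", "droplets", "junction", "frap",
                          "report"))
    problems <- c(problems, "kind: must be one of simulate, droplets, junction, frap, report")
  if (is.null(config$out_dir)) problems <- c(problems, "out_dir: missing")
  if (identical(config$kind, "junction") &&
      is.null(config$pixel_size_nm))
    problems <- c(problems,
                  "pixel_size_nm: required for junction analyses (um conversions need it)")
  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  out <- switch(config$kind,
                simulate = pipeline_simulate(config, hash),
                droplets = pipeline_droplets(config, hash),
                junction = pipeline_junction(config, hash),
                frap = pipeline_frap(config, hash),
                report = pipeline_report(config, hash))
  manifest <- list(kind = config$kind, config = config,
                   config_hash = hash,
                   package_version =
                     as.character(utils::packageVersion("condensquant")),
                   outputs = out)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

pipeline_simulate <- function(cfg, hash) {
  seed <- as.integer(cfg$seed %||% 1L)
  kind <- cfg$what %||% "droplets"
  if (kind == "droplets") {
    n <- cfg$n_droplets %||% 12L
    set.seed(seed)
    dims <- c(cfg$width %||% 256L, cfg$height %||% 256L)
    radii <- runif(n, 4, 10)
    margin <- max(radii) + 2
    centers <- cbind(runif(n, margin, dims[1] - margin),
                     runif(n, margin, dims[2] - margin))
    tr <- droplet_truth(centers, radii,
                        interior = cfg$interior %||% c(green = 10),
                        exterior = cfg$exterior %||% c(green = 2),
                        noise_sd = cfg$noise_sd %||% 0.2, seed = seed)
    field <- gen_droplet_field(tr, dims = dims)
    path <- file.path(cfg$out_dir, "field.tif")
    write_field_tiff(field, path, truth = tr)
    list(field = path)
  } else if (kind == "junction") {
    tr <- profile_truth(length_px = cfg$length_px %||% 120L,
                        centers_px = cfg$centers_px %||% c(30, 60, 90),
                        fwhm_nm = cfg$fwhm_nm %||% rep(400, 3),
                        amplitudes = cfg$amplitudes %||% rep(3, 3),
                        co_occur = cfg$co_occur %||% rep(TRUE, 3),
                        noise_sd = cfg$noise_sd %||% 0.05, seed = seed)
    prof <- gen_junction_profile(tr)
    df <- data.frame(position_px = prof$position_px,
                     position_um = prof$position_um,
                     channel1 = prof$channel1, channel2 = prof$channel2)
    path <- file.path(cfg$out_dir, "profile.csv")
    write_csv_manifest(df, path, hash)
    list(profile = path)
  } else if (kind == "frap") {
    tr <- frap_truth(tau_half = cfg$tau_half %||% 17,
                     F_mob = cfg$F_mob %||% 0.7,
                     Y0 = cfg$Y0 %||% 0.1,
                     noise_sd = cfg$noise_sd %||% 0.05, seed = seed)
    sim <- gen_frap_trace(tr)
    df <- data.frame(time_s = sim$time_s, roi = sim$roi,
                     reference = sim$reference, background = 0)
    path <- file.path(cfg$out_dir, "frap.csv")
    write_csv_manifest(df, path, hash)
    list(trace = path)
  } else stop("unknown simulation kind '", kind, "'")
}

pipeline_droplets <- function(cfg, hash) {
  field <- read_field_tiff(cfg$field)
  ch <- cfg$channel %||% names(field$channels)[1]
  ds <- segment_droplets(field, ch,
                         intensity_thresh = cfg$intensity_thresh %||% "otsu",
                         min_area = cfg$min_area %||% 10,
                         max_area = cfg$max_area %||% 1e4,
                         min_circularity = cfg$min_circularity %||% 0.8)
  classes <- unlist(cfg$channel_class %||%
                      setNames(rep("green", length(field$channels)),
                               names(field$channels)))
  metrics <- field_metrics(field, ds, channel_class = classes)
  p1 <- file.path(cfg$out_dir, "droplets.csv")
  p2 <- file.path(cfg$out_dir, "field_metrics.csv")
  write_csv_manifest(as.data.frame(ds$stats), p1, hash)
  write_csv_manifest(as.data.frame(metrics), p2, hash)
  list(droplets = p1, metrics = p2)
}

pipeline_junction <- function(cfg, hash) {
  df <- utils::read.csv(cfg$profile, comment.char = "#")
  px <- cfg$pixel_size_nm
  mk <- function(col) {
    structure(list(position_px = df$position_px,
                   position_um = df$position_px * px / 1000,
                   intensity = df[[col]],
                   width_px = cfg$width %||% 4, pixel_size_nm = px),
              class = "line_profile")
  }
  res <- analyze_contact(mk("channel1"), mk("channel2"),
                         min_amplitude = cfg$min_amplitude %||% 0.5,
                         window = cfg$window %||% 3)
  contact <- data.frame(peaks_per_um = res$peaks_per_um,
                        overlap_fraction = res$overlap_fraction,
                        r_squared = res$r_squared,
                        n_peaks_ch1 = length(res$peaks1$indices),
                        n_peaks_ch2 = length(res$peaks2$indices))
  p1 <- file.path(cfg$out_dir, "contact_metrics.csv")
  p2 <- file.path(cfg$out_dir, "cluster_sizes.csv")
  write_csv_manifest(contact, p1, hash)
  write_csv_manifest(as.data.frame(res$cluster_sizes), p2, hash)
  list(contact = p1, clusters = p2)
}

pipeline_frap <- function(cfg, hash) {
  traces <- read_frap_csv(cfg$traces, bleach_index = cfg$bleach_index)
  # CSVs from `simulate` are already normalized (time 0 at bleach)
  norm <- lapply(traces, function(tr) {
    if (isTRUE(cfg$normalized))
      structure(list(time_s = tr$time_s, roi = tr$roi,
                     reference = tr$reference,
                     bleach_index = tr$bleach_index),
                class = "frap_normalized")
    else normalize_frap(tr)
  })
  fit <- fit_recovery(norm, mode = cfg$mode %||% "ensemble-mean")
  out <- list(Y0 = fit$Y0, F_mob = fit$F_mob, tau_half = fit$tau_half)
  if (!is.null(norm[[1]]$reference))
    out$plateau_ratio <- compare_to_reference(fit, norm[[1]])$ratio
  p1 <- file.path(cfg$out_dir, "frap_fit.json")
  jsonlite::write_json(out, p1, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  p2 <- file.path(cfg$out_dir, "fitted_curve.csv")
  write_csv_manifest(data.frame(time_s = fit$time_s, fitted = fit$fitted),
                     p2, hash)
  list(fit = p1, curve = p2)
}

pipeline_report <- function(cfg, hash) {
  scores <- utils::read.csv(cfg$scores, comment.char = "#")
  scores$clustering <- as.logical(scores$clustering)
  scores$linear_junction <- as.logical(scores$linear_junction)
  scores$censored <- as.logical(scores$censored)
  summ <- summarize_contact_scores(tibble::as_tibble(scores))
  p1 <- file.path(cfg$out_dir, "contact_fractions.csv")
  p2 <- file.path(cfg$out_dir, "onset_summary.csv")
  write_csv_manifest(as.data.frame(summ$fractions), p1, hash)
  write_csv_manifest(as.data.frame(summ$onset_conditions), p2, hash)
  list(fractions = p1, onsets = p2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
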