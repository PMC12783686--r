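test_that("segmentation finds disks and rejects low-circularity shapes", {
  # uniform image: nothing above an Otsu or absolute threshold
  fu <- multichannel_field(list(g = matrix(3, 30, 30)), 120)
  expect_equal(nrow(segment_droplets(fu, "g")$stats), 0)
  expect_equal(nrow(segment_droplets(fu, "g", intensity_thresh = 10)$stats),
               0)

  # 5 disks of radius 4: exactly 5 labels, areas within 10% of pi*16
  ctr <- cbind(x = c(20, 60, 100, 140, 180), y = c(30, 70, 110, 150, 190))
  tr <- droplet_truth(ctr, rep(4, 5), interior = c(g = 10),
                      exterior = c(g = 2), seed = 3)
  f <- gen_droplet_field(tr, dims = c(220, 220))
  ds <- segment_droplets(f, "g", intensity_thresh = 6, min_area = 10)
  expect_equal(nrow(ds$stats), 5)
  expect_true(all(abs(ds$stats$area_px - pi * 16) / (pi * 16) < 0.10))
  expect_true(all(ds$stats$circularity > 0.8 & ds$stats$circularity <= 1.05))

  # a 30x2 bright bar has circularity ~0.2-0.3 and is excluded at 0.8
  bar <- matrix(0, 40, 40); bar[10:11, 5:34] <- 10
  fb <- multichannel_field(list(g = bar), 120)
  expect_equal(nrow(segment_droplets(fb, "g", intensity_thresh = 5,
                                     min_area = 10)$stats), 0)
  loose <- segment_droplets(fb, "g", intensity_thresh = 5, min_area = 10,
                            min_circularity = 0.1)
  expect_equal(nrow(loose$stats), 1)
  expect_lt(loose$stats$circularity, 0.4)

  # deterministic and idempotent
  ds2 <- segment_droplets(f, "g", intensity_thresh = 6, min_area = 10)
  expect_identical(ds$labels, ds2$labels)
  expect_identical(ds$stats, ds2$stats)
})

test_that("partition ratio recovers the generative enrichment", {
  # uniform image with an imposed mask: every ratio is 1
  fu <- multichannel_field(list(g = matrix(4, 20, 20)), 120)
  lab <- matrix(0L, 20, 20); lab[5:8, 5:8] <- 1L
  du <- structure(list(labels = lab,
                       stats = tibble::tibble(label = 1L, mean_g = 4),
                       channel = "g", threshold = 0),
                  class = "droplet_set")
  pru <- partition_ratio(fu, du, "g")
  expect_equal(pru$ratios, 1)

  # noiseless two-level disks at 8/2: ratios 4 within 1%
  ctr <- cbind(x = c(20, 50, 80), y = c(20, 50, 80))
  tr <- droplet_truth(ctr, rep(5, 3), interior = c(g = 8),
                      exterior = c(g = 2), seed = 1)
  f <- gen_droplet_field(tr, dims = c(104, 104))
  ds <- segment_droplets(f, "g", intensity_thresh = 5, min_area = 10)
  pr <- partition_ratio(f, ds, "g")
  expect_equal(length(pr$ratios), 3)
  expect_true(all(abs(pr$ratios - 4) / 4 < 0.01))
  expect_equal(pr$C_out, 2)

  # zero bulk level: ratios flagged undefined
  f0 <- multichannel_field(list(g = matrix(0, 20, 20) +
                                  (lab > 0) * 5), 120)
  pr0 <- partition_ratio(f0, du, "g")
  expect_true(all(is.na(pr0$ratios)))
})

test_that("condensed fraction matches pixel-sum arithmetic and its complement", {
  img <- matrix(1, 10, 10); img[3:4, 3:4] <- 10
  f <- multichannel_field(list(g = img), 120)
  mask <- img > 5
  expect_equal(condensed_fraction(f, NULL, "g", mask = mask), 40 / 136)
  # complement share sums to 1 exactly
  expect_equal(condensed_fraction(f, NULL, "g", mask = mask) +
                 sum(img[!mask]) / sum(img), 1)
  # no droplets -> 0; full mask -> 1
  expect_equal(condensed_fraction(f, NULL, "g",
                                  mask = matrix(FALSE, 10, 10)), 0)
  expect_equal(condensed_fraction(f, NULL, "g",
                                  mask = matrix(TRUE, 10, 10)), 1)
  # all-zero channel warns and returns 0
  fz <- multichannel_field(list(g = matrix(0, 10, 10)), 120)
  expect_warning(cf <- condensed_fraction(fz, NULL, "g", mask = mask),
                 "zero")
  expect_equal(cf, 0)
})

test_that("co-condensed fraction is the client share inside the scaffold mask", {
  tr <- droplet_truth(cbind(c(15, 40), c(15, 40)), c(6, 6),
                      interior = c(scaffold = 8, client = 6),
                      exterior = c(scaffold = 2, client = 0), seed = 2)
  f <- gen_droplet_field(tr, dims = c(60, 60))
  ds <- segment_droplets(f, "scaffold", intensity_thresh = 5,
                         min_area = 10)
  # client signal exists only inside scaffold disks -> fraction 1
  expect_equal(co_condensed_fraction(f, ds, "client"), 1)
  # scaffold channel against its own mask equals its condensed fraction
  expect_equal(co_condensed_fraction(f, ds, "scaffold"),
               condensed_fraction(f, ds, "scaffold"))
  # uniform client: fraction = mask pixels / all pixels
  fu <- multichannel_field(list(scaffold = f$channels$scaffold,
                                client = matrix(5, 60, 60)), 120)
  expect_equal(co_condensed_fraction(fu, ds, "client"),
               sum(ds$labels > 0) / (60 * 60))
  # empty scaffold warns and returns 0
  de <- segment_droplets(f, "scaffold", intensity_thresh = 100)
  expect_warning(v <- co_condensed_fraction(f, de, "client"), "empty")
  expect_equal(v, 0)
})

test_that("bleedthrough filtering excludes exactly the sub-threshold droplets", {
  ds <- structure(list(labels = matrix(0L, 4, 4),
                       stats = tibble::tibble(label = 1:4)),
                  class = "droplet_set")
  ratios <- list(mcherry = c(1.05, 1.5, 1.2, 2.0),
                 bfp = c(1.2, 1.36, 1.5, 1.34))
  cls <- c(mcherry = "red", bfp = "blue")
  filt <- filter_bleedthrough(ds, ratios, cls)
  expect_equal(filt$retained$mcherry, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(filt$retained$bfp, c(FALSE, TRUE, TRUE, FALSE))

  # monotone: raising a threshold never increases retained count
  counts <- vapply(seq(1, 3, by = 0.1), function(th) {
    sum(filter_bleedthrough(ds, ratios["mcherry"], cls["mcherry"],
                            thresholds = c(red = th))$retained$mcherry)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  # unknown channel class demands an explicit threshold
  expect_error(filter_bleedthrough(ds, list(far_red = c(1.5)),
                                   c(far_red = "infrared")),
               "class")
})

test_that("reference normalization is per-channel and anchors the reference at 1", {
  tbl <- tibble::tibble(
    condition = rep(c("ref", "mut"), each = 4),
    channel = rep(c("g", "g", "r", "r"), 2),
    value = c(2, 2, 4, 4, 3, 1, 2, 6))
  out <- normalize_to_reference(tbl, "ref")
  expect_equal(out$value_norm[out$condition == "ref"], c(1, 1, 1, 1))
  expect_equal(out$value_norm[out$condition == "mut"],
               c(3 / 2, 1 / 2, 2 / 4, 6 / 4))
  # channel independence: permuting channel labels permutes results
  tbl2 <- tbl
  tbl2$channel <- ifelse(tbl2$channel == "g", "r", "g")
  out2 <- normalize_to_reference(tbl2, "ref")
  expect_equal(out2$value_norm, out$value_norm)
  # zero reference mean is an error
  tblz <- tibble::tibble(condition = c("ref", "x"), channel = "g",
                         value = c(0, 3))
  expect_error(normalize_to_reference(tblz, "ref"), "zero")
})

test_that("field metrics assemble per-channel summaries consistently", {
  tr <- droplet_truth(cbind(c(15, 40), c(15, 40)), c(6, 6),
                      interior = c(green = 10, red = 6),
                      exterior = c(green = 2, red = 2), seed = 2)
  f <- gen_droplet_field(tr, dims = c(60, 60))
  ds <- segment_droplets(f, "green", intensity_thresh = 6, min_area = 10)
  m <- field_metrics(f, ds, channel_class = c(green = "green", red = "red"))
  expect_equal(nrow(m), 2)
  expect_true(all(m$condensed_fraction >= 0 & m$condensed_fraction <= 1))
  expect_true(all(m$co_condensed_fraction >= 0 &
                    m$co_condensed_fraction <= 1))
  g <- m[m$channel == "green", ]
  expect_equal(g$n_droplets, 2)
  expect_true(abs(g$mean_partition_ratio - 5) / 5 < 0.02)
})
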