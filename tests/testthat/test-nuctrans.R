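test_that("segmentation handles empty and malformed inputs", {
  flat <- matrix(100, 64, 64)
  expect_equal(max(segment_nuclei(flat)), 0)
  expect_error(segment_nuclei(array(1, c(4, 4, 2))), "2-D")
  expect_error(segment_nuclei(matrix(c(1, NA, 3, 4), 2)), "finite")
})

test_that("well-separated disks are each recovered near their true center", {
  sim <- simulate_cell_image(image_spec(n_cells = 10, seed = 13, noise_sd = 5))
  lab <- segment_nuclei(sim$nuclei)
  expect_equal(max(lab), 10)
  cent <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      label = lab[lab > 0],
      y = row(lab)[lab > 0],
      x = col(lab)[lab > 0]
    ), label),
    x = mean(x), y = mean(y)
  )
  # match each truth center to its nearest segmented centroid
  for (i in seq_len(nrow(sim$truth))) {
    d <- sqrt((cent$x - sim$truth$x[i])^2 + (cent$y - sim$truth$y[i])^2)
    expect_lt(min(d), 2)
  }
})

test_that("touching nuclei are split by the watershed when enabled", {
  img <- matrix(100, 90, 90)
  img[oracle_disk_mask(90, 90, 40, 38, 9)] <- 2000
  img[oracle_disk_mask(90, 90, 40, 54, 9)] <- 2000  # centers 16 px apart, r 9
  split_on <- segment_nuclei(img, segmentation_params(split_touching = TRUE))
  split_off <- segment_nuclei(img, segmentation_params(split_touching = FALSE))
  expect_equal(max(split_off), 1)
  expect_equal(max(split_on), 2)
})

test_that("shape features match per-pixel enumeration on digital disks", {
  lab <- matrix(0L, 40, 40)
  disk <- oracle_disk_mask(40, 40, 20, 20, 10)
  lab[disk] <- 1L
  feats <- shape_features(lab)
  oracle <- oracle_shape(disk)
  expect_equal(feats$area, unname(oracle["area"]))
  expect_equal(feats$perimeter, unname(oracle["perimeter"]), tolerance = 1e-12)
  expect_equal(feats$circularity, unname(oracle["circularity"]),
               tolerance = 1e-12)
  expect_gt(feats$circularity, 0.8)  # r = 10 disk survives the default filter
  expect_lt(feats$circularity, 1.1)
})

test_that("size and circularity filters remove degenerate objects", {
  lab <- matrix(0L, 60, 120)
  lab[oracle_disk_mask(60, 120, 30, 20, 10)] <- 1L  # kept
  lab[10, 40:90] <- 2L                               # 1-px line: low circularity
  lab[40:55, 60:115] <- 3L                           # area 896 < 2000: kept
  kept <- filter_nuclei(lab, segmentation_params(min_circularity = 0.8,
                                                 max_area = 2000))
  expect_equal(max(kept), 2)        # line dropped, labels consecutive
  big <- filter_nuclei(lab, segmentation_params(min_circularity = 0.1,
                                                max_area = 500))
  expect_equal(max(big), 1)         # the 896-px rectangle dropped by area
  small <- filter_nuclei(lab, segmentation_params(min_area = 5000,
                                                  max_area = 6000))
  expect_equal(max(small), 0)
})

test_that("cell mask covers cells and respects constant-image conventions", {
  expect_false(any(cell_mask(matrix(100, 50, 50))))       # flat background
  expect_true(all(cell_mask(matrix(65535, 50, 50))))      # saturated field
  sim <- simulate_cell_image(image_spec(n_cells = 30, seed = 2, noise_sd = 0))
  m <- cell_mask(sim$target)
  covered <- vapply(seq_len(nrow(sim$truth)), function(i) {
    cellpx <- oracle_disk_mask(nrow(m), ncol(m), sim$truth$y[i],
                               sim$truth$x[i], sim$truth$radius[i] + 6)
    mean(m[cellpx])
  }, numeric(1))
  expect_gte(mean(covered), 0.99)
})

test_that("a uniform target field gives ratio exactly 1 and no positives", {
  lab <- matrix(0L, 50, 50)
  lab[oracle_disk_mask(50, 50, 25, 25, 8)] <- 1L
  uniform <- matrix(100, 50, 50)
  rec <- measure_cells(lab, uniform, mask = NULL)
  expect_equal(rec$ratio, 1)
  expect_identical(rec$nuclear_mean, rec$ring_mean)
  expect_false(any(rec$positive))
})

test_that("a 5:1 nucleus over cytosol crosses the positivity threshold", {
  lab <- matrix(0L, 60, 60)
  nuc <- oracle_disk_mask(60, 60, 30, 30, 9)
  lab[nuc] <- 1L
  img <- matrix(0, 60, 60)
  img[oracle_disk_mask(60, 60, 30, 30, 15)] <- 100  # cytosol
  img[nuc] <- 500
  mask <- oracle_disk_mask(60, 60, 30, 30, 15)      # background masked out
  rec <- measure_cells(lab, img, mask)
  expect_equal(rec$ratio, 5, tolerance = 1e-12)
  expect_true(rec$positive)
  # and at exactly the threshold the call is negative (strict inequality)
  img4 <- img; img4[nuc] <- 400
  expect_false(measure_cells(lab, img4, mask)$positive)
})

test_that("pipeline means equal brute-force pixel enumeration on random fixtures", {
  geom <- ring_geometry()
  for (s in 1:20) {
    sim <- simulate_cell_image(image_spec(
      width = 150, height = 150, n_cells = 4, seed = s,
      translocated_fraction = 0.5, noise_sd = 20
    ))
    lab <- filter_nuclei(segment_nuclei(sim$nuclei))
    mask <- cell_mask(sim$target)
    rec <- measure_cells(lab, sim$target, mask, geom)
    orc <- oracle_measure(lab, sim$target, mask,
                          geom$erosion_px, geom$ring_gap_px,
                          geom$ring_width_px)
    orc_lab <- vapply(orc, `[[`, integer(1), "label")
    for (i in seq_len(nrow(rec))) {
      j <- match(rec$label[i], orc_lab)
      expect_equal(rec$nuclear_mean[i], orc[[j]]$nuclear_mean,
                   tolerance = 1e-12)
      expect_equal(rec$ring_mean[i], orc[[j]]$ring_mean, tolerance = 1e-12)
      # disjointness of the measured pixel sets
      expect_equal(sum(orc[[j]]$core & orc[[j]]$ring), 0)
      expect_equal(sum(orc[[j]]$ring & (lab > 0)), 0)
    }
  }
})

test_that("ratios and calls are invariant to intensity rescaling", {
  sim <- simulate_cell_image(image_spec(width = 200, height = 200,
                                        n_cells = 8, seed = 3))
  lab <- filter_nuclei(segment_nuclei(sim$nuclei))
  mask <- cell_mask(sim$target)
  r1 <- measure_cells(lab, sim$target, mask)
  r2 <- measure_cells(lab, sim$target * 7.3, mask)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  expect_identical(r1$positive, r2$positive)
})

test_that("zero-width rings are rejected", {
  expect_error(ring_geometry(ring_width_px = 0), "positive number of pixels")
})

test_that("image summaries count positives over kept nuclei", {
  rec <- tibble::tibble(positive = rep(c(TRUE, FALSE), c(3, 7)))
  s <- summarize_image(rec)
  expect_equal(s$pct_positive, 30)
  expect_equal(s$n_nuclei_kept, 10)
  none <- summarize_image(tibble::tibble(positive = rep(FALSE, 10)))
  expect_equal(none$pct_positive, 0)
  empty <- summarize_image(tibble::tibble(positive = logical(0)))
  expect_true(is.na(empty$pct_positive))
})

test_that("the full pipeline recovers the simulated translocated fraction", {
  for (s in 1:3) {
    sim <- simulate_cell_image(image_spec(n_cells = 200,
                                          translocated_fraction = 0.6,
                                          seed = s))
    res <- suppressMessages(score_translocation(sim$nuclei, sim$target))
    expect_lte(abs(res$summary$pct_positive -
                     100 * mean(sim$truth$translocated)), 5)
  }
})
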