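test_that("background subtraction cancels, clamps and records", {
  img <- matrix(50, 8, 8)
  out <- subtract_background(img, "constant", 50)
  expect_true(all(out == 0))
  img2 <- matrix(c(10, 20, 110), 1, 3)
  expect_equal(unname(subtract_background(img2, "constant", 0)[1, ]),
               c(10, 20, 110))
  # 5th percentile of {10, 20, 110} computed by quantile(), clamped at 0
  out2 <- subtract_background(img2, "percentile", 5)
  bg <- as.numeric(stats::quantile(c(10, 20, 110), 0.05))
  expect_equal(unname(out2[1, ]), pmax(c(10, 20, 110) - bg, 0))
  expect_equal(attr(out2, "background_value"), bg)
  expect_error(subtract_background(img2, "percentile", 101), "percentile")
})

test_that("unsharp sharpening acts as specified on flat and peaked inputs", {
  img <- matrix(3.5, 10, 10)
  expect_equal(sharpen(img, 2), img)        # flat field: zero Laplacian
  expect_identical(sharpen(img, 0), img)    # identity at amount 0
  pk <- matrix(0, 9, 9); pk[5, 5] <- 10
  sh <- sharpen(pk, 1)
  expect_equal(sh[5, 5], 50)                # center: 10 - 1*(0-4*10)
  expect_equal(sh[5, 4], 0)                 # neighbors clamp at 0
  expect_equal(sh[4, 5], 0)
})

test_that("rolling ball removes broad background but keeps sharp spikes", {
  flat <- matrix(42, 20, 20)
  expect_true(all(rolling_ball(flat, 4) == 0))
  # wide dome + one sharp spike on a 16x16 frame
  xs <- matrix(rep(1:16, each = 16), 16, 16)
  ys <- matrix(rep(1:16, times = 16), 16, 16)
  dome <- 100 * exp(-((xs - 8)^2 + (ys - 8)^2) / (2 * 100))
  img <- dome
  img[12, 12] <- img[12, 12] + 80  # one-pixel spike
  out <- rolling_ball(img, 4)
  oracle <- pmax(img - brute_opening(img, 4), 0)
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_gt(out[12, 12], 60)                # spike survives
  sel <- dome > 50; sel[12, 12] <- FALSE
  expect_lt(max(out[sel]), 20)              # broad dome removed
  expect_true(all(out <= img + 1e-12))      # opening is anti-extensive
  expect_warning(rolling_ball(matrix(1:16, 4, 4), 10), "global minimum")
})

test_that("spot segmentation thresholds, size-filters and grows", {
  blank <- matrix(0, 16, 16)
  expect_equal(max(segment_spots(blank, threshold = 10)), 0L)
  img <- matrix(0, 16, 16)
  img[3:4, 3:4] <- 100
  img[10:11, 10:11] <- 100
  img[8, 15] <- 100  # area-1 speck
  seg <- segment_spots(img, threshold = 50, min_area = 2, grow = 0)
  expect_equal(max(seg), 2L)                # two blobs, speck removed
  # otsu on an all-equal image yields an empty mask, not an error
  expect_equal(max(segment_spots(matrix(5, 8, 8), threshold = "otsu")), 0L)
  # growth keeps the two blobs distinct
  seg2 <- segment_spots(img, threshold = 50, min_area = 2, grow = 2)
  expect_equal(max(seg2), 2L)
  expect_gt(sum(seg2 == 1L), sum(seg == 1L))
})

test_that("spot measurement uses the raw image and centroid assignment", {
  mask <- matrix(FALSE, 12, 12)
  mask[3:4, 3:4] <- TRUE
  raw <- matrix(0, 12, 12)
  raw[3:4, 3:4] <- 10
  rois <- matrix(0L, 12, 12)
  rois[2:5, 2:5] <- 3L
  sp <- extract_spots(mask, raw, rois)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$area, 4)
  expect_equal(sp$mean_intensity, 10)
  expect_equal(sp$spot_value, 40)
  expect_equal(sp$cell_label, 3L)
  # straddling spot: centroid decides, totals conserved
  rois2 <- matrix(0L, 10, 10)
  rois2[, 1:5] <- 2L; rois2[, 6:10] <- 3L
  mask2 <- matrix(FALSE, 10, 10)
  mask2[5, 3:7] <- TRUE  # centroid at x = 5 -> label 2
  raw2 <- matrix(1, 10, 10)
  sp2 <- extract_spots(mask2, raw2, rois2)
  expect_equal(sp2$cell_label, 2L)
  expect_equal(sp2$spot_value, 5)
})

test_that("per-cell TFI assembles spots over DAPI with conventions", {
  dapi <- matrix(0, 12, 12)
  rois <- matrix(0L, 12, 12)
  rois[2:5, 2:5] <- 1L; rois[8:11, 8:11] <- 2L
  dapi[rois == 1L] <- 100 / 16
  dapi[rois == 2L] <- 50 / 16
  spots <- data.frame(spot_id = 1L, cell_label = 1L, area = 4,
                      mean_intensity = 5, spot_value = 20,
                      centroid_x = 3, centroid_y = 3)
  cells <- quantify_cells(spots, dapi, rois)
  expect_equal(cells$tfi[cells$cell_label == 1L], 0.2)
  # spotless cell retained with tfi zero
  expect_equal(cells$tfi[cells$cell_label == 2L], 0)
  expect_equal(cells$n_spots[cells$cell_label == 2L], 0L)
  # zero-DAPI cell excluded with a warning
  dapi0 <- dapi; dapi0[rois == 2L] <- 0
  expect_warning(cells0 <- quantify_cells(spots, dapi0, rois),
                 "non-positive DAPI")
  expect_false(2L %in% cells0$cell_label)
})

test_that("noiseless specimen is recovered almost exactly", {
  acq <- clean_acq(width = 128L, height = 128L)
  sp <- specimen_spec("clean", "x", acq,
                      list(compartment_spec("stromal", n_cells = 10,
                                            nucleus_radius = c(5, 0.4))),
                      seed = 15)
  sim <- simulate_specimen(sp)
  cfg <- pipeline_config(background = list(method = "constant", value = 0),
                         segment = list(threshold = 1))
  q <- quantify_image(sim$cy3, sim$dapi, sim$labels, cfg)
  m <- match(q$cells$cell_label, sim$truth$cell_label)
  truth_tfi <- sim$truth$T_true[m] / sim$truth$D_true[m]
  has_signal <- truth_tfi > 0
  expect_true(all(abs(q$cells$tfi[has_signal] / truth_tfi[has_signal] - 1)
                  < 0.01))
})

test_that("compartment means are recovered within 10% under default noise", {
  sp <- specimen_template("rec", epithelial_stromal_ratio = 0.9, seed = 101)
  sim <- simulate_specimen(sp)
  q <- quantify_image(sim$cy3, sim$dapi, sim$labels)
  cells <- q$cells
  m <- match(cells$cell_label, sim$truth$cell_label)
  cells$compartment <- sim$truth$compartment[m]
  truth_tfi <- sim$truth$T_true[m] / sim$truth$D_true[m]
  for (cc in c("epithelial", "stromal")) {
    s <- cells$compartment == cc
    expect_gte(sum(s), 20)
    expect_lt(abs(mean(cells$tfi[s]) / mean(truth_tfi[s]) - 1), 0.1)
  }
})

test_that("TFI scales linearly with the Cy3 channel", {
  sp <- small_template("mono", 1, seed = 55)
  sim <- simulate_specimen(sp)
  cfg1 <- pipeline_config(segment = list(threshold = 150))
  cfg3 <- pipeline_config(segment = list(threshold = 450))
  q1 <- quantify_image(sim$cy3, sim$dapi, sim$labels, cfg1)
  q3 <- quantify_image(3 * sim$cy3, sim$dapi, sim$labels, cfg3)
  # homogeneous chain + threshold scaled with the channel: identical masks,
  # every tfi exactly tripled
  expect_equal(q3$cells$tfi, 3 * q1$cells$tfi, tolerance = 1e-12)
})

test_that("every mask component is accounted for across cells + background", {
  sp <- small_template("acct", 1, seed = 66)
  sim <- simulate_specimen(sp)
  cy3b <- subtract_background(sim$cy3)
  enh <- rolling_ball(sharpen(cy3b, 1), 8)
  seg <- segment_spots(enh)
  spots <- extract_spots(seg, cy3b, sim$labels)
  cells <- quantify_cells(spots, subtract_background(sim$dapi), sim$labels)
  expect_equal(sum(cells$n_spots) + sum(spots$cell_label == 0),
               max(seg))
  expect_equal(nrow(spots), max(seg))
})
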