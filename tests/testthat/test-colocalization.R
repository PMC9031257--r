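test_that("mask correlated with itself scores 1 and known case matches formula", {
  mask <- roi_mask("m", matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(pearson_mask_score(matrix(c(1, 1, 0, 0), 2, 2), mask), 1.0)
  # mask (1,1,0,0) against intensities (1,2,3,4): r = -2/sqrt(5) = -0.8944
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(pearson_mask_score(img, mask), -2 / sqrt(5), tolerance = 1e-12)
  expect_equal(round(pearson_mask_score(img, mask), 4), -0.8944)
})

test_that("zero-variance images give an explicit undefined sentinel", {
  mask <- roi_mask("m", matrix(c(TRUE, FALSE), 1, 2))
  expect_warning(r <- pearson_mask_score(matrix(5, 1, 2), mask), "undefined")
  expect_true(is.na(r))
})

test_that("degenerate masks and shape mismatches are rejected", {
  expect_error(pearson_mask_score(matrix(1:4, 2, 2),
                                  matrix(TRUE, 2, 2)), "at least one")
  expect_error(pearson_mask_score(matrix(1:4, 2, 2),
                                  roi_mask("m", matrix(c(TRUE, FALSE), 1, 2))),
               "shape")
})

test_that("score matches the direct covariance formula and is affine-invariant", {
  set.seed(14)
  for (i in 1:50) {
    img <- matrix(rexp(24), 4, 6)
    m <- matrix(runif(24) < 0.4, 4, 6)
    if (!any(m) || all(m)) next
    r <- pearson_mask_score(img, m)
    expect_equal(r, oracle_pearson(as.numeric(m), as.numeric(img)),
                 tolerance = 1e-12)
    # positive affine rescaling of the image leaves r unchanged
    expect_equal(pearson_mask_score(3.7 * img + 11, m), r, tolerance = 1e-12)
    # complementing the mask flips the sign
    expect_equal(pearson_mask_score(img, !m), -r, tolerance = 1e-12)
  }
})

test_that("markers are ranked per ROI with exclusive best-ROI assignment", {
  # 1x4 grid, two ROIs covering pixels 1-2 and 3-4
  roiA <- roi_mask("A", matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4))
  roiB <- roi_mask("B", matrix(c(FALSE, FALSE, TRUE, TRUE), 1, 4))
  # feature 1 perfectly matches A; feature 2 perfectly matches B;
  # feature 3 noisy but closer to A
  mat <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(2, 1.5, 0.4, 0.1))
  binned <- msi_binned(c(300, 400, 500), mat, width = 4, height = 1)
  hits <- rank_markers(binned, list(roiA, roiB), min_r = 0.5, top_n = 10)
  expect_equal(hits$feature_mz[hits$roi_name == "A"], c(300, 500))
  expect_equal(hits$feature_mz[hits$roi_name == "B"], 400)
  expect_equal(hits$rank[hits$roi_name == "A"], 1:2)
  # exclusivity: feature 300 appears once, in its best ROI only
  expect_equal(sum(hits$feature_mz == 300), 1L)
  # unreachable threshold empties the table
  none <- rank_markers(binned, list(roiA, roiB), min_r = 1.01)
  expect_equal(nrow(none), 0L)
})

test_that("ties in r break by ascending m/z and top_n truncates", {
  roiA <- roi_mask("A", matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4))
  mat <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 1, 0, 0))
  binned <- msi_binned(c(300, 400, 500), mat, width = 4, height = 1)
  hits <- rank_markers(binned, list(roiA), min_r = 0.5, top_n = 2)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$feature_mz, c(300, 400))
})

test_that("planted phantom markers score highest on their own zone", {
  cfg <- small_phantom_config(seed = 12, dropout = 0, jitter_ppm_sd = 0,
                              leakage = 0)
  sim <- generate_phantom(cfg)
  binned <- suppressMessages(tic_normalize(bin_peaks(deisotope_dataset(sim$dataset))))
  rois <- lapply(names(sim$truth$region_masks), function(nm) {
    roi_mask(nm, sim$truth$region_masks[[nm]])
  })
  hits <- rank_markers(binned, rois, min_r = 0.5, top_n = 25)
  tab <- sim$truth$marker_table
  periph <- tab[tab$region == "sg_peripheral", ]
  for (i in seq_len(nrow(periph))) {
    in_roi <- hits[hits$roi_name == "sg_peripheral" &
                     abs(hits$feature_mz - periph$mz[i]) / periph$mz[i] * 1e6 <= 2.5, ]
    expect_equal(nrow(in_roi), 1L)
    expect_gte(in_roi$r, 0.9)
  }
  # no central marker leaks into the peripheral list
  central <- tab[tab$region == "sg_central", ]
  expect_false(any(abs(outer(hits$feature_mz[hits$roi_name == "sg_peripheral"],
                             central$mz, "-")) < 0.01))
  # the DG(36:1)-emulating ion scores higher on the central core than the ring
  dg_img <- ion_image(binned, central$mz[1], 2.5)
  r_central <- pearson_mask_score(dg_img, sim$truth$region_masks$sg_central)
  r_periph <- pearson_mask_score(dg_img, sim$truth$region_masks$sg_peripheral)
  expect_gt(r_central, r_periph)
})
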