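test_that("the two printed central-zone measurements fall into one bin", {
  ds <- msi_dataset(list(
    pixel_spectrum(0, 0, 661.5175, 100),
    pixel_spectrum(1, 0, 661.5187, 80)
  ), width = 2, height = 1)
  binned <- bin_peaks(ds, tolerance_ppm = 2.5)
  expect_length(binned$feature_mzs, 1L)
  expect_equal(binned$features$n_members, 2L)
  # intensity-weighted representative lies between the members
  expect_gt(binned$feature_mzs, 661.5175)
  expect_lt(binned$feature_mzs, 661.5187)
})

test_that("well-separated peaks stay in separate bins", {
  ds <- msi_dataset(list(pixel_spectrum(0, 0, c(500, 600), c(1, 1))),
                    width = 1, height = 1)
  binned <- bin_peaks(ds, tolerance_ppm = 2.5)
  expect_equal(binned$feature_mzs, c(500, 600))
  expect_equal(dim(binned$intensity_matrix), c(1L, 2L))
})

test_that("binning matches the O(n^2) single-linkage oracle", {
  set.seed(42)
  for (trial in 1:200) {
    mz <- random_peak_pool(50)
    ds <- msi_dataset(list(pixel_spectrum(0, 0, unique(mz), rep(1, length(unique(mz))))),
                      width = 1, height = 1)
    binned <- bin_peaks(ds, tolerance_ppm = 2.5)
    want <- oracle_single_linkage(unique(mz), 2.5)
    expect_equal(length(binned$feature_mzs), length(unique(want)),
                 info = paste("trial", trial))
    # contiguity: oracle labels must change exactly where bins change
    oracle_breaks <- which(diff(want) != 0)
    member <- rep(seq_along(binned$features$n_members),
                  binned$features$n_members)
    expect_equal(which(diff(member) != 0), oracle_breaks,
                 info = paste("trial", trial))
  }
})

test_that("binning is idempotent at a fixed tolerance", {
  sim <- generate_phantom(small_phantom_config(seed = 2))
  b1 <- bin_peaks(sim$dataset, 2.5)
  # re-bin the representative axis itself
  ds2 <- msi_dataset(list(pixel_spectrum(0, 0, b1$feature_mzs,
                                         rep(1, length(b1$feature_mzs)))),
                     width = 1, height = 1)
  b2 <- bin_peaks(ds2, 2.5)
  expect_equal(b2$feature_mzs, b1$feature_mzs)
})

test_that("pixel intensities sum into the right matrix cells", {
  binned <- bin_peaks(tiny_dataset(), tolerance_ppm = 2.5)
  expect_length(binned$feature_mzs, 2L)
  # raster order: (0,0), (1,0), (0,1), (1,1)
  expect_equal(binned$intensity_matrix[, 1], c(10, 20, 30, 40))
  expect_equal(binned$intensity_matrix[, 2], c(1, 2, 3, 4))
})

test_that("deisotoping removes an isotope ladder but keeps the monoisotopic peak", {
  sp <- pixel_spectrum(0, 0, c(700.5000, 701.5034, 702.5067), c(100, 40, 10))
  out <- deisotope(sp, tolerance_ppm = 2.5, max_isotopes = 3)
  expect_equal(out$mz, 700.5000)
  expect_equal(out$intensity, 100)
})

test_that("a heavier, more intense peak is not treated as an isotope", {
  sp <- pixel_spectrum(0, 0, c(700.5000, 701.5034), c(40, 100))
  out <- deisotope(sp)
  expect_equal(out$mz, c(700.5000, 701.5034))
})

test_that("single peaks and lightest peaks always survive deisotoping", {
  one <- pixel_spectrum(0, 0, 500.25, 7)
  expect_identical(deisotope(one), one)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    mz <- sort(500 + cumsum(runif(n, 0.2, 1.3)))
    sp <- pixel_spectrum(0, 0, mz, runif(n, 1, 100))
    out <- deisotope(sp)
    expect_equal(out$mz[1], mz[1])
    expect_lte(length(out$mz), n)
  }
})

test_that("TIC normalization scales nonzero pixels to unit total", {
  binned <- msi_binned(c(100, 200), rbind(c(2, 2), c(0, 0), c(1, 3), c(5, 0)),
                       width = 2, height = 2)
  expect_message(norm <- tic_normalize(binned), "zero total ion current")
  expect_equal(norm$intensity_matrix[1, ], c(0.5, 0.5))
  expect_equal(norm$intensity_matrix[2, ], c(0, 0))
  sums <- rowSums(norm$intensity_matrix)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-9))
})

test_that("ion images reshape and sum matching feature columns", {
  binned <- msi_binned(c(400.0000, 400.0004, 500.0),
                       cbind(1:4, 10 * (1:4), 100 * (1:4)),
                       width = 2, height = 2)
  # no feature near the query
  expect_equal(ion_image(binned, 900, 2.5), matrix(0, 2, 2))
  # single match reshapes the column in raster order (row-major)
  img <- ion_image(binned, 500.0, 2.5)
  expect_equal(img, matrix(c(100, 200, 300, 400), 2, 2, byrow = TRUE))
  # two features within tolerance are summed
  img2 <- ion_image(binned, 400.0002, 2.5)
  expect_equal(img2, matrix(c(11, 22, 33, 44), 2, 2, byrow = TRUE))
})
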