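test_that("identical pixels split into a degenerate zero-SSE partition", {
  x <- matrix(1, nrow = 6, ncol = 3)
  res <- bisecting_kmeans(x, k = 2, seed = 1)
  expect_equal(res$k, 2L)
  expect_equal(res$total_sse, 0)
  expect_setequal(unique(res$labels), c(0L, 1L))
})

test_that("2-means split matches the exhaustive minimum-SSE bipartition", {
  set.seed(99)
  for (trial in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rbind(matrix(rnorm(n1 * 2, mean = 0, sd = 0.4), ncol = 2),
               matrix(rnorm(n2 * 2, mean = 4, sd = 0.4), ncol = 2))
    res <- bisecting_kmeans(x, k = 2, seed = trial)
    want <- oracle_best_bipartition(x)
    got <- res$labels == res$labels[1]
    expect_true(identical(got, want$split) || identical(got, !want$split),
                info = paste("trial", trial))
    sse <- sum(vapply(0:1, function(c) {
      m <- x[res$labels == c, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }, numeric(1)))
    expect_equal(sse, want$sse, tolerance = 1e-10)
  }
})

test_that("bisecting k-means agrees with a stats::kmeans cross-check on clean data", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 2),
             matrix(rnorm(60, 5, 0.3), ncol = 2),
             matrix(rnorm(60, c(0, 10), 0.3), ncol = 2, byrow = FALSE))
  res <- bisecting_kmeans(x, k = 3, seed = 2)
  km <- stats::kmeans(x, centers = 3, nstart = 20)
  expect_equal(adjusted_rand(res$labels, km$cluster), 1.0)
  expect_equal(res$total_sse, km$tot.withinss, tolerance = 1e-8)
})

test_that("segmentation is reproducible and total SSE non-increasing in k", {
  sim <- generate_phantom(small_phantom_config(seed = 4))
  binned <- suppressMessages(tic_normalize(bin_peaks(deisotope_dataset(sim$dataset))))
  a <- segment_msi(binned, k = 5, seed = 31)
  b <- segment_msi(binned, k = 5, seed = 31)
  expect_identical(a$labels, b$labels)
  sses <- vapply(1:6, function(k) {
    segment_msi(binned, k = k, seed = 31)$total_sse
  }, numeric(1))
  expect_true(all(diff(sses) <= 1e-9))
})

test_that("total_sse equals the value recomputed from labels", {
  set.seed(8)
  x <- matrix(rnorm(200), ncol = 4)
  res <- bisecting_kmeans(x, k = 4, seed = 3)
  recomputed <- sum(vapply(0:3, function(c) {
    m <- x[res$labels == c, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }, numeric(1)))
  expect_equal(res$total_sse, recomputed, tolerance = 1e-10)
  expect_equal(nrow(res$bisection_log), 3L)
})

test_that("degenerate inputs are rejected", {
  expect_error(bisecting_kmeans(matrix(0, 0, 2), k = 1), "empty")
  expect_error(bisecting_kmeans(matrix(1:4, 2, 2), k = 3), "exceeds")
})

test_that("ROI masks come from cluster labels and reject bad ids", {
  sim <- generate_phantom(small_phantom_config(seed = 6))
  binned <- suppressMessages(tic_normalize(bin_peaks(sim$dataset)))
  seg <- segment_msi(binned, k = 1, seed = 1)
  roi <- roi_from_labels(seg, 0, "all")
  expect_true(all(roi$mask))
  expect_error(roi_from_labels(seg, 5), "0..0")
  expect_error(roi_from_labels(seg, -1), "0..0")
})

test_that("phantom SG central cluster overlaps the true central core", {
  sim <- generate_phantom(small_phantom_config(seed = 9))
  binned <- suppressMessages(tic_normalize(bin_peaks(deisotope_dataset(sim$dataset))))
  seg <- segment_msi(binned, k = length(sim$truth$region_masks) + 1L, seed = 17)
  cm <- map_clusters_to_regions(seg, sim$truth)
  central <- cm[cm$region == "sg_central", ]
  expect_equal(nrow(central), 1L)
  expect_gte(central$jaccard, 0.8)
  # SG differentiates into separate peripheral and central clusters
  expect_true("sg_peripheral" %in% cm$region)
})

test_that("adjusted Rand index matches hand-computed and reference values", {
  a <- c(0, 0, 0, 0, 1, 1, 1, 1)
  b <- c(0, 0, 1, 1, 1, 1, 1, 1)
  # contingency 2x2: {2,2;0,4}; sum C(nij,2)=8, sums 12 and 16, n=8
  expect_equal(adjusted_rand(a, b), 0.16)
  expect_equal(adjusted_rand(a, a), 1.0)
  # label permutation leaves agreement perfect
  expect_equal(adjusted_rand(a, 1 - a), 1.0)
  expect_error(adjusted_rand(a, b[1:4]), "shape")
  skip_if_not_installed("mclust")
  set.seed(3)
  for (i in 1:10) {
    u <- sample(0:3, 40, replace = TRUE)
    v <- sample(0:2, 40, replace = TRUE)
    expect_equal(adjusted_rand(u, v), mclust::adjustedRandIndex(u, v),
                 tolerance = 1e-12)
  }
})
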