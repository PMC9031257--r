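# Spatial segmentation: bisecting k-means on pixel spectra, ROI masks from
# cluster labels, adjusted Rand agreement between labelings.

with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

cluster_sse <- function(x) {
  if (nrow(x) <= 1L) return(0)
  ctr <- colMeans(x)
  sum(x^2) - nrow(x) * sum(ctr^2)
}

# One 2-means split (Lloyd). Trial 0 initializes deterministically at the
# farthest pixel from the cluster centroid and the farthest pixel from that
# one (so small, well-separated structures can be peeled off a large noisy
# cluster); the remaining `trials` use two distinct pixels drawn uniformly
# at random. The split with the lowest SSE wins. Returns assignment in
# {1,2} of the rows of x, or NULL when x is degenerate (all rows identical).
two_means_split <- function(x, trials, max_iter = 100L, max_restarts = 10L) {
  n <- nrow(x)
  xsq <- rowSums(x^2)
  ctr <- colMeans(x)
  far1 <- which.max(xsq - 2 * drop(x %*% ctr))
  far2 <- which.max(xsq - 2 * drop(x %*% x[far1, ]))
  best <- NULL
  best_sse <- Inf
  for (t in 0:trials) {
    assign_t <- NULL
    for (r in seq_len(max_restarts)) {
      init <- if (t == 0L) c(far1, far2) else sample.int(n, 2L)
      c1 <- x[init[1], ]; c2 <- x[init[2], ]
      if (all(c1 == c2)) {
        if (t == 0L) break else next
      }
      lab <- NULL
      ok <- TRUE
      for (iter in seq_len(max_iter)) {
        d1 <- xsq - 2 * drop(x %*% c1) + sum(c1^2)
        d2 <- xsq - 2 * drop(x %*% c2) + sum(c2^2)
        new_lab <- ifelse(d2 < d1, 2L, 1L)
        if (!any(new_lab == 1L) || !any(new_lab == 2L)) { ok <- FALSE; break }
        if (!is.null(lab) && all(new_lab == lab)) break
        lab <- new_lab
        c1 <- colMeans(x[lab == 1L, , drop = FALSE])
        c2 <- colMeans(x[lab == 2L, , drop = FALSE])
      }
      if (ok && !is.null(lab)) { assign_t <- lab; break }
      if (t == 0L) break  # deterministic init: no point re-trying it
    }
    if (is.null(assign_t)) next
    sse <- cluster_sse(x[assign_t == 1L, , drop = FALSE]) +
      cluster_sse(x[assign_t == 2L, , drop = FALSE])
    if (sse < best_sse) { best_sse <- sse; best <- assign_t }
  }
  best
}

#' Bisecting k-means clustering of a pixel-by-feature matrix
#'
#' Starts with all pixels in one cluster and repeatedly splits the cluster
#' with the largest within-cluster sum of squared Euclidean distances (SSE)
#' by standard 2-means (best of `trials_per_split` random two-pixel
#' initializations, Lloyd iterations to convergence or 100 iterations) until
#' `k` clusters exist. Deterministic for a fixed `seed`.
#'
#' @param matrix n_pixels x n_features numeric matrix (finite).
#' @param k target number of clusters (1 <= k <= n_pixels).
#' @param seed integer seed controlling all split initializations.
#' @param trials_per_split random restarts per split (default 10).
#' @return list of class `segmentation_result` with elements `labels`
#'   (0-based cluster id per row), `k`, `centroids` (k x n_features),
#'   `total_sse`, and `bisection_log` (data.frame of the split sequence).
#' @export
bisecting_kmeans <- function(matrix, k, seed = 1L, trials_per_split = 10L) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) == 0L) stop("empty matrix: nothing to cluster")
  if (!all(is.finite(matrix))) stop("matrix must be finite")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(matrix)) {
    stop("k (", k, ") exceeds the number of pixels (", nrow(matrix), ")")
  }
  with_rng_seed(seed, {
    members <- list(seq_len(nrow(matrix)))
    sses <- cluster_sse(matrix)
    log_rows <- list()
    step <- 0L
    while (length(members) < k) {
      step <- step + 1L
      splittable <- vapply(members, length, integer(1)) >= 2L
      if (!any(splittable)) stop("no cluster with >= 2 pixels left to split")
      cand <- which(splittable)
      target <- cand[which.max(sses[cand])]
      rows <- members[[target]]
      x <- matrix[rows, , drop = FALSE]
      split <- two_means_split(x, trials = trials_per_split)
      if (is.null(split)) {
        # all member pixels identical: degenerate split, one pixel peeled off
        split <- c(1L, rep(2L, length(rows) - 1L))
      }
      g1 <- rows[split == 1L]; g2 <- rows[split == 2L]
      sse_before <- sses[target]
      members[[target]] <- g1
      members[[length(members) + 1L]] <- g2
      sses[target] <- cluster_sse(matrix[g1, , drop = FALSE])
      sses[length(members)] <- cluster_sse(matrix[g2, , drop = FALSE])
      log_rows[[step]] <- data.frame(
        step = step, split_cluster = target - 1L,
        n_before = length(rows), sse_before = sse_before,
        n_child1 = length(g1), n_child2 = length(g2),
        sse_after = sses[target] + sses[length(members)])
    }
    labels <- integer(nrow(matrix))
    for (i in seq_along(members)) labels[members[[i]]] <- i - 1L
    centroids <- t(vapply(members, function(rows) {
      colMeans(matrix[rows, , drop = FALSE])
    }, numeric(ncol(matrix))))
    structure(list(
      labels = labels,
      k = length(members),
      centroids = centroids,
      total_sse = sum(sses),
      bisection_log = if (step) do.call(rbind, log_rows) else
        data.frame(step = integer(0), split_cluster = integer(0),
                   n_before = integer(0), sse_before = numeric(0),
                   n_child1 = integer(0), n_child2 = integer(0),
                   sse_after = numeric(0))
    ), class = "segmentation_result")
  })
}

#' Segment a binned MSI dataset into spatial clusters
#'
#' Convenience wrapper: runs [bisecting_kmeans()] on the (typically
#' TIC-normalized) intensity matrix and attaches the label grid.
#'
#' @param dataset binned-mode [msi_dataset()].
#' @inheritParams bisecting_kmeans
#' @return `segmentation_result` with an additional `label_grid`
#'   (`height` x `width` matrix of 0-based cluster ids).
#' @export
segment_msi <- function(dataset, k, seed = 1L, trials_per_split = 10L) {
  if (!is_binned(dataset)) stop("segment_msi needs a binned msi_dataset")
  res <- bisecting_kmeans(dataset$intensity_matrix, k = k, seed = seed,
                          trials_per_split = trials_per_split)
  res$label_grid <- matrix(res$labels, nrow = dataset$height,
                           ncol = dataset$width, byrow = TRUE)
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> k=%d, total SSE %.6g, %d pixels\n",
              x$k, x$total_sse, length(x$labels)))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Binary ROI mask of one cluster
#'
#' @param seg a `segmentation_result` carrying a `label_grid` (see
#'   [segment_msi()]).
#' @param cluster_id 0-based cluster id in `0..k-1`.
#' @param name label for the ROI.
#' @return list of class `roi_mask` with `name` and logical `mask`
#'   (`height` x `width`).
#' @export
roi_from_labels <- function(seg, cluster_id, name = paste0("cluster_", cluster_id)) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (is.null(seg$label_grid)) {
    stop("segmentation_result has no label grid; use segment_msi()")
  }
  cluster_id <- as.integer(cluster_id)
  if (cluster_id < 0L || cluster_id >= seg$k) {
    stop("cluster_id must lie in 0..", seg$k - 1L)
  }
  mask <- seg$label_grid == cluster_id
  if (!any(mask)) stop("cluster ", cluster_id, " is empty; no usable ROI")
  roi_mask(name, mask)
}

#' Construct an ROI mask
#'
#' @param name label string.
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(name, mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("ROI mask '", name, "' has no pixels")
  structure(list(name = name, mask = mask), class = "roi_mask")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two label grids/vectors of the same
#' shape; 1 for identical partitions (up to label permutation), ~0 for
#' independent ones.
#'
#' @param labels_a,labels_b label matrices or vectors of identical shape.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (!identical(dim(labels_a), dim(labels_b)) ||
      length(labels_a) != length(labels_b)) {
    stop("labelings must have identical shape")
  }
  a <- as.vector(labels_a); b <- as.vector(labels_b)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Export a label grid as TSV
#'
#' @param seg `segmentation_result` with `label_grid`.
#' @param path output TSV path (rows = image rows).
#' @export
write_label_grid <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation_result"), !is.null(seg$label_grid))
  utils::write.table(seg$label_grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export an ROI mask as a 0/1 TSV grid
#'
#' @param roi an `roi_mask`.
#' @param path output TSV path.
#' @export
write_roi_mask <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  utils::write.table(roi$mask + 0L, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
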