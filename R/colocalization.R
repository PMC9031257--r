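# Mask-to-ion co-localization: Pearson correlation of each feature's ion
# image against binary ROI masks, marker ranking and selection.

#' Pearson correlation between an ROI mask and an intensity image
#'
#' Correlates the flattened 0/1 mask with the flattened intensities over all
#' pixels of the section.
#'
#' @param image numeric intensity matrix.
#' @param mask an [roi_mask()] (or logical matrix) of the same shape; must
#'   contain at least one `TRUE` and one `FALSE` pixel.
#' @return Pearson r in `[-1, 1]`, or `NA_real_` (with a warning) when the
#'   image has zero variance and the correlation is undefined.
#' @export
pearson_mask_score <- function(image, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(dim(image), dim(m))) {
    stop("image and mask must have identical shape")
  }
  mv <- as.numeric(m)
  if (!any(mv == 1) || !any(mv == 0)) {
    stop("mask must contain at least one TRUE and one FALSE pixel")
  }
  iv <- as.numeric(image)
  if (stats::sd(iv) == 0) {
    warning("zero-variance image: correlation undefined")
    return(NA_real_)
  }
  stats::cor(mv, iv)
}

#' Rank co-localized marker features per ROI
#'
#' Scores every feature of a binned dataset against every ROI mask by
#' Pearson correlation, keeps features with `r >= min_r`, assigns each kept
#' feature exclusively to its best-scoring ROI, and returns per-ROI lists
#' truncated to `top_n`, ranked by descending r (ties broken by ascending
#' m/z).
#'
#' @param dataset binned-mode [msi_dataset()].
#' @param rois list of [roi_mask()] objects (distinct names).
#' @param min_r minimum Pearson r to report (default 0.5).
#' @param top_n maximum markers per ROI (default 25).
#' @return data.frame of co-localization hits with columns `roi_name`,
#'   `rank`, `feature_mz`, `r` (possibly 0 rows).
#' @export
rank_markers <- function(dataset, rois, min_r = 0.5, top_n = 25L) {
  if (!is_binned(dataset)) stop("rank_markers needs a binned msi_dataset")
  stopifnot(length(rois) >= 1L)
  roi_names <- vapply(rois, function(r) r$name, character(1))
  if (anyDuplicated(roi_names)) stop("ROI names must be distinct")
  masks <- vapply(rois, function(r) {
    if (!identical(dim(r$mask), c(dataset$height, dataset$width))) {
      stop("ROI '", r$name, "' does not match the dataset grid")
    }
    # mask grids are row-major images; matrix rows are raster-ordered pixels
    as.numeric(t(r$mask))
  }, numeric(dataset$width * dataset$height))

  empty <- data.frame(roi_name = character(0), rank = integer(0),
                      feature_mz = numeric(0), r = numeric(0))
  if (!length(dataset$feature_mzs)) return(empty)
  suppressWarnings(rmat <- stats::cor(dataset$intensity_matrix, masks))
  # zero-variance features yield NA and are never reported
  best_roi <- apply(rmat, 1L, function(z) {
    if (all(is.na(z))) NA_integer_ else which.max(z)
  })
  best_r <- rmat[cbind(seq_len(nrow(rmat)), best_roi)]
  keep <- !is.na(best_r) & best_r >= min_r
  if (!any(keep)) return(empty)
  hits <- data.frame(
    roi_name = roi_names[best_roi[keep]],
    feature_mz = dataset$feature_mzs[keep],
    r = best_r[keep], stringsAsFactors = FALSE)
  out <- lapply(split(hits, hits$roi_name), function(h) {
    h <- h[order(-h$r, h$feature_mz), , drop = FALSE]
    h <- utils::head(h, top_n)
    h$rank <- seq_len(nrow(h))
    h
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("roi_name", "rank", "feature_mz", "r")]
}

#' Write a marker table as TSV
#'
#' @param hits data.frame from [rank_markers()].
#' @param path output path.
#' @export
write_marker_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
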