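# Containers for MSI data: per-pixel centroided spectra (raw mode) or a
# binned pixel x feature intensity matrix (binned mode).

#' Construct a single-pixel centroided spectrum
#'
#' @param x,y 0-based pixel coordinates (x rightward, y downward).
#' @param mz strictly increasing m/z values (Da).
#' @param intensity non-negative abundances, same length as `mz`.
#' @return object of class `pixel_spectrum`.
#' @export
pixel_spectrum <- function(x, y, mz, intensity) {
  x <- as.integer(x); y <- as.integer(y)
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  stopifnot(length(x) == 1L, length(y) == 1L, x >= 0L, y >= 0L)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length")
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("mz must be strictly increasing; sort the peak list first")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(x = x, y = y, mz = mz, intensity = intensity),
            class = "pixel_spectrum")
}

#' Construct an MSI dataset in raw (per-pixel peak list) mode
#'
#' Pixels follow a row-major raster: index `y * width + x + 1`. Spectra may
#' cover only a subset of grid positions (e.g. after pixel dropout), but two
#' spectra may not share a position.
#'
#' @param spectra list of [pixel_spectrum()] objects.
#' @param width,height grid dimensions in pixels.
#' @param pixel_size_um physical pixel pitch in micrometres (default 10).
#' @param mz_range acquisition m/z range, default `c(200, 1500)`.
#' @return object of class `msi_dataset` with `mode = "raw"`.
#' @export
msi_dataset <- function(spectra, width, height, pixel_size_um = 10,
                        mz_range = c(200, 1500)) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 0L, height >= 0L, pixel_size_um > 0,
            length(mz_range) == 2L, mz_range[1] < mz_range[2])
  ok <- vapply(spectra, inherits, logical(1), what = "pixel_spectrum")
  if (length(spectra) && !all(ok)) stop("spectra must be pixel_spectrum objects")
  xs <- vapply(spectra, `[[`, integer(1), "x")
  ys <- vapply(spectra, `[[`, integer(1), "y")
  if (length(spectra)) {
    if (any(xs >= width) || any(ys >= height)) {
      stop("spectrum coordinates fall outside the ", width, "x", height, " grid")
    }
    idx <- ys * width + xs
    if (anyDuplicated(idx)) {
      d <- idx[duplicated(idx)][1]
      stop(sprintf("coordinate collision: more than one spectrum at pixel (x=%d, y=%d)",
                   d %% width, d %/% width))
    }
  }
  structure(list(
    mode = "raw",
    spectra = spectra,
    width = width, height = height,
    pixel_size_um = pixel_size_um,
    mz_range = as.numeric(mz_range)
  ), class = "msi_dataset")
}

#' Construct an MSI dataset in binned (feature matrix) mode
#'
#' @param feature_mzs strictly increasing representative m/z values.
#' @param intensity_matrix `width*height` x `n_features` non-negative matrix,
#'   rows in row-major raster order (y outer).
#' @param width,height,pixel_size_um,mz_range as in [msi_dataset()].
#' @param features optional data.frame describing the bins
#'   (`representative_mz`, `n_members`, `tolerance_ppm`).
#' @return object of class `msi_dataset` with `mode = "binned"`.
#' @export
msi_binned <- function(feature_mzs, intensity_matrix, width, height,
                       pixel_size_um = 10, mz_range = c(200, 1500),
                       features = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  feature_mzs <- as.numeric(feature_mzs)
  intensity_matrix <- as.matrix(intensity_matrix)
  stopifnot(nrow(intensity_matrix) == width * height,
            ncol(intensity_matrix) == length(feature_mzs))
  if (length(feature_mzs) > 1L && any(diff(feature_mzs) <= 0)) {
    stop("feature_mzs must be strictly increasing")
  }
  if (any(intensity_matrix < 0)) stop("intensities must be non-negative")
  structure(list(
    mode = "binned",
    feature_mzs = feature_mzs,
    intensity_matrix = intensity_matrix,
    width = width, height = height,
    pixel_size_um = pixel_size_um,
    mz_range = as.numeric(mz_range),
    features = features
  ), class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset %s mode> %dx%d grid, %g um pixels\n",
              x$mode, x$width, x$height, x$pixel_size_um))
  if (x$mode == "raw") {
    n <- length(x$spectra)
    npk <- if (n) sum(vapply(x$spectra, function(s) length(s$mz), integer(1))) else 0L
    cat(sprintf("  %d spectra, %d peaks total, m/z range [%g, %g]\n",
                n, npk, x$mz_range[1], x$mz_range[2]))
  } else {
    cat(sprintf("  %d features, m/z [%g, %g]\n",
                length(x$feature_mzs),
                if (length(x$feature_mzs)) min(x$feature_mzs) else NA,
                if (length(x$feature_mzs)) max(x$feature_mzs) else NA))
  }
  invisible(x)
}

is_raw <- function(dataset) {
  inherits(dataset, "msi_dataset") && identical(dataset$mode, "raw")
}

is_binned <- function(dataset) {
  inherits(dataset, "msi_dataset") && identical(dataset$mode, "binned")
}

raster_index <- function(x, y, width) y * width + x + 1L

#' Export a binned feature table as TSV
#'
#' Writes one row per feature: `feature_mz` followed by one intensity column
#' per pixel in row-major raster order (`px<index>` headers).
#'
#' @param dataset binned-mode [msi_dataset()].
#' @param path output file path.
#' @export
write_feature_table <- function(dataset, path) {
  if (!is_binned(dataset)) stop("write_feature_table needs a binned dataset")
  tab <- data.frame(feature_mz = dataset$feature_mzs,
                    t(dataset$intensity_matrix), check.names = FALSE)
  names(tab) <- c("feature_mz", paste0("px", seq_len(nrow(dataset$intensity_matrix)) - 1L))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binned feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @param width,height grid dimensions (the table itself stores only the
#'   raster-ordered pixel columns).
#' @param pixel_size_um,mz_range passed to [msi_binned()].
#' @return binned-mode [msi_dataset()].
#' @export
read_feature_table <- function(path, width, height, pixel_size_um = 10,
                               mz_range = c(200, 1500)) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  mzs <- tab$feature_mz
  mat <- t(as.matrix(tab[, -1, drop = FALSE]))
  dimnames(mat) <- NULL
  msi_binned(mzs, mat, width, height, pixel_size_um, mz_range)
}

#' Import a delimited per-pixel peak list
#'
#' Reads a delimited file with columns `x`, `y`, `mz`, `intensity` (0-based
#' pixel coordinates) into a raw-mode dataset.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param pixel_size_um,mz_range as in [msi_dataset()].
#' @return raw-mode [msi_dataset()]; grid dimensions from the maximum
#'   coordinates present.
#' @export
read_peaklist <- function(path, sep = "\t", pixel_size_um = 10,
                          mz_range = c(200, 1500)) {
  tab <- utils::read.table(path, sep = sep, header = TRUE)
  need <- c("x", "y", "mz", "intensity")
  if (!all(need %in% names(tab))) {
    stop("peak list must have columns: ", paste(need, collapse = ", "))
  }
  split_idx <- tab$y * (max(tab$x) + 1L) + tab$x
  groups <- split(tab, split_idx)
  spectra <- lapply(groups, function(g) {
    o <- order(g$mz)
    pixel_spectrum(g$x[1], g$y[1], g$mz[o], g$intensity[o])
  })
  msi_dataset(unname(spectra), width = max(tab$x) + 1L, height = max(tab$y) + 1L,
              pixel_size_um = pixel_size_um, mz_range = mz_range)
}
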