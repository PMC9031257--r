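# Peak-list preprocessing: ppm-tolerance binning onto a common feature axis,
# deisotoping of centroided spectra, TIC normalization, ion images.

#' Bin peaks from all pixels onto a common m/z feature axis
#'
#' All peaks from all spectra are pooled, sorted by m/z and partitioned by
#' greedy single linkage: a new bin starts wherever the gap to the previous
#' peak exceeds `tolerance_ppm` relative to the previous peak's m/z. Each
#' bin's representative m/z is the intensity-weighted mean of its member
#' peaks; each matrix cell is the sum of one pixel's member-peak intensities.
#'
#' @param dataset raw-mode [msi_dataset()].
#' @param tolerance_ppm positive linkage tolerance in ppm (default 2.5,
#'   matching the accurate-mass identification tolerance).
#' @return binned-mode [msi_dataset()]; its `features` element is a
#'   data.frame with `representative_mz`, `n_members` and `tolerance_ppm`.
#' @export
bin_peaks <- function(dataset, tolerance_ppm = 2.5) {
  if (!is_raw(dataset)) stop("bin_peaks needs a raw-mode msi_dataset")
  stopifnot(tolerance_ppm > 0)
  spectra <- dataset$spectra
  npix <- dataset$width * dataset$height
  lens <- vapply(spectra, function(s) length(s$mz), integer(1))
  mz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
  if (is.null(mz) || !length(mz)) {
    return(msi_binned(numeric(0), matrix(0, npix, 0), dataset$width,
                      dataset$height, dataset$pixel_size_um, dataset$mz_range,
                      features = data.frame(representative_mz = numeric(0),
                                            n_members = integer(0),
                                            tolerance_ppm = numeric(0))))
  }
  intensity <- unlist(lapply(spectra, `[[`, "intensity"), use.names = FALSE)
  pix <- rep.int(
    raster_index(vapply(spectra, `[[`, integer(1), "x"),
                 vapply(spectra, `[[`, integer(1), "y"), dataset$width),
    lens)

  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; pix <- pix[o]
  gap_ppm <- diff(mz) / mz[-length(mz)] * 1e6
  bin <- cumsum(c(TRUE, gap_ppm > tolerance_ppm))
  nbin <- bin[length(bin)]

  wsum <- rowsum_vec(mz * intensity, bin, nbin)
  isum <- rowsum_vec(intensity, bin, nbin)
  msum <- rowsum_vec(mz, bin, nbin)
  cnt <- rowsum_vec(rep(1, length(mz)), bin, nbin)
  rep_mz <- ifelse(isum > 0, wsum / isum, msum / cnt)

  # single linkage can in principle leave representatives out of order when a
  # long chain's weighted mean crosses a neighbour; enforce monotonicity
  if (is.unsorted(rep_mz, strictly = TRUE)) {
    o2 <- order(rep_mz)
    rank <- integer(nbin); rank[o2] <- seq_len(nbin)
    bin <- rank[bin]
    rep_mz <- rep_mz[o2]; cnt <- cnt[o2]
  }

  mat <- as.matrix(Matrix::sparseMatrix(i = pix, j = bin, x = intensity,
                                        dims = c(npix, nbin)))
  dimnames(mat) <- NULL
  msi_binned(rep_mz, mat, dataset$width, dataset$height,
             dataset$pixel_size_um, dataset$mz_range,
             features = data.frame(representative_mz = rep_mz,
                                   n_members = as.integer(cnt),
                                   tolerance_ppm = tolerance_ppm))
}

rowsum_vec <- function(x, g, ng) {
  out <- numeric(ng)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Remove heavy-isotope peaks from one centroided spectrum
#'
#' A peak is removed iff some *retained* lighter peak exists at
#' `mz - k * 1.0033548` (k = 1..`max_isotopes`) within `tolerance_ppm` of the
#' expected position and the peak's intensity does not exceed that lighter
#' peak's intensity. Peaks are visited in ascending m/z, so a removed isotope
#' cannot itself shield a heavier peak. Singly charged species are assumed.
#'
#' @param spectrum a [pixel_spectrum()].
#' @param tolerance_ppm matching tolerance on the expected isotope position.
#' @param max_isotopes how many 13C shifts to consider (default 3).
#' @return the deisotoped [pixel_spectrum()].
#' @export
deisotope <- function(spectrum, tolerance_ppm = 2.5, max_isotopes = 3L) {
  stopifnot(inherits(spectrum, "pixel_spectrum"), tolerance_ppm > 0,
            max_isotopes >= 1)
  mz <- spectrum$mz; it <- spectrum$intensity
  n <- length(mz)
  if (n < 2L) return(spectrum)
  keep <- rep(TRUE, n)
  for (i in 2:n) {
    tol_da <- tolerance_ppm * 1e-6 * mz[i]
    for (k in seq_len(max_isotopes)) {
      target <- mz[i] - k * ISOTOPE_SPACING
      if (target < mz[1] - tol_da) break
      lo <- findInterval(target - tol_da, mz) + 1L
      hi <- findInterval(target + tol_da, mz)
      if (hi >= lo) {
        js <- lo:hi
        if (any(keep[js] & it[js] >= it[i])) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  pixel_spectrum(spectrum$x, spectrum$y, mz[keep], it[keep])
}

#' Deisotope every spectrum of a raw-mode dataset
#'
#' @inheritParams deisotope
#' @param dataset raw-mode [msi_dataset()].
#' @return dataset with each spectrum deisotoped.
#' @export
deisotope_dataset <- function(dataset, tolerance_ppm = 2.5, max_isotopes = 3L) {
  if (!is_raw(dataset)) stop("deisotope_dataset needs a raw-mode msi_dataset")
  dataset$spectra <- lapply(dataset$spectra, deisotope,
                            tolerance_ppm = tolerance_ppm,
                            max_isotopes = max_isotopes)
  dataset
}

#' TIC-normalize a binned dataset
#'
#' Scales every pixel row so its total ion current equals 1. All-zero pixels
#' (e.g. dropped pixels) are left as zero and counted in a message.
#'
#' @param dataset binned-mode [msi_dataset()].
#' @return normalized binned-mode dataset.
#' @export
tic_normalize <- function(dataset) {
  if (!is_binned(dataset)) stop("tic_normalize needs a binned msi_dataset")
  tic <- rowSums(dataset$intensity_matrix)
  zero <- tic == 0
  if (any(zero)) {
    message(sum(zero), " pixel(s) have zero total ion current; left unscaled")
  }
  scale <- ifelse(zero, 0, 1 / tic)
  dataset$intensity_matrix <- dataset$intensity_matrix * scale
  dataset
}

#' Ion image of one m/z query
#'
#' Sums the intensity columns of all features within `tolerance_ppm` of
#' `query_mz` and reshapes them onto the pixel grid.
#'
#' @param dataset binned-mode [msi_dataset()].
#' @param query_mz query m/z in Da.
#' @param tolerance_ppm matching tolerance (default 2.5 ppm).
#' @return `height` x `width` non-negative matrix (row 1 = top row of the
#'   section); all zeros when no feature matches.
#' @export
ion_image <- function(dataset, query_mz, tolerance_ppm = 2.5) {
  if (!is_binned(dataset)) stop("ion_image needs a binned msi_dataset")
  stopifnot(query_mz > 0, tolerance_ppm > 0)
  hit <- abs(dataset$feature_mzs - query_mz) / query_mz * 1e6 <= tolerance_ppm
  v <- if (any(hit)) {
    rowSums(dataset$intensity_matrix[, hit, drop = FALSE])
  } else {
    numeric(dataset$width * dataset$height)
  }
  matrix(v, nrow = dataset$height, ncol = dataset$width, byrow = TRUE)
}
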