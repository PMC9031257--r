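# End-to-end pipeline: generate/load -> deisotope -> bin -> normalize ->
# segment -> co-localize -> annotate -> tier -> report.

#' Pipeline configuration
#'
#' @param phantom a [phantom_config()] to simulate input, or `NULL`.
#' @param imzml_path path to an existing imzML file (used when `phantom` is
#'   `NULL`).
#' @param out_dir output directory for the report bundle.
#' @param tolerance_ppm binning/annotation/matching tolerance (default 2.5).
#' @param k number of segmentation clusters; default: one per phantom
#'   region plus background when a phantom is used, else 6.
#' @param seed master seed for segmentation (phantom randomness is governed
#'   by the phantom config's own seed).
#' @param min_r,top_n marker selection parameters (see [rank_markers()]).
#' @param min_frags fragments required for tier `identified`.
#' @param fragment_fraction fraction of synthetic LC-MS features given MS2
#'   fragments (phantom runs only).
#' @param lcms_path optional LC-MS feature TSV; overrides the synthetic
#'   tables.
#' @param trials_per_split 2-means restarts per bisection.
#' @param write_pngs write segmentation and ion-image PNGs (default TRUE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = NULL, imzml_path = NULL,
                            out_dir = tempfile("skinmsi_run_"),
                            tolerance_ppm = 2.5, k = NULL, seed = 1L,
                            min_r = 0.5, top_n = 25L, min_frags = 1L,
                            fragment_fraction = 0.5, lcms_path = NULL,
                            trials_per_split = 10L, write_pngs = TRUE) {
  stopifnot(tolerance_ppm > 0, is.null(k) || k >= 1, min_frags >= 0)
  if (is.null(phantom) && is.null(imzml_path)) {
    stop("pipeline needs either a phantom config or an imzML path")
  }
  structure(list(phantom = phantom, imzml_path = imzml_path,
                 out_dir = out_dir, tolerance_ppm = tolerance_ppm, k = k,
                 seed = as.integer(seed), min_r = min_r,
                 top_n = as.integer(top_n), min_frags = as.integer(min_frags),
                 fragment_fraction = fragment_fraction,
                 lcms_path = lcms_path,
                 trials_per_split = as.integer(trials_per_split),
                 write_pngs = write_pngs),
            class = "pipeline_config")
}

clip_quantile <- function(image, q = 0.99) {
  hi <- stats::quantile(image, q, names = FALSE)
  if (hi <= 0) return(image * 0)
  pmin(image, hi) / hi
}

write_ion_png <- function(image, path, q = 0.99) {
  g <- clip_quantile(image, q)
  png::writePNG(g, path)
  invisible(path)
}

write_segmentation_png <- function(seg, path) {
  pal <- grDevices::col2rgb(grDevices::hcl.colors(max(seg$k, 2L), "Dark 3")) / 255
  arr <- array(0, dim = c(nrow(seg$label_grid), ncol(seg$label_grid), 3))
  for (ch in 1:3) {
    arr[, , ch] <- matrix(pal[ch, seg$label_grid + 1L],
                          nrow(seg$label_grid), ncol(seg$label_grid))
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Run the full marker-discovery pipeline
#'
#' Executes deisotoping, ppm binning, TIC normalization, bisecting k-means
#' segmentation, ROI extraction, Pearson co-localization marker ranking,
#' accurate-mass annotation and LC-MS evidence tiering, writing the report
#' bundle (marker/annotation/tier TSVs, segmentation and 99th-percentile
#' clipped ion-image PNGs, a parameter log) to `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param db lipid table (default: bundled table).
#' @return invisibly, a list with the intermediate objects (`dataset`,
#'   `binned`, `normalized`, `seg`, `cluster_map`, `rois`, `hits`,
#'   `annotations`, `tiers`, `truth`, `metrics`, `paths`).
#' @export
run_pipeline <- function(config, db = read_lipid_db()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("skinmsi pipeline run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  for (p in c("tolerance_ppm", "seed", "min_r", "top_n", "min_frags",
              "fragment_fraction", "trials_per_split")) {
    logf("param %s = %s", p, format(config[[p]]))
  }

  truth <- NULL
  if (!is.null(config$phantom)) {
    logf("input: synthetic phantom, seed %d, %dx%d grid",
         config$phantom$seed, config$phantom$width, config$phantom$height)
    sim <- generate_phantom(config$phantom)
    dataset <- sim$dataset
    truth <- sim$truth
  } else {
    logf("input: imzML %s", config$imzml_path)
    dataset <- read_imzml(config$imzml_path)
  }
  if (length(dataset$spectra) == 0L) {
    stop("input dataset contains no spectra")
  }

  k <- config$k
  if (is.null(k)) {
    k <- if (!is.null(truth)) length(truth$region_masks) + 1L else 6L
  }
  logf("param k = %d", k)

  dataset <- deisotope_dataset(dataset, tolerance_ppm = config$tolerance_ppm)
  binned <- bin_peaks(dataset, tolerance_ppm = config$tolerance_ppm)
  logf("binned: %d features across %d pixels", length(binned$feature_mzs),
       nrow(binned$intensity_matrix))
  normalized <- suppressMessages(tic_normalize(binned))

  seg <- segment_msi(normalized, k = k, seed = config$seed,
                     trials_per_split = config$trials_per_split)
  logf("segmentation: k = %d, total SSE = %.6g", seg$k, seg$total_sse)

  if (!is.null(truth)) {
    cluster_map <- map_clusters_to_regions(seg, truth)
  } else {
    cluster_map <- data.frame(cluster_id = 0:(seg$k - 1L),
                              region = NA_character_, jaccard = NA_real_,
                              roi_name = paste0("cluster_", 0:(seg$k - 1L)))
  }
  # marker ranking targets the morphological structures: clusters that best
  # overlap plain background are not screened as ROIs (phantom runs only)
  roi_rows <- seq_len(nrow(cluster_map))
  if (!is.null(truth)) {
    structured <- cluster_map$region != "background"
    if (any(structured)) roi_rows <- which(structured)
  }
  rois <- lapply(roi_rows, function(i) {
    roi_from_labels(seg, cluster_map$cluster_id[i], cluster_map$roi_name[i])
  })

  hits <- rank_markers(normalized, rois, min_r = config$min_r,
                       top_n = config$top_n)
  if (nrow(hits) == 0L) {
    warning("no marker features passed the co-localization threshold")
    logf("markers: none passed min_r = %g", config$min_r)
  } else {
    logf("markers: %d features across %d ROI(s)", nrow(hits),
         length(unique(hits$roi_name)))
  }

  annotations <- annotate_markers(hits, db = db,
                                  tolerance_ppm = config$tolerance_ppm)

  lcms <- if (!is.null(config$lcms_path)) {
    read_lcms_table(config$lcms_path)
  } else if (!is.null(truth)) {
    generate_lcms_tables(truth, config$phantom,
                         fragment_fraction = config$fragment_fraction)
  } else {
    list()
  }
  tiers <- tier_annotations(annotations, lcms,
                            tolerance_ppm = config$tolerance_ppm,
                            min_frags = config$min_frags)

  paths <- list(
    markers = file.path(config$out_dir, "markers.tsv"),
    annotations = file.path(config$out_dir, "annotations.tsv"),
    tiers = file.path(config$out_dir, "tiers.tsv"),
    labels = file.path(config$out_dir, "segmentation_labels.tsv"),
    log = log_path)
  write_marker_table(hits, paths$markers)
  utils::write.table(annotations, paths$annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tiers, paths$tiers, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_label_grid(seg, paths$labels)
  if (isTRUE(config$write_pngs)) {
    paths$segmentation_png <- file.path(config$out_dir, "segmentation.png")
    write_segmentation_png(seg, paths$segmentation_png)
    for (i in seq_len(nrow(hits))) {
      img <- ion_image(binned, hits$feature_mz[i],
                       tolerance_ppm = config$tolerance_ppm)
      write_ion_png(img, file.path(
        config$out_dir,
        sprintf("ion_%s_%.4f.png", hits$roi_name[i], hits$feature_mz[i])))
    }
  }

  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- list(
      ari = adjusted_rand(seg$label_grid, truth$label_grid),
      recovery = score_marker_recovery(hits, truth,
                                       tolerance_ppm = config$tolerance_ppm))
    logf("phantom ARI = %.4f, precision = %.3f, recall = %.3f",
         metrics$ari, metrics$recovery$precision, metrics$recovery$recall)
  }

  invisible(list(dataset = dataset, binned = binned, normalized = normalized,
                 seg = seg, cluster_map = cluster_map, rois = rois,
                 hits = hits, annotations = annotations, tiers = tiers,
                 truth = truth, metrics = metrics, paths = paths,
                 k = k, config = config))
}
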