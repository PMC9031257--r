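# Ground-truthed synthetic skin-section MSI phantom: an epidermis band, a
# sebaceous gland with peripheral ring and central core, and a hair follicle
# with concentric ORS/IRS/medulla/cortex layers, each carrying planted
# marker ions over a log-normal background, with ppm jitter, isotope
# partners and pixel dropout.

#' Default planted marker panel
#'
#' Eight markers, one per phantom zone (two for the inner root sheath).
#' Six are opaque m/z values; two carry full lipid identities (a
#' potassiated diglyceride in the SG central zone and a potassiated
#' phosphatidylcholine in the IRS) so that annotation and LC-MS tiering are
#' exercised end-to-end. The acyl splits of the identified species are
#' representative choices.
#'
#' @return data.frame with columns `name`, `region`, `mz`, `formula`,
#'   `acyls`, `class`, `msi_adduct`, `meanlog`, `sdlog`.
#' @export
default_marker_panel <- function() {
  p <- data.frame(
    name = c("peripheral_667", "DG(36:1)", "epidermis_705", "ors_837",
             "PC(37:1)", "irs_796", "medulla_596", "cortex_544"),
    region = c("sg_peripheral", "sg_central", "epidermis", "ors",
               "irs", "irs", "medulla", "cortex"),
    mz = c(667.4348, NA, 705.5543, 837.6818, NA, 796.5840, 596.5974, 544.9959),
    formula = c(NA, "C39H74O5", NA, NA, "C45H88NO8P", NA, NA, NA),
    acyls = c(NA, "18:0/18:1", NA, NA, "17:0/20:1", NA, NA, NA),
    class = c(NA, "DG", NA, NA, "PC", NA, NA, NA),
    msi_adduct = c(NA, "[M+K]+", NA, NA, "[M+K]+", NA, NA, NA),
    meanlog = log(20000), sdlog = 0.4,
    stringsAsFactors = FALSE)
  has_f <- !is.na(p$formula)
  p$mz[has_f] <- vapply(which(has_f), function(i) {
    adduct_mz(monoisotopic_mass(p$formula[i]), p$msi_adduct[i])
  }, numeric(1))
  p$carbons <- ifelse(has_f, vapply(p$formula, function(f) {
    if (is.na(f)) NA_integer_ else {
      cnt <- parse_formula(f); as.integer(cnt[["C"]])
    }
  }, integer(1)), NA_integer_)
  p
}

#' Phantom configuration
#'
#' Defines the geometry, marker panel and noise model of the synthetic skin
#' section. Geometry defaults scale with the grid so small test phantoms
#' keep the same anatomy.
#'
#' @param width,height grid size in pixels (default 120 x 120).
#' @param pixel_size_um pixel pitch (default 10).
#' @param seed RNG seed; all phantom randomness flows from it.
#' @param marker_panel data.frame as from [default_marker_panel()].
#' @param background_n number of uninformative features present everywhere.
#' @param background_meanlog,background_sdlog log-normal intensity
#'   parameters of background features.
#' @param jitter_ppm_sd Gaussian m/z jitter applied to every peak (ppm).
#' @param dropout fraction of pixels with no acquired spectrum, in `[0, 1)`.
#' @param leakage marker intensity scale outside its home region (fraction
#'   of the in-region draw; default 0.01).
#' @param isotopes simulate an M+1 partner for every peak (ratio 0.011 per
#'   carbon when a formula is known, else 0.4).
#' @param include_sg_central include the SG central (necrotic) core; set
#'   `FALSE` to emulate a section through an immature gland that lacks it.
#' @param geometry optional list overriding `epidermis_rows`, `sg_center`,
#'   `sg_axes`, `sg_core_frac`, `follicle_center`, `follicle_radii`.
#' @param mz_range acquisition m/z window.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(width = 120L, height = 120L, pixel_size_um = 10,
                           seed = 1L,
                           marker_panel = default_marker_panel(),
                           background_n = 200L,
                           background_meanlog = log(300),
                           background_sdlog = 0.5,
                           jitter_ppm_sd = 0.3,
                           dropout = 0.01,
                           leakage = 0.01,
                           isotopes = TRUE,
                           include_sg_central = TRUE,
                           geometry = list(),
                           mz_range = c(200, 1500)) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 16L, height >= 16L, dropout >= 0, dropout < 1,
            jitter_ppm_sd >= 0, leakage >= 0, background_n >= 0)
  s <- min(width, height)
  geo <- utils::modifyList(list(
    epidermis_rows = max(2L, round(height / 15)),
    sg_center = c(0.30 * width, 0.58 * height),
    sg_axes = c(0.15 * width, 0.12 * height),
    sg_core_frac = 0.55,
    follicle_center = c(0.70 * width, 0.62 * height),
    follicle_radii = c(0.033, 0.058, 0.083, 0.117) * s
  ), geometry)
  structure(list(
    width = width, height = height, pixel_size_um = pixel_size_um,
    seed = as.integer(seed), marker_panel = marker_panel,
    background_n = as.integer(background_n),
    background_meanlog = background_meanlog,
    background_sdlog = background_sdlog,
    jitter_ppm_sd = jitter_ppm_sd, dropout = dropout, leakage = leakage,
    isotopes = isotopes, include_sg_central = include_sg_central,
    geometry = geo, mz_range = as.numeric(mz_range)
  ), class = "phantom_config")
}

phantom_region_masks <- function(config) {
  w <- config$width; h <- config$height; geo <- config$geometry
  x <- matrix(rep(0:(w - 1L), each = h), nrow = h)   # column index
  y <- matrix(rep(0:(h - 1L), times = w), nrow = h)  # row index
  epidermis <- y < geo$epidermis_rows
  sg_out <- ((x - geo$sg_center[1]) / geo$sg_axes[1])^2 +
    ((y - geo$sg_center[2]) / geo$sg_axes[2])^2 <= 1
  masks <- list(epidermis = epidermis)
  if (config$include_sg_central) {
    core <- ((x - geo$sg_center[1]) / (geo$sg_axes[1] * geo$sg_core_frac))^2 +
      ((y - geo$sg_center[2]) / (geo$sg_axes[2] * geo$sg_core_frac))^2 <= 1
    masks$sg_peripheral <- sg_out & !core
    masks$sg_central <- core
  } else {
    masks$sg_peripheral <- sg_out
  }
  r <- sqrt((x - geo$follicle_center[1])^2 + (y - geo$follicle_center[2])^2)
  rr <- geo$follicle_radii
  masks$cortex <- r <= rr[1]
  masks$medulla <- r > rr[1] & r <= rr[2]
  masks$irs <- r > rr[2] & r <= rr[3]
  masks$ors <- r > rr[3] & r <= rr[4]
  cover <- Reduce(`+`, masks)
  if (any(cover > 1)) {
    stop("phantom regions overlap; adjust the geometry")
  }
  if (!all(vapply(masks, any, logical(1)))) {
    bad <- names(masks)[!vapply(masks, any, logical(1))]
    stop("phantom region(s) empty at this grid size: ",
         paste(bad, collapse = ", "))
  }
  masks
}

#' Generate the synthetic skin-section phantom
#'
#' Draws, for every pixel, log-normal marker peaks where the pixel lies in
#' the marker's region (scaled by `leakage` elsewhere), log-normal
#' background peaks everywhere, Gaussian ppm jitter on every m/z, optional
#' M+1 isotope partners, and drops pixels at the dropout rate.
#' Deterministic for a fixed config seed.
#'
#' @param config a [phantom_config()].
#' @return list with `dataset` (raw-mode [msi_dataset()]) and `truth`
#'   (class `phantom_truth`: `region_masks`, `label_grid`, `marker_table`,
#'   `config`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  masks <- phantom_region_masks(config)
  w <- config$width; h <- config$height
  npix <- w * h
  region_names <- names(masks)
  label_grid <- matrix(0L, h, w)
  for (i in seq_along(masks)) label_grid[masks[[i]]] <- i

  panel <- config$marker_panel
  if (!config$include_sg_central) {
    panel <- panel[panel$region != "sg_central", , drop = FALSE]
  }
  if (!all(panel$region %in% region_names)) {
    stop("marker panel names unknown region(s): ",
         paste(setdiff(panel$region, region_names), collapse = ", "))
  }
  nm <- nrow(panel)
  nb <- config$background_n

  with_rng_seed(config$seed, {
    # background m/z axis, kept clear of the planted markers (>= 10 ppm)
    bg_mz <- numeric(0)
    if (nb > 0) {
      lo <- config$mz_range[1] + 10
      hi <- config$mz_range[2] - 20
      bg_mz <- runif(nb, lo, hi)
      for (it in 1:20) {
        clash <- vapply(bg_mz, function(z) {
          any(abs(z - panel$mz) / panel$mz * 1e6 < 10)
        }, logical(1))
        if (!any(clash)) break
        bg_mz[clash] <- runif(sum(clash), lo, hi)
      }
      bg_mz <- sort(bg_mz)
    }

    feat_mz <- c(bg_mz, panel$mz)
    nf <- nb + nm
    intens <- matrix(0, npix, nf)
    if (nb > 0) {
      intens[, seq_len(nb)] <- stats::rlnorm(
        npix * nb, config$background_meanlog, config$background_sdlog)
    }
    # row-major raster order of pixels: transpose image masks
    for (j in seq_len(nm)) {
      inreg <- as.vector(t(masks[[panel$region[j]]]))
      draw <- stats::rlnorm(npix, panel$meanlog[j], panel$sdlog[j])
      intens[, nb + j] <- draw * ifelse(inreg, 1, config$leakage)
    }
    jit <- matrix(stats::rnorm(npix * nf, 0, config$jitter_ppm_sd), npix, nf)
    obs_mz <- matrix(feat_mz, npix, nf, byrow = TRUE) * (1 + jit * 1e-6)

    iso_mz <- NULL; iso_int <- NULL
    if (config$isotopes) {
      ratio <- c(rep(0.4, nb),
                 ifelse(is.na(panel$carbons), 0.4, 0.011 * panel$carbons))
      iso_jit <- matrix(stats::rnorm(npix * nf, 0, config$jitter_ppm_sd),
                        npix, nf)
      iso_mz <- (matrix(feat_mz, npix, nf, byrow = TRUE) + ISOTOPE_SPACING) *
        (1 + iso_jit * 1e-6)
      iso_int <- intens * matrix(ratio, npix, nf, byrow = TRUE)
    }

    dropped <- stats::runif(npix) < config$dropout

    spectra <- vector("list", npix)
    n_kept <- 0L
    for (p in seq_len(npix)) {
      if (dropped[p]) next
      mzv <- obs_mz[p, ]; iv <- intens[p, ]
      if (!is.null(iso_mz)) {
        mzv <- c(mzv, iso_mz[p, ]); iv <- c(iv, iso_int[p, ])
      }
      keep <- iv > 0
      mzv <- mzv[keep]; iv <- iv[keep]
      o <- order(mzv)
      n_kept <- n_kept + 1L
      spectra[[n_kept]] <- pixel_spectrum((p - 1L) %% w, (p - 1L) %/% w,
                                          mzv[o], iv[o])
    }
    spectra <- spectra[seq_len(n_kept)]

    dataset <- msi_dataset(spectra, width = w, height = h,
                           pixel_size_um = config$pixel_size_um,
                           mz_range = config$mz_range)
    truth <- structure(list(
      region_masks = masks,
      region_names = region_names,
      label_grid = label_grid,
      marker_table = panel[, c("name", "mz", "region", "formula", "acyls",
                               "class", "msi_adduct", "carbons")],
      config = config
    ), class = "phantom_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Generate companion synthetic LC-MS feature tables for the phantom
#'
#' Emits one LC-MS feature per planted marker that carries a lipid identity,
#' at the LC-MS-side adduct m/z (ammoniated for DG/TG, protonated
#' otherwise - the adduct switch relative to the potassiated/sodiated MALDI
#' ions). A configurable fraction of the features (taken in ascending m/z
#' order) carries diagnostic MS2 fragment lists so that both the
#' `identified` and the `annotated` tier arise downstream.
#'
#' @param truth `phantom_truth` from [generate_phantom()].
#' @param config the same [phantom_config()] (for seed and jitter).
#' @param fragment_fraction fraction of lipid-backed markers given MS2
#'   fragments (default 0.5).
#' @return list of [lcms_feature()] objects.
#' @export
generate_lcms_tables <- function(truth, config = truth$config,
                                 fragment_fraction = 0.5) {
  stopifnot(inherits(truth, "phantom_truth"),
            fragment_fraction >= 0, fragment_fraction <= 1)
  tab <- truth$marker_table
  tab <- tab[!is.na(tab$formula), , drop = FALSE]
  if (!nrow(tab)) return(list())
  tab <- tab[order(tab$mz), , drop = FALSE]
  n_frag <- round(fragment_fraction * nrow(tab))
  with_rng_seed(config$seed + 1000L, {
    lapply(seq_len(nrow(tab)), function(i) {
      lcms_adduct <- if (tab$class[i] %in% c("DG", "TG")) "[M+NH4]+" else "[M+H]+"
      neutral <- monoisotopic_mass(tab$formula[i])
      mz <- adduct_mz(neutral, lcms_adduct) *
        (1 + stats::rnorm(1, 0, config$jitter_ppm_sd) * 1e-6)
      fragments <- numeric(0)
      if (i <= n_frag) {
        acyls <- parse_acyls(tab$acyls[i])
        if (!is.null(acyls) && tab$class[i] %in% c("DG", "TG", "PA", "PC")) {
          losses <- mapply(fatty_acid_mass, acyls$carbons, acyls$double_bonds)
          fragments <- mz - losses
        }
        if (tab$class[i] %in% c("PC", "SM")) {
          fragments <- c(fragments, PC_HEADGROUP_MZ)
        }
        fragments <- fragments *
          (1 + stats::rnorm(length(fragments), 0, config$jitter_ppm_sd) * 1e-6)
      }
      lcms_feature(mz, rt_min = 5 + 20 * (i - 1) / max(1, nrow(tab) - 1),
                   intensity = stats::rlnorm(1, log(1e5), 0.5),
                   fragments = fragments)
    })
  })
}

#' Score recovery of the planted markers
#'
#' A reported marker hit is *correct* when its m/z lies within
#' `tolerance_ppm` of a planted marker and its ROI is that marker's true
#' region; a planted marker is *recovered* when such a hit exists.
#'
#' @param hits data.frame from [rank_markers()] whose `roi_name`s are truth
#'   region names (see [map_clusters_to_regions()]).
#' @param truth `phantom_truth`.
#' @param tolerance_ppm m/z matching tolerance.
#' @return list with `precision`, `recall`, `f1` and a per-marker data.frame
#'   `detail`.
#' @export
score_marker_recovery <- function(hits, truth, tolerance_ppm = 2.5) {
  tab <- truth$marker_table
  recovered <- vapply(seq_len(nrow(tab)), function(i) {
    any(hits$roi_name == tab$region[i] &
          abs(hits$feature_mz - tab$mz[i]) / tab$mz[i] * 1e6 <= tolerance_ppm)
  }, logical(1))
  correct_hit <- vapply(seq_len(nrow(hits)), function(j) {
    any(tab$region == hits$roi_name[j] &
          abs(hits$feature_mz[j] - tab$mz) / tab$mz * 1e6 <= tolerance_ppm)
  }, logical(1))
  precision <- if (nrow(hits)) mean(correct_hit) else NA_real_
  recall <- mean(recovered)
  f1 <- if (!is.na(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       detail = data.frame(name = tab$name, mz = tab$mz,
                           region = tab$region, recovered = recovered))
}

#' Name segmentation clusters after the truth regions they overlap
#'
#' Maps every cluster to the truth region (or `background`) with the highest
#' Jaccard overlap; clusters tied to an already-used name get a numeric
#' suffix.
#'
#' @param seg `segmentation_result` with `label_grid`.
#' @param truth `phantom_truth`.
#' @return data.frame `cluster_id`, `region`, `jaccard`, `roi_name`.
#' @export
map_clusters_to_regions <- function(seg, truth) {
  stopifnot(!is.null(seg$label_grid))
  masks <- c(truth$region_masks,
             list(background = truth$label_grid == 0L))
  out <- lapply(0:(seg$k - 1L), function(cid) {
    cm <- seg$label_grid == cid
    jac <- vapply(masks, function(m) {
      u <- sum(cm | m)
      if (u == 0) 0 else sum(cm & m) / u
    }, numeric(1))
    best <- which.max(jac)
    data.frame(cluster_id = cid, region = names(masks)[best],
               jaccard = jac[best], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  roi <- out$region
  dup <- ave(seq_along(roi), roi, FUN = seq_along)
  out$roi_name <- ifelse(dup > 1, paste0(roi, "_", dup), roi)
  out
}

#' Write phantom truth to disk
#'
#' Region masks as 0/1 TSV grids and the marker table as TSV.
#'
#' @param truth `phantom_truth`.
#' @param dir output directory (created if needed).
#' @export
write_phantom_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(truth$region_masks)) {
    utils::write.table(truth$region_masks[[nm]] + 0L,
                       file.path(dir, paste0("mask_", nm, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(truth$marker_table, file.path(dir, "marker_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
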