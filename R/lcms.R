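# Cross-platform confirmation of MSI annotations against LC-MS features,
# adduct-switch aware, and identified/annotated evidence tiering.

#' Construct an LC-MS feature
#'
#' @param mz precursor m/z in Da (> 0).
#' @param rt_min retention time in minutes.
#' @param intensity non-negative abundance.
#' @param fragments numeric vector of MS2 fragment m/z values (may be empty).
#' @return list of class `lcms_feature`.
#' @export
lcms_feature <- function(mz, rt_min = NA_real_, intensity = 0,
                         fragments = numeric(0)) {
  stopifnot(mz > 0, intensity >= 0, all(fragments > 0))
  structure(list(mz = as.numeric(mz), rt_min = as.numeric(rt_min),
                 intensity = as.numeric(intensity),
                 fragments = as.numeric(fragments)),
            class = "lcms_feature")
}

#' Read an LC-MS feature table from TSV
#'
#' Columns: `mz`, `rt_min`, `intensity`, `fragments` (semicolon-joined m/z,
#' possibly empty).
#'
#' @param path TSV path.
#' @return list of [lcms_feature()] objects.
#' @export
read_lcms_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(fragments = "character"))
  lapply(seq_len(nrow(tab)), function(i) {
    fr <- tab$fragments[i]
    fr <- if (is.na(fr) || !nzchar(fr)) numeric(0) else {
      as.numeric(strsplit(fr, ";", fixed = TRUE)[[1]])
    }
    lcms_feature(tab$mz[i], tab$rt_min[i], tab$intensity[i], fr)
  })
}

#' Write LC-MS features as TSV
#'
#' @param features list of [lcms_feature()] objects.
#' @param path output path.
#' @export
write_lcms_table <- function(features, path) {
  tab <- data.frame(
    mz = vapply(features, `[[`, numeric(1), "mz"),
    rt_min = vapply(features, `[[`, numeric(1), "rt_min"),
    intensity = vapply(features, `[[`, numeric(1), "intensity"),
    fragments = vapply(features, function(f) {
      paste(sprintf("%.5f", f$fragments), collapse = ";")
    }, character(1)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Neutral-mass candidates of an observed m/z under a set of adducts
#'
#' @param mz observed m/z in Da.
#' @param adducts adduct data.frame (see [default_adducts()]).
#' @return data.frame `adduct`, `neutral` with non-positive candidates
#'   dropped.
#' @export
neutral_candidates <- function(mz, adducts = default_adducts()) {
  stopifnot(mz > 0)
  out <- data.frame(adduct = adducts$label,
                    neutral = mz - adducts$delta_mass,
                    stringsAsFactors = FALSE)
  # non-positive neutrals (to numerical epsilon) are unphysical
  out[out$neutral > 1e-6, , drop = FALSE]
}

#' Cross-match an MSI feature against LC-MS features via shared neutrals
#'
#' Strips each platform's candidate adducts and declares a hit when an MSI
#' neutral candidate agrees with an LC-MS neutral candidate within
#' `tolerance_ppm` (computed on the neutral mass). This is adduct-switch
#' aware: a potassiated MSI ion can match an ammoniated LC-MS ion of the
#' same molecule.
#'
#' @param msi_mz MSI feature m/z.
#' @param msi_adducts adducts considered for the MSI ion.
#' @param lcms_features list of [lcms_feature()] objects.
#' @param lcms_adducts adducts considered for the LC-MS ions.
#' @param tolerance_ppm matching tolerance on the neutral mass.
#' @return one-row data.frame of the best hit (`lcms_index`, `lcms_mz`,
#'   `rt_min`, `msi_adduct`, `lcms_adduct`, `neutral_mass`, `ppm_error`), or
#'   `NULL` when nothing matches.
#' @export
cross_match <- function(msi_mz, msi_adducts = default_adducts(),
                        lcms_features = list(),
                        lcms_adducts = default_adducts(),
                        tolerance_ppm = 2.5) {
  stopifnot(tolerance_ppm > 0)
  if (!length(lcms_features)) return(NULL)
  msi_cand <- neutral_candidates(msi_mz, msi_adducts)
  if (!nrow(msi_cand)) return(NULL)
  best <- NULL
  for (i in seq_along(lcms_features)) {
    f <- lcms_features[[i]]
    lc_cand <- neutral_candidates(f$mz, lcms_adducts)
    if (!nrow(lc_cand)) next
    for (a in seq_len(nrow(msi_cand))) {
      ppm <- ppm_error(msi_cand$neutral[a], lc_cand$neutral)
      j <- which.min(abs(ppm))
      if (abs(ppm[j]) <= tolerance_ppm &&
          (is.null(best) || abs(ppm[j]) < abs(best$ppm_error))) {
        best <- data.frame(
          lcms_index = i, lcms_mz = f$mz, rt_min = f$rt_min,
          msi_adduct = msi_cand$adduct[a], lcms_adduct = lc_cand$adduct[j],
          neutral_mass = (msi_cand$neutral[a] + lc_cand$neutral[j]) / 2,
          ppm_error = ppm[j], stringsAsFactors = FALSE)
      }
    }
  }
  best
}

#' Count diagnostic MS2 fragments supporting a lipid assignment
#'
#' The expected diagnostic set is: for glycerolipid classes (DG, TG, PA, and
#' the diacyl part of PC), the neutral loss of each free fatty acid RCOOH
#' from the precursor; for the choline-head classes (PC, SM), additionally
#' the phosphocholine head-group fragment at m/z 184.0733. Observed
#' fragments are matched within `tolerance_ppm`.
#'
#' @param lipid one row of a lipid table (needs `class`; `acyls` used when
#'   `acyl_composition` is missing).
#' @param acyl_composition data.frame with `carbons`, `double_bonds` per
#'   acyl chain (or `NULL` to parse `lipid$acyls`).
#' @param precursor_mz precursor m/z the neutral losses are taken from.
#' @param observed_fragments numeric vector of observed MS2 m/z values.
#' @param tolerance_ppm matching tolerance.
#' @return integer count of expected diagnostic fragments observed; 0 with a
#'   warning for a lipid class without fragment rules.
#' @export
fragment_support <- function(lipid, acyl_composition = NULL, precursor_mz,
                             observed_fragments, tolerance_ppm = 2.5) {
  stopifnot(precursor_mz > 0, tolerance_ppm > 0)
  cls <- lipid$class
  if (is.null(acyl_composition) && !is.null(lipid$acyls)) {
    acyl_composition <- parse_acyls(lipid$acyls)
  }
  expected <- numeric(0)
  if (cls %in% c("DG", "TG", "PA", "PC")) {
    if (!is.null(acyl_composition) && nrow(acyl_composition)) {
      losses <- mapply(fatty_acid_mass, acyl_composition$carbons,
                       acyl_composition$double_bonds)
      expected <- c(expected, precursor_mz - losses)
    }
  }
  if (cls %in% c("PC", "SM")) {
    expected <- c(expected, PC_HEADGROUP_MZ)
  }
  if (!length(expected)) {
    if (!cls %in% c("DG", "TG", "PA", "PC", "SM")) {
      warning("no diagnostic fragment rules for lipid class '", cls, "'")
    }
    return(0L)
  }
  if (!length(observed_fragments)) return(0L)
  sum(vapply(expected, function(e) {
    any(abs(ppm_error(observed_fragments, e)) <= tolerance_ppm)
  }, logical(1)))
}

#' Assign an identified/annotated/unmatched evidence tier
#'
#' A feature detected on both platforms (cross-matched) with at least
#' `min_frags` diagnostic MS2 fragments is `identified`; cross-matched
#' without sufficient fragments is `annotated`; otherwise `unmatched`.
#'
#' @param match an accurate-mass annotation (one row of
#'   [annotate_markers()] output); only used to sanity-check input.
#' @param cross result of [cross_match()] (`NULL` when no hit).
#' @param frag_count diagnostic fragment count from [fragment_support()].
#' @param min_frags minimum fragments for definitive identification
#'   (default 1).
#' @return list of class `tier_evidence`: `cross_matched`,
#'   `n_diagnostic_fragments`, `tier`.
#' @export
assign_tier <- function(match, cross, frag_count, min_frags = 1L) {
  cross_matched <- !is.null(cross) && NROW(cross) > 0
  frag_count <- as.integer(frag_count)
  tier <- if (cross_matched && frag_count >= min_frags) {
    "identified"
  } else if (cross_matched) {
    "annotated"
  } else {
    "unmatched"
  }
  structure(list(cross_matched = cross_matched,
                 n_diagnostic_fragments = frag_count,
                 tier = tier),
            class = "tier_evidence")
}

#' Tier an annotation table against LC-MS features
#'
#' For every annotated marker, attempts an adduct-switch-aware cross-match
#' to the LC-MS features, counts diagnostic fragments on the matched LC-MS
#' precursor, and assigns the evidence tier.
#'
#' @param annotations data.frame from [annotate_markers()].
#' @param lcms_features list of [lcms_feature()] objects.
#' @param tolerance_ppm matching tolerance.
#' @param min_frags minimum fragments for tier `identified`.
#' @return `annotations` with added columns `cross_matched`,
#'   `lcms_adduct`, `n_fragments`, `tier`.
#' @export
tier_annotations <- function(annotations, lcms_features, tolerance_ppm = 2.5,
                             min_frags = 1L) {
  n <- nrow(annotations)
  annotations$cross_matched <- logical(n)
  annotations$lcms_adduct <- NA_character_
  annotations$n_fragments <- 0L
  annotations$tier <- "unmatched"
  for (i in seq_len(n)) {
    if (is.na(annotations$lipid_name[i])) next
    cross <- cross_match(annotations$feature_mz[i],
                         lcms_features = lcms_features,
                         tolerance_ppm = tolerance_ppm)
    frag <- 0L
    if (!is.null(cross)) {
      f <- lcms_features[[cross$lcms_index]]
      frag <- fragment_support(
        annotations[i, ], NULL, precursor_mz = f$mz,
        observed_fragments = f$fragments, tolerance_ppm = tolerance_ppm)
    }
    ev <- assign_tier(annotations[i, ], cross, frag, min_frags)
    annotations$cross_matched[i] <- ev$cross_matched
    annotations$lcms_adduct[i] <- if (!is.null(cross)) cross$lcms_adduct else NA_character_
    annotations$n_fragments[i] <- ev$n_diagnostic_fragments
    annotations$tier[i] <- ev$tier
  }
  annotations
}
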