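# Accurate-mass lipid annotation: bundled lipid table, adduct-aware ppm
# matching of marker features.

#' Load a lipid record table
#'
#' Reads a TSV with columns `name`, `class`, `formula` and optionally
#' `acyls` (slash-separated acyl chains such as `"18:0/18:1"`), computes
#' each record's neutral monoisotopic mass from its formula, and validates
#' the formulas. With no `path`, the mini lipid table bundled with the
#' package is loaded; it is a synthetic, hand-built stand-in for a full
#' lipid database, covering the DG/TG/PC/SM/PA/CerPE classes.
#'
#' @param path TSV path, or `NULL` for the bundled table.
#' @return data.frame with `name`, `class`, `formula`, `acyls`,
#'   `neutral_mass`.
#' @export
read_lipid_db <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lipid_db.tsv", package = "skinmsi",
                        mustWork = TRUE)
  }
  db <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("name", "class", "formula")
  if (!all(need %in% names(db))) {
    stop("lipid table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(db$acyls)) db$acyls <- NA_character_
  db$neutral_mass <- vapply(db$formula, monoisotopic_mass, numeric(1),
                            USE.NAMES = FALSE)
  if (any(db$neutral_mass <= 0)) stop("lipid records must have positive mass")
  db
}

parse_acyls <- function(acyls) {
  if (is.na(acyls) || !nzchar(acyls)) return(NULL)
  parts <- strsplit(acyls, "/", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(parts, function(p) {
    cd <- strsplit(sub("^d", "", p), ":", fixed = TRUE)[[1]]
    as.integer(cd)
  }))
  data.frame(carbons = m[, 1], double_bonds = m[, 2])
}

#' Match one feature m/z against a lipid table under positive adducts
#'
#' Enumerates all (record, adduct) pairs, keeps those whose theoretical m/z
#' lies within `tolerance_ppm` of the feature, and sorts by ascending
#' absolute ppm error (the match score).
#'
#' @param feature_mz observed m/z in Da.
#' @param db lipid table from [read_lipid_db()].
#' @param adducts adduct data.frame (default all of [default_adducts()]).
#' @param tolerance_ppm inclusive matching tolerance (default 2.5 ppm).
#' @return data.frame of matches: `feature_mz`, `name`, `class`, `formula`,
#'   `acyls`, `adduct`, `theoretical_mz`, `ppm_error`; 0 rows when nothing
#'   matches.
#' @export
match_database <- function(feature_mz, db, adducts = default_adducts(),
                           tolerance_ppm = 2.5) {
  stopifnot(length(feature_mz) == 1L, feature_mz > 0, tolerance_ppm > 0)
  empty <- data.frame(
    feature_mz = numeric(0), name = character(0), class = character(0),
    formula = character(0), acyls = character(0), adduct = character(0),
    theoretical_mz = numeric(0), ppm_error = numeric(0))
  if (nrow(db) == 0L || nrow(adducts) == 0L) return(empty)
  grid <- expand.grid(rec = seq_len(nrow(db)), add = seq_len(nrow(adducts)))
  theo <- db$neutral_mass[grid$rec] + adducts$delta_mass[grid$add]
  ppm <- ppm_error(feature_mz, theo)
  keep <- abs(ppm) <= tolerance_ppm
  if (!any(keep)) return(empty)
  grid <- grid[keep, , drop = FALSE]
  out <- data.frame(
    feature_mz = feature_mz,
    name = db$name[grid$rec], class = db$class[grid$rec],
    formula = db$formula[grid$rec], acyls = db$acyls[grid$rec],
    adduct = adducts$label[grid$add],
    theoretical_mz = theo[keep], ppm_error = ppm[keep],
    stringsAsFactors = FALSE)
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a marker table against a lipid database
#'
#' Runs [match_database()] for every marker feature and keeps the best match
#' (smallest absolute ppm error) per feature; unmatched features are reported
#' with NA lipid fields.
#'
#' @param hits data.frame from [rank_markers()].
#' @param db lipid table (default: bundled table).
#' @param adducts adduct set (default all four positive adducts).
#' @param tolerance_ppm matching tolerance in ppm.
#' @return data.frame: `roi_name`, `feature_mz`, `r`, `lipid_name`, `class`,
#'   `formula`, `acyls`, `adduct`, `ppm_error`.
#' @export
annotate_markers <- function(hits, db = read_lipid_db(),
                             adducts = default_adducts(),
                             tolerance_ppm = 2.5) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    m <- match_database(hits$feature_mz[i], db, adducts, tolerance_ppm)
    if (nrow(m) == 0L) {
      data.frame(roi_name = hits$roi_name[i], feature_mz = hits$feature_mz[i],
                 r = hits$r[i], lipid_name = NA_character_,
                 class = NA_character_, formula = NA_character_,
                 acyls = NA_character_, adduct = NA_character_,
                 ppm_error = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(roi_name = hits$roi_name[i], feature_mz = hits$feature_mz[i],
                 r = hits$r[i], lipid_name = m$name[1], class = m$class[1],
                 formula = m$formula[1], acyls = m$acyls[1],
                 adduct = m$adduct[1], ppm_error = m$ppm_error[1],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(roi_name = character(0), feature_mz = numeric(0),
                      r = numeric(0), lipid_name = character(0),
                      class = character(0), formula = character(0),
                      acyls = character(0), adduct = character(0),
                      ppm_error = numeric(0))
  }
  out
}
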