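# imzML 1.1.0 processed-mode reader/writer. A dataset is stored as a paired
# .imzML (XML index) and .ibd (binary) file; in processed mode every pixel
# carries its own m/z axis. Both m/z and intensity arrays are written as
# uncompressed little-endian 64-bit floats so a write/read cycle is
# value-exact.

imzml_paths <- function(path) {
  if (grepl("\\.imzml$", path, ignore.case = TRUE)) {
    base <- sub("\\.imzml$", "", path, ignore.case = TRUE)
  } else {
    base <- path
  }
  list(imzml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

format_uuid <- function(raw16) {
  hx <- paste(format(raw16), collapse = "")
  sprintf("{%s-%s-%s-%s-%s}",
          substr(hx, 1, 8), substr(hx, 9, 12), substr(hx, 13, 16),
          substr(hx, 17, 20), substr(hx, 21, 32))
}

#' Write a raw-mode MSI dataset as imzML (processed mode)
#'
#' Produces `<path>.imzML` plus its binary companion `<path>.ibd`. The ibd
#' UUID is derived from an MD5 digest of the array payload, so identical
#' datasets yield byte-identical file pairs.
#'
#' @param dataset raw-mode [msi_dataset()].
#' @param path output path; a trailing `.imzML` is optional.
#' @return invisibly, the `.imzML` path.
#' @export
write_imzml <- function(dataset, path) {
  if (is_binned(dataset)) {
    stop("dataset is in binned mode; export the feature matrix with ",
         "write_feature_table() instead of write_imzml()")
  }
  if (!is_raw(dataset)) stop("write_imzml needs a raw-mode msi_dataset")
  p <- imzml_paths(path)
  spectra <- dataset$spectra
  n <- length(spectra)
  lens <- if (n) vapply(spectra, function(s) length(s$mz), integer(1)) else integer(0)

  # payload layout: per spectrum, m/z array then intensity array (float64)
  payload <- unlist(lapply(spectra, function(s) c(s$mz, s$intensity)),
                    use.names = FALSE)
  if (is.null(payload)) payload <- numeric(0)
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, "wb")
  writeBin(payload, con, size = 8, endian = "little")
  close(con)
  uuid_raw <- as.raw(strtoi(substring(unname(tools::md5sum(tmp)),
                                      seq(1, 31, 2), seq(2, 32, 2)), 16L))
  con <- file(p$ibd, "wb")
  writeBin(uuid_raw, con)
  close(con)
  file.append(p$ibd, tmp)
  ibd_md5 <- toupper(unname(tools::md5sum(p$ibd)))

  mz_off <- integer(0); int_off <- integer(0)
  if (n) {
    ends <- cumsum(2 * lens * 8)
    starts <- 16 + c(0, ends[-n])
    mz_off <- starts
    int_off <- starts + lens * 8
  }

  cv <- function(ref, acc, name, value = "") {
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s" value="%s"/>',
            ref, acc, name, value)
  }
  header <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    cv("MS", "MS:1000127", "centroid spectrum"),
    cv("IMS", "IMS:1000031", "processed"),
    cv("IMS", "IMS:1000080", "universally unique identifier", format_uuid(uuid_raw)),
    cv("IMS", "IMS:1000091", "ibd MD5", ibd_md5),
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="skinmsi" version="0.1.0"/></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scansettings1">',
    cv("IMS", "IMS:1000042", "max count of pixel x", dataset$width),
    cv("IMS", "IMS:1000043", "max count of pixel y", dataset$height),
    cv("IMS", "IMS:1000046", "pixel size x", dataset$pixel_size_um),
    cv("IMS", "IMS:1000047", "pixel size y", dataset$pixel_size_um),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="skinmsi">',
    cv("MS", "MS:1000544", "Conversion to mzML"),
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="ic1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">', n)
  )

  spec_xml <- character(0)
  if (n) {
    xs <- vapply(spectra, `[[`, integer(1), "x") + 1L
    ys <- vapply(spectra, `[[`, integer(1), "y") + 1L
    arr <- function(acc, name, off, len) {
      paste0(
        '<binaryDataArray encodedLength="0">',
        cv("MS", acc, name),
        cv("MS", "MS:1000523", "64-bit float"),
        cv("MS", "MS:1000576", "no compression"),
        cv("IMS", "IMS:1000101", "external data", "true"),
        cv("IMS", "IMS:1000102", "external offset", sprintf("%.0f", off)),
        cv("IMS", "IMS:1000103", "external array length", len),
        cv("IMS", "IMS:1000104", "external encoded length",
           sprintf("%.0f", len * 8)),
        '<binary/></binaryDataArray>'
      )
    }
    spec_xml <- paste0(
      sprintf('<spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">',
              seq_len(n), seq_len(n) - 1L, lens),
      cv("MS", "MS:1000127", "centroid spectrum"),
      '<scanList count="1">', cv("MS", "MS:1000795", "no combination"),
      '<scan>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>', xs),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>', ys),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      arr("MS:1000514", "m/z array", mz_off, lens),
      arr("MS:1000515", "intensity array", int_off, lens),
      '</binaryDataArrayList></spectrum>'
    )
  }
  footer <- c('</spectrumList></run></mzML>')
  con <- file(p$imzml, "wb")  # binary mode: byte-stable newlines across platforms
  writeLines(c(header, spec_xml, footer), con, sep = "\n")
  close(con)
  invisible(p$imzml)
}

binary_array_nodes <- function(doc, ns, accession, groups) {
  conds <- sprintf(".//d1:cvParam[@accession='%s']", accession)
  gids <- names(groups)[vapply(groups, function(a) accession %in% a, logical(1))]
  conds <- c(conds, sprintf(".//d1:referenceableParamGroupRef[@ref='%s']", gids))
  xml2::xml_find_all(
    doc, sprintf("//d1:binaryDataArray[%s]", paste(conds, collapse = " or ")), ns)
}

array_param <- function(nodes, ns, accession) {
  hits <- xml2::xml_find_first(
    nodes, sprintf(".//d1:cvParam[@accession='%s']", accession), ns)
  xml2::xml_attr(hits, "value")
}

#' Read an imzML file (processed mode) into a raw-mode MSI dataset
#'
#' Coordinates are shifted to a 0-based grid (minimum observed position maps
#' to 0). Unsorted peak lists are sorted by m/z with intensities permuted
#' consistently. Peaks outside `mz_range` are discarded when
#' `filter_mz_range` is `TRUE`.
#'
#' @param path path to the `.imzML` file (binary companion `.ibd` must sit
#'   alongside it).
#' @param mz_range acquisition m/z window, default `c(200, 1500)`.
#' @param filter_mz_range apply the window on read (default `TRUE`).
#' @return raw-mode [msi_dataset()].
#' @export
read_imzml <- function(path, mz_range = c(200, 1500), filter_mz_range = TRUE) {
  p <- imzml_paths(path)
  if (!file.exists(p$imzml)) stop("imzML file not found: ", p$imzml)
  if (!file.exists(p$ibd)) {
    stop(errorCondition(
      paste0("missing binary companion (.ibd) for ", p$imzml,
             ": expected ", p$ibd),
      class = c("imzml_missing_ibd_error", "error", "condition")))
  }
  doc <- xml2::read_xml(p$imzml)
  ns <- xml2::xml_ns(doc)

  # referenceable param groups (other writers hang array metadata there)
  gnodes <- xml2::xml_find_all(doc, "//d1:referenceableParamGroup", ns)
  groups <- lapply(gnodes, function(g) {
    xml2::xml_attr(xml2::xml_find_all(g, ".//d1:cvParam", ns), "accession")
  })
  names(groups) <- xml2::xml_attr(gnodes, "id")

  snodes <- xml2::xml_find_all(doc, "//d1:spectrum", ns)
  n <- length(snodes)
  px_attr <- function(acc) {
    v <- xml2::xml_attr(xml2::xml_find_first(
      snodes, sprintf(".//d1:cvParam[@accession='%s']", acc), ns), "value")
    as.integer(v)
  }
  if (n) {
    xs <- px_attr("IMS:1000050")
    ys <- px_attr("IMS:1000051")
    if (anyNA(xs) || anyNA(ys)) stop("spectrum without pixel coordinates")
    xs <- xs - min(xs); ys <- ys - min(ys)
  } else {
    xs <- ys <- integer(0)
  }

  read_arrays <- function(accession) {
    nodes <- binary_array_nodes(doc, ns, accession, groups)
    if (length(nodes) != n) {
      stop("expected one ", accession, " array per spectrum (found ",
           length(nodes), " for ", n, " spectra)")
    }
    if (n == 0) return(list())
    off <- as.numeric(array_param(nodes, ns, "IMS:1000102"))
    len <- as.integer(array_param(nodes, ns, "IMS:1000103"))
    is32 <- !is.na(xml2::xml_attr(xml2::xml_find_first(
      nodes, ".//d1:cvParam[@accession='MS:1000521']", ns), "value"))
    size <- ifelse(is32, 4L, 8L)
    con <- file(p$ibd, "rb")
    on.exit(close(con), add = TRUE)
    lapply(seq_len(n), function(i) {
      seek(con, where = off[i], origin = "start")
      readBin(con, what = "double", n = len[i], size = size[i],
              endian = "little")
    })
  }
  mzs <- read_arrays("MS:1000514")
  ints <- read_arrays("MS:1000515")

  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    mz <- mzs[[i]]; it <- ints[[i]]
    if (length(mz) != length(it)) {
      stop("m/z and intensity array lengths differ for spectrum ", i)
    }
    if (length(mz) > 1L && is.unsorted(mz, strictly = TRUE)) {
      o <- order(mz)
      mz <- mz[o]; it <- it[o]
    }
    if (filter_mz_range && length(mz)) {
      keep <- mz >= mz_range[1] & mz <= mz_range[2]
      mz <- mz[keep]; it <- it[keep]
    }
    spectra[[i]] <- pixel_spectrum(xs[i], ys[i], mz, it)
  }
  width <- if (n) max(xs) + 1L else 0L
  height <- if (n) max(ys) + 1L else 0L

  px <- xml2::xml_attr(xml2::xml_find_first(
    doc, "//d1:cvParam[@accession='IMS:1000046']", ns), "value")
  pixel_size <- if (is.na(px)) 10 else as.numeric(px)

  msi_dataset(spectra, width = width, height = height,
              pixel_size_um = pixel_size, mz_range = mz_range)
}
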