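# imzML 1.1 + ibd input/output.
#
# imzML is an mzML XML document whose binary arrays live in a sibling .ibd
# file addressed by (offset, length) cvParams; "continuous" files share one
# m/z axis across pixels, "processed" files store one axis per pixel. The ibd
# starts with the 16-byte UUID that is also declared in the XML.

IMS_X <- "IMS:1000050"
IMS_Y <- "IMS:1000051"
IMS_OFFSET <- "IMS:1000102"
IMS_LENGTH <- "IMS:1000103"
IMS_ENC_LENGTH <- "IMS:1000104"
IMS_CONTINUOUS <- "IMS:1000030"
IMS_PROCESSED <- "IMS:1000031"

ibd_path_for <- function(path) {
  sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
}

#' Read an imzML/ibd image file
#'
#' Supports both continuous and processed binary modes, 32- and 64-bit float
#' arrays. The acquisition order of pixels is taken to be the spectrum storage
#' order in the file (1-based), the only ordering the format exposes.
#'
#' @param path Path to the `.imzML` file; the `.ibd` must sit next to it.
#' @param sample_id Sample identifier; defaults to the file stem.
#' @param ionization_mode,group,sex,run_order,scan_range Sample metadata
#'   passed through to [msi_sample()].
#'
#' @return An [msi_sample()].
#' @export
read_imzml <- function(path, sample_id = NULL,
                       ionization_mode = "positive",
                       group = NA_character_, sex = NA_character_,
                       run_order = 1L, scan_range = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("imzML file not found: %s", path))
  }
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd)) {
    rlang::abort(sprintf("missing .ibd binary file: %s", ibd))
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.imzml$", "", basename(path), ignore.case = TRUE)
  }

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  mode_node <- xml2::xml_find_first(
    doc, sprintf("//fileContent/cvParam[@accession='%s']", IMS_PROCESSED))
  processed <- !inherits(mode_node, "xml_missing")

  centroid_node <- xml2::xml_find_first(
    doc, "//cvParam[@accession='MS:1000127']")
  centroided <- !inherits(centroid_node, "xml_missing")

  # which referenceable param groups describe the m/z and intensity arrays,
  # and at what precision
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  group_info <- purrr::map(groups, function(g) {
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "./cvParam"), "accession")
    kind <- if ("MS:1000514" %in% acc) "mz"
            else if ("MS:1000515" %in% acc) "intensity"
            else NA_character_
    size <- if ("MS:1000523" %in% acc) 8L
            else if ("MS:1000521" %in% acc) 4L
            else 8L
    list(id = xml2::xml_attr(g, "id"), kind = kind, size = size)
  })
  group_kind <- setNames(
    purrr::map_chr(group_info, "kind"),
    purrr::map_chr(group_info, "id"))
  group_size <- setNames(
    purrr::map_int(group_info, "size"),
    purrr::map_chr(group_info, "id"))

  spectra_nodes <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
  if (length(spectra_nodes) == 0L) {
    rlang::abort(sprintf("no spectra found in %s", path))
  }

  param_value <- function(node, accession) {
    p <- xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", accession))
    as.numeric(xml2::xml_attr(p, "value"))
  }

  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)

  read_array <- function(offset, n, size) {
    seek(con, where = offset, origin = "start")
    readBin(con, what = "numeric", n = n, size = size, endian = "little")
  }

  rows <- purrr::map(spectra_nodes, function(sn) {
    x <- param_value(sn, IMS_X)
    y <- param_value(sn, IMS_Y)
    arrays <- xml2::xml_find_all(sn, ".//binaryDataArray")
    mz <- NULL
    intensity <- NULL
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, "./referenceableParamGroupRef"), "ref")
      kind <- group_kind[[ref]]
      vals <- read_array(param_value(arr, IMS_OFFSET),
                         param_value(arr, IMS_LENGTH),
                         group_size[[ref]])
      if (identical(kind, "mz")) mz <- vals else intensity <- vals
    }
    list(x = as.integer(x), y = as.integer(y), mz = mz, intensity = intensity)
  })

  spectra <- tibble::tibble(
    x = purrr::map_int(rows, "x"),
    y = purrr::map_int(rows, "y"),
    acquisition_index = seq_along(rows),
    mz = purrr::map(rows, "mz"),
    intensity = purrr::map(rows, "intensity")
  )

  msi_sample(spectra, sample_id = sample_id,
             ionization_mode = ionization_mode, group = group, sex = sex,
             run_order = run_order, scan_range = scan_range,
             centroided = centroided)
}

#' Write an MSI sample as imzML/ibd
#'
#' Arrays are stored as little-endian 64-bit floats so that a write/read
#' round trip is the identity. In `"auto"` mode the file is written as
#' continuous when all pixels share an identical m/z axis and as processed
#' otherwise.
#'
#' @param sample An [msi_sample()].
#' @param path Destination `.imzML` path; the `.ibd` is written alongside.
#' @param mode `"auto"`, `"continuous"` or `"processed"`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(sample, path, mode = c("auto", "continuous", "processed")) {
  mode <- match.arg(mode)
  validate_msi_sample(sample)
  sp <- sample$spectra
  if (nrow(sp) == 0L || all(lengths(sp$mz) == 0L)) {
    rlang::abort("sample has no spectra to encode")
  }

  shared_axis <- length(unique(purrr::map(sp$mz, ~ .x))) == 1L
  if (mode == "auto") mode <- if (shared_axis) "continuous" else "processed"
  if (mode == "continuous" && !shared_axis) {
    rlang::abort("continuous mode requires an identical m/z axis in every pixel")
  }

  ibd <- ibd_path_for(path)
  uuid_raw <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  uuid_hex <- paste(format(uuid_raw), collapse = "")
  uuid_str <- paste0("{", substr(uuid_hex, 1, 8), "-", substr(uuid_hex, 9, 12),
                     "-", substr(uuid_hex, 13, 16), "-",
                     substr(uuid_hex, 17, 20), "-",
                     substr(uuid_hex, 21, 32), "}")

  con <- tryCatch(file(ibd, "wb"),
                  error = function(e) rlang::abort(
                    sprintf("cannot write ibd file: %s", ibd)))
  writeBin(uuid_raw, con)
  offset <- 16

  n <- nrow(sp)
  mz_offset <- numeric(n); mz_len <- integer(n)
  int_offset <- numeric(n); int_len <- integer(n)

  write_array <- function(vals) {
    writeBin(as.double(vals), con, size = 8L, endian = "little")
    start <- offset
    offset <<- offset + 8 * length(vals)
    start
  }

  if (mode == "continuous") {
    shared <- sp$mz[[1]]
    shared_off <- write_array(shared)
    for (i in seq_len(n)) {
      mz_offset[i] <- shared_off
      mz_len[i] <- length(shared)
      int_offset[i] <- write_array(sp$intensity[[i]])
      int_len[i] <- length(sp$intensity[[i]])
    }
  } else {
    for (i in seq_len(n)) {
      mz_offset[i] <- write_array(sp$mz[[i]])
      mz_len[i] <- length(sp$mz[[i]])
      int_offset[i] <- write_array(sp$intensity[[i]])
      int_len[i] <- length(sp$intensity[[i]])
    }
  }
  close(con)

  sha1 <- if (requireNamespace("digest", quietly = TRUE)) {
    digest::digest(file = ibd, algo = "sha1")
  } else NA_character_

  mode_acc <- if (mode == "continuous") IMS_CONTINUOUS else IMS_PROCESSED
  mode_name <- if (mode == "continuous") "continuous" else "processed"
  spectrum_repr <- if (sample$centroided) {
    "<cvParam cvRef=\"MS\" accession=\"MS:1000127\" name=\"centroid spectrum\" value=\"\"/>"
  } else {
    "<cvParam cvRef=\"MS\" accession=\"MS:1000128\" name=\"profile spectrum\" value=\"\"/>"
  }

  header <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<mzML xmlns=\"http://psi.hupo.org/ms/mzml\" version=\"1.1\">",
    "<cvList count=\"3\">",
    "<cv id=\"MS\" fullName=\"Proteomics Standards Initiative Mass Spectrometry Ontology\" URI=\"https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo\"/>",
    "<cv id=\"UO\" fullName=\"Unit Ontology\" URI=\"https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo\"/>",
    "<cv id=\"IMS\" fullName=\"Imaging MS Ontology\" URI=\"https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo\"/>",
    "</cvList>",
    "<fileDescription>",
    "<fileContent>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000579\" name=\"MS1 spectrum\" value=\"\"/>",
    spectrum_repr,
    sprintf("<cvParam cvRef=\"IMS\" accession=\"%s\" name=\"%s\" value=\"\"/>",
            mode_acc, mode_name),
    sprintf("<cvParam cvRef=\"IMS\" accession=\"IMS:1000080\" name=\"universally unique identifier\" value=\"%s\"/>",
            uuid_str),
    if (!is.na(sha1)) sprintf("<cvParam cvRef=\"IMS\" accession=\"IMS:1000091\" name=\"ibd SHA-1\" value=\"%s\"/>", sha1),
    "</fileContent>",
    "</fileDescription>",
    "<referenceableParamGroupList count=\"2\">",
    "<referenceableParamGroup id=\"mzArray\">",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000514\" name=\"m/z array\" value=\"\" unitCvRef=\"MS\" unitAccession=\"MS:1000040\" unitName=\"m/z\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\" value=\"\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\" value=\"\"/>",
    "<cvParam cvRef=\"IMS\" accession=\"IMS:1000101\" name=\"external data\" value=\"true\"/>",
    "</referenceableParamGroup>",
    "<referenceableParamGroup id=\"intensityArray\">",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000515\" name=\"intensity array\" value=\"\" unitCvRef=\"MS\" unitAccession=\"MS:1000131\" unitName=\"number of detector counts\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\" value=\"\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\" value=\"\"/>",
    "<cvParam cvRef=\"IMS\" accession=\"IMS:1000101\" name=\"external data\" value=\"true\"/>",
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    "<softwareList count=\"1\">",
    "<software id=\"msiregion\" version=\"0.1.0\">",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000799\" name=\"custom unreleased software tool\" value=\"msiregion\"/>",
    "</software>",
    "</softwareList>",
    "<scanSettingsList count=\"1\">",
    "<scanSettings id=\"scanSettings1\">",
    sprintf("<cvParam cvRef=\"IMS\" accession=\"IMS:1000042\" name=\"max count of pixels x\" value=\"%d\"/>",
            max(sp$x)),
    sprintf("<cvParam cvRef=\"IMS\" accession=\"IMS:1000043\" name=\"max count of pixels y\" value=\"%d\"/>",
            max(sp$y)),
    "</scanSettings>",
    "</scanSettingsList>",
    "<instrumentConfigurationList count=\"1\">",
    "<instrumentConfiguration id=\"IC1\"/>",
    "</instrumentConfigurationList>",
    "<dataProcessingList count=\"1\">",
    "<dataProcessing id=\"export\">",
    "<processingMethod order=\"1\" softwareRef=\"msiregion\">",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000544\" name=\"Conversion to mzML\" value=\"\"/>",
    "</processingMethod>",
    "</dataProcessing>",
    "</dataProcessingList>",
    sprintf("<run id=\"%s\" defaultInstrumentConfigurationRef=\"IC1\">",
            sample$sample_id),
    sprintf("<spectrumList count=\"%d\" defaultDataProcessingRef=\"export\">", n)
  )

  spectrum_xml <- vapply(seq_len(n), function(i) {
    paste0(
      sprintf("<spectrum index=\"%d\" id=\"spectrum=%d\" defaultArrayLength=\"%d\">",
              i - 1L, i, int_len[i]),
      "<scanList count=\"1\"><scan>",
      sprintf("<cvParam cvRef=\"IMS\" accession=\"%s\" name=\"position x\" value=\"%d\"/>",
              IMS_X, sp$x[i]),
      sprintf("<cvParam cvRef=\"IMS\" accession=\"%s\" name=\"position y\" value=\"%d\"/>",
              IMS_Y, sp$y[i]),
      "</scan></scanList>",
      "<binaryDataArrayList count=\"2\">",
      "<binaryDataArray encodedLength=\"0\">",
      "<referenceableParamGroupRef ref=\"mzArray\"/>",
      sprintf("<cvParam cvRef=\"IMS\" accession=\"%s\" name=\"external offset\" value=\"%.0f\"/>",
              IMS_OFFSET, mz_offset[i]),
      sprintf("<cvParam cvRef=\"IMS\" accession=\"%s\" name=\"external array length\" value=\"%d\"/>",
              IMS_LENGTH, mz_len[i]),
      sprintf("<cvParam cvRef=\"IMS\" accession=\"%s\" name=\"external encoded length\" value=\"%d\"/>",
              IMS_ENC_LENGTH, 8L * mz_len[i]),
      "<binary/></binaryDataArray>",
      "<binaryDataArray encodedLength=\"0\">",
      "<referenceableParamGroupRef ref=\"intensityArray\"/>",
      sprintf("<cvParam cvRef=\"IMS\" accession=\"%s\" name=\"external offset\" value=\"%.0f\"/>",
              IMS_OFFSET, int_offset[i]),
      sprintf("<cvParam cvRef=\"IMS\" accession=\"%s\" name=\"external array length\" value=\"%d\"/>",
              IMS_LENGTH, int_len[i]),
      sprintf("<cvParam cvRef=\"IMS\" accession=\"%s\" name=\"external encoded length\" value=\"%d\"/>",
              IMS_ENC_LENGTH, 8L * int_len[i]),
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList>",
      "</spectrum>"
    )
  }, character(1))

  footer <- c("</spectrumList>", "</run>", "</mzML>")

  tryCatch(
    writeLines(c(header, spectrum_xml, footer), path),
    error = function(e) rlang::abort(sprintf("cannot write imzML file: %s", path))
  )
  invisible(path)
}
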