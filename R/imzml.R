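#' Write an MSI dataset to imzML
#'
#' Emits a processed-mode imzML 1.1 file pair: an XML part (`.imzML`)
#' and the binary data part (`.ibd`) holding the m/z arrays as 64-bit
#' and the intensities as 32-bit little-endian IEEE floats. The two
#' files are linked by a UUID stored both in the XML and in the first
#' 16 bytes of the binary part, and the XML records the MD5 checksum of
#' the binary part. Pixel coordinates are converted from the package's
#' 0-based image convention to the standard's 1-based positions.
#'
#' @param dataset An [msi_dataset()].
#' @param path Output path of the `.imzML` file; the `.ibd` companion is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")

  sp <- dataset$spectra
  n_spec <- nrow(sp)
  lens <- if (n_spec > 0) lengths(sp$mz) else integer(0)

  # binary payload first; the UUID is content-derived (MD5 of payload)
  payload_path <- tempfile(fileext = ".bin")
  con <- file(payload_path, "wb")
  for (i in seq_len(n_spec)) {
    writeBin(as.numeric(sp$mz[[i]]), con, size = 8, endian = "little")
    writeBin(as.numeric(sp$intensity[[i]]), con, size = 4, endian = "little")
  }
  close(con)
  uuid_raw <- md5_raw(payload_path)
  uuid_str <- format_uuid(uuid_raw)

  con <- file(ibd_path, "wb")
  writeBin(uuid_raw, con)
  payload <- readBin(payload_path, "raw", n = file.info(payload_path)$size)
  writeBin(payload, con)
  close(con)
  unlink(payload_path)
  checksum <- unname(tools::md5sum(ibd_path))

  # byte offsets of each array within the ibd (after the 16-byte UUID)
  mz_bytes <- 8 * lens
  int_bytes <- 4 * lens
  block <- mz_bytes + int_bytes
  mz_offset <- 16 + cumsum(c(0, block))[seq_len(n_spec)]
  int_offset <- mz_offset + mz_bytes

  cv <- function(cvref, acc, name, value = NULL, unit = NULL) {
    paste0('<cvParam cvRef="', cvref, '" accession="', acc, '" name="', name, '"',
           if (!is.null(value)) paste0(' value="', value, '"') else ' value=""',
           if (!is.null(unit)) unit else "", "/>")
  }
  spec_xml <- character(n_spec)
  for (i in seq_len(n_spec)) {
    spec_xml[i] <- paste0(
      '<spectrum id="spectrum=', i, '" defaultArrayLength="', lens[i],
      '" index="', i - 1, '">',
      '<scanList count="1">', cv("MS", "MS:1000795", "no combination"),
      '<scan>',
      cv("IMS", "IMS:1000050", "position x", sp$x[i] + 1L),
      cv("IMS", "IMS:1000051", "position y", sp$y[i] + 1L),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cv("IMS", "IMS:1000103", "external array length", lens[i]),
      cv("IMS", "IMS:1000104", "external encoded length", mz_bytes[i]),
      cv("IMS", "IMS:1000102", "external offset", sprintf("%.0f", mz_offset[i])),
      "<binary/></binaryDataArray>",
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cv("IMS", "IMS:1000103", "external array length", lens[i]),
      cv("IMS", "IMS:1000104", "external encoded length", int_bytes[i]),
      cv("IMS", "IMS:1000102", "external offset", sprintf("%.0f", int_offset[i])),
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList></spectrum>")
  }

  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    cv("MS", "MS:1000579", "MS1 spectrum"),
    cv("MS", "MS:1000127", "centroid spectrum"),
    cv("IMS", "IMS:1000031", "processed"),
    cv("IMS", "IMS:1000080", "universally unique identifier",
       paste0("{", uuid_str, "}")),
    cv("IMS", "IMS:1000090", "ibd MD5", toupper(checksum)),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS", "MS:1000514", "m/z array", unit = ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"'),
    cv("MS", "MS:1000523", "64-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cv("MS", "MS:1000515", "intensity array", unit = ' unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"'),
    cv("MS", "MS:1000521", "32-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    cv("IMS", "IMS:1000042", "max count of pixels x", dataset$grid_shape[1]),
    cv("IMS", "IMS:1000043", "max count of pixels y", dataset$grid_shape[2]),
    cv("IMS", "IMS:1000046", "pixel size (x)", dataset$pixel_size_um,
       ' unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"'),
    "</scanSettings></scanSettingsList>",
    '<run id="run1">',
    paste0('<spectrumList count="', n_spec, '">'),
    spec_xml,
    "</spectrumList></run></mzML>")
  writeLines(xml, path)
  invisible(path)
}

#' Read an imzML MSI dataset
#'
#' Supports both continuous and processed binary modes with 32- or
#' 64-bit float arrays. The UUID embedded in the binary part must match
#' the one declared in the XML; profile-mode files are rejected (the
#' package models centroid spectra only). The standard's 1-based pixel
#' positions are shifted to the package's 0-based convention, and the
#' spectrum order in the file is preserved as acquisition order.
#'
#' @param path Path to the `.imzML` file; the `.ibd` companion must sit
#'   next to it.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(path)) stop("imzML file not found: ", path, call. = FALSE)
  if (!file.exists(ibd_path)) {
    stop("imzML format error: binary companion not found: ", ibd_path, call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  fc_acc <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//fileDescription/fileContent/cvParam"), "accession")
  if ("MS:1000128" %in% fc_acc) {
    stop("unsupported mode: profile spectra must be centroided before import",
         call. = FALSE)
  }
  uuid_node <- xml2::xml_find_first(doc, "//cvParam[@accession='IMS:1000080']")
  if (inherits(uuid_node, "xml_missing")) {
    stop("imzML format error: no UUID declared in ", path, call. = FALSE)
  }
  uuid_xml <- normalize_uuid(xml2::xml_attr(uuid_node, "value"))
  uuid_ibd <- paste(sprintf("%02x", as.integer(
    readBin(ibd_path, "raw", n = 16))), collapse = "")
  if (!identical(uuid_xml, uuid_ibd)) {
    stop("imzML format error: UUID mismatch between XML (", uuid_xml,
         ") and ibd (", uuid_ibd, ")", call. = FALSE)
  }

  # per-array-type binary width from the referenceable param groups
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  width_of <- list()
  for (g in groups) {
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "cvParam"), "accession")
    kind <- if ("MS:1000514" %in% acc) "mz"
            else if ("MS:1000515" %in% acc) "intensity" else next
    width <- if ("MS:1000523" %in% acc) 8L
             else if ("MS:1000521" %in% acc) 4L
             else stop("imzML format error: unsupported binary data type for the ",
                       kind, " array (only 32/64-bit floats)", call. = FALSE)
    width_of[[xml2::xml_attr(g, "id")]] <- list(kind = kind, width = width)
  }

  spec_nodes <- xml2::xml_find_all(doc, "//run/spectrumList/spectrum")
  n_spec <- length(spec_nodes)
  grab1 <- function(node, xpath) {
    xml2::xml_attr(xml2::xml_find_first(node, xpath), "value")
  }
  px <- as.integer(vapply(spec_nodes, grab1, character(1),
    ".//cvParam[@accession='IMS:1000050']")) - 1L
  py <- as.integer(vapply(spec_nodes, grab1, character(1),
    ".//cvParam[@accession='IMS:1000051']")) - 1L
  if (anyNA(px) || anyNA(py)) {
    stop("imzML format error: spectrum without pixel position", call. = FALSE)
  }

  con <- file(ibd_path, "rb")
  on.exit(close(con))
  read_array <- function(offset, n, width) {
    seek(con, where = offset, origin = "start")
    readBin(con, "numeric", n = n, size = width, endian = "little")
  }
  mz_list <- vector("list", n_spec)
  int_list <- vector("list", n_spec)
  for (i in seq_len(n_spec)) {
    arrays <- xml2::xml_find_all(spec_nodes[[i]], ".//binaryDataArray")
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, "referenceableParamGroupRef"), "ref")
      info <- width_of[[ref]]
      if (is.null(info)) {
        # fall back to inline cvParams
        acc <- xml2::xml_attr(xml2::xml_find_all(arr, "cvParam"), "accession")
        kind <- if ("MS:1000514" %in% acc) "mz"
                else if ("MS:1000515" %in% acc) "intensity"
                else stop("imzML format error: binaryDataArray of unknown kind",
                          call. = FALSE)
        width <- if ("MS:1000523" %in% acc) 8L else 4L
        info <- list(kind = kind, width = width)
      }
      offset <- as.numeric(grab1(arr, "cvParam[@accession='IMS:1000102']"))
      n_elem <- as.integer(grab1(arr, "cvParam[@accession='IMS:1000103']"))
      values <- read_array(offset, n_elem, info$width)
      if (info$kind == "mz") mz_list[[i]] <- values else int_list[[i]] <- values
    }
  }

  gx <- as.numeric(xml2::xml_attr(
    xml2::xml_find_first(doc, "//cvParam[@accession='IMS:1000042']"), "value"))
  gy <- as.numeric(xml2::xml_attr(
    xml2::xml_find_first(doc, "//cvParam[@accession='IMS:1000043']"), "value"))
  if (is.na(gx)) gx <- max(px, 0L) + 1L
  if (is.na(gy)) gy <- max(py, 0L) + 1L
  psz_node <- xml2::xml_find_first(doc, "//cvParam[@accession='IMS:1000046']")
  psz <- if (inherits(psz_node, "xml_missing")) NA_real_
         else as.numeric(xml2::xml_attr(psz_node, "value"))
  mode <- if ("IMS:1000030" %in% fc_acc) "continuous" else "processed"

  msi_dataset(
    tibble::tibble(x = px, y = py, mz = mz_list, intensity = int_list),
    grid_shape = c(gx, gy),
    pixel_size_um = if (is.na(psz)) 40 else psz,
    metadata = list(source = path, imzml_mode = mode, uuid = uuid_xml)
  )
}

#' Read and write centroid peak lists (TSV)
#'
#' The exchange format for MS/MS spectra: a two-column tab-separated
#' table with a mandatory `mz`/`intensity` header.
#'
#' @param path File path.
#' @return `read_peaklist()` returns a tibble with columns `mz`,
#'   `intensity`, sorted by m/z.
#' @export
read_peaklist <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("peak list must have a header with columns 'mz' and 'intensity'",
         call. = FALSE)
  }
  out <- tibble::as_tibble(df[c("mz", "intensity")])
  dplyr::arrange(out, .data$mz)
}

#' @rdname read_peaklist
#' @param peaks A data frame with columns `mz` and `intensity`.
#' @export
write_peaklist <- function(peaks, path) {
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  utils::write.table(peaks[c("mz", "intensity")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

md5_raw <- function(path) {
  hex <- unname(tools::md5sum(path))
  as.raw(strtoi(substring(hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

format_uuid <- function(raw16) {
  hex <- paste(sprintf("%02x", as.integer(raw16)), collapse = "")
  paste(substring(hex, c(1, 9, 13, 17, 21), c(8, 12, 16, 20, 32)), collapse = "-")
}

normalize_uuid <- function(x) {
  tolower(gsub("[{}\\-]", "", x))
}
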