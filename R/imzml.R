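#' Write an MSI dataset as continuous-mode imzML
#'
#' Produces an `.imzML` metadata file plus its binary `.ibd` sibling. The
#' shared m/z axis is stored once (continuous mode) as 64-bit floats,
#' followed by one 64-bit float intensity array per pixel; the XML carries
#' standard IMS/MS controlled-vocabulary accessions so the files are
#' readable by common imzML parsers. Pixel positions are written 1-based as
#' the format requires; this package's 0-based grid coordinates are
#' restored on read.
#'
#' @param ds an [msi_dataset()].
#' @param path path of the `.imzML` file to create; the `.ibd` file is
#'   written next to it.
#' @return `path`, invisibly.
#' @seealso [read_imzml()]
#' @export
write_imzml <- function(ds, path) {
  stopifnot(inherits(ds, "msi_dataset"))
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")

  n <- nrow(ds$spectra); m <- length(ds$mz)
  uuid <- as.raw(c(1:15, 255))  # fixed writer uuid; identity checked on read
  ibd <- file(ibd_path, "wb")
  writeBin(uuid, ibd)
  writeBin(as.double(ds$mz), ibd, size = 8, endian = "little")
  for (i in seq_len(n))
    writeBin(as.double(ds$spectra[i, ]), ibd, size = 8, endian = "little")
  close(ibd)

  cv <- function(acc, name, value = NULL, unit = NULL) {
    ref <- sub(":.*", "", acc)
    v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>', ref, acc, name, v)
  }
  mz_off <- 16
  int_off <- mz_off + 8 * m + 8 * m * (seq_len(n) - 1)
  spectra_xml <- vapply(seq_len(n), function(i) paste0(
    sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">', i - 1, i, m),
    '<scanList count="1"><scan>',
    cv("IMS:1000050", "position x", ds$coords[i, 1] + 1),
    cv("IMS:1000051", "position y", ds$coords[i, 2] + 1),
    '</scan></scanList>',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>',
    cv("IMS:1000103", "external array length", m),
    cv("IMS:1000104", "external encoded length", 8 * m),
    cv("IMS:1000102", "external offset", mz_off),
    '<binary/></binaryDataArray>',
    '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>',
    cv("IMS:1000103", "external array length", m),
    cv("IMS:1000104", "external encoded length", 8 * m),
    cv("IMS:1000102", "external offset", int_off[i]),
    '<binary/></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'), character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    cv("IMS:1000030", "continuous"),
    cv("IMS:1000080", "universally unique identifier",
       paste0("{", paste(sprintf("%02x", as.integer(uuid)), collapse = ""), "}")),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS:1000514", "m/z array"), cv("MS:1000523", "64-bit float"),
    cv("MS:1000576", "no compression"), cv("IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cv("MS:1000515", "intensity array"), cv("MS:1000523", "64-bit float"),
    cv("MS:1000576", "no compression"), cv("IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    cv("IMS:1000042", "max count of pixels x", max(ds$coords[, 1]) + 1),
    cv("IMS:1000043", "max count of pixels y", max(ds$coords[, 2]) + 1),
    cv("IMS:1000046", "pixel size (x)", ds$pitch),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="instrument1"/>',
    '</instrumentConfigurationList>',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="instrument1"><spectrumList count="%d" defaultDataProcessingRef="dp1">', n),
    paste(spectra_xml, collapse = ""),
    '</spectrumList></run></mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Read a continuous-mode imzML file
#'
#' Parses the XML metadata, then pulls the shared m/z axis and the
#' per-pixel intensity arrays from the `.ibd` sibling using the external
#' offset/length accessions. Both 64-bit and 32-bit float arrays are
#' supported; processed-mode files (per-pixel m/z axes) are rejected.
#'
#' @param path path to the `.imzML` file; the `.ibd` file must sit next to
#'   it (same basename).
#' @return an [msi_dataset()] with 0-based grid coordinates.
#' @export
read_imzml <- function(path) {
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("missing .ibd sibling for ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  acc <- function(node, a)
    xml2::xml_attr(xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", a)), "value")
  has_acc <- function(node, a)
    !is.na(xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", a)))
  if (!has_acc(doc, "IMS:1000030"))
    stop("only continuous-mode imzML is supported (accession IMS:1000030 absent)")

  # bytes per value per referenceable group (MS:1000523 = 64-bit, MS:1000521 = 32-bit)
  grp_size <- function(id) {
    g <- xml2::xml_find_first(doc, sprintf(".//referenceableParamGroup[@id='%s']", id))
    if (has_acc(g, "MS:1000523")) 8L else if (has_acc(g, "MS:1000521")) 4L
    else stop("unsupported binary data type in group '", id, "'")
  }
  sizes <- c(mzArray = grp_size("mzArray"), intensityArray = grp_size("intensityArray"))

  spectra_nodes <- xml2::xml_find_all(doc, ".//spectrum")
  n <- length(spectra_nodes)
  if (n == 0) stop("no spectra found in ", path)

  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd))
  read_array <- function(offset, len, size) {
    seek(ibd, where = offset, origin = "start")
    readBin(ibd, "double", n = len, size = size, endian = "little")
  }

  coords <- matrix(NA_real_, n, 2)
  mz <- NULL
  spectra <- NULL
  for (i in seq_len(n)) {
    sp <- spectra_nodes[[i]]
    coords[i, ] <- c(as.numeric(acc(sp, "IMS:1000050")),
                     as.numeric(acc(sp, "IMS:1000051"))) - 1
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref")
      off <- as.numeric(acc(bda, "IMS:1000102"))
      len <- as.integer(acc(bda, "IMS:1000103"))
      if (is.na(ref) || is.na(off) || is.na(len))
        stop("spectrum ", i, ": binaryDataArray lacks external offset/length")
      if (ref == "mzArray") {
        if (is.null(mz)) mz <- read_array(off, len, sizes["mzArray"])
      } else {
        if (is.null(spectra)) spectra <- matrix(NA_real_, n, len)
        spectra[i, ] <- read_array(off, len, sizes["intensityArray"])
      }
    }
  }
  if (is.null(mz) || is.null(spectra))
    stop("missing m/z or intensity arrays in ", path)
  pitch <- suppressWarnings(as.numeric(acc(doc, "IMS:1000046")))
  msi_dataset(coords, spectra, mz, if (is.finite(pitch)) pitch else 70)
}
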