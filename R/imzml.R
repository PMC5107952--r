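# imzML I/O: the open XML + binary (.ibd) interchange format for MSI data.
# Both the "continuous" dialect (shared m/z axis, one intensity array per
# pixel) and the "processed" dialect (per-pixel m/z and intensity arrays)
# are supported.  Arrays are 64-bit little-endian floats.

.IMS_CONTINUOUS <- "IMS:1000030"
.IMS_PROCESSED  <- "IMS:1000031"
.IMS_POS_X      <- "IMS:1000050"
.IMS_POS_Y      <- "IMS:1000051"
.IMS_EXT_OFFSET <- "IMS:1000102"
.IMS_EXT_LEN    <- "IMS:1000103"
.IMS_EXT_ENC    <- "IMS:1000104"
.MS_MZ_ARRAY    <- "MS:1000514"
.MS_INT_ARRAY   <- "MS:1000515"
.MS_F64         <- "MS:1000523"
.MS_F32         <- "MS:1000521"

#' Read an imzML mass spectrometry imaging file
#'
#' Parses the XML index and the companion `.ibd` binary file into an
#' [msi_dataset()].  imzML stores pixel positions 1-based; they are
#' converted to the package's 0-based convention on read (and restored
#' on write).
#'
#' @param path Path to the `.imzML` file; the `.ibd` file is expected
#'   alongside it with the same stem.
#' @param mass_range Numeric `(lo, hi)`; m/z values outside this window
#'   are dropped from every spectrum.  Default `c(460, 1200)`, the lipid
#'   mass window of the targeted acquisitions.
#' @param mode Ionization mode to tag the dataset with when the file
#'   does not record a polarity.
#' @param spacing_um Pixel pitch in micrometers for the restored grid.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path, mass_range = c(460, 1200),
                       mode = c("positive", "negative"),
                       spacing_um = 100) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  if (!file.exists(ibd_path)) stop("companion .ibd file not found: ", ibd_path)

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  fc_acc <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//fileContent/cvParam"), "accession")
  continuous <- .IMS_CONTINUOUS %in% fc_acc
  if (!continuous && !(.IMS_PROCESSED %in% fc_acc))
    stop("malformed imzML: neither continuous nor processed declared")

  pol <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//spectrum/cvParam"), "accession")
  if ("MS:1000129" %in% pol) mode <- "negative"
  if ("MS:1000130" %in% pol) mode <- "positive"

  # array-type and encoding of the two referenceable param groups
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  ginfo <- lapply(groups, function(g) {
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "./cvParam"), "accession")
    list(id = xml2::xml_attr(g, "id"),
         type = if (.MS_MZ_ARRAY %in% acc) "mz"
                else if (.MS_INT_ARRAY %in% acc) "intensity" else NA,
         bytes = if (.MS_F32 %in% acc) 4L else 8L)
  })
  names(ginfo) <- vapply(ginfo, `[[`, character(1), "id")

  spectra_nodes <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra_nodes) == 0L) stop("malformed imzML: empty pixel list")

  con <- file(ibd_path, "rb")
  on.exit(close(con))

  read_array <- function(offset, n, bytes) {
    seek(con, where = offset, origin = "start")
    readBin(con, what = "double", n = n, size = bytes, endian = "little")
  }

  xs <- integer(length(spectra_nodes)); ys <- integer(length(spectra_nodes))
  shared_mz <- NULL
  spectra <- vector("list", length(spectra_nodes))
  for (i in seq_along(spectra_nodes)) {
    sp <- spectra_nodes[[i]]
    pos_par <- xml2::xml_find_all(sp, ".//scan/cvParam")
    acc <- xml2::xml_attr(pos_par, "accession")
    val <- as.numeric(xml2::xml_attr(pos_par, "value"))
    xi <- val[match(.IMS_POS_X, acc)]; yi <- val[match(.IMS_POS_Y, acc)]
    if (is.na(xi) || is.na(yi)) stop("malformed imzML: missing pixel position")
    xs[i] <- as.integer(xi) - 1L; ys[i] <- as.integer(yi) - 1L

    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- NULL; ints <- NULL
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, "./referenceableParamGroupRef"), "ref")
      par <- xml2::xml_find_all(arr, "./cvParam")
      aacc <- xml2::xml_attr(par, "accession")
      aval <- xml2::xml_attr(par, "value")
      type <- if (!is.na(ref) && ref %in% names(ginfo)) ginfo[[ref]]$type
              else if (.MS_MZ_ARRAY %in% aacc) "mz"
              else if (.MS_INT_ARRAY %in% aacc) "intensity" else NA
      bytes <- if (!is.na(ref) && ref %in% names(ginfo)) ginfo[[ref]]$bytes
               else if (.MS_F32 %in% aacc) 4L else 8L
      offset <- as.numeric(aval[match(.IMS_EXT_OFFSET, aacc)])
      n <- as.numeric(aval[match(.IMS_EXT_LEN, aacc)])
      if (is.na(offset) || is.na(n))
        stop("malformed imzML: missing external offset/length")
      vals <- read_array(offset, n, bytes)
      if (identical(type, "mz")) mz <- vals else ints <- vals
    }
    if (is.null(ints)) stop("malformed imzML: spectrum without intensities")
    if (is.null(mz)) {
      if (!continuous || is.null(shared_mz))
        stop("malformed imzML: spectrum without m/z array")
      mz <- shared_mz
    }
    if (continuous && is.null(shared_mz)) shared_mz <- mz
    keep <- mz >= mass_range[1] & mz <= mass_range[2]
    spectra[[i]] <- msi_spectrum(mz[keep], pmax(ints[keep], 0), mode = mode)
  }
  msi_dataset(pixel_grid(xs, ys, spacing_um = spacing_um), spectra,
              mode = mode)
}

#' Write an MSI dataset to imzML
#'
#' Writes the `.imzML` XML index plus the companion `.ibd` binary file
#' (64-bit little-endian floats).  Continuous output requires all
#' spectra to share one m/z axis; processed output stores each pixel's
#' axis.  [read_imzml()] is the inverse.
#'
#' @param ds An [msi_dataset()].
#' @param path Output `.imzML` path; the `.ibd` is written alongside.
#' @param dialect `"processed"` (default; always valid) or
#'   `"continuous"`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(ds, path, dialect = c("processed", "continuous")) {
  stopifnot(inherits(ds, "msi_dataset"))
  dialect <- match.arg(dialect)
  if (dialect == "continuous") {
    ax <- ds$spectra[[1]]$mz
    same <- vapply(ds$spectra, function(s) identical(s$mz, ax), logical(1))
    if (!all(same)) stop("continuous dialect requires a shared m/z axis")
  }
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")

  uuid_bytes <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  uuid_hex <- paste(format(uuid_bytes), collapse = "")
  uuid_str <- sprintf("{%s-%s-%s-%s-%s}",
                      substr(uuid_hex, 1, 8), substr(uuid_hex, 9, 12),
                      substr(uuid_hex, 13, 16), substr(uuid_hex, 17, 20),
                      substr(uuid_hex, 21, 32))

  con <- file(ibd_path, "wb")
  writeBin(uuid_bytes, con)
  offset <- 16
  put <- function(v) {
    writeBin(as.numeric(v), con, size = 8, endian = "little")
    off <- offset; offset <<- offset + 8 * length(v)
    c(offset = off, n = length(v), enc = 8 * length(v))
  }
  n_spec <- length(ds$spectra)
  mz_loc <- vector("list", n_spec); int_loc <- vector("list", n_spec)
  if (dialect == "continuous") {
    shared <- put(ds$spectra[[1]]$mz)
    for (i in seq_len(n_spec)) {
      mz_loc[[i]] <- shared
      int_loc[[i]] <- put(ds$spectra[[i]]$intensity)
    }
  } else {
    for (i in seq_len(n_spec)) {
      mz_loc[[i]] <- put(ds$spectra[[i]]$mz)
      int_loc[[i]] <- put(ds$spectra[[i]]$intensity)
    }
  }
  close(con)

  cv <- function(cvref, acc, name, value = NULL) {
    v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>',
            cvref, acc, name, v)
  }
  mode_cv <- if (ds$mode == "positive")
    cv("MS", "MS:1000130", "positive scan") else
    cv("MS", "MS:1000129", "negative scan")
  dialect_cv <- if (dialect == "continuous")
    cv("IMS", .IMS_CONTINUOUS, "continuous") else
    cv("IMS", .IMS_PROCESSED, "processed")

  spec_xml <- vapply(seq_len(n_spec), function(i) {
    m <- mz_loc[[i]]; it <- int_loc[[i]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, it[["n"]]),
      mode_cv,
      '<scanList count="1">', cv("MS", "MS:1000795", "no combination"),
      '<scan>',
      cv("IMS", .IMS_POS_X, "position x", ds$grid$x[i] + 1L),
      cv("IMS", .IMS_POS_Y, "position y", ds$grid$y[i] + 1L),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>%s%s%s<binary/></binaryDataArray>',
              cv("IMS", .IMS_EXT_OFFSET, "external offset", m[["offset"]]),
              cv("IMS", .IMS_EXT_LEN, "external array length", m[["n"]]),
              cv("IMS", .IMS_EXT_ENC, "external encoded length", m[["enc"]])),
      sprintf('<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>%s%s%s<binary/></binaryDataArray>',
              cv("IMS", .IMS_EXT_OFFSET, "external offset", it[["offset"]]),
              cv("IMS", .IMS_EXT_LEN, "external array length", it[["n"]]),
              cv("IMS", .IMS_EXT_ENC, "external encoded length", it[["enc"]])),
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    cv("MS", "MS:1000294", "mass spectrum"),
    dialect_cv,
    cv("IMS", "IMS:1000080", "universally unique identifier", uuid_str),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS", .MS_MZ_ARRAY, "m/z array"),
    cv("MS", .MS_F64, "64-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cv("MS", .MS_INT_ARRAY, "intensity array"),
    cv("MS", .MS_F64, "64-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1"><software id="msigrade" version="0.1.0"/></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    cv("IMS", "IMS:1000042", "max count of pixels x", max(ds$grid$x) + 1L),
    cv("IMS", "IMS:1000043", "max count of pixels y", max(ds$grid$y) + 1L),
    cv("IMS", "IMS:1000046", "pixel size (x)", grid_spacing(ds$grid)),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="msigrade">',
    cv("MS", "MS:1000544", "Conversion to mzML"),
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('<spectrumList count="%d">', n_spec),
    paste(spec_xml, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}
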