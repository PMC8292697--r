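# Minimal DICOM codec: Explicit VR Little Endian only, with the tag subset
# needed for the RT Structure Set / RT Dose / RT Plan storage classes.
# Datasets are ordered lists of elements: list(group, element, vr, value).
# SQ values are lists of nested datasets; OB/OW values are raw vectors.

.DCM_TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"

.SOP_CLASS <- c(
  RTSTRUCT = "1.2.840.10008.5.1.4.1.1.481.3",
  RTDOSE   = "1.2.840.10008.5.1.4.1.1.481.2",
  RTPLAN   = "1.2.840.10008.5.1.4.1.1.481.5"
)

# name -> (group, element, VR)
.DCM_DICT <- list(
  FileMetaInformationGroupLength = list(0x0002L, 0x0000L, "UL"),
  FileMetaInformationVersion     = list(0x0002L, 0x0001L, "OB"),
  MediaStorageSOPClassUID        = list(0x0002L, 0x0002L, "UI"),
  MediaStorageSOPInstanceUID     = list(0x0002L, 0x0003L, "UI"),
  TransferSyntaxUID              = list(0x0002L, 0x0010L, "UI"),
  ImplementationClassUID         = list(0x0002L, 0x0012L, "UI"),

  SOPClassUID           = list(0x0008L, 0x0016L, "UI"),
  SOPInstanceUID        = list(0x0008L, 0x0018L, "UI"),
  StudyDate             = list(0x0008L, 0x0020L, "DA"),
  Modality              = list(0x0008L, 0x0060L, "CS"),
  ReferencedSOPClassUID    = list(0x0008L, 0x1150L, "UI"),
  ReferencedSOPInstanceUID = list(0x0008L, 0x1155L, "UI"),

  PatientName      = list(0x0010L, 0x0010L, "PN"),
  PatientID        = list(0x0010L, 0x0020L, "LO"),
  PatientBirthDate = list(0x0010L, 0x0030L, "DA"),

  StudyInstanceUID      = list(0x0020L, 0x000DL, "UI"),
  SeriesInstanceUID     = list(0x0020L, 0x000EL, "UI"),
  ImagePositionPatient  = list(0x0020L, 0x0032L, "DS"),
  ImageOrientationPatient = list(0x0020L, 0x0037L, "DS"),
  FrameOfReferenceUID   = list(0x0020L, 0x0052L, "UI"),

  SamplesPerPixel           = list(0x0028L, 0x0002L, "US"),
  PhotometricInterpretation = list(0x0028L, 0x0004L, "CS"),
  NumberOfFrames            = list(0x0028L, 0x0008L, "IS"),
  Rows                      = list(0x0028L, 0x0010L, "US"),
  Columns                   = list(0x0028L, 0x0011L, "US"),
  PixelSpacing              = list(0x0028L, 0x0030L, "DS"),
  BitsAllocated             = list(0x0028L, 0x0100L, "US"),
  BitsStored                = list(0x0028L, 0x0101L, "US"),
  HighBit                   = list(0x0028L, 0x0102L, "US"),
  PixelRepresentation       = list(0x0028L, 0x0103L, "US"),

  DoseUnits           = list(0x3004L, 0x0002L, "CS"),
  DoseType            = list(0x3004L, 0x0004L, "CS"),
  DoseSummationType   = list(0x3004L, 0x000AL, "CS"),
  GridFrameOffsetVector = list(0x3004L, 0x000CL, "DS"),
  DoseGridScaling     = list(0x3004L, 0x000EL, "DS"),

  StructureSetLabel        = list(0x3006L, 0x0002L, "SH"),
  StructureSetROISequence  = list(0x3006L, 0x0020L, "SQ"),
  ROINumber                = list(0x3006L, 0x0022L, "IS"),
  ReferencedFrameOfReferenceUID = list(0x3006L, 0x0024L, "UI"),
  ROIName                  = list(0x3006L, 0x0026L, "LO"),
  ROIDisplayColor          = list(0x3006L, 0x002AL, "IS"),
  ROIContourSequence       = list(0x3006L, 0x0039L, "SQ"),
  ContourSequence          = list(0x3006L, 0x0040L, "SQ"),
  ContourGeometricType     = list(0x3006L, 0x0042L, "CS"),
  NumberOfContourPoints    = list(0x3006L, 0x0046L, "IS"),
  ContourData              = list(0x3006L, 0x0050L, "DS"),
  ReferencedROINumber      = list(0x3006L, 0x0084L, "IS"),

  RTPlanLabel            = list(0x300AL, 0x0002L, "SH"),
  RTPlanDescription      = list(0x300AL, 0x0004L, "ST"),
  DoseReferenceSequence  = list(0x300AL, 0x0010L, "SQ"),
  DoseReferenceDescription = list(0x300AL, 0x0016L, "LO"),
  TargetPrescriptionDose = list(0x300AL, 0x0026L, "DS"),
  FractionGroupSequence  = list(0x300AL, 0x0070L, "SQ"),
  NumberOfFractionsPlanned = list(0x300AL, 0x0078L, "IS"),

  PixelData = list(0x7FE0L, 0x0010L, "OW")
)

.DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.DCM_STRING_VRS <- c("UI", "CS", "SH", "LO", "PN", "DA", "TM", "DS", "IS",
                     "ST", "LT", "AE", "AS", "UT")

.dcm_tag_name <- function(group, element) {
  for (nm in names(.DCM_DICT)) {
    d <- .DCM_DICT[[nm]]
    if (d[[1]] == group && d[[2]] == element) return(nm)
  }
  sprintf("(%04X,%04X)", group, element)
}

#' Construct a DICOM element by dictionary name
#' @param name element keyword from the built-in dictionary
#' @param value element value (character, numeric, raw, or list of item
#'   datasets for SQ)
#' @return an element list (group, element, vr, name, value)
#' @keywords internal
dcm_el <- function(name, value) {
  d <- .DCM_DICT[[name]]
  if (is.null(d)) stop("unknown DICOM keyword: ", name)
  list(group = d[[1]], element = d[[2]], vr = d[[3]], name = name,
       value = value)
}

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32le <- function(x) {
  # lengths can exceed .Machine$integer.max in principle; ours never do
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

.dcm_format_ds <- function(x) {
  s <- vapply(x, function(v) sprintf("%.10g", v), character(1))
  paste(s, collapse = "\\")
}

.dcm_encode_value <- function(vr, value) {
  if (vr %in% c("DS")) {
    b <- charToRaw(.dcm_format_ds(as.numeric(value)))
  } else if (vr == "IS") {
    b <- charToRaw(paste(format(as.integer(value), trim = TRUE,
                                scientific = FALSE), collapse = "\\"))
  } else if (vr %in% .DCM_STRING_VRS) {
    b <- charToRaw(paste(as.character(value), collapse = "\\"))
  } else if (vr == "US") {
    b <- writeBin(as.integer(value), raw(), size = 2L, endian = "little")
  } else if (vr == "UL") {
    b <- writeBin(as.integer(value), raw(), size = 4L, endian = "little")
  } else if (vr == "FD") {
    b <- writeBin(as.double(value), raw(), size = 8L, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    b <- as.raw(value)
  } else {
    stop("unsupported VR for encoding: ", vr)
  }
  if (length(b) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else if (vr %in% .DCM_STRING_VRS)
      charToRaw(" ") else as.raw(0L)
    b <- c(b, pad)
  }
  b
}

.dcm_encode_element <- function(el) {
  if (el$vr == "SQ") {
    items <- lapply(el$value, function(item_ds) {
      body <- .dcm_encode_dataset(item_ds)
      c(.u16le(c(0xFFFEL, 0xE000L)), .u32le(length(body)), body)
    })
    vb <- do.call(c, c(items, list(raw(0))))
  } else {
    vb <- .dcm_encode_value(el$vr, el$value)
  }
  hdr <- c(.u16le(c(el$group, el$element)), charToRaw(el$vr))
  if (el$vr %in% .DCM_LONG_VRS) {
    hdr <- c(hdr, as.raw(c(0L, 0L)), .u32le(length(vb)))
  } else {
    if (length(vb) > 65534L) stop("value too long for short VR ", el$vr)
    hdr <- c(hdr, .u16le(length(vb)))
  }
  c(hdr, vb)
}

.dcm_encode_dataset <- function(ds) {
  if (length(ds) == 0L) return(raw(0))
  ord <- order(vapply(ds, function(e) e$group * 2^16 + e$element, numeric(1)))
  do.call(c, lapply(ds[ord], .dcm_encode_element))
}

#' Write a DICOM file (Explicit VR Little Endian)
#'
#' Low-level writer used by the RT writers. The dataset must contain
#' SOPClassUID and SOPInstanceUID elements; file meta is generated.
#'
#' @param ds ordered list of elements (see [dcm_el()])
#' @param path output file path
#' @return `path`, invisibly
#' @export
dcm_write <- function(ds, path) {
  get1 <- function(name) {
    v <- dcm_get(ds, name)
    if (is.null(v)) stop("dataset lacks required element ", name)
    v
  }
  meta <- list(
    dcm_el("FileMetaInformationVersion", as.raw(c(0L, 1L))),
    dcm_el("MediaStorageSOPClassUID", get1("SOPClassUID")),
    dcm_el("MediaStorageSOPInstanceUID", get1("SOPInstanceUID")),
    dcm_el("TransferSyntaxUID", .DCM_TRANSFER_SYNTAX_ELE),
    dcm_el("ImplementationClassUID", "2.25.730462847501")
  )
  meta_body <- .dcm_encode_dataset(meta)
  meta_len <- dcm_el("FileMetaInformationGroupLength", length(meta_body))
  buf <- c(as.raw(rep(0L, 128L)), charToRaw("DICM"),
           .dcm_encode_element(meta_len), meta_body,
           .dcm_encode_dataset(ds))
  writeBin(buf, path)
  invisible(path)
}

.rd_u16 <- function(buf, pos) {
  readBin(buf[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
.rd_u32 <- function(buf, pos) {
  # read as double to be safe with 0xFFFFFFFF
  b <- as.integer(buf[pos:(pos + 3L)])
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

.dcm_rawToChar <- function(vb) {
  vb <- vb[vb != as.raw(0L)]  # UI padding
  s <- rawToChar(vb)
  sub(" +$", "", s)
}

.dcm_decode_value <- function(vr, vb) {
  if (vr %in% c("DS", "IS")) {
    s <- .dcm_rawToChar(vb)
    if (nchar(s) == 0L) return(numeric(0))
    v <- as.numeric(strsplit(s, "\\\\")[[1]])
    if (vr == "IS") v <- as.integer(v)
    v
  } else if (vr %in% .DCM_STRING_VRS) {
    s <- .dcm_rawToChar(vb)
    if (nchar(s) == 0L) return(character(0))
    strsplit(s, "\\\\")[[1]]
  } else if (vr == "US") {
    readBin(vb, "integer", n = length(vb) / 2L, size = 2L, signed = FALSE,
            endian = "little")
  } else if (vr == "UL") {
    readBin(vb, "integer", n = length(vb) / 4L, size = 4L, endian = "little")
  } else if (vr == "FD") {
    readBin(vb, "double", n = length(vb) / 8L, size = 8L, endian = "little")
  } else {
    vb  # OB/OW/unknown: keep raw
  }
}

# parse elements from buf[pos..limit]; returns list(elements, pos)
.dcm_parse <- function(buf, pos, limit) {
  els <- list()
  while (pos <= limit) {
    group <- .rd_u16(buf, pos); element <- .rd_u16(buf, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFEL && element %in% c(0xE00DL, 0xE0DDL)) {
      pos <- pos + 4L  # delimiter length (0)
      return(list(elements = els, pos = pos, delimiter = element))
    }
    vr <- rawToChar(buf[pos:(pos + 1L)])
    if (vr %in% .DCM_LONG_VRS) {
      len <- .rd_u32(buf, pos + 4L); pos <- pos + 8L
    } else {
      len <- .rd_u16(buf, pos + 2L); pos <- pos + 4L
    }
    nm <- .dcm_tag_name(group, element)
    if (vr == "SQ") {
      if (len == 4294967295) {
        res <- .dcm_parse_sq_items(buf, pos, length(buf), undefined = TRUE)
      } else {
        res <- .dcm_parse_sq_items(buf, pos, pos + len - 1L, undefined = FALSE)
      }
      value <- res$items; pos <- res$pos
    } else {
      if (len == 4294967295) stop("undefined length on non-SQ element ", nm)
      value <- if (len > 0L) .dcm_decode_value(vr, buf[pos:(pos + len - 1L)])
               else .dcm_decode_value(vr, raw(0))
      pos <- pos + len
    }
    els[[length(els) + 1L]] <- list(group = group, element = element,
                                    vr = vr, name = nm, value = value)
  }
  list(elements = els, pos = pos, delimiter = NA_integer_)
}

.dcm_parse_sq_items <- function(buf, pos, limit, undefined) {
  items <- list()
  while (pos <= limit) {
    group <- .rd_u16(buf, pos); element <- .rd_u16(buf, pos + 2L)
    len <- .rd_u32(buf, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFEL && element == 0xE0DDL) {
      return(list(items = items, pos = pos))
    }
    if (!(group == 0xFFFEL && element == 0xE000L)) {
      stop("malformed sequence: expected item tag, got ",
           sprintf("(%04X,%04X)", group, element))
    }
    if (len == 4294967295) {
      res <- .dcm_parse(buf, pos, length(buf))
      if (!identical(res$delimiter, 0xE00DL)) stop("unterminated item")
    } else {
      res <- .dcm_parse(buf, pos, pos + len - 1L)
    }
    items[[length(items) + 1L]] <- res$elements
    pos <- res$pos
  }
  list(items = items, pos = pos)
}

#' Read a DICOM file (Explicit VR Little Endian)
#'
#' @param path DICOM file path
#' @return object of class `rtqa_dicom`: list with `meta` and `elements`
#' @export
dcm_read <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  # file meta group length element
  group <- .rd_u16(buf, pos); element <- .rd_u16(buf, pos + 2L)
  if (group != 2L || element != 0L) stop("missing file meta group length")
  vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
  len <- .rd_u16(buf, pos + 6L)
  meta_len <- .dcm_decode_value("UL", buf[(pos + 8L):(pos + 8L + len - 1L)])
  pos <- pos + 8L + len
  meta <- .dcm_parse(buf, pos, pos + meta_len - 1L)
  pos <- meta$pos
  ts <- dcm_get(meta$elements, "TransferSyntaxUID")
  if (!identical(ts, .DCM_TRANSFER_SYNTAX_ELE))
    stop("unsupported transfer syntax: ", ts)
  body <- .dcm_parse(buf, pos, length(buf))
  structure(list(meta = meta$elements, elements = body$elements, path = path),
            class = "rtqa_dicom")
}

#' Get the value of the first element with a given keyword
#' @param ds an `rtqa_dicom` object or plain element list
#' @param name dictionary keyword
#' @return the element value, or NULL if absent
#' @export
dcm_get <- function(ds, name) {
  els <- if (inherits(ds, "rtqa_dicom")) ds$elements else ds
  for (e in els) if (identical(e$name, name)) return(e$value)
  NULL
}

# replace (or append) an element value in a plain element list
dcm_set <- function(els, name, value) {
  for (i in seq_along(els)) {
    if (identical(els[[i]]$name, name)) {
      els[[i]]$value <- value
      return(els)
    }
  }
  c(els, list(dcm_el(name, value)))
}

dcm_remove <- function(els, name) {
  keep <- vapply(els, function(e) !identical(e$name, name), logical(1))
  els[keep]
}

#' Deterministic UID derivation
#'
#' Derives a DICOM UID under `root` from arbitrary key material via a
#' cryptographic hash, so repeated calls with the same inputs give the
#' same UID.
#'
#' @param ... character fragments hashed into the UID
#' @param root UID root (default "2.25", the UUID-derived arc)
#' @return a UID string
#' @export
rtqa_uid <- function(..., root = "2.25") {
  h <- digest::digest(paste(c(...), collapse = "|"), algo = "sha256",
                      serialize = FALSE)
  a <- strtoi(substr(h, 1, 7), 16L)
  b <- strtoi(substr(h, 8, 14), 16L)
  c_ <- strtoi(substr(h, 15, 21), 16L)
  paste(root, a, b, c_, sep = ".")
}

#' @export
print.rtqa_dicom <- function(x, ...) {
  cat("<DICOM dataset>", if (!is.null(x$path)) x$path else "", "\n")
  cat("  SOP class:", dcm_get(x, "SOPClassUID"), "\n")
  cat("  elements:", length(x$elements), "\n")
  invisible(x)
}
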