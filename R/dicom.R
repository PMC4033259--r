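# Classic single-frame DICOM reading and writing (explicit/implicit VR,
# little endian). Only the dialect needed by this toolkit is supported:
# uncompressed MONOCHROME2 pixel data, 16-bit unsigned, no sequences.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
.SOP_MR_IMAGE <- "1.2.840.10008.5.1.4.1.1.4"
.IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.9.7411.1"

# Tag keys are "gggg,eeee" in lower-case hex. The identification attributes
# (0008,0096) etc. are sequences in the standard; this toolkit reads and
# writes them as plain text, which is sufficient for a removal-only profile.
.dcm_dict_raw <- c(
  "0002,0001", "OB", "File Meta Information Version",
  "0002,0002", "UI", "Media Storage SOP Class UID",
  "0002,0003", "UI", "Media Storage SOP Instance UID",
  "0002,0010", "UI", "Transfer Syntax UID",
  "0002,0012", "UI", "Implementation Class UID",
  "0008,0016", "UI", "SOP Class UID",
  "0008,0018", "UI", "SOP Instance UID",
  "0008,0050", "SH", "Accession Number",
  "0008,0060", "CS", "Modality",
  "0008,0080", "LO", "Institution Name",
  "0008,0090", "PN", "Referring Physician's Name",
  "0008,0096", "LO", "Referring Physician Identification",
  "0008,1048", "PN", "Physician(s) of Record",
  "0008,1049", "LO", "Physician(s) of Record Identification",
  "0008,1050", "PN", "Performing Physician's Name",
  "0008,1052", "LO", "Performing Physician Identification",
  "0008,1060", "PN", "Name of Physician(s) Reading Study",
  "0008,1062", "LO", "Physician(s) Reading Study Identification",
  "0008,103e", "LO", "Series Description",
  "0010,0010", "PN", "Patient's Name",
  "0010,0020", "LO", "Patient ID",
  "0010,0030", "DA", "Patient's Birth Date",
  "0010,0040", "CS", "Patient's Sex",
  "0010,0050", "LO", "Patient's Insurance Plan Code",
  "0010,0101", "LO", "Patient's Primary Language Code",
  "0010,1000", "LO", "Other Patient IDs",
  "0010,1001", "PN", "Other Patient Names",
  "0010,1002", "LO", "Other Patient IDs Sequence",
  "0010,1005", "PN", "Patient's Birth Name",
  "0010,1010", "AS", "Patient's Age",
  "0010,1040", "LO", "Patient's Address",
  "0010,1060", "PN", "Patient's Mother's Birth Name",
  "0018,0050", "DS", "Slice Thickness",
  "0018,9087", "FD", "Diffusion b-value",
  "0018,9089", "FD", "Diffusion Gradient Orientation",
  "0020,000d", "UI", "Study Instance UID",
  "0020,000e", "UI", "Series Instance UID",
  "0020,0011", "IS", "Series Number",
  "0020,0013", "IS", "Instance Number",
  "0020,0032", "DS", "Image Position (Patient)",
  "0020,0037", "DS", "Image Orientation (Patient)",
  "0028,0002", "US", "Samples per Pixel",
  "0028,0004", "CS", "Photometric Interpretation",
  "0028,0010", "US", "Rows",
  "0028,0011", "US", "Columns",
  "0028,0030", "DS", "Pixel Spacing",
  "0028,0100", "US", "Bits Allocated",
  "0028,0101", "US", "Bits Stored",
  "0028,0102", "US", "High Bit",
  "0028,0103", "US", "Pixel Representation",
  "0032,4000", "LT", "Study Comments",
  "7fe0,0010", "OW", "Pixel Data"
)
.dcm_dict <- local({
  m <- matrix(.dcm_dict_raw, ncol = 3, byrow = TRUE)
  data.frame(tag = m[, 1], vr = m[, 2], name = m[, 3],
             stringsAsFactors = FALSE)
})

.STRING_VRS <- c("UI", "SH", "LO", "LT", "PN", "CS", "DA", "TM", "AS",
                 "ST", "IS", "DS", "AE", "UT")
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Look up the dictionary name of a DICOM tag
#'
#' @param tag Tag key in `"gggg,eeee"` lower-case hex form.
#' @return The attribute name, or `"Unknown"` if the tag is not in the
#'   toolkit's dictionary.
#' @export
dcm_tag_name <- function(tag) {
  i <- match(tolower(tag), .dcm_dict$tag)
  ifelse(is.na(i), "Unknown", .dcm_dict$name[i])
}

.dcm_vr_for <- function(tag) {
  i <- match(tag, .dcm_dict$tag)
  if (is.na(i)) "UN" else .dcm_dict$vr[i]
}

.tag_key <- function(group, element) sprintf("%04x,%04x", group, element)

.tag_group <- function(key) strtoi(substr(key, 1, 4), 16L)
.tag_element <- function(key) strtoi(substr(key, 6, 9), 16L)

.u16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}
.u32 <- function(buf, pos) {
  as.integer(buf[pos]) + 256 * as.integer(buf[pos + 1L]) +
    65536 * as.integer(buf[pos + 2L]) + 16777216 * as.integer(buf[pos + 3L])
}
.raw_u16 <- function(v) {
  v <- as.integer(v)
  as.raw(rbind(v %% 256L, v %/% 256L))
}
.raw_u32 <- function(v) {
  v <- as.numeric(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256,
               (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
}

.decode_value <- function(vr, bytes) {
  if (vr %in% .STRING_VRS) {
    pad <- bytes == as.raw(0) | bytes == as.raw(0x20)
    keep <- if (all(pad)) 0L else max(which(!pad))
    rawToChar(bytes[seq_len(keep)])
  } else if (vr == "US") {
    if (length(bytes) == 0) integer(0) else
      readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
              endian = "little", signed = FALSE)
  } else if (vr == "UL") {
    if (length(bytes) == 0) numeric(0) else
      readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
              endian = "little")
  } else if (vr == "FD") {
    if (length(bytes) == 0) numeric(0) else
      readBin(bytes, "double", n = length(bytes) / 8, size = 8,
              endian = "little")
  } else {
    bytes  # OB/OW/UN and anything unrecognized kept raw
  }
}

.encode_value <- function(vr, value) {
  if (vr %in% .STRING_VRS) {
    b <- charToRaw(as.character(value))
    if (length(b) %% 2 == 1)
      b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    b
  } else if (vr == "US") {
    .raw_u16(value)
  } else if (vr == "UL") {
    .raw_u32(value)
  } else if (vr == "FD") {
    writeBin(as.double(value), raw(), size = 8, endian = "little")
  } else {
    b <- as.raw(value)
    if (length(b) %% 2 == 1) b <- c(b, as.raw(0))
    b
  }
}

.encode_element <- function(key, vr, value, explicit = TRUE) {
  bytes <- .encode_value(vr, value)
  head <- c(.raw_u16(.tag_group(key)), .raw_u16(.tag_element(key)))
  if (explicit) {
    if (vr %in% .LONG_VRS) {
      c(head, charToRaw(vr), as.raw(c(0, 0)), .raw_u32(length(bytes)), bytes)
    } else {
      c(head, charToRaw(vr), .raw_u16(length(bytes)), bytes)
    }
  } else {
    c(head, .raw_u32(length(bytes)), bytes)
  }
}

#' Read one classic DICOM file
#'
#' Parses the file meta header and data set of a single-frame little-endian
#' DICOM file (explicit or implicit VR). Files without the `DICM` magic are
#' not DICOM and yield `NULL` rather than an error, so directory scans can
#' skip them.
#'
#' @param path Path to the file.
#' @return A `dicom_entity` (see [dicom_entity()]) or `NULL` if the file is
#'   not parseable DICOM.
#' @export
read_dicom <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 140) return(NULL)
  buf <- readBin(path, "raw", sz)
  if (rawToChar(buf[129:132]) != "DICM") return(NULL)
  pos <- 133L

  parse_one <- function(explicit) {
    group <- .u16(buf, pos); element <- .u16(buf, pos + 2L)
    key <- .tag_key(group, element)
    if (explicit) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% .LONG_VRS) {
        len <- .u32(buf, pos + 8L); off <- 12L
      } else {
        len <- .u16(buf, pos + 6L); off <- 8L
      }
    } else {
      vr <- .dcm_vr_for(key)
      len <- .u32(buf, pos + 4L); off <- 8L
    }
    bytes <- if (len > 0) buf[(pos + off):(pos + off + len - 1L)] else raw(0)
    pos <<- pos + off + as.integer(len)
    list(key = key, vr = vr, value = .decode_value(vr, bytes))
  }

  # file meta group is always explicit VR little endian
  first <- parse_one(TRUE)
  if (first$key != "0002,0000") return(NULL)
  meta_end <- pos + as.integer(first$value)
  ts <- .TS_EXPLICIT_LE
  while (pos < meta_end) {
    el <- parse_one(TRUE)
    if (el$key == "0002,0010") ts <- el$value
  }
  if (!ts %in% c(.TS_EXPLICIT_LE, .TS_IMPLICIT_LE)) return(NULL)
  explicit <- identical(ts, .TS_EXPLICIT_LE)

  tags <- list(); vrs <- character(0)
  while (pos <= sz - 7L) {
    el <- tryCatch(parse_one(explicit), error = function(e) NULL)
    if (is.null(el)) return(NULL)
    tags[[el$key]] <- el$value
    vrs[el$key] <- el$vr
  }

  pixel <- NULL
  if (!is.null(tags[["7fe0,0010"]])) {
    rows <- tags[["0028,0010"]]; cols <- tags[["0028,0011"]]
    bits <- tags[["0028,0100"]]
    if (!is.null(rows) && !is.null(cols) && identical(as.integer(bits), 16L)) {
      vals <- readBin(tags[["7fe0,0010"]], "integer", n = rows * cols,
                      size = 2, endian = "little", signed = FALSE)
      pixel <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
    }
    tags[["7fe0,0010"]] <- NULL
    vrs <- vrs[names(vrs) != "7fe0,0010"]
  }

  dicom_entity(filepath = path, tags = tags, vrs = vrs, pixel = pixel)
}

#' Construct a DICOM entity
#'
#' The in-memory representation of one parsed DICOM file: a named list of
#' data-set attribute values keyed by `"gggg,eeee"` tag, the value
#' representation of each attribute, and the decoded pixel matrix.
#' String-typed attributes (including decimal strings) are held verbatim so
#' a write-then-read round trip is lossless.
#'
#' @param filepath Origin path (informational).
#' @param tags Named list of attribute values.
#' @param vrs Named character vector of value representations.
#' @param pixel Integer matrix `rows x cols`, or `NULL`.
#' @return An object of class `dicom_entity`.
#' @export
dicom_entity <- function(filepath = NA_character_, tags = list(),
                         vrs = character(0), pixel = NULL) {
  structure(list(filepath = filepath, tags = tags, vrs = vrs, pixel = pixel),
            class = "dicom_entity")
}

#' @export
print.dicom_entity <- function(x, ...) {
  cat("<dicom_entity> ", basename(as.character(x$filepath)), "\n", sep = "")
  cat("  patient_id: ", dcm_string(x, "0010,0020"),
      "  study_uid: ", dcm_string(x, "0020,000d"), "\n", sep = "")
  cat("  ", length(x$tags), " attributes",
      if (!is.null(x$pixel))
        sprintf(", pixel %dx%d", nrow(x$pixel), ncol(x$pixel)),
      "\n", sep = "")
  invisible(x)
}

#' Get a DICOM attribute as a string
#'
#' @param entity A `dicom_entity`.
#' @param tag Tag key `"gggg,eeee"`.
#' @param default Value returned when the attribute is absent.
#' @return Character scalar (multi-valued attributes keep the `\\` value
#'   separator) or `default`.
#' @export
dcm_string <- function(entity, tag, default = NA_character_) {
  v <- entity$tags[[tolower(tag)]]
  if (is.null(v)) return(default)
  if (is.raw(v)) return(default)
  as.character(v)[1]
}

#' Get a DICOM attribute as a numeric vector
#'
#' Splits multi-valued decimal/integer strings on the DICOM `\\` separator;
#' binary numeric attributes are returned as stored.
#'
#' @inheritParams dcm_string
#' @return Numeric vector (length 0 if absent).
#' @export
dcm_numeric <- function(entity, tag) {
  v <- entity$tags[[tolower(tag)]]
  if (is.null(v) || is.raw(v)) return(numeric(0))
  if (is.character(v)) {
    if (!nzchar(v)) return(numeric(0))
    as.numeric(strsplit(v, "\\", fixed = TRUE)[[1]])
  } else {
    as.numeric(v)
  }
}

#' Set a DICOM attribute
#'
#' @inheritParams dcm_string
#' @param value New value; its encoding follows `vr`.
#' @param vr Value representation; defaults to the dictionary entry.
#' @return The modified entity.
#' @export
dcm_set <- function(entity, tag, value, vr = NULL) {
  tag <- tolower(tag)
  if (is.null(vr)) vr <- .dcm_vr_for(tag)
  entity$tags[[tag]] <- value
  entity$vrs[tag] <- vr
  entity
}

#' Remove a DICOM attribute
#'
#' Removing an absent attribute is a no-op, so removal is idempotent.
#'
#' @inheritParams dcm_string
#' @return The modified entity.
#' @export
dcm_remove <- function(entity, tag) {
  tag <- tolower(tag)
  entity$tags[[tag]] <- NULL
  entity$vrs <- entity$vrs[names(entity$vrs) != tag]
  entity
}

# Derived header accessors used throughout the toolkit
dcm_patient_id <- function(e) dcm_string(e, "0010,0020")
dcm_study_uid <- function(e) dcm_string(e, "0020,000d")
dcm_series_uid <- function(e) dcm_string(e, "0020,000e")
dcm_instance_number <- function(e) {
  v <- dcm_numeric(e, "0020,0013")
  if (length(v) == 0) NA_integer_ else as.integer(v[1])
}
dcm_pixel_spacing <- function(e) {
  v <- dcm_numeric(e, "0028,0030")
  if (length(v) == 2) v else c(1, 1)
}
dcm_slice_position <- function(e) {
  v <- dcm_numeric(e, "0020,0032")
  if (length(v) == 3) v else c(0, 0, 0)
}
dcm_orientation <- function(e) {
  v <- dcm_numeric(e, "0020,0037")
  if (length(v) == 6) v else c(1, 0, 0, 0, 1, 0)
}

#' Write one classic DICOM file
#'
#' Serializes a `dicom_entity` as explicit VR little endian with a standard
#' 128-byte preamble and file meta group. Attributes are written in
#' ascending tag order; the pixel matrix, if present, becomes a 16-bit
#' unsigned `OW` Pixel Data element. The writer is canonical: writing the
#' same entity twice produces byte-identical files.
#'
#' @param entity A `dicom_entity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(entity, path) {
  keys <- names(entity$tags)
  if (is.null(keys)) keys <- character(0)
  keys <- keys[!startsWith(keys, "0002")]
  ord <- order(vapply(keys, .tag_group, 0L), vapply(keys, .tag_element, 0L))
  keys <- keys[ord]

  body <- lapply(keys, function(k) {
    vr <- entity$vrs[[k]]
    if (is.null(vr) || is.na(vr)) vr <- .dcm_vr_for(k)
    .encode_element(k, vr, entity$tags[[k]])
  })
  if (!is.null(entity$pixel)) {
    vals <- as.integer(t(entity$pixel))
    body <- c(body, list(c(
      .raw_u16(0x7fe0), .raw_u16(0x0010), charToRaw("OW"), as.raw(c(0, 0)),
      .raw_u32(2 * length(vals)), .raw_u16(vals))))
  }
  body <- do.call(c, c(body, list(raw(0))))

  sop_instance <- dcm_string(entity, "0008,0018",
                             default = "1.2.826.0.1.3680043.9.7411.0.0")
  sop_class <- dcm_string(entity, "0008,0016", default = .SOP_MR_IMAGE)
  meta_els <- c(
    .encode_element("0002,0001", "OB", as.raw(c(0, 1))),
    .encode_element("0002,0002", "UI", sop_class),
    .encode_element("0002,0003", "UI", sop_instance),
    .encode_element("0002,0010", "UI", .TS_EXPLICIT_LE),
    .encode_element("0002,0012", "UI", .IMPLEMENTATION_UID))
  meta <- c(.encode_element("0002,0000", "UL", length(meta_els)), meta_els)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

#' SHA-256 digest of an entity's pixel data
#'
#' Used to demonstrate that de-identification never touches image content.
#'
#' @param entity A `dicom_entity`.
#' @return Hex digest string, or `NA` if the entity carries no pixels.
#' @export
pixel_digest <- function(entity) {
  if (is.null(entity$pixel)) return(NA_character_)
  digest::digest(as.integer(entity$pixel), algo = "sha256")
}
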