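# Minimal DICOM (Explicit VR Little Endian, Secondary Capture, single-frame
# 16-bit monochrome) reader/writer. Planar scintigrams are stored one view
# per file; patient id, view and label travel in standard header elements
# (PatientID, SeriesDescription, ImageComments) and may be overridden by a
# CSV manifest when headers are anonymized. Vendor private tags are ignored.

SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
TS_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"

# --- low-level byte helpers -------------------------------------------------

uint16le <- function(v) {
  v <- as.integer(v)
  writeBin(ifelse(v > 32767L, v - 65536L, v), raw(), size = 2,
           endian = "little")
}

uint32le <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")

pad_even <- function(x, pad = as.raw(0x20)) {
  if (length(x) %% 2 == 1) c(x, pad) else x
}

# one explicit-VR element
dcm_element <- function(group, elem, vr, value) {
  if (vr %in% c("UI")) {
    bytes <- pad_even(charToRaw(value), as.raw(0x00))
  } else if (vr %in% c("LO", "CS", "DS", "IS", "SH", "LT", "PN")) {
    bytes <- pad_even(charToRaw(value))
  } else if (vr == "US") {
    bytes <- uint16le(value)
  } else if (vr == "OW") {
    bytes <- value # already raw
  } else stop("unsupported VR: ", vr)
  hdr <- c(uint16le(group), uint16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), uint32le(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65535) stop("element too long for short VR")
    c(hdr, uint16le(length(bytes)), bytes)
  }
}

#' Write a scintigram to a minimal DICOM file
#'
#' Emits a single-frame 16-bit unsigned monochrome Secondary Capture object
#' (Explicit VR Little Endian) that [read_scinti_dicom()] inverts exactly.
#' Patient id, view and label are carried in PatientID, SeriesDescription and
#' ImageComments.
#'
#' @param image A valid [scinti_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scinti_dicom <- function(image, path) {
  validate_scinti_image(image)
  p <- image$pixels
  # DICOM PixelData is row-major: serialize the transpose column-major
  pix_raw <- uint16le(as.integer(t(p)))

  uid <- sprintf("1.2.826.0.1.3680043.9.9999.%.0f.%d.%d",
                 sum(as.double(p)) %% 1e8, nrow(p), ncol(p))

  meta <- c(
    dcm_element(0x0002, 0x0002, "UI", SOP_SECONDARY_CAPTURE),
    dcm_element(0x0002, 0x0003, "UI", uid),
    dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_VR_LE)
  )
  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", SOP_SECONDARY_CAPTURE),
    dcm_element(0x0008, 0x0018, "UI", uid),
    dcm_element(0x0008, 0x0060, "CS", "NM"),
    dcm_element(0x0008, 0x103E, "LO", image$view),
    dcm_element(0x0010, 0x0020, "LO", image$patient_id),
    dcm_element(0x0020, 0x4000, "LT",
                if (is.na(image$label)) "" else image$label),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", nrow(p)),
    dcm_element(0x0028, 0x0011, "US", ncol(p)),
    dcm_element(0x0028, 0x0030, "DS",
                sprintf("%g\\%g", image$pixel_size_mm, image$pixel_size_mm)),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
  )
  # file-meta group length element, written by hand (UL)
  gl <- c(uint16le(0x0002), uint16le(0x0000), charToRaw("UL"),
          uint16le(4L), uint32le(length(meta)))
  out <- c(raw(128), charToRaw("DICM"), gl, meta, ds)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# --- reader -----------------------------------------------------------------

read_u16 <- function(bytes, off) {
  as.integer(bytes[off + 1]) + 256L * as.integer(bytes[off + 2])
}
read_u32 <- function(bytes, off) {
  sum(as.double(bytes[off + 1:4]) * c(1, 256, 65536, 16777216))
}

#' Read a planar scintigram from a DICOM file
#'
#' Parses an Explicit VR Little Endian monochrome single-frame DICOM object.
#' No rescaling is applied: pixel values are the stored 16-bit counts.
#' PatientID, SeriesDescription (view) and ImageComments (label) populate the
#' metadata when present; a manifest row can supply them otherwise.
#'
#' @param path DICOM file path.
#' @param patient_id,view,label Optional sidecar metadata overriding (or
#'   supplying missing) header fields.
#' @return A [scinti_image()].
#' @export
read_scinti_dicom <- function(path, patient_id = NULL, view = NULL,
                              label = NULL) {
  if (!file.exists(path)) stop("cannot read DICOM file: ", path)
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)

  off <- 132L
  n <- length(bytes)
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 8 <= n) {
    group <- read_u16(bytes, off); elem <- read_u16(bytes, off + 2L)
    vr <- rawToChar(bytes[off + 5:6])
    if (vr %in% long_vrs) {
      len <- read_u32(bytes, off + 8L)
      hoff <- 12L
    } else {
      len <- read_u16(bytes, off + 6L)
      hoff <- 8L
    }
    if (off + hoff + len > n) stop("truncated DICOM element at offset ", off)
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, off = off + hoff, len = len)
    off <- off + hoff + as.integer(len)
  }

  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t) || t$len == 0) return(NULL)
    b <- bytes[t$off + seq_len(t$len)]
    trimws(rawToChar(b[b != as.raw(0)]))
  }
  get_u16 <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    read_u16(bytes, t$off)
  }

  rows <- get_u16("0028,0010"); cols <- get_u16("0028,0011")
  bits <- get_u16("0028,0100")
  if (is.null(rows) || is.null(cols)) stop("DICOM lacks Rows/Columns")
  pd <- tags[["7FE0,0010"]]
  if (is.null(pd)) stop("DICOM lacks PixelData")
  if (!is.null(bits) && bits != 16L)
    stop("only 16-bit monochrome supported; BitsAllocated = ", bits)
  vals <- readBin(bytes[pd$off + seq_len(pd$len)], "integer", n = pd$len / 2,
                  size = 2, signed = FALSE, endian = "little")
  if (length(vals) != rows * cols)
    stop("PixelData length does not match Rows x Columns")
  pixels <- t(matrix(vals, nrow = cols, ncol = rows)) # row-major on disk

  spacing <- get_str("0028,0030")
  px_mm <- if (!is.null(spacing))
    as.numeric(strsplit(spacing, "\\\\")[[1]][1]) else 2.26

  nd <- native_dims()
  if (rows * cols == 0 || nd[1] %% rows != 0 || nd[2] %% cols != 0 ||
      nd[1] %/% rows != nd[2] %/% cols)
    stop(sprintf(
      "pixel array is %d x %d; expected (1024, 256) or an integer downscale",
      rows, cols))
  ds <- nd[1] %/% rows

  hdr_label <- label %||% get_str("0020,4000")
  if (!is.null(hdr_label) && !nzchar(hdr_label)) hdr_label <- NULL
  scinti_image(pixels,
               patient_id = patient_id %||% get_str("0010,0020") %||% "unknown",
               view = view %||% get_str("0008,103E") %||% "anterior",
               label = hdr_label %||% NA_character_,
               pixel_size_mm = px_mm,
               provenance = "clinical",
               downscale = ds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- cohort manifest --------------------------------------------------------

#' Read or write a cohort manifest
#'
#' The manifest is a CSV with fixed columns `(file, patient_id, view, label)`
#' carrying sidecar metadata for anonymized DICOM files.
#'
#' @param path CSV path.
#' @return `read_manifest()`: a data.frame with the four columns.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("file", "patient_id", "view", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m[, need]
}

#' @rdname read_manifest
#' @param manifest Data frame with columns `(file, patient_id, view, label)`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("file", "patient_id", "view", "label")],
                   path, row.names = FALSE)
  invisible(path)
}
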