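# Minimal DICOM codec (explicit VR little endian) covering the subset of the
# standard needed for RT Ion Plan spot data: flat elements, nested sequences
# (defined or undefined length), and the string/binary VRs used by the Ion
# Beams module. Files are written with undefined-length sequences, a standard
# 128-byte preamble, and a group-0002 file meta header, so they are readable
# by general-purpose DICOM software.

.UID_TRANSFER_LE_EXPLICIT <- "1.2.840.10008.1.2.1"
.UID_RT_ION_PLAN <- "1.2.840.10008.5.1.4.1.1.481.8"
.UID_IMPL_ROOT <- "1.2.826.0.1.3680043.10.424"

.LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
.UNDEF_LEN <- 4294967295

# ---- byte helpers (all little endian, lengths handled as doubles) ----------

.u16_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))

.u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

.read_u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}

.read_u32 <- function(bytes, pos) {
  sum(as.numeric(bytes[pos:(pos + 3L)]) * c(1, 256, 65536, 16777216))
}

.f32_raw <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")

.read_f32 <- function(bytes, pos, n) {
  readBin(bytes[pos:(pos + 4L * n - 1L)], "numeric", n = n, size = 4L, endian = "little")
}

# ---- element construction --------------------------------------------------

.pad_even <- function(value, pad = as.raw(0L)) {
  if (length(value) %% 2L == 1L) c(value, pad) else value
}

.dcm_string_raw <- function(x, vr) {
  pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  .pad_even(charToRaw(paste(x, collapse = "\\")), pad)
}

# One encoded data element as a raw vector. `value` is already raw.
.dcm_element <- function(group, elem, vr, value) {
  n <- length(value)
  head <- c(.u16_raw(group), .u16_raw(elem), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), .u32_raw(n), value)
  } else {
    .assert(n <= 65534, "value of (%04X,%04X) %s too long for explicit VR (%d bytes > 65534)",
            group, elem, vr, n)
    c(head, .u16_raw(n), value)
  }
}

.el_str <- function(group, elem, vr, x) .dcm_element(group, elem, vr, .dcm_string_raw(x, vr))
.el_ds <- function(group, elem, x) .el_str(group, elem, "DS", sprintf("%.10g", x))
.el_is <- function(group, elem, x) .el_str(group, elem, "IS", sprintf("%d", as.integer(x)))
.el_fl <- function(group, elem, x) .dcm_element(group, elem, "FL", .f32_raw(x))

# Sequence with undefined length; items is a list of raw vectors (item bodies).
.el_sq <- function(group, elem, items) {
  body <- lapply(items, function(it) {
    c(.u16_raw(0xFFFE), .u16_raw(0xE000), .u32_raw(.UNDEF_LEN), it,
      .u16_raw(0xFFFE), .u16_raw(0xE00D), .u32_raw(0))
  })
  value <- c(do.call(c, c(body, list(raw(0)))),
             .u16_raw(0xFFFE), .u16_raw(0xE0DD), .u32_raw(0))
  c(.u16_raw(group), .u16_raw(elem), charToRaw("SQ"), as.raw(c(0L, 0L)),
    .u32_raw(.UNDEF_LEN), value)
}

# ---- parsing ---------------------------------------------------------------

# Drop trailing NUL / space padding bytes, then decode to character.
.strip_pad <- function(value) {
  n <- length(value)
  pad <- c(as.raw(0L), charToRaw(" "))
  while (n > 0L && value[n] %in% pad) n <- n - 1L
  rawToChar(value[seq_len(n)])
}

.vr_decode <- function(vr, value) {
  if (vr %in% c("UI", "SH", "LO", "CS", "DA", "TM", "AE", "PN", "LT", "ST", "UT", "AS", "DT")) {
    .strip_pad(value)
  } else if (vr == "DS") {
    as.numeric(strsplit(.strip_pad(value), "\\", fixed = TRUE)[[1L]])
  } else if (vr == "IS") {
    as.integer(strsplit(.strip_pad(value), "\\", fixed = TRUE)[[1L]])
  } else if (vr == "FL") {
    readBin(value, "numeric", n = length(value) %/% 4L, size = 4L, endian = "little")
  } else if (vr == "FD") {
    readBin(value, "numeric", n = length(value) %/% 8L, size = 8L, endian = "little")
  } else if (vr == "UL") {
    readBin(value, "integer", n = length(value) %/% 4L, size = 4L, endian = "little")
  } else if (vr == "US") {
    readBin(value, "integer", n = length(value) %/% 2L, size = 2L, signed = FALSE, endian = "little")
  } else {
    value
  }
}

.tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

# Recursive-descent parse of a dataset in [pos, end]; stops at `end` or at an
# item-delimitation tag (consumed by the caller). Returns list(elements, pos).
.parse_dataset <- function(bytes, pos, end, path) {
  elements <- list()
  while (pos <= end) {
    .assert(pos + 7L <= end + 1L, "truncated DICOM element header at byte %d (%s)", pos, path)
    group <- .read_u16(bytes, pos)
    elem <- .read_u16(bytes, pos + 2L)
    if (group == 0xFFFE && elem == 0xE00D) { # item delimitation: end of item
      return(list(elements = elements, pos = pos + 8L))
    }
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- .read_u32(bytes, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- .read_u16(bytes, pos + 6L)
      pos <- pos + 8L
    }
    key <- .tag_key(group, elem)
    if (vr == "SQ") {
      parsed <- .parse_sequence(bytes, pos, len, end, path)
      elements[[key]] <- parsed$items
      pos <- parsed$pos
    } else {
      .assert(len != .UNDEF_LEN, "undefined length on non-sequence element %s (%s)", key, path)
      .assert(pos + len - 1L <= end, "truncated value of %s at byte %d (%s)", key, pos, path)
      value <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
      elements[[key]] <- .vr_decode(vr, value)
      pos <- pos + len
    }
  }
  list(elements = elements, pos = pos)
}

.parse_sequence <- function(bytes, pos, len, end, path) {
  items <- list()
  seq_end <- if (len == .UNDEF_LEN) end else pos + len - 1L
  while (pos <= seq_end) {
    group <- .read_u16(bytes, pos)
    elem <- .read_u16(bytes, pos + 2L)
    ilen <- .read_u32(bytes, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && elem == 0xE0DD) break # sequence delimitation
    .assert(group == 0xFFFE && elem == 0xE000, "malformed sequence item at byte %d (%s)", pos - 8L, path)
    if (ilen == .UNDEF_LEN) {
      parsed <- .parse_dataset(bytes, pos, seq_end, path)
    } else {
      parsed <- .parse_dataset(bytes, pos, pos + ilen - 1L, path)
    }
    items[[length(items) + 1L]] <- parsed$elements
    pos <- parsed$pos
    if (len != .UNDEF_LEN && pos > seq_end) break
  }
  list(items = items, pos = pos)
}

# Read a DICOM file; returns list(meta, data) of named element lists.
.read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  .assert(length(bytes) > 132L && rawToChar(bytes[129:132]) == "DICM",
          "not a DICOM file (missing DICM marker): %s", path)
  pos <- 133L
  # group 0002 file meta: first element is the group length (UL)
  g <- .read_u16(bytes, pos)
  .assert(g == 2L, "missing DICOM file meta group: %s", path)
  meta_len <- .read_u32(bytes, pos + 8L)
  meta <- .parse_dataset(bytes, pos, pos + 11L + meta_len, path)$elements
  pos <- pos + 12L + meta_len
  ts <- meta[["0002,0010"]]
  .assert(identical(ts, .UID_TRANSFER_LE_EXPLICIT),
          "unsupported transfer syntax '%s' (only explicit VR little endian): %s", ts, path)
  data <- .parse_dataset(bytes, pos, length(bytes), path)$elements
  list(meta = meta, data = data)
}

# Assemble preamble + file meta + dataset and write to path.
.write_dicom <- function(dataset_raw, sop_instance_uid, path) {
  meta_body <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .el_str(0x0002, 0x0002, "UI", .UID_RT_ION_PLAN),
    .el_str(0x0002, 0x0003, "UI", sop_instance_uid),
    .el_str(0x0002, 0x0010, "UI", .UID_TRANSFER_LE_EXPLICIT),
    .el_str(0x0002, 0x0012, "UI", .UID_IMPL_ROOT)
  )
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", .u32_raw(length(meta_body))), meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(dataset_raw, con)
  invisible(path)
}
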