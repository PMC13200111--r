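# The PQA1 delivery-log format
# ----------------------------
# The vendor's delivery logs ("demand data") are proprietary and undocumented,
# so this package defines its own openly documented, versioned binary format.
# All integers are little-endian; strings are UTF-8 with a uint32 byte-length
# prefix; all record fields are float64.
#
#   bytes 0-3   magic "PQA1"
#   uint32      format version (currently 1)
#   string      room identifier
#   string      session date, ISO-8601 (YYYY-MM-DD)
#   string      plan identifier
#   uint32      number of layers L
#   L blocks:   float64 nominal energy (MeV)
#               uint32  spot count S
#               S records of 7 float64:
#                 layer_index, spot_index, x_spm, y_spm, width_x, width_y,
#                 mu_delivered
#
# Record width is fixed (56 bytes), so the exact file size is computable from
# the header: see pqa_file_size().

.PQA_MAGIC <- "PQA1"
.PQA_VERSION <- 1L
.PQA_RECORD_FIELDS <- c("layer_index", "spot_index", "x_spm", "y_spm",
                        "width_x", "width_y", "mu")

#' Construct a delivery session
#'
#' One delivery log's worth of data: per-spot coordinates as recorded by the
#' spot position monitor (SPM plane, millimetres), measured spot widths, and
#' delivered MU, plus session metadata (treatment room, calendar date,
#' referenced plan).
#'
#' @param room Room identifier (e.g. `"G1"`, `"G2"`).
#' @param date Session date (`Date` or `"YYYY-MM-DD"`); sessions are
#'   day-resolved.
#' @param plan_id Identifier of the delivered plan.
#' @param energies Numeric per-layer nominal energies (MeV), delivery order.
#' @param records `data.frame` with columns `layer_index`, `spot_index`,
#'   `x_spm`, `y_spm`, `width_x`, `width_y`, `mu` in delivery order.
#' @return An object of class `delivery_session`.
#' @export
delivery_session <- function(room, date, plan_id, energies, records) {
  .assert(is.character(room) && length(room) == 1L && nzchar(room), "room must be a non-empty string")
  date <- .as_iso_date(date)
  .assert(length(date) == 1L, "date must be a single calendar date")
  .assert(is.character(plan_id) && length(plan_id) == 1L, "plan_id must be a string")
  .assert(is.data.frame(records) && all(.PQA_RECORD_FIELDS %in% names(records)),
          "records must contain columns %s", paste(.PQA_RECORD_FIELDS, collapse = ", "))
  if (nrow(records) > 0L) {
    .assert(all(vapply(records[.PQA_RECORD_FIELDS], function(v) all(is.finite(v)), TRUE)),
            "all record fields must be finite")
    .assert(!anyDuplicated(records[, c("layer_index", "spot_index")]),
            "(layer_index, spot_index) must be unique within a session")
    .assert(all(records$width_x >= 0) && all(records$width_y >= 0), "spot widths must be >= 0")
    .assert(all(records$mu >= 0), "delivered MU must be >= 0")
  }
  structure(list(room = room, date = date, plan_id = plan_id,
                 energies = as.numeric(energies),
                 records = as.data.frame(records)[, .PQA_RECORD_FIELDS, drop = FALSE]),
            class = "delivery_session")
}

#' @export
print.delivery_session <- function(x, ...) {
  cat(sprintf("<delivery_session> %s @ %s (plan %s): %d layers, %d spot records\n",
              x$room, format(x$date), x$plan_id, length(x$energies), nrow(x$records)))
  invisible(x)
}

.pqa_str_raw <- function(s) {
  b <- charToRaw(enc2utf8(s))
  c(.u32_raw(length(b)), b)
}

#' Exact size in bytes of a PQA1 log file
#'
#' @param session A [delivery_session()].
#' @return File size in bytes as a double.
#' @export
pqa_file_size <- function(session) {
  strings <- c(session$room, format(session$date), session$plan_id)
  n_per_layer <- tabulate(match(session$records$layer_index, seq_along(session$energies)),
                          nbins = length(session$energies))
  4 + 4 + sum(4 + nchar(strings, type = "bytes")) + 4 +
    sum(12 + 56 * n_per_layer)
}

#' Write a delivery session as a PQA1 binary log
#'
#' Writing is deterministic: two writes of the same session produce
#' byte-identical files.
#'
#' @param session A [delivery_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_log()], [pqa_file_size()]
#' @export
write_log <- function(session, path) {
  .assert(inherits(session, "delivery_session"), "session must be a delivery_session")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.PQA_MAGIC), con)
  writeBin(.u32_raw(.PQA_VERSION), con)
  writeBin(do.call(c, lapply(c(session$room, format(session$date), session$plan_id), .pqa_str_raw)), con)
  writeBin(.u32_raw(length(session$energies)), con)
  rec <- session$records
  for (k in seq_along(session$energies)) {
    block <- rec[rec$layer_index == k, , drop = FALSE]
    writeBin(as.numeric(session$energies[k]), con, size = 8L, endian = "little")
    writeBin(.u32_raw(nrow(block)), con)
    if (nrow(block) > 0L) {
      m <- t(as.matrix(block[, .PQA_RECORD_FIELDS]))
      writeBin(as.numeric(m), con, size = 8L, endian = "little")
    }
  }
  invisible(path)
}

.pqa_take <- function(bytes, pos, n, path) {
  if (pos + n - 1 > length(bytes)) {
    .stop_fmt("corrupt PQA1 log: truncated at byte %d (needed %d more bytes): %s",
              length(bytes), pos + n - 1 - length(bytes), path)
  }
  bytes[pos:(pos + n - 1)]
}

#' Read a PQA1 binary delivery log
#'
#' @param path Path to a file written by [write_log()].
#' @return A [delivery_session()].
#' @export
read_log <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  .assert(length(bytes) >= 8L && rawToChar(bytes[1:4]) == .PQA_MAGIC,
          "not a PQA1 delivery log (bad magic): %s", path)
  version <- .read_u32(bytes, 5L)
  .assert(version == .PQA_VERSION, "unsupported PQA1 format version %d: %s", version, path)
  pos <- 9L

  read_str <- function() {
    n <- .read_u32(.pqa_take(bytes, pos, 4L, path), 1L)
    s <- rawToChar(.pqa_take(bytes, pos + 4L, n, path))
    pos <<- pos + 4L + n
    s
  }
  room <- read_str()
  date <- read_str()
  plan_id <- read_str()
  n_layers <- .read_u32(.pqa_take(bytes, pos, 4L, path), 1L)
  pos <- pos + 4L

  energies <- numeric(n_layers)
  blocks <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    hdr <- .pqa_take(bytes, pos, 12L, path)
    energies[k] <- readBin(hdr[1:8], "numeric", size = 8L, endian = "little")
    n_spots <- .read_u32(hdr, 9L)
    pos <- pos + 12L
    nbytes <- 56 * n_spots
    vals <- readBin(.pqa_take(bytes, pos, nbytes, path), "numeric",
                    n = 7L * n_spots, size = 8L, endian = "little")
    pos <- pos + nbytes
    m <- matrix(vals, ncol = 7L, byrow = TRUE)
    colnames(m) <- .PQA_RECORD_FIELDS
    blocks[[k]] <- as.data.frame(m)
  }
  records <- if (n_layers > 0L) do.call(rbind, blocks) else
    as.data.frame(matrix(numeric(0), ncol = 7L, dimnames = list(NULL, .PQA_RECORD_FIELDS)))
  delivery_session(room = room, date = date, plan_id = plan_id,
                   energies = energies, records = records)
}

#' Flat tabular export of a delivery log
#'
#' One row per spot with session metadata attached; the shape used by the
#' `log to-csv` command-line export.
#'
#' @param session A [delivery_session()].
#' @return A `data.frame`.
#' @export
log_to_table <- function(session) {
  rec <- session$records
  data.frame(room = session$room, date = format(session$date),
             plan_id = session$plan_id,
             energy = session$energies[rec$layer_index], rec,
             row.names = NULL)
}
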