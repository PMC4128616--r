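# ABIF (.ab1) container: big-endian header + typed tag directory.
# Only the tags this pipeline needs are written: DATA9-12 (processed
# channels), FWO_1 (channel order), PBAS1 (basecalls), PCON1 (qualities),
# PLOC1 (peak scan indices), SMPL1/MODL1 (metadata). The reader tolerates
# files with more tags and prefers tag number 1, falling back to 2, since
# basecallers differ in which copy they populate.

ABIF_TYPE_BYTE <- 1L    # unsigned 8-bit
ABIF_TYPE_CHAR <- 2L
ABIF_TYPE_SHORT <- 4L   # signed 16-bit
ABIF_TYPE_PSTRING <- 18L

abif_entry <- function(name, number, type, elem_size, n_elem, data) {
  list(name = name, number = as.integer(number), type = as.integer(type),
       elem_size = as.integer(elem_size), n_elem = as.integer(n_elem),
       data = data)  # data: raw vector, already big-endian encoded
}

enc_int32 <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}
enc_int16 <- function(x) {
  writeBin(as.integer(x), raw(), size = 2L, endian = "big")
}
enc_uint8 <- function(x) as.raw(as.integer(x))

#' Write a trace record as a minimal ABIF (.ab1) file
#'
#' Emits a big-endian ABIF container holding the processed channels
#' (`DATA9`-`DATA12`, in `FWO_` order), channel order (`FWO_1`), basecalls
#' (`PBAS1`), qualities (`PCON1`), peak locations (`PLOC1`) and sample /
#' instrument metadata. Files round-trip exactly through [read_abif()] and
#' open in standard trace viewers. Channel intensities and peak positions
#' are stored as 16-bit integers, so they must be whole numbers in
#' `[0, 32767]`; out-of-range records are rejected before any write.
#'
#' @param record A valid [trace_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abif <- function(record, path) {
  validate_trace_record(record)
  for (ch in record$channels) {
    if (any(ch != round(ch)) || any(ch > 32767)) {
      abort("channel intensities must be integers in [0, 32767] for ABIF storage.")
    }
  }
  if (length(record$peak_positions) &&
      max(record$peak_positions) > 32767L) {
    abort("peak positions must fit 16-bit ABIF storage (<= 32767).")
  }
  if (nchar(record$sample) > 255L) {
    abort("sample name longer than 255 characters.")
  }

  order_bases <- strsplit(record$channel_order, "")[[1]]
  entries <- list()
  for (k in seq_len(4L)) {
    entries[[length(entries) + 1L]] <- abif_entry(
      "DATA", 8L + k, ABIF_TYPE_SHORT, 2L,
      length(record$channels[[order_bases[[k]]]]),
      enc_int16(record$channels[[order_bases[[k]]]])
    )
  }
  entries[[length(entries) + 1L]] <- abif_entry(
    "FWO_", 1L, ABIF_TYPE_CHAR, 1L, 4L, charToRaw(record$channel_order))
  entries[[length(entries) + 1L]] <- abif_entry(
    "PBAS", 1L, ABIF_TYPE_CHAR, 1L, nchar(record$basecalls),
    charToRaw(record$basecalls))
  entries[[length(entries) + 1L]] <- abif_entry(
    "PCON", 1L, ABIF_TYPE_BYTE, 1L, length(record$qualities),
    enc_uint8(record$qualities))
  entries[[length(entries) + 1L]] <- abif_entry(
    "PLOC", 1L, ABIF_TYPE_SHORT, 2L, length(record$peak_positions),
    enc_int16(record$peak_positions))
  entries[[length(entries) + 1L]] <- abif_entry(
    "SMPL", 1L, ABIF_TYPE_PSTRING, 1L, nchar(record$sample) + 1L,
    c(as.raw(nchar(record$sample)), charToRaw(record$sample)))
  if (nzchar(record$instrument)) {
    entries[[length(entries) + 1L]] <- abif_entry(
      "MODL", 1L, ABIF_TYPE_CHAR, 1L, nchar(record$instrument),
      charToRaw(record$instrument))
  }

  # lay out: 128-byte header, data blocks (> 4 bytes) in entry order, then
  # the directory; blocks of <= 4 bytes live inline in the offset field
  offset <- 128L
  blocks <- list()
  dir_raw <- raw(0)
  for (e in entries) {
    dsize <- length(e$data)
    if (dsize > 4L) {
      doff_field <- enc_int32(offset)
      blocks[[length(blocks) + 1L]] <- e$data
      offset <- offset + dsize
    } else {
      doff_field <- c(e$data, raw(4L - dsize))
    }
    dir_raw <- c(dir_raw, charToRaw(e$name), enc_int32(e$number),
                 enc_int16(e$type), enc_int16(e$elem_size),
                 enc_int32(e$n_elem), enc_int32(dsize), doff_field,
                 enc_int32(0L))
  }
  dir_offset <- offset

  header <- c(
    charToRaw("ABIF"), enc_int16(101L),
    charToRaw("tdir"), enc_int32(1L), enc_int16(1023L), enc_int16(28L),
    enc_int32(length(entries)), enc_int32(28L * length(entries)),
    enc_int32(dir_offset), enc_int32(0L)
  )
  header <- c(header, raw(128L - length(header)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, do.call(c, c(blocks, list(raw(0)))), dir_raw), con)
  invisible(path)
}

dec_int32 <- function(r, off, n = 1L) {
  readBin(r[(off + 1L):(off + 4L * n)], "integer", n = n, size = 4L,
          endian = "big")
}
dec_int16 <- function(r, off, n = 1L) {
  if (n == 0L) return(integer())
  readBin(r[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
          endian = "big", signed = TRUE)
}
dec_uint8 <- function(r, off, n = 1L) {
  if (n == 0L) return(integer())
  as.integer(r[(off + 1L):(off + n)])
}
dec_chars <- function(r, off, n) {
  if (n == 0L) return("")
  rawToChar(r[(off + 1L):(off + n)])
}

#' Read an ABIF (.ab1) Sanger trace file
#'
#' Parses the big-endian ABIF tag directory and assembles a
#' [trace_record()] from `PBAS` (basecalls), `PCON` (per-base quality),
#' `PLOC` (peak scan indices), `DATA9`-`DATA12` (processed channels) and
#' `FWO_` (channel order). For each tag, number 1 is preferred and number 2
#' used as fallback. Optional tags (`SMPL`, `MODL`) populate the metadata
#' when present.
#'
#' @param path Path to a `.ab1` file.
#' @return A [trace_record()].
#' @section Errors: a file without the `ABIF` magic bytes raises
#'   "not an ABIF file"; a missing mandatory tag raises "incomplete trace";
#'   inconsistent lengths between `PBAS`/`PCON`/`PLOC` or between channels
#'   raise "corrupt trace".
#' @export
read_abif <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  r <- readBin(path, raw(), n = file.size(path))
  if (length(r) < 34L || rawToChar(r[1:4]) != "ABIF") {
    abort("not an ABIF file")
  }
  n_entries <- dec_int32(r, 18L)
  dir_offset <- dec_int32(r, 26L)
  if (n_entries < 0L || dir_offset + 28L * n_entries > length(r)) {
    abort("corrupt trace: directory out of bounds")
  }

  entries <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    off <- dir_offset + 28L * (i - 1L)
    dsize <- dec_int32(r, off + 16L)
    doff <- if (dsize > 4L) dec_int32(r, off + 20L) else off + 20L
    if (doff + dsize > length(r)) abort("corrupt trace: tag data out of bounds")
    entries[[i]] <- list(
      name = dec_chars(r, off, 4L),
      number = dec_int32(r, off + 4L),
      type = dec_int16(r, off + 8L),
      n_elem = dec_int32(r, off + 12L),
      dsize = dsize,
      doff = doff
    )
  }
  key <- vapply(entries, function(e) paste0(e$name, e$number), character(1))

  grab <- function(name, mandatory = TRUE) {
    for (num in c(1L, 2L)) {
      i <- match(paste0(name, num), key)
      if (!is.na(i)) return(entries[[i]])
    }
    if (mandatory) abort(paste0("incomplete trace: missing tag ", name))
    NULL
  }
  decode <- function(e) {
    switch(as.character(e$type),
      "1" = dec_uint8(r, e$doff, e$n_elem),
      "2" = dec_chars(r, e$doff, e$n_elem),
      "4" = dec_int16(r, e$doff, e$n_elem),
      "18" = if (e$n_elem <= 1L) "" else dec_chars(r, e$doff + 1L, e$n_elem - 1L),
      abort(paste0("unsupported ABIF element type ", e$type))
    )
  }

  basecalls <- decode(grab("PBAS"))
  qualities <- decode(grab("PCON"))
  peaks <- decode(grab("PLOC"))
  fwo <- decode(grab("FWO_"))
  if (nchar(basecalls) != length(qualities) ||
      nchar(basecalls) != length(peaks)) {
    abort("corrupt trace: PBAS/PCON/PLOC length mismatch")
  }

  order_bases <- strsplit(fwo, "")[[1]]
  if (length(order_bases) != 4L ||
      !setequal(order_bases, c("A", "C", "G", "T"))) {
    abort("corrupt trace: FWO_ is not a permutation of ACGT")
  }
  channels <- vector("list", 4L)
  names(channels) <- order_bases
  for (k in seq_len(4L)) {
    e <- grab_data_channel(entries, key, k)
    channels[[order_bases[[k]]]] <- decode(e)
  }
  if (length(unique(vapply(channels, length, integer(1)))) != 1L) {
    abort("corrupt trace: channel length mismatch")
  }

  smpl <- grab("SMPL", mandatory = FALSE)
  modl <- grab("MODL", mandatory = FALSE)
  trace_record(
    channels = channels[c("A", "C", "G", "T")],
    peak_positions = peaks,
    basecalls = basecalls,
    qualities = qualities,
    channel_order = fwo,
    sample = if (is.null(smpl)) "" else decode(smpl),
    instrument = if (is.null(modl)) "" else decode(modl)
  )
}

grab_data_channel <- function(entries, key, k) {
  # processed channels are DATA9-12
  i <- match(paste0("DATA", 8L + k), key)
  if (is.na(i)) abort(paste0("incomplete trace: missing tag DATA", 8L + k))
  entries[[i]]
}
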