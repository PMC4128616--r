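#' Construct a chromatogram trace record
#'
#' A `trace_record` holds one processed Sanger chromatogram: the four
#' dye-channel intensity arrays (one per nucleotide), the scan index of each
#' called peak, the called base string and its per-base Phred quality values.
#' All scan coordinates are 0-based; 1-based coordinates appear only in
#' user-facing report tables.
#'
#' @param channels Named list with elements `A`, `C`, `G`, `T`: non-negative
#'   intensity vectors of identical length, indexed by scan number.
#' @param peak_positions Integer vector of 0-based scan indices of the called
#'   peaks; strictly increasing and within the channel arrays.
#' @param basecalls Single IUPAC base string, one character per peak.
#' @param qualities Integer vector of Phred QVs in `[0, 93]`, one per base.
#' @param channel_order 4-character string giving the dye-to-nucleotide order
#'   used in the ABIF `FWO_` field (instruments vary; `"GATC"` is common).
#' @param sample Free-text sample name.
#' @param instrument Free-text instrument description.
#'
#' @return An object of class `trace_record`.
#' @seealso [read_abif()], [write_abif()], [to_read()], [simulate_trace()]
#' @export
#' @examples
#' tr <- trace_record(
#'   channels = list(A = c(0, 9, 0, 0), C = c(0, 0, 0, 8),
#'                   G = c(1, 0, 0, 0), T = c(0, 0, 1, 0)),
#'   peak_positions = c(1L, 3L),
#'   basecalls = "AC",
#'   qualities = c(40L, 38L)
#' )
#' tr
trace_record <- function(channels, peak_positions, basecalls, qualities,
                         channel_order = "GATC", sample = "", instrument = "") {
  rec <- structure(
    list(
      channels = lapply(channels[c("A", "C", "G", "T")], as.numeric),
      channel_order = channel_order,
      peak_positions = as.integer(peak_positions),
      basecalls = as.character(basecalls),
      qualities = as.integer(qualities),
      sample = as.character(sample),
      instrument = as.character(instrument)
    ),
    class = "trace_record"
  )
  validate_trace_record(rec)
  rec
}

validate_trace_record <- function(rec) {
  ch <- rec$channels
  if (!is.list(ch) || !identical(sort(names(ch)), c("A", "C", "G", "T"))) {
    abort("`channels` must be a named list with elements A, C, G, T.")
  }
  lens <- vapply(ch, length, integer(1))
  if (length(unique(lens)) != 1L) {
    abort("all four channel arrays must have identical length.")
  }
  if (any(vapply(ch, function(x) any(!is.finite(x)) || any(x < 0), logical(1)))) {
    abort("channel intensities must be finite and >= 0.")
  }
  nb <- nchar(rec$basecalls)
  if (nb != length(rec$qualities) || nb != length(rec$peak_positions)) {
    abort("basecalls, qualities and peak_positions must have equal length.")
  }
  if (any(rec$qualities < 0L | rec$qualities > 93L)) {
    abort("qualities must be Phred QVs in [0, 93].")
  }
  if (nb > 1L && any(diff(rec$peak_positions) <= 0L)) {
    abort("peak_positions must be strictly increasing.")
  }
  if (nb > 0L &&
      (min(rec$peak_positions) < 0L || max(rec$peak_positions) >= lens[[1]])) {
    abort("peak_positions must lie within the channel arrays.")
  }
  if (nchar(rec$channel_order) != 4L ||
      !identical(sort(strsplit(rec$channel_order, "")[[1]]), c("A", "C", "G", "T"))) {
    abort("`channel_order` must be a permutation of \"ACGT\".")
  }
  invisible(rec)
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf(
    "<trace_record> %s: %d bases, %d scans%s\n",
    if (nzchar(x$sample)) x$sample else "(unnamed)",
    nchar(x$basecalls), length(x$channels$A),
    if (nzchar(x$instrument)) paste0(" [", x$instrument, "]") else ""
  ))
  if (nchar(x$basecalls) > 0L) {
    n <- min(nchar(x$basecalls), 40L)
    cat("  calls: ", substr(x$basecalls, 1L, n),
        if (nchar(x$basecalls) > n) "..." else "", "\n", sep = "")
    cat("  QV: median ", median(x$qualities), ", range [",
        min(x$qualities), ", ", max(x$qualities), "]\n", sep = "")
  }
  invisible(x)
}

#' Construct a called read (sequence plus per-base qualities)
#'
#' @param sequence IUPAC base string.
#' @param qualities Integer Phred QVs in `[0, 93]`, one per base.
#' @param id Free-text identifier.
#'
#' @return An object of class `sanger_read`.
#' @export
#' @examples
#' sanger_read("ACGT", c(40, 40, 12, 40), id = "demo")
sanger_read <- function(sequence, qualities, id = "") {
  rd <- structure(
    list(sequence = as.character(sequence),
         qualities = as.integer(qualities),
         id = as.character(id)),
    class = "sanger_read"
  )
  if (nchar(rd$sequence) != length(rd$qualities)) {
    abort("`sequence` and `qualities` must have equal length.")
  }
  if (any(rd$qualities < 0L | rd$qualities > 93L)) {
    abort("qualities must be Phred QVs in [0, 93].")
  }
  rd
}

#' @export
print.sanger_read <- function(x, ...) {
  cat(sprintf("<sanger_read> %s: %d bases\n",
              if (nzchar(x$id)) x$id else "(unnamed)", nchar(x$sequence)))
  invisible(x)
}

#' @export
length.sanger_read <- function(x) nchar(x$sequence)

#' Extract the called read from a trace record
#'
#' Carries over basecalls (verbatim, including any IUPAC ambiguity codes),
#' per-base qualities and the sample name.
#'
#' @param record A [trace_record()].
#' @return A [sanger_read()].
#' @export
to_read <- function(record) {
  validate_trace_record(record)
  sanger_read(record$basecalls, record$qualities, id = record$sample)
}

#' Per-base tidy view of a trace record
#'
#' @param x A [trace_record()].
#' @param ... Unused.
#' @return A tibble with one row per called base: `base` (1-based index),
#'   `call`, `qv`, `peak_scan` (0-based scan index).
#' @export
tidy.trace_record <- function(x, ...) {
  tibble(
    base = seq_len(nchar(x$basecalls)),
    call = if (nchar(x$basecalls)) strsplit(x$basecalls, "")[[1]] else character(),
    qv = x$qualities,
    peak_scan = x$peak_positions
  )
}
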