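#' Read paired FASTA + QUAL files into reads
#'
#' The FASTA file is read with Biostrings; the phred-scale QUAL file (same
#' record ids, whitespace-separated integer QVs) uses an in-package parser
#' since the numeric QUAL dialect has no reader among the sequence packages.
#' Records must appear with matching ids and lengths in both files.
#'
#' @param fasta,qual Paths to the paired files.
#' @return A list of [sanger_read()] objects, in file order.
#' @section Errors: mismatched ids or per-record length disagreements raise
#'   "paired file mismatch".
#' @export
read_fasta_qual <- function(fasta, qual) {
  seqs <- if (file.size(fasta) == 0) {
    setNames(character(), character())
  } else {
    s <- Biostrings::readBStringSet(fasta)
    setNames(as.character(s), names(s))
  }
  quals <- parse_qual_file(qual)
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1,
                USE.NAMES = FALSE)
  qids <- names(quals)
  if (!identical(ids, qids)) {
    abort("paired file mismatch: record ids differ between FASTA and QUAL")
  }
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    if (nchar(seqs[[i]]) != length(quals[[i]])) {
      abort(paste0("paired file mismatch: length differs for record ", ids[[i]]))
    }
    out[[i]] <- sanger_read(seqs[[i]], quals[[i]], id = ids[[i]])
  }
  out
}

parse_qual_file <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) return(setNames(list(), character()))
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr) && any(nzchar(trimws(lines)))) {
    abort("paired file mismatch: QUAL file has values before any header")
  }
  idx <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "[ \t]"), `[[`, character(1), 1,
                USE.NAMES = FALSE)
  vals <- lapply(split(lines[!hdr], idx[!hdr]), function(body) {
    toks <- unlist(strsplit(paste(body, collapse = " "), "[ \t]+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) && any(is.na(suppressWarnings(as.integer(toks))))) {
      abort("paired file mismatch: non-integer value in QUAL file")
    }
    as.integer(toks)
  })
  out <- rep(list(integer()), length(ids))
  present <- as.integer(names(vals))
  keep <- present > 0L
  out[present[keep]] <- vals[keep]
  setNames(out, ids)
}

#' Write reads as paired FASTA + QUAL files
#'
#' @param reads List of [sanger_read()] objects.
#' @param fasta,qual Output paths.
#' @return `reads`, invisibly. Round-trips exactly through
#'   [read_fasta_qual()].
#' @export
write_fasta_qual <- function(reads, fasta, qual) {
  ids <- vapply(reads, function(r) r$id, character(1))
  if (any(!nzchar(ids))) {
    abort("all reads need non-empty ids for paired FASTA/QUAL output.")
  }
  if (anyDuplicated(ids)) {
    abort("duplicate read ids in paired FASTA/QUAL output.")
  }
  seqs <- Biostrings::BStringSet(setNames(
    vapply(reads, function(r) r$sequence, character(1)), ids))
  Biostrings::writeXStringSet(seqs, fasta, width = 70L)
  qcon <- file(qual, "w")
  on.exit(close(qcon))
  for (r in reads) {
    writeLines(paste0(">", r$id), qcon)
    if (length(r$qualities)) {
      chunks <- split(r$qualities,
                      ceiling(seq_along(r$qualities) / 20L))
      writeLines(vapply(chunks, paste, character(1), collapse = " "), qcon)
    }
  }
  invisible(reads)
}
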