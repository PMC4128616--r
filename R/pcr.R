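#' Define a (possibly degenerate) PCR primer
#'
#' @param name Primer name.
#' @param sequence 5'->3' sequence in IUPAC notation; degenerate codes
#'   (R, Y, S, W, K, M, B, D, H, V, N) are allowed.
#' @return An object of class `pcr_primer`.
#' @export
#' @examples
#' pcr_primer("TAReukREV3", "ACTTTCGTTCTTGATYRA")
pcr_primer <- function(name, sequence) {
  sequence <- toupper(sequence)
  ok <- strsplit(sequence, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!nzchar(sequence) || !all(ok)) {
    abort("primer sequence must be a non-empty IUPAC nucleotide string.")
  }
  structure(list(name = name, sequence = sequence), class = "pcr_primer")
}

#' @export
print.pcr_primer <- function(x, ...) {
  cat(sprintf("<pcr_primer> %s: 5'-%s-3' (%d expansions)\n",
              x$name, x$sequence,
              prod(nchar(Biostrings::IUPAC_CODE_MAP[
                strsplit(x$sequence, "")[[1]]]))))
  invisible(x)
}

#' Built-in V4 18S rDNA primer pair
#'
#' The eukaryote-universal pair amplifying the hypervariable V4 region of
#' the 18S rRNA gene: TAReuk454FWD1 (CCAGCASCYGCGGTAATTCC) and TAReukREV3
#' (ACTTTCGTTCTTGATYRA).
#'
#' @return Named list with elements `fwd` and `rev` ([pcr_primer()]s).
#' @export
v4_primers <- function() {
  list(fwd = pcr_primer("TAReuk454FWD1", "CCAGCASCYGCGGTAATTCC"),
       rev = pcr_primer("TAReukREV3", "ACTTTCGTTCTTGATYRA"))
}

#' Expand a degenerate IUPAC sequence into all concrete sequences
#'
#' @param sequence IUPAC nucleotide string.
#' @return Character vector of all ACGT expansions, in lexicographic order;
#'   its length is the product of the per-position degeneracies.
#' @export
#' @examples
#' expand_degenerate("ACRT")  # "ACAT" "ACGT"
expand_degenerate <- function(sequence) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  sets <- Biostrings::IUPAC_CODE_MAP[chars]
  if (length(chars) == 0L || any(is.na(names(sets)) | is.na(sets))) {
    abort("`sequence` must be a non-empty IUPAC nucleotide string.")
  }
  grids <- lapply(sets, function(s) strsplit(s, "")[[1]])
  out <- do.call(paste0, rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
  sort(out)
}

#' Find degenerate-primer binding sites on a template
#'
#' A site is any position where some concrete expansion of the primer
#' matches with at most `max_mismatch` substitutions; degenerate primer
#' positions match any base of their code set at zero cost. Both strands
#' are searched: a minus-strand site is a match of the primer's reverse
#' complement, reported by the 0-based plus-strand start of its footprint.
#'
#' @param template Template sequence (character or `DNAString`).
#' @param primer A [pcr_primer()].
#' @param max_mismatch Maximum substitutions (default 0).
#' @return A tibble with columns `position` (0-based footprint start on the
#'   plus strand) and `strand` (`"+"`/`"-"`), sorted by position.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 0) {
  stopifnot(inherits(primer, "pcr_primer"), max_mismatch >= 0)
  subject <- Biostrings::DNAString(as.character(template))
  pat <- Biostrings::DNAString(primer$sequence)
  if (length(pat) > length(subject)) {
    return(tibble(position = integer(), strand = character()))
  }
  hit_starts <- function(p) {
    m <- Biostrings::matchPattern(p, subject, max.mismatch = max_mismatch,
                                  fixed = "subject")
    Biostrings::start(m) - 1L
  }
  plus <- hit_starts(pat)
  minus <- hit_starts(Biostrings::reverseComplement(pat))
  out <- tibble(
    position = c(plus, minus),
    strand = c(rep("+", length(plus)), rep("-", length(minus)))
  )
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Predict PCR products for a primer pair on a template
#'
#' Enumerates all primer-inclusive products in both orientations: a
#' forward-primer site on one strand paired with a downstream
#' reverse-primer site on the other, with non-overlapping footprints.
#' Product sizes are primer-inclusive, matching gel sizing of the full
#' amplicon. No thermodynamic model is applied; matching is by substitution
#' count only (default 0 mismatches, reflecting clean single-band
#' amplification).
#'
#' @param template Template sequence (character or `DNAString`), plus
#'   strand.
#' @param fwd,rev [pcr_primer()]s (default: the V4 18S pair).
#' @param max_mismatch Maximum substitutions per primer site (default 0).
#' @param id Template id carried into the output (default `"template"`).
#' @return A tibble of class `amplicon_table`: `template_id`, `start`,
#'   `end` (0-based half-open, plus strand, primer-inclusive), `length`,
#'   `strand` (strand carrying the forward primer) and `sequence` (the
#'   product, written 5'->3' from the forward primer), sorted by `start`
#'   then `length`.
#' @export
#' @examples
#' tpl <- paste0("CCAGCAGCCGCGGTAATTCC", strrep("A", 10),
#'               "TYRATCAAGAACGAAAGT")  # fwd + spacer + revcomp(rev)
#' amplify(expand_degenerate(tpl)[1])
amplify <- function(template, fwd = v4_primers()$fwd, rev = v4_primers()$rev,
                    max_mismatch = 0, id = "template") {
  template <- as.character(template)
  n <- nchar(template)
  fwd_sites <- find_primer_sites(template, fwd, max_mismatch)
  rev_sites <- find_primer_sites(template, rev, max_mismatch)
  lf <- nchar(fwd$sequence)
  lr <- nchar(rev$sequence)

  pair_up <- function(f_pos, r_pos, strand) {
    # forward footprint [f, f+lf) must precede reverse footprint [r, r+lr)
    out <- list()
    for (f in f_pos) {
      for (r in r_pos) {
        if (f + lf <= r) {
          out[[length(out) + 1L]] <- c(start = f, end = r + lr)
        }
      }
    }
    if (!length(out)) {
      return(tibble(start = integer(), end = integer(), strand = character()))
    }
    m <- do.call(rbind, out)
    tibble(start = as.integer(m[, "start"]), end = as.integer(m[, "end"]),
           strand = strand)
  }

  # orientation A: fwd on plus strand, rev on minus
  a <- pair_up(fwd_sites$position[fwd_sites$strand == "+"],
               rev_sites$position[rev_sites$strand == "-"], "+")
  # orientation B: fwd on minus strand, rev on plus (product read 3'->5'
  # on the plus strand); plus-strand footprint of the product is
  # [rev_site, fwd_site_end)
  b_f <- fwd_sites$position[fwd_sites$strand == "-"]
  b_r <- rev_sites$position[rev_sites$strand == "+"]
  b <- list()
  for (f in b_f) {
    for (r in b_r) {
      if (r + lr <= f) {
        b[[length(b) + 1L]] <- c(start = r, end = f + lf)
      }
    }
  }
  b <- if (length(b)) {
    m <- do.call(rbind, b)
    tibble(start = as.integer(m[, "start"]), end = as.integer(m[, "end"]),
           strand = "-")
  } else {
    tibble(start = integer(), end = integer(), strand = character())
  }

  out <- dplyr::bind_rows(a, b)
  out <- dplyr::distinct(out)
  out <- dplyr::mutate(out,
    template_id = id,
    length = .data$end - .data$start,
    sequence = vapply(seq_len(nrow(out)), function(i) {
      s <- substr(template, out$start[[i]] + 1L, out$end[[i]])
      if (out$strand[[i]] == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      } else {
        s
      }
    }, character(1))
  )
  out <- dplyr::arrange(
    dplyr::select(out, "template_id", "start", "end", "length", "strand",
                  "sequence"),
    .data$start, .data$length)
  structure(out, class = c("amplicon_table", class(out)))
}

#' In-silico PCR over a FASTA file of templates
#'
#' @param fasta Path to a FASTA file of template sequences.
#' @inheritParams amplify
#' @return Row-bound [amplify()] results, one block per template.
#' @export
amplify_fasta <- function(fasta, fwd = v4_primers()$fwd,
                          rev = v4_primers()$rev, max_mismatch = 0) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1,
                USE.NAMES = FALSE)
  out <- purrr::map2(as.character(seqs), ids, function(s, id) {
    amplify(s, fwd, rev, max_mismatch, id = id)
  })
  res <- dplyr::bind_rows(out)
  structure(res, class = c("amplicon_table", class(res)))
}
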