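#' Trimming parameters
#'
#' The two-rule quality trim: (a) the read starts at the first position, at
#' or after an initial skip of `head_skip` bases, where `window` consecutive
#' calls all exceed `qv_threshold`; (b) scanning resumes `tail_scan_start`
#' bases past that start, and the read ends just before the first `window`
#' consecutive calls that contain more than `max_bad_in_window` calls below
#' `qv_threshold`. All comparisons are strict: a call of exactly
#' `qv_threshold` neither qualifies a 5' window nor counts against a 3' one.
#'
#' @param qv_threshold Phred QV threshold (default 20).
#' @param head_skip Bases skipped before the 5' scan begins (default 25; the
#'   operator latitude in routine use is 25-35).
#' @param window Window length in bases (default 20).
#' @param tail_scan_start Offset, in bases past the 5' trim point, at which
#'   the 3' scan begins (default 350). This is also the guaranteed minimum
#'   retained length whenever the read reaches that far, which keeps even
#'   noisy mixed-template reads long enough for a reliable purity call.
#' @param max_bad_in_window Sub-threshold calls tolerated per 3' window
#'   (default 1).
#'
#' @return An object of class `trim_params`.
#' @export
trim_params <- function(qv_threshold = 20, head_skip = 25, window = 20,
                        tail_scan_start = 350, max_bad_in_window = 1) {
  p <- structure(
    list(qv_threshold = as.numeric(qv_threshold),
         head_skip = as.integer(head_skip),
         window = as.integer(window),
         tail_scan_start = as.integer(tail_scan_start),
         max_bad_in_window = as.integer(max_bad_in_window)),
    class = "trim_params"
  )
  if (p$window < 1L || p$head_skip < 0L || p$tail_scan_start < 0L ||
      p$max_bad_in_window < 0L) {
    abort("need window >= 1, head_skip >= 0, tail_scan_start >= 0, max_bad_in_window >= 0.")
  }
  p
}

#' Locate the 5' trim point
#'
#' Returns the smallest 0-based index `s >= head_skip` such that every QV in
#' the window starting at `s` is strictly above `qv_threshold`. Windows are
#' `window` bases long; a shorter window that runs exactly to the read end is
#' also accepted (it must contain at least one base), so a short clean read
#' is trimmed rather than discarded.
#'
#' @param qualities Integer/numeric vector of per-base QVs.
#' @param params A [trim_params()].
#' @return 0-based start index, or `NA_integer_` when no qualifying window
#'   exists (the read fails head trimming).
#' @export
find_head_trim <- function(qualities, params = trim_params()) {
  n <- length(qualities)
  w <- params$window
  skip <- params$head_skip
  if (n == 0L || skip >= n) return(NA_integer_)
  good <- qualities > params$qv_threshold
  # full windows: s (0-based) in [skip, n - w]
  if (n - w >= skip) {
    cs <- cumsum(c(0L, good))
    starts <- skip:(n - w)                        # 0-based
    hits <- starts[cs[starts + 1L + w] - cs[starts + 1L] == w]
    if (length(hits)) return(hits[[1L]])
  }
  # truncated windows flush with the read end
  trunc_from <- max(skip, n - w + 1L)
  if (trunc_from <= n - 1L) {
    for (s in trunc_from:(n - 1L)) {
      if (all(good[(s + 1L):n])) return(as.integer(s))
    }
  }
  NA_integer_
}

#' Locate the 3' trim point
#'
#' Scanning offsets `s >= tail_scan_start` counted from the 5' trim point
#' `start`, returns the 0-based exclusive end `start + s` for the smallest
#' `s` whose full window of `window` calls contains strictly more than
#' `max_bad_in_window` calls strictly below `qv_threshold`. If no such
#' window exists — including when the read is too short for the scan to
#' begin — the read is kept to its end.
#'
#' @param qualities Integer/numeric vector of per-base QVs (the whole read).
#' @param start 0-based 5' trim point, as returned by [find_head_trim()].
#' @param params A [trim_params()].
#' @return 0-based exclusive end index of the retained interval.
#' @export
find_tail_trim <- function(qualities, start, params = trim_params()) {
  n <- length(qualities)
  w <- params$window
  first <- start + params$tail_scan_start        # 0-based window start
  if (first + w > n) return(as.integer(n))
  bad <- qualities < params$qv_threshold
  cs <- cumsum(c(0L, bad))
  starts <- first:(n - w)                        # 0-based
  counts <- cs[starts + 1L + w] - cs[starts + 1L]
  hits <- starts[counts > params$max_bad_in_window]
  if (length(hits)) as.integer(hits[[1L]]) else as.integer(n)
}

#' Trim a read by the two-rule quality trim
#'
#' Composes [find_head_trim()] and [find_tail_trim()] and applies the
#' retained interval to both sequence and qualities.
#'
#' @param read A [sanger_read()].
#' @param params A [trim_params()].
#'
#' @return An object of class `trim_result`: `status` (`"trimmed"` or
#'   `"failed_head"`), and for trimmed reads `start`/`end` (0-based
#'   half-open retained interval on the input read) and `read`, the trimmed
#'   [sanger_read()]. Reads that fail head trimming carry no interval; they
#'   are reported downstream as indeterminate, never silently classified.
#' @export
#' @examples
#' rd <- sanger_read(strrep("A", 600), rep(40L, 600))
#' trim_read(rd)  # retains [25, 600)
trim_read <- function(read, params = trim_params()) {
  stopifnot(inherits(read, "sanger_read"))
  s <- find_head_trim(read$qualities, params)
  if (is.na(s)) {
    return(structure(list(status = "failed_head", id = read$id,
                          start = NA_integer_, end = NA_integer_,
                          read = NULL, params = params),
                     class = "trim_result"))
  }
  e <- find_tail_trim(read$qualities, s, params)
  trimmed <- sanger_read(substr(read$sequence, s + 1L, e),
                         read$qualities[(s + 1L):e], id = read$id)
  structure(list(status = "trimmed", id = read$id,
                 start = as.integer(s), end = as.integer(e),
                 read = trimmed, params = params),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  if (x$status == "trimmed") {
    cat(sprintf("<trim_result> %s: trimmed to [%d, %d), %d bases retained\n",
                if (nzchar(x$id)) x$id else "(unnamed)",
                x$start, x$end, x$end - x$start))
  } else {
    cat(sprintf("<trim_result> %s: failed_head (no clean 5' window)\n",
                if (nzchar(x$id)) x$id else "(unnamed)"))
  }
  invisible(x)
}

#' One-row tidy summary of a trim result
#'
#' Report coordinates are 1-based inclusive, as in user-facing tables;
#' internal indices are 0-based half-open.
#'
#' @param x A `trim_result`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `status`, `start`, `end`,
#'   `retained_length`.
#' @export
tidy.trim_result <- function(x, ...) {
  if (x$status == "trimmed") {
    tibble(id = x$id, status = x$status,
           start = x$start + 1L, end = x$end,
           retained_length = x$end - x$start)
  } else {
    tibble(id = x$id, status = x$status,
           start = NA_integer_, end = NA_integer_,
           retained_length = NA_integer_)
  }
}
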