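#' Purity-screen parameters
#'
#' A trimmed read is classified `unialgal` when the fraction of its calls
#' below `qv_threshold` is strictly smaller than `max_bad_fraction`
#' (default 1%); otherwise `mixed`. Reads that failed head trimming are
#' `indeterminate`.
#'
#' @param qv_threshold Phred QV threshold (default 20; shared with
#'   [trim_params()]).
#' @param max_bad_fraction Strict upper bound on the sub-threshold fraction
#'   (default 0.01), `0 < max_bad_fraction < 1`.
#'
#' @return An object of class `purity_params`.
#' @export
purity_params <- function(qv_threshold = 20, max_bad_fraction = 0.01) {
  p <- structure(
    list(qv_threshold = as.numeric(qv_threshold),
         max_bad_fraction = as.numeric(max_bad_fraction)),
    class = "purity_params"
  )
  if (!(p$max_bad_fraction > 0 && p$max_bad_fraction < 1)) {
    abort("`max_bad_fraction` must lie strictly between 0 and 1.")
  }
  p
}

#' Sub-threshold quality fraction
#'
#' Counts calls strictly below the threshold; a call of exactly the
#' threshold is not counted.
#'
#' @param qualities Non-empty vector of per-base QVs.
#' @param qv_threshold Phred QV threshold (default 20).
#' @return A list with `count` and `fraction` (= count / length).
#' @export
#' @examples
#' subqv_fraction(c(rep(30, 99), 10))  # 1 call, fraction 0.01
subqv_fraction <- function(qualities, qv_threshold = 20) {
  if (length(qualities) == 0L) {
    abort("`qualities` must be non-empty.")
  }
  count <- sum(qualities < qv_threshold)
  list(count = as.integer(count), fraction = count / length(qualities))
}

#' Classify a trimmed read as unialgal or mixed
#'
#' @param trim A `trim_result` from [trim_read()].
#' @param params A [purity_params()].
#'
#' @return An object of class `purity_result` with fields `id`, `status`,
#'   `start`, `end`, `retained_length`, `n_subthreshold`,
#'   `fraction_subthreshold`, `percent_subthreshold` (rounded to 2 decimals
#'   for reporting) and `classification` (`unialgal`, `mixed` or
#'   `indeterminate`).
#' @export
classify_purity <- function(trim, params = purity_params()) {
  stopifnot(inherits(trim, "trim_result"), inherits(params, "purity_params"))
  if (trim$status != "trimmed") {
    res <- list(id = trim$id, status = trim$status,
                start = NA_integer_, end = NA_integer_,
                retained_length = NA_integer_,
                n_subthreshold = NA_integer_,
                fraction_subthreshold = NA_real_,
                percent_subthreshold = NA_real_,
                classification = "indeterminate")
    return(structure(res, class = "purity_result"))
  }
  sq <- subqv_fraction(trim$read$qualities, params$qv_threshold)
  cls <- if (sq$fraction < params$max_bad_fraction) "unialgal" else "mixed"
  structure(
    list(id = trim$id, status = trim$status,
         start = trim$start, end = trim$end,
         retained_length = trim$end - trim$start,
         n_subthreshold = sq$count,
         fraction_subthreshold = sq$fraction,
         percent_subthreshold = round(100 * sq$fraction, 2),
         classification = cls),
    class = "purity_result"
  )
}

#' @export
print.purity_result <- function(x, ...) {
  if (x$classification == "indeterminate") {
    cat(sprintf("<purity_result> %s: indeterminate (%s)\n",
                if (nzchar(x$id)) x$id else "(unnamed)", x$status))
  } else {
    cat(sprintf("<purity_result> %s: %s (%.2f%% of %d bases < QV20)\n",
                if (nzchar(x$id)) x$id else "(unnamed)",
                x$classification, x$percent_subthreshold, x$retained_length))
  }
  invisible(x)
}

#' @describeIn classify_purity One-row tidy summary (1-based report
#'   coordinates).
#' @param x A `purity_result`.
#' @param ... Unused.
#' @export
tidy.purity_result <- function(x, ...) {
  tibble(
    id = x$id, status = x$status,
    start = if (is.na(x$start)) NA_integer_ else x$start + 1L,
    end = x$end,
    retained_length = x$retained_length,
    n_subthreshold = x$n_subthreshold,
    percent_subthreshold = x$percent_subthreshold,
    classification = x$classification
  )
}

#' Screen a batch of traces or reads for culture purity
#'
#' Runs trim + classify over a set of inputs and returns one report row per
#' input. File-level failures (unreadable, corrupt, not ABIF) become
#' `indeterminate` rows carrying the error message in `reason`; they never
#' abort the batch. Row order follows input order.
#'
#' @param inputs Either a character vector of `.ab1` paths, or a list of
#'   [sanger_read()] / [trace_record()] objects (mixtures allowed).
#' @param trim A [trim_params()].
#' @param purity A [purity_params()].
#'
#' @return A tibble of class `screen_report` with columns `id`, `status`,
#'   `start`, `end`, `retained_length`, `n_subthreshold`,
#'   `percent_subthreshold`, `classification`, `reason` (start/end 1-based
#'   inclusive).
#' @export
#' @examples
#' cfg <- sim_config(templates = random_template(600, seed = 7), seed = 7)
#' tr <- simulate_trace(cfg)$record
#' screen_batch(list(tr))
screen_batch <- function(inputs, trim = trim_params(),
                         purity = purity_params()) {
  empty <- tibble(
    id = character(), status = character(),
    start = integer(), end = integer(), retained_length = integer(),
    n_subthreshold = integer(), percent_subthreshold = double(),
    classification = character(), reason = character()
  )
  if (length(inputs) == 0L) {
    return(structure(empty, class = c("screen_report", class(empty))))
  }
  if (is.character(inputs)) inputs <- as.list(inputs)
  rows <- purrr::imap(inputs, function(input, i) {
    res <- tryCatch({
      rd <- resolve_read_input(input)
      if (!nzchar(rd$id)) {
        rd$id <- if (is.character(input)) basename(input) else paste0("read", i)
      }
      pr <- classify_purity(trim_read(rd, trim), purity)
      dplyr::mutate(tidy(pr), reason = NA_character_)
    }, error = function(e) {
      id <- if (is.character(input)) basename(input) else paste0("read", i)
      tibble(id = id, status = "error",
             start = NA_integer_, end = NA_integer_,
             retained_length = NA_integer_, n_subthreshold = NA_integer_,
             percent_subthreshold = NA_real_,
             classification = "indeterminate",
             reason = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("screen_report", class(out)))
}

resolve_read_input <- function(input) {
  if (inherits(input, "sanger_read")) return(input)
  if (inherits(input, "trace_record")) return(to_read(input))
  if (is.character(input) && length(input) == 1L) {
    return(to_read(read_abif(input)))
  }
  abort("inputs must be .ab1 paths, sanger_read or trace_record objects.")
}

#' Write a screen report as TSV
#'
#' @param report A `screen_report` tibble from [screen_batch()].
#' @param path Output file path.
#' @return `report`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(report)
}

#' Summary counts for a screen report
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return One-row tibble: number screened, unialgal, mixed, indeterminate,
#'   and the median sub-QV20 percentage among classified reads.
#' @export
glance.screen_report <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_unialgal = sum(x$classification == "unialgal"),
    n_mixed = sum(x$classification == "mixed"),
    n_indeterminate = sum(x$classification == "indeterminate"),
    median_percent_subqv = median(x$percent_subthreshold, na.rm = TRUE)
  )
}
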