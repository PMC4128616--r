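#' Plot a chromatogram section
#'
#' Draws the four channel intensity profiles with called bases marked at
#' their peak scans and coloured by whether the call clears QV 20 — the
#' visual contrast between a clean single-template trace and the stacked
#' near-equal peaks of a mixed culture.
#'
#' @param object A [trace_record()].
#' @param from,to 1-based base-call range to display (default: first 60
#'   calls).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trace_record <- function(object, from = 1, to = 60, ...) {
  to <- min(to, nchar(object$basecalls))
  stopifnot(from >= 1, from <= to)
  scan_lo <- object$peak_positions[[from]] - 6L
  scan_hi <- object$peak_positions[[to]] + 6L
  scans <- max(0L, scan_lo):min(length(object$channels$A) - 1L, scan_hi)
  prof <- dplyr::bind_rows(lapply(c("A", "C", "G", "T"), function(b) {
    tibble(scan = scans, channel = b,
           intensity = object$channels[[b]][scans + 1L])
  }))
  calls <- tidy(object)[from:to, ]
  calls$quality <- ifelse(calls$qv >= 20, "QV ≥ 20", "QV < 20")
  ggplot2::ggplot(prof, ggplot2::aes(.data$scan, .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_text(
      data = calls,
      ggplot2::aes(x = .data$peak_scan, y = -0.04 * max(prof$intensity),
                   label = .data$call, alpha = .data$quality),
      colour = "black", size = 2.6, inherit.aes = FALSE) +
    ggplot2::scale_alpha_manual(values = c("QV ≥ 20" = 1,
                                           "QV < 20" = 0.35),
                                name = NULL) +
    ggplot2::scale_colour_manual(values = c(A = "#33a02c", C = "#1f78b4",
                                            G = "#111111", T = "#e31a1c")) +
    ggplot2::labs(x = "scan", y = "intensity",
                  title = object$sample) +
    ggplot2::theme_minimal()
}

#' Plot a purity screen report
#'
#' One bar per read showing the percentage of retained calls below QV 20,
#' with the 1% classification cutoff marked.
#'
#' @param object A `screen_report` from [screen_batch()].
#' @param cutoff_percent Classification cutoff to draw (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, cutoff_percent = 1, ...) {
  dat <- object[!is.na(object$percent_subthreshold), ]
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$id, .data$percent_subthreshold),
    y = .data$percent_subthreshold, fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cutoff_percent, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(unialgal = "#33a02c",
                                          mixed = "#e31a1c",
                                          indeterminate = "grey60")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of retained calls < QV20") +
    ggplot2::theme_minimal()
}
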