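#' Phred conversions between error probability and quality value
#'
#' The Phred quality value of a base call with error probability `pe` is
#' `QV = -10 * log10(pe)`; `qv_to_pe()` is its inverse, `pe = 10^(-qv/10)`.
#' `pe_to_qv()` returns the exact (unrounded) value; storage as integer QVs
#' happens in [assign_qualities()].
#'
#' @param pe Error probability, `0 < pe <= 1`. Vectorised.
#' @param qv Quality value in Phred units, `qv >= 0`. Vectorised.
#'
#' @return `pe_to_qv()`: quality values (double); `qv_to_pe()`: error
#'   probabilities.
#' @export
#' @examples
#' pe_to_qv(0.01)  # 20
#' qv_to_pe(30)    # 0.001
pe_to_qv <- function(pe) {
  if (length(pe) && (any(!is.finite(pe)) || any(pe <= 0) || any(pe > 1))) {
    abort("`pe` must satisfy 0 < pe <= 1.")
  }
  -10 * log10(pe)
}

#' @rdname pe_to_qv
#' @export
qv_to_pe <- function(qv) {
  if (length(qv) && (any(!is.finite(qv)) || any(qv < 0))) {
    abort("`qv` must be >= 0.")
  }
  10^(-qv / 10)
}

#' Parameters of the trace-feature quality model
#'
#' The simulator (and any re-scoring of a trace) derives each base's error
#' probability from three chromatogram features: the uncalled/called peak
#' ratio (the tell-tale of a mixed template), the loss of peak resolution,
#' and the deviation of peak spacing from its running mean. The error
#' probability is a weighted sum of the three, clipped to
#' `[pe_floor, pe_ceiling]`:
#'
#' `pe = clip(w_ratio * sec/pri + w_res * (1 - res) + w_space * dev,
#'            pe_floor, pe_ceiling)`
#'
#' Defaults put half the weight on the peak ratio so that a 50:50 mixed base
#' (ratio 1) gets `pe >= 0.5`, i.e. QV <= 3 — an uncallable position — while
#' a clean base sits at the floor (QV 40).
#'
#' @param w_ratio Weight on the uncalled/called peak-height ratio.
#' @param w_res Weight on `1 - resolution`.
#' @param w_space Weight on the normalised peak-spacing deviation.
#' @param pe_floor,pe_ceiling Clip bounds on the error probability,
#'   `0 < pe_floor < pe_ceiling <= 1`.
#'
#' @return An object of class `quality_model_params`.
#' @export
quality_model_params <- function(w_ratio = 0.5, w_res = 0.3, w_space = 0.2,
                                 pe_floor = 1e-4, pe_ceiling = 0.75) {
  p <- structure(
    list(w_ratio = w_ratio, w_res = w_res, w_space = w_space,
         pe_floor = pe_floor, pe_ceiling = pe_ceiling),
    class = "quality_model_params"
  )
  if (any(c(p$w_ratio, p$w_res, p$w_space) < 0) ||
      (p$w_ratio + p$w_res + p$w_space) <= 0) {
    abort("weights must be >= 0 with a positive sum.")
  }
  if (!(p$pe_floor > 0 && p$pe_floor < p$pe_ceiling && p$pe_ceiling <= 1)) {
    abort("need 0 < pe_floor < pe_ceiling <= 1.")
  }
  p
}

#' Assign per-base quality values from measured peak features
#'
#' @param features A data frame as returned by [measure_features()], with
#'   columns `primary`, `secondary`, `resolution` (in `[0,1]`) and
#'   `spacing_dev` (>= 0), one row per base.
#' @param params A [quality_model_params()].
#'
#' @return Integer vector of Phred QVs (rounded, capped at 93), one per base.
#'   A base whose primary peak height is 0 is fully ambiguous and receives
#'   `pe_ceiling`.
#' @export
assign_qualities <- function(features, params = quality_model_params()) {
  stopifnot(inherits(params, "quality_model_params"))
  features <- as.data.frame(features)
  need <- c("primary", "secondary", "resolution", "spacing_dev")
  if (!all(need %in% names(features))) {
    abort(paste0("`features` must have columns ",
                 paste(need, collapse = ", "), "."))
  }
  n <- nrow(features)
  if (n == 0L) return(integer())
  ratio <- ifelse(features$primary > 0,
                  features$secondary / features$primary, NA_real_)
  pe <- params$w_ratio * ratio +
    params$w_res * (1 - features$resolution) +
    params$w_space * features$spacing_dev
  pe <- pmin(pmax(pe, params$pe_floor), params$pe_ceiling)
  pe[features$primary <= 0] <- params$pe_ceiling
  qv <- as.integer(round(pe_to_qv(pe)))
  pmin(qv, 93L)
}
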