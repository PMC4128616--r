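# Chromatogram simulator. Each template contributes, at every consensus
# position, a Gaussian peak on the channel of its own base, with height
# proportional to its mixing weight; mixed templates therefore produce
# near-equal stacked peaks exactly at their divergent positions, which is
# the signal the purity screen keys on. Peak width grows towards the 3'
# end (resolution loss) and a contaminant peak ramp models the universal
# low-quality 5' start.

SIM_AMPLITUDE <- 1000

#' Simulation configuration
#'
#' @param templates Character vector of template sequences (e.g. V4
#'   amplicons from [amplify()], or [random_template()] output).
#' @param proportions Non-negative mixing weights, one per template,
#'   summing to 1 (default: equal).
#' @param peak_spacing_mean Scans per base (default 12).
#' @param peak_sigma Gaussian peak width at the 5' end, in scans
#'   (default 1.2).
#' @param noise_sd Additive intensity noise, in intensity units on a peak
#'   amplitude of 1000 (default 0.5).
#' @param resolution_decay Reciprocal base-scale of peak broadening: peak
#'   width is `peak_sigma * (1 + (resolution_decay * i)^3)` at base `i`, a
#'   slow-onset broadening that becomes severe around
#'   `1/resolution_decay` bases (default 0.0019, i.e. ~525 bases).
#' @param head_ramp_len Number of initial bases carrying the 5'
#'   low-quality ramp (default 25).
#' @param indel_offsets Integer per-template base offsets modelling
#'   interspecific length polymorphism: template `t` is read starting
#'   `indel_offsets[t]` bases in, so a one-base offset scrambles every
#'   downstream consensus position (default all 0).
#' @param seed Integer seed; the trace is fully deterministic given the
#'   config.
#' @param id Optional sample id (default derived from the seed).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(templates, proportions = NULL,
                       peak_spacing_mean = 12, peak_sigma = 1.2,
                       noise_sd = 0.5, resolution_decay = 0.0019,
                       head_ramp_len = 25, indel_offsets = NULL,
                       seed = 1L, id = NULL) {
  templates <- toupper(as.character(templates))
  nt <- length(templates)
  if (nt < 1L || any(!nzchar(templates))) {
    abort("need at least one non-empty template.")
  }
  if (is.null(proportions)) proportions <- rep(1 / nt, nt)
  if (is.null(indel_offsets)) indel_offsets <- rep(0L, nt)
  cfg <- structure(
    list(templates = templates,
         proportions = as.numeric(proportions),
         peak_spacing_mean = peak_spacing_mean,
         peak_sigma = peak_sigma,
         noise_sd = noise_sd,
         resolution_decay = resolution_decay,
         head_ramp_len = as.integer(head_ramp_len),
         indel_offsets = as.integer(indel_offsets),
         seed = as.integer(seed),
         id = if (is.null(id)) sprintf("sim_seed%d", as.integer(seed)) else id),
    class = "sim_config"
  )
  if (length(cfg$proportions) != nt || any(cfg$proportions < 0) ||
      abs(sum(cfg$proportions) - 1) > 1e-9) {
    abort("`proportions` must be non-negative, one per template, summing to 1.")
  }
  if (length(cfg$indel_offsets) != nt || any(cfg$indel_offsets < 0)) {
    abort("`indel_offsets` must be non-negative, one per template.")
  }
  if (cfg$peak_spacing_mean <= 0 || cfg$peak_sigma <= 0 ||
      cfg$noise_sd <= 0 || cfg$resolution_decay <= 0) {
    abort("rate/scale parameters must be > 0.")
  }
  if (cfg$head_ramp_len < 0L) abort("`head_ramp_len` must be >= 0.")
  cfg
}

#' Random ACGT template
#'
#' @param length Template length in bases (default 600, long enough that
#'   the 350-base 3' scan floor is exercised).
#' @param seed Integer seed.
#' @return A single ACGT string.
#' @export
random_template <- function(length = 600, seed = 1L) {
  with_local_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  })
}

#' Mutate a fixed fraction of template positions
#'
#' Produces a second template at a chosen divergence from the first, for
#' building mixed-template simulations with known divergent positions.
#'
#' @param template ACGT string.
#' @param divergence Fraction of positions substituted (default 0.1).
#' @param seed Integer seed.
#' @return A template of the same length differing from `template` at
#'   exactly `round(divergence * nchar(template))` positions.
#' @export
divergent_template <- function(template, divergence = 0.1, seed = 1L) {
  chars <- strsplit(toupper(template), "")[[1]]
  n_mut <- round(divergence * length(chars))
  with_local_seed(seed + 7919L, {
    pos <- sample(seq_along(chars), n_mut)
    for (p in pos) {
      chars[[p]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[p]]), 1L)
    }
  })
  paste(chars, collapse = "")
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a Sanger chromatogram from one or more templates
#'
#' Builds the four processed channels as sums of Gaussian peaks (one peak
#' per template per base, height proportional to the template's mixing
#' weight), adds intensity noise, re-calls bases as the maximum channel at
#' each peak, measures chromatogram features and assigns per-base QVs via
#' [assign_qualities()]. Ground truth (divergent positions, mixture flag)
#' is returned alongside the trace.
#'
#' @param config A [sim_config()].
#' @param quality_params A [quality_model_params()].
#' @return A list with elements `record` (a [trace_record()]) and `truth`
#'   (class `sim_truth`: `config`, `consensus_length`,
#'   `divergent_positions` — 0-based, after indel-offset alignment — and
#'   `is_mixture`).
#' @export
#' @examples
#' out <- simulate_trace(sim_config(random_template(200, seed = 3), seed = 3))
#' out$truth$is_mixture
simulate_trace <- function(config, quality_params = quality_model_params()) {
  stopifnot(inherits(config, "sim_config"))
  nt <- length(config$templates)
  L <- min(nchar(config$templates) - config$indel_offsets)
  if (L < 1L) abort("templates are shorter than their indel offsets.")

  base_mat <- matrix("", nrow = nt, ncol = L)
  for (t in seq_len(nt)) {
    off <- config$indel_offsets[[t]]
    base_mat[t, ] <- strsplit(substr(config$templates[[t]], off + 1L,
                                     off + L), "")[[1]]
  }
  active <- config$proportions > 0
  divergent <- which(apply(base_mat[active, , drop = FALSE], 2L,
                           function(b) length(unique(b)) > 1L)) - 1L

  sp <- config$peak_spacing_mean
  i0 <- seq_len(L) - 1L
  sigma <- config$peak_sigma * (1 + (config$resolution_decay * i0)^3)

  rec <- with_local_seed(config$seed, {
    mu <- sp * seq_len(L) + rnorm(L, 0, 0.15)
    peaks <- as.integer(round(mu))
    if (L > 1L) {  # guard against jitter collapsing adjacent peaks
      for (i in 2:L) if (peaks[[i]] <= peaks[[i - 1L]]) {
        peaks[[i]] <- peaks[[i - 1L]] + 1L
      }
    }
    n_scans <- as.integer(ceiling(max(mu) + 4 * max(sigma) + sp))
    chan <- matrix(0, nrow = n_scans, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))

    ramp <- config$head_ramp_len
    for (i in seq_len(L)) {
      heights <- tapply(SIM_AMPLITUDE * config$proportions[active],
                        base_mat[active, i], sum)
      if (i - 1L < ramp) {
        # 5' contaminant peak on a random unused channel, decaying linearly
        h <- SIM_AMPLITUDE * (1 - (i - 1L) / ramp)
        free <- setdiff(c("A", "C", "G", "T"), names(heights))
        pick <- if (length(free)) sample(free, 1L) else sample(names(heights), 1L)
        heights[pick] <- (if (is.na(heights[pick])) 0 else heights[pick]) + h
        heights <- heights[!is.na(heights)]
      }
      lo <- max(1L, as.integer(floor(mu[[i]] - 4 * sigma[[i]])))
      hi <- min(n_scans, as.integer(ceiling(mu[[i]] + 4 * sigma[[i]])))
      x <- lo:hi
      g <- exp(-((x - mu[[i]])^2) / (2 * sigma[[i]]^2))
      for (b in names(heights)) {
        chan[x, b] <- chan[x, b] + heights[[b]] * g
      }
    }
    chan <- chan + rnorm(length(chan), 0, config$noise_sd)
    chan <- pmin(pmax(round(chan), 0), 32767)

    calls <- apply(chan[peaks + 1L, , drop = FALSE], 1L,
                   function(v) c("A", "C", "G", "T")[which.max(v)])
    channels <- list(A = chan[, "A"], C = chan[, "C"],
                     G = chan[, "G"], T = chan[, "T"])
    feats <- measure_features_impl(channels, peaks, calls)
    qv <- assign_qualities(feats, quality_params)
    trace_record(channels, peaks, paste(calls, collapse = ""), qv,
                 channel_order = "GATC", sample = config$id,
                 instrument = "puritrace simulator")
  })

  truth <- structure(
    list(config = config, consensus_length = L,
         divergent_positions = as.integer(divergent),
         is_mixture = sum(active) >= 2L),
    class = "sim_truth"
  )
  list(record = rec, truth = truth)
}

#' Measure per-base chromatogram features from a trace
#'
#' Features feeding the quality model: the called (primary) and strongest
#' uncalled (secondary) channel heights at each peak, a valley-to-peak
#' resolution in `[0,1]` against the neighbouring peaks on the summed
#' profile, and the relative deviation of the local peak spacing from the
#' trace-wide mean spacing.
#'
#' @param record A [trace_record()].
#' @return A tibble with one row per base: `primary`, `secondary`,
#'   `resolution`, `spacing_dev`.
#' @export
measure_features <- function(record) {
  validate_trace_record(record)
  calls <- if (nchar(record$basecalls)) strsplit(record$basecalls, "")[[1]]
           else character()
  measure_features_impl(record$channels, record$peak_positions, calls)
}

measure_features_impl <- function(channels, peaks, calls) {
  L <- length(peaks)
  if (L == 0L) {
    return(tibble(primary = double(), secondary = double(),
                  resolution = double(), spacing_dev = double()))
  }
  at <- peaks + 1L  # 1-based scan index
  heights <- cbind(A = channels$A[at], C = channels$C[at],
                   G = channels$G[at], T = channels$T[at])
  primary <- double(L)
  secondary <- double(L)
  for (i in seq_len(L)) {
    b <- calls[[i]]
    if (b %in% c("A", "C", "G", "T")) {
      primary[[i]] <- heights[i, b]
      secondary[[i]] <- max(heights[i, setdiff(c("A", "C", "G", "T"), b)])
    } else {
      primary[[i]] <- 0
      secondary[[i]] <- max(heights[i, ])
    }
  }

  total <- channels$A + channels$C + channels$G + channels$T
  peak_tot <- total[at]
  if (L > 1L) {
    valleys <- vapply(seq_len(L - 1L), function(i) {
      min(total[at[[i]]:at[[i + 1L]]])
    }, double(1))
    side <- cbind(left = c(NA, valleys), right = c(valleys, NA))
    vmean <- rowMeans(side, na.rm = TRUE)
    resolution <- 1 - pmin(pmax(ifelse(peak_tot > 0, vmean / peak_tot, 1),
                                0), 1)
  } else {
    resolution <- 1
  }

  if (L > 1L) {
    d <- diff(peaks)
    mean_d <- mean(d)
    dev <- abs(d - mean_d) / mean_d
    spacing_dev <- c(dev[[1L]], dev)
  } else {
    spacing_dev <- 0
  }

  tibble(primary = primary, secondary = secondary,
         resolution = resolution, spacing_dev = spacing_dev)
}

#' Simulate a dataset of traces with a ground-truth table
#'
#' Writes one `.ab1` file per config (via [write_abif()]) plus a
#' `truth.tsv` table. Re-running with identical configs reproduces
#' byte-identical files.
#'
#' @param configs List of [sim_config()]s.
#' @param outdir Output directory (created if absent; must be writable).
#' @return The truth tibble: `id`, `file`, `is_mixture`, `n_templates`,
#'   `proportions` (comma-joined), `seed`, `n_divergent`,
#'   `consensus_length`.
#' @export
generate_dataset <- function(configs, outdir) {
  stopifnot(all(vapply(configs, inherits, logical(1), "sim_config")))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    abort(paste0("cannot create output directory: ", outdir))
  }
  if (file.access(outdir, 2L) != 0L) {
    abort(paste0("output directory not writable: ", outdir))
  }
  empty <- tibble(id = character(), file = character(),
                  is_mixture = logical(), n_templates = integer(),
                  proportions = character(), seed = integer(),
                  n_divergent = integer(), consensus_length = integer())
  rows <- purrr::imap(configs, function(cfg, k) {
    id <- if (nzchar(cfg$id)) cfg$id else sprintf("sim%03d", k)
    out <- simulate_trace(cfg)
    file <- file.path(outdir, paste0(id, ".ab1"))
    write_abif(out$record, file)
    tibble(id = id, file = basename(file),
           is_mixture = out$truth$is_mixture,
           n_templates = length(cfg$templates),
           proportions = paste(cfg$proportions, collapse = ","),
           seed = cfg$seed,
           n_divergent = length(out$truth$divergent_positions),
           consensus_length = out$truth$consensus_length)
  })
  truth <- dplyr::bind_rows(c(list(empty), rows))
  utils::write.table(as.data.frame(truth), file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth
}
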