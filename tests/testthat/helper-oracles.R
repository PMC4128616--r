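# Independent brute-force window scanners used as oracles for the trimming
# implementation. They materialise every window explicitly (embed() for
# full windows, direct slicing for windows truncated at the read end)
# instead of using the cumulative-sum scan the package implements.

oracle_head_trim <- function(q, params = trim_params()) {
  n <- length(q)
  w <- params$window
  skip <- params$head_skip
  if (n == 0L || skip >= n) return(NA_integer_)
  good <- q > params$qv_threshold
  if (n >= w) {
    wins <- embed(as.integer(good), w)      # row j = positions j..j+w-1
    full <- which(rowSums(wins) == w) - 1L  # 0-based starts
    full <- full[full >= skip]
    if (length(full)) return(full[[1L]])
  }
  trunc_from <- max(skip, n - w + 1L)
  if (trunc_from <= n - 1L) {
    for (s in trunc_from:(n - 1L)) {
      if (all(good[(s + 1L):n])) return(as.integer(s))
    }
  }
  NA_integer_
}

oracle_tail_trim <- function(q, start, params = trim_params()) {
  n <- length(q)
  w <- params$window
  first <- start + params$tail_scan_start
  if (first + w > n) return(as.integer(n))
  bad <- q < params$qv_threshold
  wins <- embed(as.integer(bad), w)
  starts <- which(rowSums(wins) > params$max_bad_in_window) - 1L
  starts <- starts[starts >= first]
  if (length(starts)) as.integer(starts[[1L]]) else as.integer(n)
}

# A structurally valid flat trace: one unit peak per base on the channel of
# its call, evenly spaced, with caller-chosen qualities.
make_flat_record <- function(qualities, calls = NULL, sample = "flat") {
  n <- length(qualities)
  if (is.null(calls)) calls <- rep("A", n)
  spacing <- 4L
  n_scans <- max(spacing * n + spacing, spacing)
  channels <- list(A = numeric(n_scans), C = numeric(n_scans),
                   G = numeric(n_scans), T = numeric(n_scans))
  peaks <- spacing * seq_len(n) - 1L
  for (i in seq_len(n)) {
    ch <- if (calls[[i]] %in% names(channels)) calls[[i]] else "A"
    channels[[ch]][peaks[[i]] + 1L] <- 100
  }
  trace_record(channels, peaks, paste(calls, collapse = ""),
               as.integer(qualities), sample = sample)
}

random_trace_record <- function(seed) {
  set.seed(seed)
  n <- sample(0:60, 1)
  spacing <- sample(3:12, 1)
  n_scans <- max(spacing * (n + 1L), 8L)
  channels <- lapply(setNames(1:4, c("A", "C", "G", "T")), function(i) {
    sample(0:32767, n_scans, replace = TRUE)
  })
  peaks <- if (n > 0) sort(sample(0:(n_scans - 1L), n)) else integer()
  calls <- paste(sample(c("A", "C", "G", "T", "N", "Y", "R"), n,
                        replace = TRUE), collapse = "")
  quals <- sample(0:93, n, replace = TRUE)
  ord <- paste(sample(c("A", "C", "G", "T")), collapse = "")
  trace_record(channels, peaks, calls, quals, channel_order = ord,
               sample = paste0("rnd", seed))
}

# Pinned-seed simulated batch: 3 pure + 2 divergent 50:50 mixtures.
make_fixture_batch <- function(dir) {
  cfgs <- list()
  for (s in 1:3) {
    cfgs[[s]] <- sim_config(random_template(600, seed = 200 + s),
                            seed = 200 + s, id = sprintf("pure%d", s))
  }
  for (s in 1:2) {
    t1 <- random_template(600, seed = 300 + s)
    t2 <- divergent_template(t1, 0.1, seed = 300 + s)
    cfgs[[3 + s]] <- sim_config(c(t1, t2), proportions = c(0.5, 0.5),
                                seed = 300 + s, id = sprintf("mix%d", s))
  }
  generate_dataset(cfgs, dir)
}
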