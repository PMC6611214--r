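# Shared builders for small synthetic inputs.

# a fast, low-resolution ground truth for pipeline-level tests
tiny_truth <- function(...) {
  args <- list(...)
  defaults <- list(n_participants = 6, trials_per_item = 8,
                   sampling_rate = 64, noise_sd = 5,
                   artifact_fraction = 0, seed = 11L)
  do.call(simulation_truth, utils::modifyList(defaults, args))
}

# wrap a raw voltage array into an epoch_set for unit tests
make_epoch_set <- function(data, times,
                           channels = dimnames(data)[[4]]) {
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[4]))
  structure(list(data = data, channels = channels, times = times,
                 artifact_flags = array(FALSE, dim(data)[1:4])),
            class = "epoch_set")
}

# epoch_set holding a single epoch with the given channel x time matrix
single_epoch <- function(values, times) {
  d <- array(0, dim = c(1, 1, 1, nrow(values), ncol(values)))
  d[1, 1, 1, , ] <- values
  make_epoch_set(d, times, channels = rownames(values))
}

# complete pairwise-choice records for one or more participants where the
# winner of each pair is decided by `winner(a, b, block)`
make_choice_records <- function(winner, n_items = 12, n_blocks = 7,
                                participants = 1) {
  pairs <- t(utils::combn(n_items, 2))
  do.call(rbind, lapply(participants, function(p) {
    do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      data.frame(participant = p, block = b,
                 item_a = pairs[, 1], item_b = pairs[, 2],
                 chosen = mapply(winner, pairs[, 1], pairs[, 2], b),
                 side = "left")
    }))
  }))
}

# a preference_profile built directly from a counts matrix
profile_from_counts <- function(counts) {
  group_counts <- colMeans(counts)
  ranks <- rank(-group_counts, ties.method = "first")
  structure(list(counts = counts, group_counts = group_counts,
                 ranks = ranks,
                 labels = ifelse(ranks <= ncol(counts) / 2, "HP", "LP"),
                 n_blocks = 7),
            class = "preference_profile")
}

# random erp_waveform list over k items (shared grid)
random_item_waveforms <- function(k = 6, n_ch = 3, n_t = 40) {
  times <- seq(0, by = 10, length.out = n_t)
  lapply(seq_len(k), function(i) {
    erp_waveform(matrix(rnorm(n_ch * n_t), n_ch, n_t),
                 paste0("ch", seq_len(n_ch)), times,
                 n_trials = sample(10:30, 1), condition = i)
  })
}

# independent brute-force Benjamini-Hochberg step-up (oracle); the strict
# threshold p_(k) < k * alpha / m matches the package's `p_adj < alpha`
brute_force_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[ord[i]] <- min(1, min(m * p[ord[i:m]] / (i:m)))
  }
  k <- which(p[ord] < seq_len(m) * alpha / m)
  reject <- rep(FALSE, m)
  if (length(k)) reject[ord[seq_len(max(k))]] <- TRUE
  list(p_adj = adj, reject = reject)
}
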