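#' @title ERP waveform container
#' @description Average voltage trace per channel for one condition (a
#'   single item, a preference group, or a leave-one-out group), with the
#'   number of trials that entered the average.
#' @param values channel x time matrix, microvolts.
#' @param channels channel labels (row order of `values`).
#' @param times sample times in ms.
#' @param n_trials trials averaged.
#' @param condition condition label (item id or group name).
#' @param participant participant id, if participant-level.
#' @return an `erp_waveform`.
#' @export
erp_waveform <- function(values, channels, times, n_trials,
                         condition = NA, participant = NA) {
  stopifnot(nrow(values) == length(channels), ncol(values) == length(times),
            n_trials >= 1)
  structure(list(values = values, channels = channels, times = times,
                 n_trials = n_trials, condition = condition,
                 participant = participant),
            class = "erp_waveform")
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean voltage over the pre-stimulus
#' window from the whole epoch. Applying the correction twice equals
#' applying it once.
#'
#' @param epochs an `epoch_set`.
#' @param window c(start, end) in ms; samples with `start <= t <= end`.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (!length(idx))
    stop("baseline window [", window[1], ", ", window[2],
         "] contains no samples")
  d <- epochs$data
  dm <- dim(d)
  nt <- dm[5]
  m <- matrix(d, ncol = nt)        # rows: (participant, item, trial, channel)
  bl <- rowMeans(m[, idx, drop = FALSE])
  epochs$data <- array(m - bl, dim = dm, dimnames = dimnames(d))
  epochs
}

#' Reject epochs on amplitude criteria
#'
#' An epoch is rejected when on any channel the peak-to-peak range exceeds
#' `range_thresh` or any step between adjacent samples exceeds
#' `step_thresh` (both in microvolts). Run after baseline correction.
#'
#' @param epochs an `epoch_set`.
#' @param range_thresh max-minus-min threshold, default 120.
#' @param step_thresh adjacent-sample threshold, default 75.
#' @return list with `rejected` (participant x item x trial logical array)
#'   and `report` (data.frame: participant, item, trials_total,
#'   trials_rejected, trials_kept).
#' @export
reject_artifacts <- function(epochs, range_thresh = 120, step_thresh = 75) {
  stopifnot(range_thresh > 0, step_thresh > 0)
  d <- epochs$data
  dm <- dim(d)                     # P, I, R, C, T
  nt <- dm[5]
  m <- matrix(d, ncol = nt)
  lo <- hi <- m[, 1]
  step <- rep(0, nrow(m))
  for (j in 2:nt) {
    lo <- pmin(lo, m[, j])
    hi <- pmax(hi, m[, j])
    step <- pmax(step, abs(m[, j] - m[, j - 1]))
  }
  bad_ch <- array(hi - lo > range_thresh | step > step_thresh, dim = dm[1:4])
  rejected <- apply(bad_ch, c(1, 2, 3), any)
  rej_count <- apply(rejected, c(1, 2), sum)
  report <- data.frame(
    participant = rep(seq_len(dm[1]), times = dm[2]),
    item = rep(seq_len(dm[2]), each = dm[1]),
    trials_total = dm[3],
    trials_rejected = as.vector(rej_count)
  )
  report$trials_kept <- report$trials_total - report$trials_rejected
  list(rejected = rejected, report = report)
}

#' Participants failing the minimum-trial rule
#'
#' A participant is excluded when any item retains fewer than `min_trials`
#' artifact-free trials, so that every single-item average keeps an
#' acceptable signal-to-noise ratio.
#'
#' @param report rejection report from [reject_artifacts()].
#' @param min_trials inclusion threshold (default 16; "at least 16" keeps a
#'   participant with exactly 16 everywhere).
#' @return integer vector of excluded participant ids (possibly empty).
#' @export
enforce_min_trials <- function(report, min_trials = 16) {
  excluded <- sort(unique(report$participant[report$trials_kept < min_trials]))
  n_all <- length(unique(report$participant))
  if (length(excluded) == n_all)
    stop("all ", n_all, " participants excluded by the ", min_trials,
         "-trial rule")
  excluded
}

#' Average the kept trials of one item for one participant
#'
#' @param epochs an `epoch_set`.
#' @param participant,item indices.
#' @param keep logical vector over trials (default: all kept); typically
#'   `!rejected[participant, item, ]`.
#' @return an `erp_waveform` with `n_trials` recorded.
#' @export
average_item <- function(epochs, participant, item, keep = NULL) {
  n_tr <- dim(epochs$data)[3]
  if (is.null(keep)) keep <- rep(TRUE, n_tr)
  if (!any(keep))
    stop("no kept trials for participant ", participant, ", item ", item)
  d <- epochs$data[participant, item, keep, , , drop = FALSE]
  dim(d) <- c(sum(keep), length(epochs$channels) * length(epochs$times))
  vals <- matrix(colMeans(d), length(epochs$channels), length(epochs$times))
  erp_waveform(vals, epochs$channels, epochs$times, n_trials = sum(keep),
               condition = item, participant = participant)
}

#' Average item waveforms into a group waveform
#'
#' Unweighted mean across item-level waveforms — each item counts once
#' regardless of its trial count — optionally excluding one item
#' (leave-one-out). Equal weighting makes the leave-one-out identity
#' `loo_i = (k * mean_all - w_i) / (k - 1)` exact.
#'
#' @param item_waveforms list of `erp_waveform`s with item ids in their
#'   `condition` field.
#' @param exclude_item item id to leave out, or NULL.
#' @return an `erp_waveform`; `condition` records the exclusion,
#'   `n_trials` the summed trials of the included items.
#' @export
average_group <- function(item_waveforms, exclude_item = NULL) {
  items <- vapply(item_waveforms, function(w) w$condition, numeric(1))
  use <- if (is.null(exclude_item)) rep(TRUE, length(items))
         else items != exclude_item
  if (!any(use)) stop("excluding item ", exclude_item, " empties the group")
  ws <- item_waveforms[use]
  vals <- Reduce(`+`, lapply(ws, `[[`, "values")) / length(ws)
  w1 <- ws[[1]]
  cond <- if (is.null(exclude_item)) "group"
          else paste0("group-minus-", exclude_item)
  erp_waveform(vals, w1$channels, w1$times,
               n_trials = sum(vapply(ws, `[[`, numeric(1), "n_trials")),
               condition = cond, participant = w1$participant)
}

#' Average a waveform over a region of interest
#'
#' @param waveform an `erp_waveform`.
#' @param channels channel labels to average (e.g. `c("F3","Fz","F4")` for
#'   the anterior ROI or `c("P3","Pz","P4")` for the posterior ROI).
#' @return numeric vector: the ROI mean trace over time.
#' @export
roi_average <- function(waveform, channels) {
  missing <- setdiff(channels, waveform$channels)
  if (length(missing))
    stop("channel not in waveform: ", paste(missing, collapse = ", "))
  colMeans(waveform$values[match(channels, waveform$channels), , drop = FALSE])
}

#' Peak-to-peak N200 amplitude
#'
#' The negative extremum in the N200 search window minus the positive
#' extremum in the preceding P200 window (closed windows; the earliest
#' sample wins ties). Because the two windows overlap at 200-230 ms the
#' result can never be positive. Adding a constant offset to the trace
#' leaves the value unchanged.
#'
#' @param trace numeric voltage trace (e.g. an ROI average).
#' @param times sample times in ms, same length as `trace`.
#' @param p200_window,n200_window closed search windows in ms.
#' @return amplitude difference in microvolts (<= 0 with the default
#'   overlapping windows).
#' @export
n200_peak_to_peak <- function(trace, times,
                              p200_window = c(130, 230),
                              n200_window = c(200, 400)) {
  ip <- which(times >= p200_window[1] & times <= p200_window[2])
  iN <- which(times >= n200_window[1] & times <= n200_window[2])
  if (!length(ip) || !length(iN) ||
      min(times) > p200_window[1] || max(times) < n200_window[2])
    stop("peak search windows fall outside the trace")
  min(trace[iN]) - max(trace[ip])
}

#' Mean amplitude over a latency window
#'
#' Arithmetic mean of the samples in the half-open interval
#' `[start, end)`, so that consecutive windows partition the epoch without
#' sharing samples.
#'
#' @param trace numeric voltage trace.
#' @param times sample times in ms.
#' @param window c(start, end) in ms.
#' @return mean amplitude in microvolts.
#' @export
window_mean <- function(trace, times, window) {
  if (window[1] < min(times) || window[2] > max(times) + diff(times[1:2]))
    stop("window [", window[1], ", ", window[2], ") outside the trace")
  idx <- which(times >= window[1] & times < window[2])
  if (!length(idx))
    stop("window [", window[1], ", ", window[2], ") contains no samples")
  mean(trace[idx])
}

#' Optional zero-phase band-pass filter
#'
#' Forward-backward 4th-order Butterworth band-pass over the time axis of
#' every epoch. Off by default in the pipeline: the synthetic generator is
#' already band-limited.
#'
#' @param epochs an `epoch_set`.
#' @param low,high band edges in Hz.
#' @param order filter order.
#' @return filtered `epoch_set`.
#' @export
filter_epochs <- function(epochs, low = 0.01, high = 30, order = 4) {
  fs <- 1000 / diff(epochs$times[1:2])
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  d <- epochs$data
  dm <- dim(d)
  m <- matrix(d, ncol = dm[5])
  m <- t(apply(m, 1, function(v) signal::filtfilt(bf, v)))
  epochs$data <- array(m, dim = dm, dimnames = dimnames(d))
  epochs
}

## ---- component scoring ------------------------------------------------

#' Single-item time windows of the analysis
#' @return character vector of the six window labels: the N200 complex and
#'   the five late-positivity windows.
#' @export
si_windows <- function() {
  c("n200", "400-800", "800-1200", "1200-1600", "1600-2000", "2000-3000")
}

#' Score one trace on one measure
#'
#' `"n200"` is the peak-to-peak P200-to-N200 measure;
#' `"n200_mean_200_400"` and `"n200_mean_228_344"` are its mean-amplitude
#' alternatives; any `"a-b"` label is the window mean over \[a, b) ms.
#'
#' @param trace numeric voltage trace.
#' @param times sample times, ms.
#' @param measure measure label.
#' @return microvolt score.
#' @export
measure_trace <- function(trace, times, measure) {
  if (measure == "n200") return(n200_peak_to_peak(trace, times))
  if (measure == "n200_mean_200_400") return(window_mean(trace, times, c(200, 400)))
  if (measure == "n200_mean_228_344") return(window_mean(trace, times, c(228, 344)))
  bounds <- suppressWarnings(as.numeric(strsplit(measure, "-")[[1]]))
  if (length(bounds) != 2 || anyNA(bounds))
    stop("unknown measure: ", measure)
  window_mean(trace, times, bounds)
}

#' Per-participant single-item ROI traces
#'
#' Averages the kept trials of every (participant, item) into an item
#' waveform and reduces it to the anterior ROI trace (F3, Fz, F4; used for
#' the N200) and the posterior ROI trace (P3, Pz, P4; used for the LPP and
#' slow-wave windows).
#'
#' @param epochs an `epoch_set` (baseline-corrected).
#' @param rejected participant x item x trial logical array from
#'   [reject_artifacts()], or NULL for no rejection.
#' @param participants participant indices to keep (default all).
#' @param anterior,posterior ROI channel sets.
#' @return list with `anterior` and `posterior` (participant x item x time
#'   arrays), `times`, and `participants`.
#' @export
si_roi_traces <- function(epochs, rejected = NULL, participants = NULL,
                          anterior = c("F3", "Fz", "F4"),
                          posterior = c("P3", "Pz", "P4")) {
  dm <- dim(epochs$data)
  if (is.null(participants)) participants <- seq_len(dm[1])
  nt <- length(epochs$times)
  ant <- post <- array(NA_real_, dim = c(length(participants), dm[2], nt))
  for (pi in seq_along(participants)) {
    p <- participants[pi]
    for (i in seq_len(dm[2])) {
      keep <- if (is.null(rejected)) NULL else !rejected[p, i, ]
      w <- average_item(epochs, p, i, keep)
      ant[pi, i, ] <- roi_average(w, anterior)
      post[pi, i, ] <- roi_average(w, posterior)
    }
  }
  list(anterior = ant, posterior = post, times = epochs$times,
       participants = participants)
}

#' Per-electrode component scores for the group-level analysis
#'
#' For every participant, item and channel, scores the item-average
#' waveform on one measure. Used to build the 2 x 3 x 3
#' (Preference x Anterior-Posterior x Laterality) ANOVA cells.
#'
#' @param epochs an `epoch_set` (baseline-corrected).
#' @param measures one or more measure labels, see [measure_trace()]; all
#'   are scored in a single pass over the item waveforms.
#' @param rejected optional rejection array.
#' @param participants participant indices to keep.
#' @return data.frame: participant, item, channel, measure, value.
#' @export
electrode_scores <- function(epochs, measures, rejected = NULL,
                             participants = NULL) {
  dm <- dim(epochs$data)
  if (is.null(participants)) participants <- seq_len(dm[1])
  rows <- list()
  for (p in participants) {
    for (i in seq_len(dm[2])) {
      keep <- if (is.null(rejected)) NULL else !rejected[p, i, ]
      w <- average_item(epochs, p, i, keep)
      for (ms in measures) {
        vals <- apply(w$values, 1, measure_trace,
                      times = epochs$times, measure = ms)
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, item = i, channel = epochs$channels,
          measure = ms, value = unname(vals))
      }
    }
  }
  do.call(rbind, rows)
}
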