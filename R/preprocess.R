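#' Evoked field (trial average)
#'
#' @param data channels x samples matrix (tesla).
#' @param sfreq_hz Sampling rate.
#' @param t0_s First-sample time relative to stimulus onset.
#' @param transition_s Noise-to-pitch transition time (s).
#' @param n_trials_used Number of trials averaged.
#' @param provenance List of processing steps applied (filter, baseline, ...).
#' @return An `evoked_field` object.
#' @export
evoked_field <- function(data, sfreq_hz, t0_s, transition_s,
                         n_trials_used = NA_integer_, provenance = list()) {
  stopifnot(is.matrix(data))
  structure(list(data = data, sfreq_hz = sfreq_hz, t0_s = t0_s,
                 transition_s = transition_s, n_trials_used = n_trials_used,
                 provenance = provenance),
            class = "evoked_field")
}

#' @export
print.evoked_field <- function(x, ...) {
  cat("<evoked_field> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sfreq_hz, " Hz; ", x$n_trials_used, " trials; steps: ",
      paste(names(x$provenance), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

evoked_times <- function(x) x$t0_s + (seq_len(ncol(x$data)) - 1) / x$sfreq_hz

#' Reject artifact trials by peak-to-peak amplitude
#'
#' A trial is dropped iff its maximum over channels of the per-channel
#' peak-to-peak amplitude (max minus min over samples) exceeds the
#' threshold. The default 5e-12 T is the classification criterion used for
#' whole-head MEG recordings of this kind.
#'
#' @param epochs An [epoch_set()].
#' @param threshold_T Peak-to-peak rejection threshold in tesla (> 0).
#' @return The pruned [epoch_set()]; attribute `"rejection_fraction"` logs
#'   the fraction removed and `retained` the per-trial bookkeeping.
#' @export
reject_artifacts <- function(epochs, threshold_T = 5e-12) {
  check_scalar(threshold_T, "threshold_T")
  if (threshold_T <= 0) stop_config("threshold_T must be positive")
  d <- epochs$data
  p2p <- apply(d, 1, function(tr) max(apply(tr, 1, function(ch) {
    max(ch) - min(ch)
  })))
  keep <- p2p <= threshold_T
  if (!any(keep)) {
    stop_input("all ", length(keep), " trials exceeded the ",
               format(threshold_T), " T peak-to-peak threshold")
  }
  out <- epoch_set(d[keep, , , drop = FALSE], epochs$sfreq_hz, epochs$t0_s,
                   epochs$transition_s, retained = keep)
  attr(out, "rejection_fraction") <- mean(!keep)
  out
}

#' Average retained epochs into an evoked field
#'
#' @param epochs An [epoch_set()].
#' @return An [evoked_field()] (arithmetic mean over trials).
#' @export
average_epochs <- function(epochs) {
  d <- epochs$data
  avg <- apply(d, c(2, 3), mean)
  evoked_field(avg, epochs$sfreq_hz, epochs$t0_s, epochs$transition_s,
               n_trials_used = dim(d)[1],
               provenance = list(average = list(n_trials = dim(d)[1])))
}

#' Zero-phase low-pass filter an evoked field
#'
#' Forward-backward (zero-phase) 4th-order Butterworth low-pass.
#'
#' @param evoked An [evoked_field()].
#' @param cutoff_hz Cutoff frequency (default 20 Hz; must be below Nyquist).
#' @param order Butterworth order of each pass.
#' @return Filtered [evoked_field()] with provenance appended.
#' @export
lowpass <- function(evoked, cutoff_hz = 20, order = 4) {
  check_scalar(cutoff_hz, "cutoff_hz")
  nyq <- evoked$sfreq_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop_config("cutoff_hz must lie in (0, Nyquist = ", nyq, ")")
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  out <- evoked
  out$data <- t(apply(evoked$data, 1, function(ch) {
    signal::filtfilt(bf, ch)
  }))
  out$provenance <- c(evoked$provenance,
                      list(lowpass = list(cutoff_hz = cutoff_hz,
                                          order = order, zero_phase = TRUE)))
  out
}

#' Baseline-correct an evoked field
#'
#' Subtracts, per channel, the mean over the baseline window. The default
#' window is the 100 ms immediately preceding the noise-to-pitch transition.
#'
#' @param evoked An [evoked_field()].
#' @param window_s Length-2 window (s, relative to stimulus onset); `NULL`
#'   uses `[transition - 0.1, transition)`.
#' @return Corrected [evoked_field()].
#' @export
baseline_correct <- function(evoked, window_s = NULL) {
  window_s <- window_s %||% c(evoked$transition_s - 0.1, evoked$transition_s)
  times <- evoked_times(evoked)
  sel <- times >= window_s[1] & times < window_s[2]
  if (!any(sel)) stop_config("baseline window outside the epoch")
  out <- evoked
  out$data <- evoked$data - rowMeans(evoked$data[, sel, drop = FALSE])
  out$provenance <- c(evoked$provenance,
                      list(baseline = list(window_s = window_s)))
  out
}

#' Find the peak latency of an evoked response
#'
#' Peak = time of maximal global field power (root-mean-square over
#' channels) within the search window. Exact ties break to the earliest
#' sample; a flat signal additionally warns.
#'
#' @param evoked An [evoked_field()].
#' @param search_window_s Length-2 window relative to the transition
#'   (default 0 to 0.4 s post-transition).
#' @return List: `latency_s` (relative to the transition), `time_s`
#'   (epoch time), `index` (sample index), `gfp` (peak global field power).
#' @export
find_peak_latency <- function(evoked, search_window_s = c(0, 0.4)) {
  times <- evoked_times(evoked)
  rel <- times - evoked$transition_s
  sel <- which(rel >= search_window_s[1] & rel <= search_window_s[2])
  if (!length(sel)) stop_config("empty search window")
  gfp <- sqrt(colMeans(evoked$data[, sel, drop = FALSE]^2))
  if (max(gfp) - min(gfp) <= 0) {
    warn("flat signal in the search window; returning earliest sample")
  }
  i <- sel[which.max(gfp)]
  list(latency_s = rel[i], time_s = times[i], index = i, gfp = max(gfp))
}

#' Anti-aliased decimation of epoched data
#'
#' Low-pass filters each trial and channel at 80% of the target Nyquist
#' (zero-phase Butterworth) and keeps every `factor`-th sample.
#'
#' @param epochs An [epoch_set()].
#' @param factor Integer decimation factor (>= 2).
#' @return Decimated [epoch_set()].
#' @export
decimate_epochs <- function(epochs, factor) {
  check_scalar(factor, "factor")
  if (factor < 2) stop_config("factor must be >= 2")
  new_sf <- epochs$sfreq_hz / factor
  bf <- signal::butter(4, 0.8 * (new_sf / 2) / (epochs$sfreq_hz / 2), "low")
  d <- epochs$data
  keep <- seq(1, dim(d)[3], by = factor)
  out <- array(0, c(dim(d)[1], dim(d)[2], length(keep)))
  for (tr in seq_len(dim(d)[1])) {
    filt <- t(apply(d[tr, , , drop = TRUE], 1,
                    function(ch) signal::filtfilt(bf, ch)))
    out[tr, , ] <- filt[, keep]
  }
  epoch_set(out, new_sf, epochs$t0_s, epochs$transition_s, epochs$retained)
}
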