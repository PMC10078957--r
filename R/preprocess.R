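#' Bandpass filter a recording
#'
#' Butterworth bandpass applied per channel. Default 2nd-order 0.1-25 Hz.
#' Zero-phase (forward-backward) filtering is the default for offline
#' analysis; the causal mode replays the filter in one direction for
#' pseudo-online use. Filter settings are recorded in the recording's
#' provenance.
#'
#' @param recording an `eeg_recording`.
#' @param low_hz,high_hz cutoff frequencies; 0 < low < high < rate/2.
#' @param order Butterworth design order (per band edge).
#' @param zero_phase logical; TRUE = forward-backward filtering.
#' @return the filtered recording.
#' @export
bandpass_filter <- function(recording, low_hz = 0.1, high_hz = 25,
                            order = 2, zero_phase = TRUE) {
  rate <- recording$rate_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rate / 2))
    stop("bandpass_filter: need 0 < low_hz < high_hz < rate/2")
  bf <- signal::butter(order, c(low_hz, high_hz) / (rate / 2), type = "pass")
  if (max(Mod(polyroot(rev(bf$a)))) >= 1)
    stop("bandpass_filter: unstable filter design (cutoffs too close to Nyquist)")
  for (ch in recording$channels) {
    x <- recording$data[ch, ]
    recording$data[ch, ] <- if (zero_phase) signal::filtfilt(bf, x)
                            else as.numeric(signal::filter(bf, x))
  }
  recording$provenance$filter <- list(low_hz = low_hz, high_hz = high_hz,
                                      order = order,
                                      mode = if (zero_phase) "zero-phase"
                                             else "causal")
  recording
}

#' Segment a recording into stimulus-locked epochs
#'
#' Cuts one 500 ms epoch per event: the half-open sample window
#' `[onset - pre, onset + post)` on the 0-based acquisition clock, i.e.
#' 100 ms baseline and 400 ms post-stimulus at the defaults. Events too
#' close to a recording edge are skipped with a warning.
#'
#' @param recording an `eeg_recording`.
#' @param pre,post samples before/after stimulus onset.
#' @return object of class `epoch_set`: `data` is a channels x samples x
#'   epochs array; `events` holds the retained events in acquisition order;
#'   `kept`/`reason` track artifact rejection.
#' @export
epoch_recording <- function(recording, pre = EPOCH_PRE, post = EPOCH_POST) {
  ev <- recording$events
  n <- ncol(recording$data)
  ok <- ev$onset_sample >= pre & ev$onset_sample + post <= n
  if (any(!ok))
    warning(sprintf("epoch_recording: %d of %d events too close to a recording edge; skipped",
                    sum(!ok), nrow(ev)))
  ev <- ev[ok, , drop = FALSE]
  k <- nrow(ev)
  data <- array(0, dim = c(length(recording$channels), pre + post, k),
                dimnames = list(recording$channels, NULL, NULL))
  for (i in seq_len(k)) {
    idx <- (ev$onset_sample[i] - pre + 1):(ev$onset_sample[i] + post)
    data[, , i] <- recording$data[, idx]
  }
  structure(list(data = data, events = ev,
                 kept = rep(TRUE, k), reason = rep(NA_character_, k),
                 channels = recording$channels, rate_hz = recording$rate_hz,
                 pre = pre, post = post,
                 provenance = recording$provenance),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d kept) x %d channels x %d samples (%d+%d)\n",
              dim(x$data)[3], sum(x$kept), dim(x$data)[1], dim(x$data)[2],
              x$pre, x$post))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and epoch, the mean of the pre-stimulus baseline
#' window from the whole epoch.
#'
#' @param epochs an `epoch_set`.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  bl <- apply(epochs$data[, seq_len(epochs$pre), , drop = FALSE],
              c(1, 3), mean)
  epochs$data <- sweep(epochs$data, c(1, 3), bl)
  epochs$provenance$baseline <- sprintf("mean of %d pre-stimulus samples",
                                        epochs$pre)
  epochs
}

#' Reject artifact-contaminated epochs by amplitude thresholds
#'
#' Dual-threshold rule over the full 500 ms epoch: an epoch is rejected when
#' the absolute value on any scalp EEG channel crosses (strictly exceeds)
#' `eeg_thr_uV`, or on Fp1 crosses `eog_thr_uV` (blink artifacts).
#' Boundary-equal values are kept. The check is idempotent and independent
#' of epoch order.
#'
#' @param epochs an `epoch_set`.
#' @param eeg_thr_uV scalp-channel threshold, microvolts.
#' @param eog_thr_uV Fp1 threshold, microvolts.
#' @return the `epoch_set` with `kept`/`reason` updated ("EEG" or "EOG")
#'   and a `rejection` summary element (counts per cluster).
#' @export
reject_artifacts <- function(epochs, eeg_thr_uV = 50, eog_thr_uV = 80) {
  scalp <- intersect(SCALP_CHANNELS, epochs$channels)
  if (!"Fp1" %in% epochs$channels)
    stop("reject_artifacts: Fp1 channel required for the EOG rule")
  scalp_max <- apply(abs(epochs$data[scalp, , , drop = FALSE]), 3, max)
  eog_max <- apply(abs(epochs$data["Fp1", , , drop = FALSE]), 3, max)
  eeg_bad <- scalp_max > eeg_thr_uV
  eog_bad <- eog_max > eog_thr_uV
  epochs$kept <- !(eeg_bad | eog_bad)
  epochs$reason <- ifelse(eeg_bad, "EEG", ifelse(eog_bad, "EOG", NA))
  cl <- paste0("A", epochs$events$attended_location, "S",
               epochs$events$location)
  epochs$rejection <- data.frame(
    cluster = sort(unique(cl)),
    kept = as.integer(tapply(epochs$kept, cl, sum)[sort(unique(cl))]),
    rejected = as.integer(tapply(!epochs$kept, cl, sum)[sort(unique(cl))]),
    row.names = NULL)
  epochs$provenance$thresholds <- c(eeg_uV = eeg_thr_uV, eog_uV = eog_thr_uV)
  epochs
}
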