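## Preprocessing of continuous sessions: common average reference,
## zero-phase Butterworth band-pass, epoching with baseline correction,
## amplitude/SD artifact rejection, and removal of non-target epochs
## overlapping the target response in RSVP streams.

#' Common average reference
#'
#' Subtracts the instantaneous mean over all channels from every channel,
#' so the channel mean is zero at every sample.
#'
#' @param session An `eeg_session`.
#' @return A new re-referenced `eeg_session` (the input is not modified).
#' @export
common_average_reference <- function(session) {
  stopifnot(inherits(session, "eeg_session"))
  if (nrow(session$signal) < 2) {
    stop("common average reference needs at least 2 channels")
  }
  session$signal <- sweep(session$signal, 2, colMeans(session$signal))
  session
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass, realised as a high-pass/low-pass
#' cascade (each of order `order`) and applied forward-backward
#' (zero-phase) per channel so ERP latencies are not shifted by filter
#' group delay. The effective magnitude response is the squared cascade
#' response.
#'
#' @param session An `eeg_session`.
#' @param low,high Cut-off frequencies in Hz (0 < low < high < rate / 2).
#' @param order Butterworth order of each cascade section.
#' @return A filtered `eeg_session`.
#' @export
bandpass_filter <- function(session, low = 0.5, high = 10, order = 4) {
  stopifnot(inherits(session, "eeg_session"))
  nyq <- session$rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("cut-offs must satisfy 0 < low < high < rate/2")
  }
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  x <- t(session$signal)                 # samples x channels
  x <- .filtfilt_mat(hp, x)
  x <- .filtfilt_mat(lp, x)
  session$signal <- t(x)
  session
}

## Zero-phase (forward-backward) IIR filtering of every column of `x`
## (samples x channels) with zero initial conditions, in whole-matrix
## calls: the moving-average part as a one-sided convolution, the
## autoregressive part recursively.
.filt_mat <- function(b, a, x) {
  nb <- length(b)
  if (nb > 1) {
    pad <- rbind(matrix(0, nb - 1, ncol(x)), x)
    z <- stats::filter(pad, b, method = "convolution", sides = 1)
    z <- z[nb:nrow(z), , drop = FALSE]
  } else {
    z <- b * x
  }
  if (length(a) > 1) {
    z <- stats::filter(z, -a[-1], method = "recursive")
  }
  matrix(as.numeric(z), nrow(x), ncol(x))
}

.filtfilt_mat <- function(filt, x) {
  b <- filt$b / filt$a[1]
  a <- filt$a / filt$a[1]
  y <- .filt_mat(b, a, x)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- .filt_mat(b, a, y)
  y[rev(seq_len(nrow(y))), , drop = FALSE]
}

.new_epoch_set <- function(data, events, rate, times_ms, baseline_ms,
                           channel_names, kind) {
  structure(
    list(data = data,                # epochs x channels x samples
         labels = events$stim_type,
         events = events,
         rate = rate,
         times_ms = times_ms,
         baseline_ms = baseline_ms,
         channel_names = channel_names,
         kind = kind,
         reject_mask = rep(FALSE, nrow(events)),
         reject_reason = rep(NA_character_, nrow(events))),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "Epoch set (%s): %d epochs (%d targets) x %d channels x %d samples @ %g Hz; %d flagged\n",
    x$kind, dim(x$data)[1], sum(x$labels == "target"), dim(x$data)[2],
    dim(x$data)[3], x$rate, sum(x$reject_mask)))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]

#' Cut stimulus-locked epochs with baseline correction
#'
#' Extracts, for every event, the window `window_ms` relative to stimulus
#' onset (half-open; the onset sample is included) and subtracts the mean
#' of the `baseline_ms` window per epoch and channel. Sample counts use
#' the floor convention: an 800 ms window at 512 Hz has 409 samples and a
#' 200 ms baseline has 102. Events too close to the recording edges are
#' dropped with a warning.
#'
#' @param session An `eeg_session`.
#' @param window_ms Post-onset window in ms, default `c(0, 800)`.
#' @param baseline_ms Baseline window in ms, default `c(-200, 0)`.
#' @return An `epoch_set`.
#' @export
extract_epochs <- function(session, window_ms = c(0, 800),
                           baseline_ms = c(-200, 0)) {
  stopifnot(inherits(session, "eeg_session"))
  fs <- session$rate
  n_samp <- ncol(session$signal)
  n_ch <- nrow(session$signal)
  ep_start <- floor(window_ms[1] / 1000 * fs)          # offset from onset
  ep_len <- floor(diff(window_ms) / 1000 * fs)
  bl_end <- floor(baseline_ms[2] / 1000 * fs)          # exclusive
  bl_len <- floor(diff(baseline_ms) / 1000 * fs)
  bl_start <- bl_end - bl_len

  onset <- session$events$sample                        # 0-based
  lo <- onset + min(ep_start, bl_start)
  hi <- onset + max(ep_start + ep_len - 1, bl_start + bl_len - 1)
  ok <- lo >= 0 & hi < n_samp
  if (!all(ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  events <- session$events[ok, , drop = FALSE]
  rownames(events) <- NULL
  onset <- events$sample
  n_ep <- length(onset)
  if (n_ep == 0) stop("no events with complete epochs")

  ## gather: channels x (epochs * samples), then fold into 3-D
  post_idx <- as.vector(outer(ep_start + seq_len(ep_len) - 1, onset, "+")) + 1
  post <- session$signal[, post_idx, drop = FALSE]
  dim(post) <- c(n_ch, ep_len, n_ep)

  bl_idx <- as.vector(outer(bl_start + seq_len(bl_len) - 1, onset, "+")) + 1
  bl <- session$signal[, bl_idx, drop = FALSE]
  dim(bl) <- c(n_ch, bl_len, n_ep)
  bl_mean <- colMeans(aperm(bl, c(2, 1, 3)))            # channels x epochs

  ## subtract the per-(channel, epoch) baseline mean
  dim(post) <- c(n_ch, ep_len * n_ep)
  post <- post - bl_mean[, rep(seq_len(n_ep), each = ep_len), drop = FALSE]
  dim(post) <- c(n_ch, ep_len, n_ep)

  data <- aperm(post, c(3, 1, 2))                       # epochs x ch x samples
  times_ms <- window_ms[1] + (seq_len(ep_len) - 1) / fs * 1000
  .new_epoch_set(data, events, fs, times_ms, baseline_ms,
                 session$channel_names, session$kind)
}

#' Flag artifact epochs
#'
#' Flags epochs whose peak absolute amplitude on any channel exceeds
#' `abs_thresh` (reason `"abs"`), or whose per-channel peak absolute
#' amplitude deviates from the across-trial distribution of that channel
#' by more than `sd_mult` standard deviations (reason `"sd"`). The
#' across-trial mean and SD for an epoch are computed over the other
#' epochs (leave-one-out), so a single extreme epoch cannot mask itself
#' by inflating the spread. Flagged epochs stay in the set but are
#' excluded from all downstream statistics via the rejection mask.
#'
#' @param epochs An `epoch_set` with at least 2 epochs.
#' @param abs_thresh Absolute amplitude threshold in uV.
#' @param sd_mult Multiple of the across-trial SD.
#' @return The `epoch_set` with an updated rejection mask.
#' @export
reject_artifacts <- function(epochs, abs_thresh = 100, sd_mult = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ep <- n_epochs(epochs)
  if (n_ep < 2) stop("the SD rule needs at least 2 epochs")
  ## per-epoch, per-channel peak absolute amplitude (flattened running max
  ## over the sample dimension; epochs x channels is the fastest-varying
  ## block of the array layout)
  d <- dim(epochs$data)
  flat <- abs(epochs$data)
  dim(flat) <- c(d[1] * d[2], d[3])
  peak <- flat[, 1]
  for (s in seq_len(d[3])[-1]) peak <- pmax(peak, flat[, s])
  dim(peak) <- c(d[1], d[2])                             # epochs x channels
  bad_abs <- apply(peak, 1, max) > abs_thresh
  ## leave-one-out mean and SD per channel, from running sums
  S <- colSums(peak)
  Q <- colSums(peak^2)
  m_loo <- (matrix(S, n_ep, length(S), byrow = TRUE) - peak) / (n_ep - 1)
  if (n_ep > 2) {
    q_loo <- matrix(Q, n_ep, length(Q), byrow = TRUE) - peak^2
    v_loo <- pmax((q_loo - (n_ep - 1) * m_loo^2) / (n_ep - 2), 0)
  } else {
    v_loo <- matrix(0, n_ep, ncol(peak))
  }
  sd_loo <- sqrt(v_loo)
  bad_sd <- rowSums(abs(peak - m_loo) > sd_mult * sd_loo & sd_loo > 0) > 0
  new_bad <- (bad_abs | bad_sd) & !epochs$reject_mask
  epochs$reject_mask[new_bad] <- TRUE
  epochs$reject_reason[new_bad & bad_abs] <- "abs"
  epochs$reject_reason[new_bad & !bad_abs & bad_sd] <- "sd"
  epochs
}

#' Drop non-target epochs adjacent to targets
#'
#' In fast RSVP streams the epochs of the first `k` non-targets after a
#' target still contain the target-evoked response, so they are flagged
#' (reason `"adjacent"`) and excluded from analysis.
#'
#' @param epochs An RSVP `epoch_set` with stream-position metadata
#'   (`flash_id` = position within the stream).
#' @param k Number of following non-targets to drop per target.
#' @return The `epoch_set` with an updated rejection mask.
#' @export
drop_adjacent_nontargets <- function(epochs, k = 3) {
  stopifnot(inherits(epochs, "epoch_set"))
  ev <- epochs$events
  if (is.null(ev$trial_id) || is.null(ev$flash_id)) {
    stop("epochs lack stream-position metadata (trial_id / flash_id)")
  }
  tgt <- which(ev$stim_type == "target")
  bad <- logical(nrow(ev))
  for (i in tgt) {
    sel <- ev$trial_id == ev$trial_id[i] &
      ev$flash_id > ev$flash_id[i] &
      ev$flash_id <= ev$flash_id[i] + k &
      ev$stim_type == "nontarget"
    bad <- bad | sel
  }
  new_bad <- bad & !epochs$reject_mask
  epochs$reject_mask[new_bad] <- TRUE
  epochs$reject_reason[new_bad] <- "adjacent"
  epochs
}

#' Subset an epoch set to the retained (unflagged) epochs
#'
#' @param epochs An `epoch_set`.
#' @return An `epoch_set` containing only unflagged epochs; the counts of
#'   extracted/flagged epochs are kept in attributes `n_extracted` and
#'   `n_flagged`.
#' @export
retained_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- !epochs$reject_mask
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$labels <- epochs$labels[keep]
  out$events <- epochs$events[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out$reject_mask <- rep(FALSE, sum(keep))
  out$reject_reason <- rep(NA_character_, sum(keep))
  attr(out, "n_extracted") <- n_epochs(epochs)
  attr(out, "n_flagged") <- sum(!keep)
  out
}

#' Full preprocessing chain for one session
#'
#' Applies, in order: common average reference, zero-phase band-pass,
#' epoching with baseline correction, artifact rejection, and (for RSVP
#' sessions) removal of the `k_adjacent` non-targets following each
#' target. An identity hook is provided where component-based ocular
#' artifact correction would run on real recordings; the synthetic data
#' carry no ocular artifacts.
#'
#' @param session An `eeg_session`.
#' @param low,high,order Band-pass settings, see [bandpass_filter()].
#' @param abs_thresh,sd_mult Rejection settings, see [reject_artifacts()].
#' @param k_adjacent Adjacent non-targets to drop (RSVP only).
#' @param window_ms,baseline_ms Epoch windows, see [extract_epochs()].
#' @param ica_hook Function applied to the re-referenced, filtered
#'   session before epoching; defaults to the identity.
#' @return An `epoch_set` with rejection mask populated.
#' @export
preprocess_session <- function(session, low = 0.5, high = 10, order = 4,
                               abs_thresh = 100, sd_mult = 5,
                               k_adjacent = 3,
                               window_ms = c(0, 800),
                               baseline_ms = c(-200, 0),
                               ica_hook = identity) {
  session <- common_average_reference(session)
  session <- bandpass_filter(session, low = low, high = high, order = order)
  session <- ica_hook(session)
  epochs <- extract_epochs(session, window_ms = window_ms,
                           baseline_ms = baseline_ms)
  epochs <- reject_artifacts(epochs, abs_thresh = abs_thresh,
                             sd_mult = sd_mult)
  if (session$kind == "rsvp") {
    epochs <- drop_adjacent_nontargets(epochs, k = k_adjacent)
  }
  epochs
}
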