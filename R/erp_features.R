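## Per-subject RSVP features: T1 detection rate (X1), P300 amplitude (X2)
## and latency (X3) from per-trial peak extraction on the channel-averaged
## waveform, and their trial-level standard deviations (X4, X5).

#' Average epochs over a channel subset
#'
#' Sample-wise mean over the named channels, yielding one waveform per
#' epoch. The default subset (Fz, Cz, Pz, CP1, CP2) covers the
#' fronto-parietal attention network and raises the single-trial
#' signal-to-noise ratio.
#'
#' @param epochs An `epoch_set`.
#' @param channels Channel names to average.
#' @return Numeric matrix, epochs x samples, with attributes `times_ms`,
#'   `rate` and the originating events.
#' @export
channel_average <- function(epochs,
                            channels = c("Fz", "Cz", "Pz", "CP1", "CP2")) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- match(channels, epochs$channel_names)
  if (anyNA(idx)) {
    stop("missing channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  }
  sub <- epochs$data[, idx, , drop = FALSE]
  out <- colMeans(aperm(sub, c(2, 1, 3)))   # epochs x samples
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  attr(out, "times_ms") <- epochs$times_ms
  attr(out, "rate") <- epochs$rate
  attr(out, "events") <- epochs$events
  out
}

#' P300 peak amplitude and latency of one waveform
#'
#' The latency is the time of the maximum sample within the search window
#' (earliest sample on ties); the amplitude is the mean of the samples
#' within +/- `halfwindow_ms` of that peak, the averaging window clipped
#' at the epoch edges.
#'
#' @param waveform Single-channel sample vector.
#' @param times_ms Sample times in ms (same length as `waveform`).
#' @param search_ms Peak search window in ms, default `c(250, 750)`
#'   (the canonical P300 latency range).
#' @param halfwindow_ms Half width of the averaging window in ms.
#' @return Named numeric vector `c(amplitude, latency)`.
#' @export
p300_peak <- function(waveform, times_ms, search_ms = c(250, 750),
                      halfwindow_ms = 50) {
  if (all(is.na(waveform))) stop("all-NaN waveform")
  stopifnot(length(waveform) == length(times_ms))
  win <- which(times_ms >= search_ms[1] & times_ms <= search_ms[2])
  if (length(win) == 0) stop("search window outside the epoch")
  peak_rel <- which.max(waveform[win])    # earliest index on ties
  peak_idx <- win[peak_rel]
  latency <- times_ms[peak_idx]
  avg <- abs(times_ms - latency) <= halfwindow_ms
  c(amplitude = mean(waveform[avg]), latency = latency)
}

## Vectorized p300_peak over the rows of a waveform matrix.
.peak_matrix <- function(waves, times_ms, search_ms = c(250, 750),
                         halfwindow_ms = 50) {
  win <- which(times_ms >= search_ms[1] & times_ms <= search_ms[2])
  sub <- waves[, win, drop = FALSE]
  ## earliest maximum per row (max.col with ties.method "first")
  peak_rel <- max.col(sub, ties.method = "first")
  peak_idx <- win[peak_rel]
  latency <- times_ms[peak_idx]
  ## windowed mean around the peak via row-wise cumulative sums
  ## (computed as one matrix product with an upper-triangular ones matrix)
  n <- length(times_ms)
  tri <- matrix(0, n, n)
  tri[upper.tri(tri, diag = TRUE)] <- 1
  cs <- cbind(0, waves %*% tri)
  dt <- if (n > 1) times_ms[2] - times_ms[1] else 1
  half_n <- floor(halfwindow_ms / dt)
  lo <- pmax(peak_idx - half_n, 1L)
  hi <- pmin(peak_idx + half_n, n)
  rows <- seq_len(nrow(waves))
  amp <- (cs[cbind(rows, hi + 1L)] - cs[cbind(rows, lo)]) / (hi - lo + 1L)
  cbind(amplitude = amp, latency = latency)
}

#' Per-trial P300 peak series of the target epochs
#'
#' Runs [p300_peak()] on the channel-averaged waveform of every retained
#' target epoch.
#'
#' @param epochs A (preprocessed) RSVP `epoch_set`.
#' @param channels Channels to average, see [channel_average()].
#' @param search_ms,halfwindow_ms Passed to [p300_peak()].
#' @return A tibble with columns `trial_id`, `amplitude`, `latency`.
#' @export
trial_peak_series <- function(epochs,
                              channels = c("Fz", "Cz", "Pz", "CP1", "CP2"),
                              search_ms = c(250, 750), halfwindow_ms = 50) {
  ep <- retained_epochs(epochs)
  keep <- ep$labels == "target"
  ep$data <- ep$data[keep, , , drop = FALSE]
  ep$labels <- ep$labels[keep]
  ep$events <- ep$events[keep, , drop = FALSE]
  wave <- channel_average(ep, channels)
  pk <- .peak_matrix(wave, ep$times_ms, search_ms, halfwindow_ms)
  tibble::tibble(trial_id = ep$events$trial_id,
                 amplitude = pk[, "amplitude"],
                 latency = pk[, "latency"])
}

#' Trial-level variation of a per-trial ERP measure
#'
#' Sample standard deviation (n - 1 denominator) across trials.
#'
#' @param values Per-trial amplitudes (uV) or latencies (ms).
#' @return SD in the same units.
#' @export
trial_variation <- function(values) {
  if (length(values) < 2) stop("trial variation needs at least 2 trials")
  stats::sd(values)
}

#' RSVP T1 detection percentage
#'
#' Percentage of trials with a correct target report; a non-response
#' counts as a wrong answer.
#'
#' @param log Behavior log data frame with a logical `correct` column.
#' @return Percentage in \[0, 100\].
#' @export
rsvp_t1_percent <- function(log) {
  if (is.null(log) || nrow(log) == 0) stop("empty behavior log")
  100 * mean(log$correct)
}

#' Per-subject RSVP feature vector
#'
#' Computes the five features from a preprocessed RSVP epoch set and its
#' behavior log, optionally restricted to the first `first_n` trials:
#' X1 = T1% over trials 1..N; X2/X3 = mean over retained target trials of
#' the per-trial peak amplitude/latency on the channel-averaged waveform;
#' X4/X5 = trial-level SDs of the same per-trial series. If fewer than
#' `first_n` trials are retained, all remaining are used.
#'
#' @param rsvp_epochs A preprocessed RSVP `epoch_set`.
#' @param log Behavior log for the same session.
#' @param first_n Number of leading trials to use, or `Inf` for all.
#' @param channels Channels averaged for the ERP features.
#' @param series Optional precomputed [trial_peak_series()] (skips peak
#'   re-extraction, e.g. inside the trial-count sweep).
#' @return A one-row tibble: `t1_percent`, `p300_amplitude`,
#'   `p300_latency`, `amp_trial_sd`, `lat_trial_sd`, `n_trials_used`.
#' @export
subject_features <- function(rsvp_epochs, log, first_n = Inf,
                             channels = c("Fz", "Cz", "Pz", "CP1", "CP2"),
                             series = NULL) {
  if (is.null(series)) {
    series <- trial_peak_series(rsvp_epochs, channels)
  }
  series <- series[series$trial_id <= first_n, , drop = FALSE]
  log_n <- log[log$trial_id <= first_n, , drop = FALSE]
  n_used <- nrow(series)
  if (n_used < 5) {
    stop("fewer than 5 retained target trials; trial variations undefined")
  }
  tibble::tibble(
    t1_percent = rsvp_t1_percent(log_n),
    p300_amplitude = mean(series$amplitude),
    p300_latency = mean(series$latency),
    amp_trial_sd = trial_variation(series$amplitude),
    lat_trial_sd = trial_variation(series$latency),
    n_trials_used = n_used)
}

#' Per-channel RSVP ERP features
#'
#' Same per-trial peak extraction as [subject_features()], but on each
#' channel separately; used for correlation topographies and group scalp
#' patterns.
#'
#' @param rsvp_epochs A preprocessed RSVP `epoch_set`.
#' @param search_ms,halfwindow_ms Passed to [p300_peak()].
#' @return A tibble with one row per channel: `channel`,
#'   `p300_amplitude`, `p300_latency`, `amp_trial_sd`, `lat_trial_sd`.
#' @export
channel_features <- function(rsvp_epochs, search_ms = c(250, 750),
                             halfwindow_ms = 50) {
  ep <- retained_epochs(rsvp_epochs)
  keep <- ep$labels == "target"
  dat <- ep$data[keep, , , drop = FALSE]
  n_tr <- dim(dat)[1]; n_ch <- dim(dat)[2]; n_s <- dim(dat)[3]
  ## fold (trial, channel) into rows and extract all peaks in one pass
  waves <- matrix(dat, nrow = n_tr * n_ch, ncol = n_s)
  pk <- .peak_matrix(waves, ep$times_ms, search_ms, halfwindow_ms)
  amp <- matrix(pk[, "amplitude"], n_tr, n_ch)
  lat <- matrix(pk[, "latency"], n_tr, n_ch)
  tibble::tibble(channel = ep$channel_names,
                 p300_amplitude = colMeans(amp),
                 p300_latency = colMeans(lat),
                 amp_trial_sd = apply(amp, 2, stats::sd),
                 lat_trial_sd = apply(lat, 2, stats::sd))
}
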