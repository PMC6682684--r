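#' Standard 32-channel montage used by the simulator
#'
#' Channel labels of the 32-electrode 10-20 montage (BioSemi layout),
#' including the centro-parietal subset (Fz, Cz, Pz, CP1, CP2) used for
#' channel-averaged ERP features.
#'
#' @return Character vector of 32 channel names.
#' @export
montage_32 <- function() {
  c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
    "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
    "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
    "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz")
}

#' Default spatial gain profile for the P300 source
#'
#' Per-channel unitless weights applied to the P300 template (and to the
#' background noise) when projecting onto the montage. The gain is maximal
#' (1.0) over the centro-parietal channels where the P3b component is
#' largest, and decays to 0.3 at the frontal/temporal/occipital periphery.
#'
#' @param channel_names Channel labels; defaults to [montage_32()].
#' @return Named numeric vector of gains in (0, 1].
#' @export
default_topo_gain <- function(channel_names = montage_32()) {
  gain_table <- c(
    Pz = 1.0, CP1 = 1.0, CP2 = 1.0, Cz = 1.0,
    P3 = 0.85, P4 = 0.85, C3 = 0.8, C4 = 0.8,
    FC1 = 0.75, FC2 = 0.75, Fz = 0.7, CP5 = 0.7, CP6 = 0.7,
    PO3 = 0.6, PO4 = 0.6, FC5 = 0.55, FC6 = 0.55,
    F3 = 0.5, F4 = 0.5, Oz = 0.5,
    P7 = 0.4, P8 = 0.4, O1 = 0.4, O2 = 0.4,
    Fp1 = 0.3, Fp2 = 0.3, AF3 = 0.3, AF4 = 0.3,
    F7 = 0.3, F8 = 0.3, T7 = 0.3, T8 = 0.3
  )
  out <- gain_table[channel_names]
  if (anyNA(out)) {
    out[is.na(out)] <- 0.3
  }
  names(out) <- channel_names
  out
}

#' Symbols of the 6 x 6 speller matrix
#'
#' Letters A-Z, digits 1-9 and space ("_"), laid out row-major.
#'
#' @return Character vector of length 36.
#' @export
speller_matrix <- function() {
  c(LETTERS, as.character(1:9), "_")
}

#' Paradigm configuration
#'
#' Bundles the stimulus-timing parameters of the RSVP task (21-character
#' streams at 10 Hz, one target per trial, 40 trials) and the 6 x 6 matrix
#' speller (125 ms flash, 62.5 ms inter-stimulus interval, 15 repetitions
#' of 12 row/column flashes per character).
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param n_channels Number of EEG channels (must match `channel_names`).
#' @param channel_names Channel labels.
#' @param rsvp_rate RSVP presentation rate in Hz.
#' @param rsvp_stream_len Characters per RSVP stream.
#' @param rsvp_trials Number of RSVP trials.
#' @param response_window Seconds allotted for the keyboard response after
#'   each stream.
#' @param flash_ms Speller flash duration (ms).
#' @param isi_ms Speller inter-stimulus interval (ms); flash + ISI is the
#'   stimulus-onset asynchrony (187.5 ms by default).
#' @param repetitions Speller repetitions (sequences of 12 flashes) per
#'   character.
#' @param calib_words Calibration words.
#' @param test_words Test words.
#' @return An object of class `paradigm_config`.
#' @export
paradigm_config <- function(sampling_rate = 512,
                            n_channels = 32,
                            channel_names = montage_32(),
                            rsvp_rate = 10,
                            rsvp_stream_len = 21,
                            rsvp_trials = 40,
                            response_window = 5,
                            flash_ms = 125,
                            isi_ms = 62.5,
                            repetitions = 15,
                            calib_words = c("BRAIN", "POWER"),
                            test_words = c("SUBJECT", "NEURONS",
                                           "IMAGINE", "QUALITY")) {
  stopifnot(sampling_rate > 0, n_channels >= 2,
            length(channel_names) == n_channels,
            rsvp_rate > 0, rsvp_stream_len >= 2,
            rsvp_trials >= 1, response_window >= 0,
            flash_ms > 0, isi_ms >= 0, repetitions >= 1)
  cfg <- list(
    sampling_rate = sampling_rate,
    n_channels = n_channels,
    channel_names = channel_names,
    rsvp_rate = rsvp_rate,
    rsvp_stream_len = rsvp_stream_len,
    rsvp_trials = rsvp_trials,
    response_window = response_window,
    matrix_size = 6,
    flash_ms = flash_ms,
    isi_ms = isi_ms,
    soa_ms = flash_ms + isi_ms,
    repetitions = repetitions,
    calib_words = calib_words,
    test_words = test_words
  )
  class(cfg) <- "paradigm_config"
  cfg
}

#' @export
print.paradigm_config <- function(x, ...) {
  cat("Paradigm configuration\n")
  cat(sprintf("  EEG: %d channels @ %g Hz\n", x$n_channels, x$sampling_rate))
  cat(sprintf("  RSVP: %d trials, %d-character streams @ %g Hz, %g s response window\n",
              x$rsvp_trials, x$rsvp_stream_len, x$rsvp_rate, x$response_window))
  cat(sprintf("  Speller: 6x6 matrix, %g ms flash + %g ms ISI (SOA %g ms), %d repetitions\n",
              x$flash_ms, x$isi_ms, x$soa_ms, x$repetitions))
  invisible(x)
}
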