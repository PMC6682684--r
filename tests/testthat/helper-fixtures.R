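## Shared builders for small in-code fixtures.

## A subject profile with a derived simulation seed attached.
quick_profile <- function(seed = 1, amp_mean = 2.88, amp_sd = 1,
                          lat_mean = 455.8, lat_sd = 60, t1_prob = 0.92,
                          noise_sd = 4) {
  prof <- subject_profile(sprintf("t%03d", seed), amp_mean = amp_mean,
                          amp_sd = amp_sd, lat_mean = lat_mean,
                          lat_sd = lat_sd, t1_prob = t1_prob,
                          noise_sd = noise_sd)
  attr(prof, "sim_seed") <- 10000 + seed
  prof
}

## Small paradigm for fast unit tests.
quick_config <- function(...) {
  paradigm_config(sampling_rate = 128, rsvp_trials = 8,
                  response_window = 0.5, repetitions = 2,
                  test_words = "BRAIN", ...)
}

## Wrap a raw channels x samples matrix as a session.
toy_session <- function(signal, rate = 512, kind = "rsvp",
                        events = NULL) {
  n_ch <- nrow(signal)
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), stim_type = character(0),
                         trial_id = integer(0), flash_id = integer(0),
                         character = character(0))
  }
  structure(list(signal = signal, rate = rate,
                 channel_names = paste0("ch", seq_len(n_ch)),
                 events = events, kind = kind),
            class = "eeg_session")
}

## Assemble an epoch_set directly from a data array and event table.
toy_epochs <- function(data, events, rate = 512,
                       channel_names = paste0("ch", seq_len(dim(data)[2])),
                       kind = "rsvp") {
  times_ms <- (seq_len(dim(data)[3]) - 1) / rate * 1000
  structure(
    list(data = data, labels = events$stim_type, events = events,
         rate = rate, times_ms = times_ms, baseline_ms = c(-200, 0),
         channel_names = channel_names, kind = kind,
         reject_mask = rep(FALSE, dim(data)[1]),
         reject_reason = rep(NA_character_, dim(data)[1])),
    class = "epoch_set")
}

## Analytic magnitude response of the zero-phase Butterworth cascade:
## |H_hp|^2 * |H_lp|^2 at frequency f (each section order `order`,
## squared because the filter runs forward and backward).
cascade_gain <- function(f, low = 0.5, high = 10, order = 4) {
  hp <- 1 / (1 + (low / f)^(2 * order))
  lp <- 1 / (1 + (f / high)^(2 * order))
  hp * lp
}
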