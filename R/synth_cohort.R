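## Synthetic cohort generation: latent subject profiles and continuous
## multichannel RSVP / matrix-speller recordings with known ground truth.

#' Subject profile
#'
#' Latent simulator parameters for one subject: the mean and trial-level
#' standard deviation of the P300 amplitude (uV) and latency (ms), the
#' probability of a correct T1 report in the RSVP task, the broadband
#' background-noise level (uV), and the per-channel spatial gain.
#'
#' @param subject_id Subject identifier.
#' @param amp_mean Mean single-trial P300 amplitude in uV (> 0).
#' @param amp_sd Trial-level SD of the P300 amplitude in uV (>= 0).
#' @param lat_mean Mean P300 latency in ms post-onset.
#' @param lat_sd Trial-level SD of the P300 latency in ms (>= 0).
#' @param t1_prob Probability of a correct T1 report, in \[0, 1\].
#' @param noise_sd Background noise SD in uV (> 0), at unit spatial gain.
#' @param topo_gain Named per-channel gain vector; defaults to
#'   [default_topo_gain()].
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, amp_mean, amp_sd, lat_mean, lat_sd,
                            t1_prob, noise_sd,
                            topo_gain = default_topo_gain()) {
  stopifnot(amp_mean > 0, amp_sd >= 0, lat_sd >= 0,
            t1_prob >= 0, t1_prob <= 1, noise_sd > 0,
            all(topo_gain > 0))
  structure(
    list(subject_id = as.character(subject_id),
         amp_mean = amp_mean, amp_sd = amp_sd,
         lat_mean = lat_mean, lat_sd = lat_sd,
         t1_prob = t1_prob, noise_sd = noise_sd,
         topo_gain = topo_gain),
    class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "Subject %s: P300 %.2f +/- %.2f uV @ %.0f +/- %.0f ms, T1 p=%.2f, noise %.1f uV\n",
    x$subject_id, x$amp_mean, x$amp_sd, x$lat_mean, x$lat_sd,
    x$t1_prob, x$noise_sd))
  invisible(x)
}

#' Population distribution of subject profiles
#'
#' Describes the across-subject distribution each latent trait is drawn
#' from: a truncated normal with mean `mean`, SD `sd` and bounds
#' `lower`/`upper`. The defaults place the P300 amplitude at
#' 2.88 +/- 0.92 uV and the latency at 455.8 +/- 65.6 ms across subjects,
#' with a T1 detection probability of 0.92 +/- 0.06. Trial-level jitter
#' SDs and the noise level are set to values typical of band-limited
#' scalp EEG (see the methods vignette).
#'
#' A single latent "engagement" factor couples the traits: each trait is
#' drawn as `mu + sd * (rho * g + sqrt(1 - rho^2) * e)` with shared
#' `g ~ N(0,1)` and independent `e ~ N(0,1)`. By default the T1
#' detection probability loads at +0.7, the latency jitter at -0.7 and
#' the P300 amplitude at +0.4 on this factor: attentive subjects report
#' targets more reliably, lock their P300 more tightly, and produce
#' somewhat larger responses, so the behavioral channel carries
#' predictive information independent of the EEG noise level. Set all
#' `rho = 0` for fully independent traits.
#'
#' @param amp_mean,amp_sd,lat_mean,lat_sd,t1_prob,noise_sd Lists with
#'   elements `mean`, `sd`, `lower`, `upper` and optionally `rho`
#'   (loading on the shared engagement factor).
#' @return An object of class `cohort_population`.
#' @export
cohort_population <- function(
    amp_mean = list(mean = 2.88, sd = 0.92, lower = 0.5, upper = Inf,
                    rho = 0.4),
    amp_sd   = list(mean = 1.0,  sd = 0.3,  lower = 0.1, upper = Inf),
    lat_mean = list(mean = 455.8, sd = 65.6, lower = 300, upper = 650),
    lat_sd   = list(mean = 60,   sd = 12,   lower = 5,   upper = Inf,
                    rho = -0.7),
    t1_prob  = list(mean = 0.92, sd = 0.06, lower = 0.5, upper = 1,
                    rho = 0.8),
    noise_sd = list(mean = 4,    sd = 0.6,  lower = 2.5, upper = 6)) {
  pop <- list(amp_mean = amp_mean, amp_sd = amp_sd, lat_mean = lat_mean,
              lat_sd = lat_sd, t1_prob = t1_prob, noise_sd = noise_sd)
  for (nm in names(pop)) {
    spec <- pop[[nm]]
    if (!all(c("mean", "sd") %in% names(spec))) {
      stop("population entry '", nm, "' must have elements 'mean' and 'sd'")
    }
    if (spec$sd < 0) stop("population entry '", nm, "' has negative sd")
    if (is.null(spec$lower)) pop[[nm]]$lower <- -Inf
    if (is.null(spec$upper)) pop[[nm]]$upper <- Inf
    if (is.null(spec$rho)) pop[[nm]]$rho <- 0
    if (abs(pop[[nm]]$rho) > 1) stop("|rho| must be <= 1 for '", nm, "'")
  }
  class(pop) <- "cohort_population"
  pop
}

## Truncated-normal draw given standard-normal deviates, by clipping the
## untruncated draw to the bounds (mass at the bounds rather than
## renormalised; adequate for the mild truncations used here).
.trait_draw <- function(spec, z) {
  x <- spec$mean + spec$sd * z
  pmin(pmax(x, spec$lower), spec$upper)
}

#' Sample a cohort of subject profiles
#'
#' Draws `n_subjects` latent profiles from a population specification,
#' reproducibly from `seed`. Per-subject simulation seeds are derived from
#' the same seed, so downstream session generation is reproducible too.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param population A [cohort_population()] specification.
#' @param seed Integer seed.
#' @param channel_names Montage the spatial gain is defined over.
#' @return List of [subject_profile()] objects; each carries a derived
#'   `sim_seed` attribute used by the session generators.
#' @export
sample_cohort <- function(n_subjects, population = cohort_population(),
                          seed, channel_names = montage_32()) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("n_subjects must be a positive count")
  }
  if (missing(seed)) stop("a seed is required")
  if (!inherits(population, "cohort_population")) {
    population <- do.call(cohort_population, population)
  }
  n <- as.integer(n_subjects)
  set.seed(as.integer(seed))
  g <- stats::rnorm(n)  # shared engagement factor
  traits <- lapply(population, function(spec) {
    e <- stats::rnorm(n)
    z <- spec$rho * g + sqrt(1 - spec$rho^2) * e
    .trait_draw(spec, z)
  })
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n)
  gain <- default_topo_gain(channel_names)
  lapply(seq_len(n), function(i) {
    prof <- subject_profile(
      subject_id = sprintf("s%02d", i),
      amp_mean = traits$amp_mean[i], amp_sd = traits$amp_sd[i],
      lat_mean = traits$lat_mean[i], lat_sd = traits$lat_sd[i],
      t1_prob = traits$t1_prob[i], noise_sd = traits$noise_sd[i],
      topo_gain = gain)
    attr(prof, "sim_seed") <- sim_seeds[i]
    prof
  })
}

#' Gaussian P300 template waveform
#'
#' Single-channel surrogate of the P300 deflection: a unimodal positive
#' Gaussian bump peaking exactly at the sample nearest `latency`, with
#' peak value `amplitude`, hard-zeroed beyond 3 widths from the peak.
#'
#' @param amplitude Peak amplitude in uV (>= 0).
#' @param latency Peak latency in ms from template start.
#' @param width Full width at half maximum in ms (> 0); the Gaussian
#'   sigma is `width / 2.355`.
#' @param rate Sampling rate in Hz.
#' @param span_ms Template support in ms, default `c(0, 800)`.
#' @return Numeric vector of `floor(diff(span_ms) / 1000 * rate)` samples.
#' @export
p300_template <- function(amplitude, latency, width = 100, rate = 512,
                          span_ms = c(0, 800)) {
  if (width <= 0) stop("width must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  n <- floor(diff(span_ms) / 1000 * rate)
  t_ms <- span_ms[1] + (seq_len(n) - 1) / rate * 1000
  ## snap the peak onto the sample grid so the maximum equals `amplitude`
  peak_idx <- round((latency - span_ms[1]) / 1000 * rate) + 1
  peak_idx <- min(max(peak_idx, 1L), n)
  sigma <- width / 2.355
  d <- t_ms - t_ms[peak_idx]
  w <- amplitude * exp(-d^2 / (2 * sigma^2))
  w[abs(d) > 3 * width] <- 0
  w
}

## Band-limited background noise: AR(1) (phi = 0.95) plus white noise,
## mixed 80/20 in power and scaled to unit SD analytically, one channel
## per row. 1/f-like spectrum typical of spontaneous EEG.
.eeg_noise <- function(n_channels, n_samples, ar = 0.95,
                       ar_power = 0.8) {
  ar_gain <- sqrt(1 - ar^2)          # unit-variance AR(1) innovation scale
  out <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    e <- stats::rnorm(n_samples)
    a <- as.numeric(stats::filter(e, ar, method = "recursive")) * ar_gain
    w <- stats::rnorm(n_samples)
    out[ch, ] <- sqrt(ar_power) * a + sqrt(1 - ar_power) * w
  }
  out
}

.draw_trial_amp <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)

.draw_trial_lat <- function(n, mean, sd, lower = 100, upper = 780) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

.new_session <- function(signal, rate, channel_names, events, kind) {
  events <- events[order(events$sample), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(signal = signal, rate = rate,
                 channel_names = channel_names,
                 events = events, kind = kind),
            class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("EEG session (%s): %d channels x %d samples @ %g Hz, %d events (%d targets)\n",
              x$kind, nrow(x$signal), ncol(x$signal), x$rate,
              nrow(x$events), sum(x$events$stim_type == "target")))
  invisible(x)
}

## Channels whose average defines the observed ERP amplitude scale.
ERP_CHANNELS <- c("Fz", "Cz", "Pz", "CP1", "CP2")

## The profile's amplitude parameters are expressed in observed units:
## the channel-averaged (Fz/Cz/Pz/CP1/CP2), common-average-referenced
## amplitude the standard pipeline reports. Re-referencing subtracts the
## montage-mean gain, so the injected template is scaled up by the
## inverse of the net gain to make one latent microvolt one observed
## microvolt.
.erp_gain_scale <- function(topo_gain) {
  erp <- ERP_CHANNELS[ERP_CHANNELS %in% names(topo_gain)]
  net <- mean(topo_gain[erp]) - mean(topo_gain)
  if (net <= 0.05) stop("degenerate spatial gain: ERP channels must carry
    more gain than the montage average")
  1 / net
}

## Add the per-event P300 template into the continuous signal, projected
## through the spatial gain. `onsets` are 0-based sample indices.
.add_templates <- function(signal, onsets, amps, lats, topo_gain, rate,
                           width = 100) {
  amps <- amps * .erp_gain_scale(topo_gain)
  tmpl_len <- floor(0.8 * rate)
  for (i in seq_along(onsets)) {
    if (amps[i] <= 0) next
    w <- p300_template(amps[i], lats[i], width = width, rate = rate)
    cols <- onsets[i] + seq_len(tmpl_len)
    signal[, cols] <- signal[, cols] + outer(topo_gain, w)
  }
  signal
}

#' Generate one synthetic RSVP session
#'
#' Builds a continuous recording of `rsvp_trials` streams of
#' `rsvp_stream_len` characters at `rsvp_rate` Hz, one green target per
#' stream at a uniformly random position 5-17. Target onsets receive the
#' P300 template with per-trial amplitude drawn from
#' `Normal(amp_mean, amp_sd)` truncated at 0 and latency from
#' `Normal(lat_mean, lat_sd)` clipped to the epoch; non-targets evoke no
#' template. Background noise is an AR(1)-plus-white mixture with SD
#' `noise_sd`, scaled per channel by the spatial gain. The behavior log
#' marks each trial correct with probability `t1_prob`; wrong trials are
#' split between misreports and non-responses.
#'
#' @param profile A [subject_profile()].
#' @param config A [paradigm_config()].
#' @param seed Integer seed; defaults to the profile's derived `sim_seed`.
#' @return List with elements `session` (class `eeg_session`) and
#'   `behavior` (data frame: trial_id, true_target, response, correct).
#' @export
generate_rsvp_session <- function(profile, config = paradigm_config(),
                                  seed = attr(profile, "sim_seed")) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "paradigm_config"))
  if (is.null(seed)) stop("a seed is required")
  if (config$rsvp_stream_len < 2) stop("stream length must be >= 2")
  set.seed(as.integer(seed))

  fs <- config$sampling_rate
  n_tr <- config$rsvp_trials
  slen <- config$rsvp_stream_len
  stream_dur <- slen / config$rsvp_rate
  trial_period <- stream_dur + config$response_window
  pad <- 1                                      # seconds before/after
  total_s <- 2 * pad + n_tr * trial_period
  n_samp <- ceiling(total_s * fs)

  ## stimulus schedule
  pos_hi <- min(slen - 3, 17)                   # leave >= 3 trailing non-targets
  pos_lo <- min(5, pos_hi)
  target_pos <- sample(pos_lo:pos_hi, n_tr, replace = TRUE)
  trial_id <- rep(seq_len(n_tr), each = slen)
  stream_pos <- rep(seq_len(slen), times = n_tr)
  onset_s <- pad + (trial_id - 1) * trial_period +
    (stream_pos - 1) / config$rsvp_rate
  onset_sample <- round(onset_s * fs)
  is_target <- stream_pos == target_pos[trial_id]
  chars <- unlist(lapply(seq_len(n_tr), function(t)
    sample(LETTERS, slen, replace = FALSE)))

  epoch_len <- floor(0.8 * fs)
  if (max(onset_sample) + epoch_len >= n_samp) {
    stop("a target epoch would exceed the recording")
  }

  ## signal
  signal <- .eeg_noise(config$n_channels, n_samp) *
    (profile$noise_sd * profile$topo_gain)
  amps <- .draw_trial_amp(n_tr, profile$amp_mean, profile$amp_sd)
  lats <- .draw_trial_lat(n_tr, profile$lat_mean, profile$lat_sd)
  signal <- .add_templates(signal, onset_sample[is_target], amps, lats,
                           profile$topo_gain, fs)

  events <- data.frame(
    sample = onset_sample,
    stim_type = ifelse(is_target, "target", "nontarget"),
    trial_id = trial_id,
    flash_id = stream_pos,
    character = chars,
    stringsAsFactors = FALSE)

  ## behavior log
  correct <- stats::runif(n_tr) < profile$t1_prob
  true_target <- chars[is_target][order(trial_id[is_target])]
  response <- true_target
  wrong <- which(!correct)
  for (i in wrong) {
    response[i] <- if (stats::runif(1) < 0.5) NA_character_ else
      sample(setdiff(LETTERS, true_target[i]), 1)
  }
  behavior <- data.frame(trial_id = seq_len(n_tr),
                         true_target = true_target,
                         response = response,
                         correct = correct,
                         stringsAsFactors = FALSE)

  list(session = .new_session(signal, fs, config$channel_names, events,
                              kind = "rsvp"),
       behavior = behavior)
}

#' Generate one synthetic matrix-speller session
#'
#' For each character of `words`, simulates `repetitions` sequences of 12
#' row/column flashes in random order at the configured SOA. The two
#' flashes per sequence containing the target character (its row and its
#' column) receive the P300 template with per-flash jittered amplitude
#' and latency; event labels record the target/non-target ground truth.
#'
#' Attentional lapses are modelled through the profile's `t1_prob`: each
#' target flash is unattended with probability `2 * (1 - t1_prob)`
#' (capped at 0.6), and an unattended flash evokes no P300. The lapse
#' process that produces missed T1 reports in the brief RSVP streams
#' recurs - amplified by the long monotonous flash sequences - in the
#' speller task, so the behavioral detection rate carries information
#' about speller performance beyond what the RSVP ERP measures capture.
#'
#' @param profile A [subject_profile()].
#' @param config A [paradigm_config()].
#' @param words Character vector of words to spell, drawn from the 36
#'   speller symbols.
#' @param seed Integer seed; defaults to the profile's `sim_seed` plus 1.
#' @param kind Session kind label (`"speller_test"` or `"speller_calib"`).
#' @return An `eeg_session`.
#' @export
generate_speller_session <- function(profile, config = paradigm_config(),
                                     words = config$test_words,
                                     seed = attr(profile, "sim_seed") + 1,
                                     kind = "speller_test") {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "paradigm_config"))
  if (is.null(seed)) stop("a seed is required")
  symbols <- speller_matrix()
  spell <- strsplit(paste(words, collapse = ""), "")[[1]]
  if (!all(spell %in% symbols)) {
    stop("word contains a symbol absent from the 6x6 matrix: ",
         paste(setdiff(spell, symbols), collapse = ", "))
  }
  set.seed(as.integer(seed))

  fs <- config$sampling_rate
  soa_s <- config$soa_ms / 1000
  n_char <- length(spell)
  reps <- config$repetitions
  flashes_per_char <- reps * 12
  char_dur <- flashes_per_char * soa_s
  gap <- 2                                      # seconds between characters
  pad <- 1
  total_s <- 2 * pad + n_char * char_dur + (n_char - 1) * gap
  n_samp <- ceiling(total_s * fs)

  ## flash schedule: flash_id 1..6 = rows, 7..12 = columns
  sym_idx <- match(spell, symbols) - 1L
  target_row <- sym_idx %/% 6 + 1L
  target_col <- sym_idx %% 6 + 7L
  flash_id <- unlist(lapply(seq_len(n_char), function(i)
    unlist(lapply(seq_len(reps), function(r) sample.int(12)))))
  char_id <- rep(seq_len(n_char), each = flashes_per_char)
  within_char <- unlist(lapply(seq_len(n_char), function(i)
    seq_len(flashes_per_char)))
  onset_s <- pad + (char_id - 1) * (char_dur + gap) +
    (within_char - 1) * soa_s
  onset_sample <- round(onset_s * fs)
  is_target <- flash_id == target_row[char_id] |
    flash_id == target_col[char_id]

  epoch_len <- floor(0.8 * fs)
  if (max(onset_sample) + epoch_len >= n_samp) {
    stop("a flash epoch would exceed the recording")
  }

  signal <- .eeg_noise(config$n_channels, n_samp) *
    (profile$noise_sd * profile$topo_gain)
  n_t <- sum(is_target)
  amps <- .draw_trial_amp(n_t, profile$amp_mean, profile$amp_sd)
  lapse_rate <- min(2 * (1 - profile$t1_prob), 0.6)
  attended <- stats::runif(n_t) >= lapse_rate
  amps <- amps * attended
  lats <- .draw_trial_lat(n_t, profile$lat_mean, profile$lat_sd)
  signal <- .add_templates(signal, onset_sample[is_target], amps, lats,
                           profile$topo_gain, fs)

  events <- data.frame(
    sample = onset_sample,
    stim_type = ifelse(is_target, "target", "nontarget"),
    trial_id = char_id,
    flash_id = flash_id,
    character = spell[char_id],
    stringsAsFactors = FALSE)

  .new_session(signal, fs, config$channel_names, events, kind = kind)
}
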