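test_that("channel averaging equals the direct mean", {
  set.seed(21)
  data <- array(rnorm(6 * 5 * 40), c(6, 5, 40))
  ev <- data.frame(sample = 1:6 * 100, stim_type = "target",
                   trial_id = 1:6, flash_id = 5, character = "A")
  ep <- toy_epochs(data, ev, channel_names = c("Fz", "Cz", "Pz",
                                               "CP1", "CP2"))
  avg <- channel_average(ep)
  ## direct-summation oracle
  for (e in c(1, 4)) {
    for (s in c(1, 20, 40)) {
      expect_equal(avg[e, s], mean(data[e, , s]))
    }
  }

  ## identical channels pass through unchanged
  same <- array(rep(data[, 1, ], times = 5), c(6, 40, 5))
  ep2 <- toy_epochs(aperm(same, c(1, 3, 2)), ev,
                    channel_names = c("Fz", "Cz", "Pz", "CP1", "CP2"))
  expect_equal(channel_average(ep2)[1, ], data[1, 1, ])

  ## constant channels valued 1..5 average to 3
  const <- array(rep(1:5, each = 6), c(6, 5, 40))
  ep3 <- toy_epochs(const, ev, channel_names = c("Fz", "Cz", "Pz",
                                                 "CP1", "CP2"))
  expect_true(all(channel_average(ep3) == 3))

  expect_error(channel_average(ep, channels = c("Fz", "XX")), "missing")
})

test_that("peak extraction follows the windowed-mean definition", {
  fs <- 512
  times <- (0:408) / fs * 1000

  ## constant epoch: tie broken toward the search-window start
  pk <- p300_peak(rep(2.5, 409), times)
  expect_equal(unname(pk["amplitude"]), 2.5)
  expect_equal(unname(pk["latency"]), times[times >= 250][1])

  ## noiseless template, peak 5 uV at 400 ms: latency recovered on the
  ## grid, amplitude equals the brute-force +/-50 ms index-window mean
  w <- p300_template(5, 400, width = 100, rate = fs)
  pk2 <- p300_peak(w, times)
  expect_equal(unname(pk2["latency"]), times[round(0.4 * fs) + 1])
  idx <- which(abs(times - pk2["latency"]) <= 50)
  expect_equal(unname(pk2["amplitude"]), mean(w[idx]))
  expect_lt(unname(pk2["amplitude"]), 5)  # window mean below the peak

  ## two equal maxima: the earlier one wins
  v <- rep(0, 409)
  v[round(0.3 * fs) + 1] <- 1
  v[round(0.5 * fs) + 1] <- 1
  expect_equal(unname(p300_peak(v, times)["latency"]),
               times[round(0.3 * fs) + 1])

  ## vectorized path agrees with the scalar definition
  set.seed(3)
  waves <- matrix(rnorm(20 * 409), 20)
  pkm <- rsvp300:::.peak_matrix(waves, times)
  for (i in c(1, 7, 20)) {
    expect_equal(pkm[i, ], p300_peak(waves[i, ], times))
  }

  expect_error(p300_peak(rep(NA_real_, 409), times), "NaN")
})

test_that("trial variation is the sample SD with its invariances", {
  expect_equal(trial_variation(c(4, 4, 4, 4)), 0)
  expect_equal(trial_variation(c(1, 3)), sqrt(2))
  set.seed(5)
  v <- rnorm(20)
  expect_equal(trial_variation(v + 17.3), trial_variation(v))
  expect_error(trial_variation(3), "2 trials")
})

test_that("T1% counts non-responses as wrong", {
  mk <- function(correct) data.frame(trial_id = seq_along(correct),
                                     correct = correct)
  expect_equal(rsvp_t1_percent(mk(rep(TRUE, 40))), 100)
  expect_equal(rsvp_t1_percent(mk(c(rep(TRUE, 30), rep(FALSE, 10)))), 75)
  expect_equal(rsvp_t1_percent(mk(rep(FALSE, 10))), 0)
  expect_error(rsvp_t1_percent(mk(logical(0))), "empty")
})

test_that("subject features behave in the noiseless limit and count trials", {
  cfg <- paradigm_config(sampling_rate = 128, rsvp_trials = 8,
                         response_window = 0.5)
  prof <- subject_profile("nz", amp_mean = 4, amp_sd = 0, lat_mean = 450,
                          lat_sd = 0, t1_prob = 1, noise_sd = 1e-9)
  out <- generate_rsvp_session(prof, cfg, seed = 6)
  ep <- preprocess_session(out$session)
  fe <- subject_features(ep, out$behavior)
  expect_equal(fe$lat_trial_sd, 0)
  ## the slow high-pass recovery of neighbouring targets leaks a little
  ## trial-to-trial amplitude variation even without injected jitter, so
  ## "zero" here means far below any physiological variation (~2 uV)
  expect_lt(fe$amp_trial_sd, 0.05)
  expect_equal(fe$t1_percent, 100)
  expect_equal(fe$n_trials_used, 8)

  ## requesting more trials than retained uses all remaining
  fe2 <- subject_features(ep, out$behavior, first_n = 40)
  expect_equal(fe2$n_trials_used, 8)
  fe3 <- subject_features(ep, out$behavior, first_n = 6)
  expect_equal(fe3$n_trials_used, 6)

  expect_error(subject_features(ep, out$behavior, first_n = 3),
               "fewer than 5")
})

test_that("latency jitter is recovered at low noise", {
  cfg <- paradigm_config(sampling_rate = 128, response_window = 0.5)
  x5 <- vapply(1:5, function(s) {
    prof <- quick_profile(s, lat_sd = 60, noise_sd = 0.5)
    out <- generate_rsvp_session(prof, cfg)
    ep <- preprocess_session(out$session)
    subject_features(ep, out$behavior)$lat_trial_sd
  }, 0)
  expect_lt(abs(mean(x5) - 60) / 60, 0.25)
})

test_that("measured P300 amplitude increases with injected amplitude", {
  cfg <- paradigm_config(sampling_rate = 128, rsvp_trials = 10,
                         response_window = 0.5)
  amps <- c(1, 2, 3.5, 5, 7)
  x2 <- vapply(seq_along(amps), function(i) {
    prof <- quick_profile(100 + i, amp_mean = amps[i], amp_sd = 0.5)
    out <- generate_rsvp_session(prof, cfg)
    ep <- preprocess_session(out$session)
    subject_features(ep, out$behavior)$p300_amplitude
  }, 0)
  expect_true(all(diff(x2) > 0))
})
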