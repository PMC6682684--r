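test_that("common average reference zeroes the channel mean", {
  ses <- toy_session(matrix(c(3, 1), nrow = 2, ncol = 10))
  out <- common_average_reference(ses)
  expect_equal(out$signal, matrix(c(1, -1), nrow = 2, ncol = 10))
  ## idempotence on an already zero-mean montage
  expect_equal(common_average_reference(out)$signal, out$signal)

  set.seed(42)
  big <- toy_session(matrix(rnorm(32 * 500), nrow = 32))
  ref <- common_average_reference(big)
  ## direct-summation oracle
  for (j in c(1, 250, 500)) {
    expect_lt(abs(sum(ref$signal[, j]) / 32), 1e-10)
  }
  expect_lt(max(abs(colMeans(ref$signal))), 1e-10)

  expect_error(common_average_reference(toy_session(matrix(1, 1, 10))),
               "2 channels")
})

test_that("band-pass matches the analytic Butterworth cascade response", {
  fs <- 512
  t <- (0:(20 * fs - 1)) / fs
  mk <- function(x) toy_session(rbind(x, x), rate = fs)
  mid <- (8 * fs):(12 * fs)              # steady-state section

  ## DC is rejected by the 0.5 Hz high-pass
  dc <- bandpass_filter(mk(rep(3, length(t))))
  expect_lt(max(abs(dc$signal[1, mid])), 1e-4)

  ## passband sinusoid preserved within 5%, and within 2% of the
  ## analytic |H|^2 of the zero-phase cascade
  for (f in c(2, 5)) {
    y <- bandpass_filter(mk(sin(2 * pi * f * t)))$signal[1, mid]
    amp <- max(abs(y))
    expect_gt(amp, 0.95)
    expect_lt(amp, 1.05)
    expect_lt(abs(amp - cascade_gain(f)), 0.02)
  }

  ## stopband attenuation
  y50 <- bandpass_filter(mk(sin(2 * pi * 50 * t)))$signal[1, mid]
  expect_lt(max(abs(y50)), 0.01)
  expect_lt(abs(max(abs(y50)) - cascade_gain(50)), 0.005)

  expect_error(bandpass_filter(mk(t), low = 10, high = 5), "cut-offs")
  expect_error(bandpass_filter(mk(t), high = 300), "cut-offs")
})

test_that("epoch extraction uses the documented sample conventions", {
  fs <- 512
  n <- 4 * fs
  set.seed(7)
  sig <- matrix(rnorm(2 * n), nrow = 2)
  ev <- data.frame(sample = c(600, 1200), stim_type = c("target", "nontarget"),
                   trial_id = 1:2, flash_id = c(10, 11),
                   character = c("A", "B"))
  ses <- toy_session(sig, rate = fs, events = ev)
  ep <- extract_epochs(ses)
  expect_equal(dim(ep$data), c(2, 2, 409))       # 512 Hz x 0.8 s -> 409
  expect_equal(ep$labels, c("target", "nontarget"))

  ## direct-summation oracle: epoch = slice minus its own 102-sample
  ## pre-onset baseline mean
  for (e in 1:2) {
    on <- ev$sample[e]
    for (ch in 1:2) {
      base <- mean(sig[ch, (on - 102):(on - 1) + 1])
      expect_equal(ep$data[e, ch, ], sig[ch, on + 0:408 + 1] - base)
    }
  }

  ## constant signal epochs vanish after baseline correction
  cs <- toy_session(matrix(5, 2, n), rate = fs, events = ev)
  expect_true(all(extract_epochs(cs)$data == 0))

  ## events too close to the edge are dropped with a warning
  ev_bad <- rbind(ev, data.frame(sample = n - 10, stim_type = "nontarget",
                                 trial_id = 3, flash_id = 1,
                                 character = "C"))
  expect_warning(ep2 <- extract_epochs(toy_session(sig, rate = fs,
                                                   events = ev_bad)),
                 "dropped")
  expect_equal(dim(ep2$data)[1], 2)
})

test_that("artifact rejection applies the absolute and SD rules", {
  set.seed(11)
  n_ep <- 20
  data <- array(rnorm(n_ep * 2 * 50), c(n_ep, 2, 50))
  ev <- data.frame(sample = seq_len(n_ep) * 100,
                   stim_type = rep("nontarget", n_ep),
                   trial_id = seq_len(n_ep), flash_id = 1,
                   character = "A")
  ## absolute rule
  d1 <- data
  d1[3, 1, 10] <- 150
  ep <- reject_artifacts(toy_epochs(d1, ev))
  expect_true(ep$reject_mask[3])
  expect_equal(ep$reject_reason[3], "abs")

  ## identical epochs: zero variance never exceeded
  same <- array(rep(data[1, , ], each = n_ep), c(n_ep, 2, 50))
  expect_false(any(reject_artifacts(toy_epochs(same, ev))$reject_mask))

  ## one epoch whose peak sits 8 clean-data SDs above the mean; the
  ## brute-force oracle recomputes the leave-one-out rule from scratch
  d2 <- data
  peaks0 <- apply(abs(data), c(1, 2), max)
  target_peak <- mean(peaks0[, 2]) + 8 * sd(peaks0[, 2])
  d2[7, 2, ] <- d2[7, 2, ] * target_peak / peaks0[7, 2]
  ep2 <- reject_artifacts(toy_epochs(d2, ev), abs_thresh = 1e6)
  peaks <- apply(abs(d2), c(1, 2), max)
  brute <- rep(FALSE, n_ep)
  for (e in seq_len(n_ep)) {
    for (ch in 1:2) {
      others <- peaks[-e, ch]
      if (sd(others) > 0 &&
          abs(peaks[e, ch] - mean(others)) > 5 * sd(others)) {
        brute[e] <- TRUE
      }
    }
  }
  expect_equal(ep2$reject_mask, brute)
  expect_true(ep2$reject_mask[7])
  expect_equal(ep2$reject_reason[7], "sd")
})

test_that("non-targets trailing each target are excluded", {
  mk_rsvp_epochs <- function(target_pos, slen = 21) {
    ev <- data.frame(sample = seq_len(slen) * 100,
                     stim_type = ifelse(seq_len(slen) == target_pos,
                                        "target", "nontarget"),
                     trial_id = 1, flash_id = seq_len(slen),
                     character = "A")
    toy_epochs(array(0, c(slen, 1, 10)), ev)
  }
  ep <- drop_adjacent_nontargets(mk_rsvp_epochs(10))
  dropped <- which(ep$reject_mask)
  expect_equal(ep$events$flash_id[dropped], c(11, 12, 13))
  expect_equal(sum(ep$labels == "nontarget" & !ep$reject_mask), 17)

  ## boundary: target at the final stream position
  ep_end <- drop_adjacent_nontargets(mk_rsvp_epochs(21))
  expect_false(any(ep_end$reject_mask))

  ## full default 40-trial bookkeeping: 40 targets, 40 x 3 adjacent
  ## non-targets flagged, 680 non-targets retained
  cfg <- paradigm_config(sampling_rate = 128, response_window = 0.5)
  out <- generate_rsvp_session(quick_profile(9), cfg, seed = 2)
  ep40 <- drop_adjacent_nontargets(extract_epochs(out$session))
  expect_equal(n_epochs(ep40), 840)
  expect_equal(sum(ep40$labels == "target"), 40)
  expect_equal(sum(ep40$reject_mask), 120)
  expect_equal(sum(ep40$labels == "nontarget" & !ep40$reject_mask), 680)

  bad <- mk_rsvp_epochs(10)
  bad$events$flash_id <- NULL
  expect_error(drop_adjacent_nontargets(bad), "metadata")
})

test_that("preprocessing preserves counts and is deterministic", {
  cfg <- quick_config()
  out <- generate_rsvp_session(quick_profile(4), cfg, seed = 8)
  ep1 <- preprocess_session(out$session)
  ep2 <- preprocess_session(out$session)
  expect_identical(ep1$data, ep2$data)
  expect_identical(ep1$reject_mask, ep2$reject_mask)
  ## conservation: retained + flagged = extracted
  ret <- retained_epochs(ep1)
  expect_equal(n_epochs(ret) + attr(ret, "n_flagged"), n_epochs(ep1))
})
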