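# recording with a single injected signal on all channels, long enough for
# filter transients to die out
tone_recording <- function(x, events = data.frame(onset_sample = integer(),
                                                  location = character(),
                                                  block = integer(),
                                                  sub_block = integer(),
                                                  attended_location = character())) {
  data <- matrix(rep(x, each = 6), nrow = 6,
                 dimnames = list(c("C3", "Cz", "C4", "CP3", "Pz", "Fp1")))
  structure(list(data = data, rate_hz = 1200,
                 channels = c("C3", "Cz", "C4", "CP3", "Pz", "Fp1"),
                 events = events, unit = "uV", provenance = list()),
            class = "eeg_recording")
}

test_that("the bandpass rejects 50 Hz and preserves 10 Hz", {
  n <- 24000
  t <- (0:(n - 1)) / 1200
  # analytic two-pass magnitude of the digital design at f Hz
  bf <- signal::butter(2, c(0.1, 25) / 600, type = "pass")
  H <- function(f) {
    z <- exp(-1i * 2 * pi * f / 1200 * (0:4))
    Mod(sum(bf$b * z) / sum(bf$a * z))
  }
  mains <- tone_recording(sin(2 * pi * 50 * t))
  out <- bandpass_filter(mains)$data["C3", ]
  mid <- 4000:20000
  rms_ratio <- sqrt(mean(out[mid]^2)) / sqrt(mean(sin(2 * pi * 50 * t)^2))
  expect_lt(rms_ratio, 0.10)
  expect_equal(rms_ratio, H(50)^2, tolerance = 0.05)  # squared: zero-phase

  alpha <- tone_recording(sin(2 * pi * 10 * t))
  out10 <- bandpass_filter(alpha)$data["C3", ]
  expect_equal(max(abs(out10[mid])), 1, tolerance = 0.05)
})

test_that("filtering zeros stays zero and bad designs error", {
  z <- tone_recording(numeric(5000))
  expect_equal(bandpass_filter(z)$data, z$data)
  expect_error(bandpass_filter(z, low_hz = 0, high_hz = 25), "low_hz")
  expect_error(bandpass_filter(z, low_hz = 1, high_hz = 700), "rate/2")
})

test_that("epoching slices the exact half-open window [onset-120, onset+480)", {
  n <- 6000
  onsets <- c(500L, 2000L, 4000L)
  ev <- data.frame(onset_sample = onsets, location = c("D", "V", "D"),
                   block = 1L, sub_block = 1L, attended_location = "D")
  rec <- tone_recording(as.numeric(0:(n - 1)), ev)  # ramp x[k] = k (0-based)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data), c(6, 600, 3))
  for (i in 1:3)
    expect_equal(ep$data["C3", , i], as.numeric((onsets[i] - 120):(onsets[i] + 479)))
})

test_that("epoch count matches the event count and edge events are skipped", {
  sch <- generate_schedule(small_config(seed = 1))
  ep <- epoch_recording(simulate_recording(sch, clean_subject()))
  expect_equal(dim(ep$data)[3], nrow(sch$events))

  ev <- data.frame(onset_sample = c(50L, 1000L), location = "D", block = 1L,
                   sub_block = 1L, attended_location = "D")
  rec <- tone_recording(numeric(2000), ev)
  expect_warning(ep2 <- epoch_recording(rec), "skipped")
  expect_equal(dim(ep2$data)[3], 1L)
})

test_that("baseline correction subtracts the pre-stimulus mean per channel", {
  ev <- data.frame(onset_sample = 1000L, location = "D", block = 1L,
                   sub_block = 1L, attended_location = "D")
  rec <- tone_recording(numeric(2000), ev)
  rec$data[] <- 7.5                                   # constant epoch -> zeros
  ep <- baseline_correct(epoch_recording(rec))
  expect_equal(ep$data[, , 1], matrix(0, 6, 600), ignore_attr = TRUE)

  rec$data[] <- 0
  rec$data["C3", ] <- c(rep(2, 1000), rep(5, 1000))   # baseline 2, post 5
  ep2 <- baseline_correct(epoch_recording(rec))
  expect_equal(unique(ep2$data["C3", 1:120, 1]), 0)
  expect_equal(unique(ep2$data["C3", 121:600, 1]), 3)
  expect_equal(mean(ep2$data["Cz", 1:120, 1]), 0)     # zero-mean baseline unchanged
})

test_that("artifact rejection applies the dual thresholds strictly", {
  ev <- data.frame(onset_sample = c(1000L, 3000L, 5000L), location = "D",
                   block = 1L, sub_block = 1L, attended_location = "D")
  rec <- tone_recording(numeric(7000), ev)
  # epoch 1: just below both thresholds -> kept
  rec$data["C3", 1001] <- 49.9; rec$data["Fp1", 1001] <- 79
  # epoch 2: one scalp sample crosses 50 -> EEG rejection
  rec$data["Pz", 3100] <- 50.1
  # epoch 3: Fp1 crosses 80, scalp below 50 -> EOG rejection
  rec$data["Fp1", 5200] <- 100
  ep <- reject_artifacts(epoch_recording(rec))
  expect_equal(ep$kept, c(TRUE, FALSE, FALSE))
  expect_equal(ep$reason, c(NA, "EEG", "EOG"))

  # boundary-equal values are kept ("crossed" is strict)
  rec2 <- tone_recording(numeric(2000),
                         ev[1, , drop = FALSE])
  rec2$data["C3", 1001] <- 50; rec2$data["Fp1", 1001] <- 80
  expect_true(reject_artifacts(epoch_recording(rec2))$kept)
})

test_that("rejection is idempotent, order-independent, and conserves counts", {
  sch <- generate_schedule(small_config(seed = 9))
  sub <- subject_model(attention_gain = 1.5, noise_sd_uV = 10,
                       blink_rate_hz = 0.2, seed = 31)
  ep <- baseline_correct(epoch_recording(simulate_recording(sch, sub)))
  r1 <- reject_artifacts(ep)
  r2 <- reject_artifacts(r1)
  expect_identical(r1$kept, r2$kept)
  expect_equal(r1$rejection$kept + r1$rejection$rejected,
               as.integer(table(paste0("A", ep$events$attended_location,
                                       "S", ep$events$location))))
  # order independence: permuting epochs permutes the verdicts
  perm <- rev(seq_len(dim(ep$data)[3]))
  ep_rev <- ep
  ep_rev$data <- ep$data[, , perm]
  ep_rev$events <- ep$events[perm, ]
  r_rev <- reject_artifacts(ep_rev)
  expect_identical(r_rev$kept, r1$kept[perm])
})

test_that("clean noise-free epochs are never rejected", {
  sch <- generate_schedule(small_config(seed = 12))
  ep <- preprocessed_epochs(sch, clean_subject(gain = 2))
  expect_true(all(ep$kept))
})
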