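tone_recording <- function(freqs, amps = 1, fs = 25000, dur = 1,
                           events = numeric(0)) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- rowSums(vapply(seq_along(freqs), function(i) {
    rep_len(amps, length(freqs))[i] * sin(2 * pi * freqs[i] * t)
  }, numeric(length(t))))
  recording(matrix(x, 1), fs, event_times = events)
}

test_that("band separation passes in-band tones and rejects out-of-band", {
  fs <- 25000
  # 100 Hz through the LFP band: amplitude preserved within 1%
  lfp <- bandpass(tone_recording(100, fs = fs), "lfp")
  mid <- 5000:20000
  expect_lt(abs(max(abs(lfp$samples[1, mid])) - 1), 0.01)
  # 4 kHz through the LFP band: attenuated by > 20 dB
  hi <- bandpass(tone_recording(4000, fs = fs), "lfp")
  expect_lt(max(abs(hi$samples[1, mid])), 10^(-20 / 20))
  # DC offsets are removed by either band
  dc <- recording(matrix(2.5 + sin(2 * pi * 100 * (1:fs) / fs), 1), fs)
  whole <- 5001:20000  # an integer number of 100 Hz cycles
  # mean reduced from 2.5 to below 0.1% of it (residual is filter edge bleed)
  expect_lt(abs(mean(bandpass(dc, "lfp")$samples[1, whole])), 2.5e-3)
  expect_lt(abs(mean(bandpass(dc, "unit")$samples[1, whole])), 2.5e-3)
  # both bands attenuate at the shared 500 Hz corner
  corner <- tone_recording(500, fs = fs)
  a_lfp <- max(abs(bandpass(corner, "lfp")$samples[1, mid]))
  a_unit <- max(abs(bandpass(corner, "unit")$samples[1, mid]))
  expect_lt(a_lfp, 10^(-3 / 20) * 1.05)
  expect_lt(a_unit, 10^(-3 / 20) * 1.05)
  # cutoffs above Nyquist are rejected
  expect_error(bandpass(recording(matrix(0, 1, 100), 10000), "unit"),
               "Nyquist")
})

test_that("epoch averaging is the time-locked trial mean", {
  fs <- 1000
  tpl <- sin(2 * pi * 20 * seq(0, 0.15, by = 1 / fs)[1:150])
  nt <- 2000
  events <- seq(0.2, 1.7, by = 0.3)
  x <- numeric(nt)
  for (ev in events) {
    i0 <- round(ev * fs) + 1L
    x[i0:(i0 + 149)] <- x[i0:(i0 + 149)] + tpl
  }
  rec <- recording(matrix(x, 1), fs, event_times = events)
  erp <- epoch_average(rec, window = c(-0.05, 0.1))
  expect_equal(ncol(erp), 151L)
  expect_equal(attr(erp, "n_trials"), length(events))
  # identical epochs: the ERP is any single epoch
  expect_equal(erp[1, 51:151], tpl[1:101], tolerance = 1e-12)
  expect_equal(erp[1, 1:50], rep(0, 50))
  # single event reproduces that epoch
  rec1 <- recording(matrix(x, 1), fs, event_times = events[1])
  erp1 <- epoch_average(rec1, window = c(-0.05, 0.1))
  i0 <- round(events[1] * fs) + 1L
  expect_equal(erp1[1, ], x[(i0 - 50):(i0 + 100)])
  # linearity in the recording
  rec2 <- recording(matrix(2 * x, 1), fs, event_times = events)
  expect_equal(epoch_average(rec2, c(-0.05, 0.1)), 2 * erp)
  # out-of-bounds events are listed
  bad <- recording(matrix(x, 1), fs, event_times = c(0.01, events))
  expect_error(epoch_average(bad, c(-0.05, 0.1)), "event\\(s\\): 1")
})

test_that("trial averaging shrinks additive noise like 1/n", {
  fs <- 1000
  set.seed(77)
  events <- seq(0.5, 99.5, by = 1)[1:100]
  x <- rnorm(100 * fs + 200)
  rec <- recording(matrix(x, 1), fs, event_times = events)
  erp <- epoch_average(rec, window = c(-0.05, 0.1))
  ratio <- stats::var(erp[1, ]) / stats::var(x)
  expect_lt(ratio, 2.5 / 100)
  expect_gt(ratio, 0.3 / 100)
})

test_that("spike detection finds injected templates and honors dead time", {
  fs <- 25000
  set.seed(55)
  n <- fs * 2
  x <- rnorm(n, sd = 1)
  tpl <- -8 * exp(-((-8:11) / 3)^2)   # trough at sample 9 of 20
  at <- c(5000, 12000, 30000, 44000)
  for (i0 in at) x[i0:(i0 + 19)] <- x[i0:(i0 + 19)] + tpl
  rec <- recording(matrix(x, 1), fs)
  st <- detect_spikes(rec)
  # every injected spike recovered within one sample of its trough
  troughs <- at + 8
  hits <- vapply(troughs, function(tr) min(abs(st$trough_index - tr)),
                 numeric(1))
  expect_true(all(hits <= 1))
  expect_equal(ncol(st$waveform), 20L)
  # scale invariance: positive rescaling leaves detections unchanged
  st2 <- detect_spikes(recording(matrix(5 * x, 1), fs))
  expect_equal(st2$trough_index, st$trough_index)
  # two spikes 1.0 ms apart: only the first is detected
  y <- rnorm(n, sd = 1)
  y[10000:10019] <- y[10000:10019] + tpl
  y[10025:10044] <- y[10025:10044] + tpl   # 1 ms later at 25 kHz
  st3 <- detect_spikes(recording(matrix(y, 1), fs))
  near <- st3$trough_index[abs(st3$trough_index - 10010) < 80]
  expect_length(near, 1L)
})

test_that("threshold crossings on pure noise occur at roughly the 4-sigma rate", {
  fs <- 25000
  set.seed(66)
  x <- rnorm(fs * 20)
  st <- detect_spikes(recording(matrix(x, 1), fs))
  # expected rate of independent-sample downward crossings of -4 sd,
  # thinned by the dead time; agreement within a factor of 2
  p <- pnorm(-4)
  expected <- length(x) * p
  expect_gt(nrow(st), expected / 2)
  expect_lt(nrow(st), expected * 2)
})

test_that("spike-triggered averaging recovers a spike-locked waveform", {
  fs <- 10000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  art <- sin(2 * pi * 10 * t)             # 100 ms periodic artifact
  rec <- recording(matrix(art, 1), fs)
  # triggers locked to the artifact phase
  spk <- tibble::tibble(channel = 1L, time_s = seq(1, 19, by = 0.1))
  stap <- spike_triggered_average(rec, spk, window = c(-0.02, 0.02))
  tt <- attr(stap, "time_s")
  expect_equal(stap[1, ], sin(2 * pi * 10 * (tt + 1)), tolerance = 1e-6)
  # a single usable spike returns exactly that epoch
  one <- spike_triggered_average(rec, spk[3, ], window = c(-0.02, 0.02))
  i0 <- round(spk$time_s[3] * fs) + 1L
  expect_equal(one[1, ], art[(i0 - 200):(i0 + 200)])
  # random triggers on noise shrink like 1/sqrt(count)
  set.seed(88)
  noise <- recording(matrix(rnorm(fs * 20), 1), fs)
  few <- spike_triggered_average(noise,
    tibble::tibble(time_s = runif(10, 1, 19)), c(-0.02, 0.02))
  many <- spike_triggered_average(noise,
    tibble::tibble(time_s = runif(640, 1, 19)), c(-0.02, 0.02))
  expect_lt(stats::sd(many[1, ]) / stats::sd(few[1, ]), 3 / sqrt(64))
  # no usable spikes is an error
  expect_error(
    spike_triggered_average(noise, tibble::tibble(time_s = 0.001),
                            c(-0.02, 0.02)),
    class = "vcsd_empty_result")
})

test_that("recordings round-trip through the CSV schema", {
  set.seed(10)
  rec <- recording(matrix(rnorm(40), 4), 2000, event_times = c(0.001, 0.004))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$samples, rec$samples)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$event_times, rec$event_times)
})
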