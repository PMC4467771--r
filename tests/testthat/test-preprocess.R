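# Filtering, epoching, baseline correction, artifact rejection.

emptyEvents <- function() {
  data.frame(sample = integer(0), onset_s = numeric(0), word_id = integer(0),
             trial = integer(0), block = integer(0), task = character(0))
}

recordingFrom <- function(mat, fs = 256, events = emptyEvents()) {
  new("EEGRecording", data = mat,
      channels = paste0("CH", seq_len(nrow(mat))), samplingRate = fs,
      events = events)
}

test_that("band-pass response: passband unity, stopband and DC suppressed", {
  fs <- 256
  tt <- seq(0, 20, by = 1 / fs)
  rec <- recordingFrom(rbind(sin(2 * pi * 5 * tt),
                             sin(2 * pi * 30 * tt),
                             rep(1, length(tt))))
  out <- eegData(bandpassFilter(rec))
  mid <- 1500:3500    # away from edges
  expect_gt(max(abs(out[1, mid])), 0.95)          # 5 Hz within 5%
  expect_lt(max(abs(out[2, mid])), 0.10)          # 30 Hz >= 90% attenuated
  expect_lt(abs(mean(out[3, mid])), 1e-4)         # DC removed
  expect_lt(max(abs(out[3, mid])), 1e-2)
  expect_error(bandpassFilter(rec, low = 5, high = 2), "low < high")
  expect_error(bandpassFilter(rec, high = 200), "twice the upper edge")
})

test_that("frequency-domain filtering agrees with a filtfilt oracle", {
  skip_if_not_installed("signal")
  fs <- 256
  set.seed(10)
  x <- as.numeric(stats::filter(rnorm(6000), 0.9, method = "recursive"))
  rec <- recordingFrom(matrix(x, 1))
  mine <- eegData(bandpassFilter(rec))[1, ]
  hp <- signal::butter(4, 0.5 / (fs / 2), type = "high")
  lp <- signal::butter(4, 10 / (fs / 2), type = "low")
  oracle <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  mid <- 1000:5000
  expect_gt(stats::cor(mine[mid], oracle[mid]), 0.999)
  expect_lt(mean((mine[mid] - oracle[mid])^2) / mean(oracle[mid]^2), 0.005)
})

test_that("epoch windows follow the floor(onset*fs) index arithmetic", {
  fs <- 256
  x <- matrix(0, 2, 2000)
  x[1, 950] <- 7     # 0-based sample 949: first sample of the epoch
  x[1, 1257] <- 9    # 0-based sample 1256: last sample
  ev <- data.frame(sample = 1000L, onset_s = 1000 / fs, word_id = 0L,
                   trial = 1L, block = 1L, task = "AT")
  rec <- recordingFrom(x, fs, ev)
  ep <- epochRecording(rec)
  expect_identical(dim(eegData(ep))[2], 308L)
  expect_equal(eegData(ep)[1, 1, 1], 7)
  expect_equal(eegData(ep)[1, 308, 1], 9)
  expect_equal(epochTimes(ep)[1], -51 / fs)
  expect_equal(epochTimes(ep)[308], 1)
})

test_that("events outside the recording are dropped, in-bounds ones kept", {
  fs <- 256
  ev <- data.frame(sample = c(10L, 600L, 900L, 1900L),
                   onset_s = c(10, 600, 900, 1900) / fs,
                   word_id = 0L, trial = 1:4, block = 1L, task = "AT")
  rec <- recordingFrom(matrix(rnorm(2 * 2000), 2), fs, ev)
  expect_warning(ep <- epochRecording(rec), "dropped")
  expect_identical(nEpochs(ep), 2L)          # conservation of valid events
  expect_identical(epochInfo(ep)$trial, c(2L, 3L))
  ev2 <- data.frame(sample = 50L, onset_s = 50 / fs, word_id = 0L,
                    trial = 1L, block = 1L, task = "AT")
  rec2 <- recordingFrom(matrix(0, 2, 100), fs, ev2)
  expect_error(suppressWarnings(epochRecording(rec2)), "inside the recording")
})

test_that("baseline correction zeroes the prestimulus mean and is idempotent", {
  set.seed(11)
  arr <- array(rnorm(4 * 308 * 10, mean = 3), c(4, 308, 10))
  ep <- makeEpochSet(arr, channels = paste0("CH", 1:4),
                     times = (-51:256) / 256)
  out <- baselineCorrect(ep)
  bl <- epochTimes(out) < 0
  base <- apply(eegData(out)[, bl, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(base)), 1e-10)
  # constant epochs become exactly zero
  cst <- baselineCorrect(makeEpochSet(array(5, c(4, 308, 2)),
                                      channels = paste0("CH", 1:4),
                                      times = (-51:256) / 256))
  expect_equal(max(abs(eegData(cst))), 0)
  # projection: correcting twice equals correcting once
  twice <- baselineCorrect(out)
  expect_equal(eegData(twice), eegData(out))
})

test_that("artifact rejection flags spikes and spares clean data", {
  set.seed(12)
  arr <- array(rnorm(16 * 308 * 60, sd = 10), c(16, 308, 60))
  arr[3, 100, 7] <- 500                       # extreme-value epoch
  arr[5, , 13] <- seq(-80, 80, length.out = 308) +
    rnorm(308, sd = 2)                        # strong linear trend
  ep <- makeEpochSet(arr, times = (-51:256) / 256)
  res <- rejectArtifacts(ep)
  expect_true(7 %in% res$report$rejected_epochs)
  expect_true(13 %in% res$report$rejected_epochs)
  expect_gte(res$report$by_criterion[["amplitude"]], 1)
  expect_gte(res$report$by_criterion[["trend"]], 1)
  expect_identical(res$report$n_input, 60L)
  expect_identical(nEpochs(res$epochs), res$report$n_retained)
  # clean synthetic epochs at default thresholds: >= 95% retained
  clean <- makeEpochSet(array(rnorm(16 * 308 * 100, sd = 10),
                              c(16, 308, 100)), times = (-51:256) / 256)
  resClean <- rejectArtifacts(clean)
  expect_gte(resClean$report$n_retained, 95)
  # thresholds at infinity: identity
  none <- rejectArtifacts(clean, artifactCriteria(Inf, Inf, Inf, Inf, Inf))
  expect_identical(eegData(none$epochs), eegData(clean))
  expect_identical(none$report$n_rejected, 0L)
})

test_that("pipeline preprocessing is deterministic given identical input", {
  ses1 <- miniSession(21, noiseSD = 4, trials = 1:2)
  ses2 <- miniSession(21, noiseSD = 4, trials = 1:2)
  expect_identical(eegData(ses1$epochs), eegData(ses2$epochs))
  expect_identical(epochInfo(ses1$epochs), epochInfo(ses2$epochs))
})
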