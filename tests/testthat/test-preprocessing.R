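# Band-pass filtering, channel rejection, baseline correction, segmentation.

test_that("zero-phase band-pass passes in-band and suppresses out-of-band tones", {
  fs <- 500
  t <- seq(0, 30, by = 1 / fs)[-1]
  rec10 <- tinyRecording(matrix(sin(2 * pi * 10 * t), 1), fs = fs)
  out <- recordingData(bandpassFilter(rec10, 8, 13))[1, ]
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_gt(max(abs(out[mid])), 0.95)        # < 5% steady-state attenuation
  expect_equal(length(out), length(t))       # length preserved

  # 50 Hz tone through 1-45 Hz: residual matches the filter's own squared
  # magnitude response at 50 Hz (zero-phase = forward + backward pass)
  rec50 <- tinyRecording(matrix(sin(2 * pi * 50 * t), 1), fs = fs)
  res <- recordingData(bandpassFilter(rec50, 1, 45))[1, ]
  bf <- signal::butter(4, c(1, 45) / (fs / 2), type = "pass")
  zw <- exp(-1i * 2 * pi * 50 / fs * (seq_along(bf$b) - 1))
  H <- sum(bf$b * zw) / sum(bf$a * exp(-1i * 2 * pi * 50 / fs * (seq_along(bf$a) - 1)))
  predicted <- Mod(H)^2                       # amplitude gain after filtfilt
  measured <- sqrt(mean(res[mid]^2)) * sqrt(2) # RMS -> amplitude
  expect_equal(measured, predicted, tolerance = 0.05)

  expect_error(bandpassFilter(rec10, 8, 300), "Nyquist")
})

test_that("delta-filtered white noise carries almost no power above 6 Hz", {
  fs <- 500
  set.seed(8)
  rec <- tinyRecording(matrix(rnorm(30 * fs), 1), fs = fs)
  out <- recordingData(bandpassFilter(rec, 1, 4))[1, ]
  psd <- welchPsd(out, fs, windowLen = 4096, nfft = 4096)
  f <- psdFrequencies(psd); p <- psdPower(psd)[1, ]
  expect_lt(sum(p[f > 6]) / sum(p), 0.01)
})

test_that("channel rejection implements the strict >20% epoch rule", {
  fs <- 100
  nEpochs <- 50
  elen <- 2 * fs
  n <- nEpochs * elen
  clean <- rnorm(n, sd = 5)
  spiky30 <- rnorm(n, sd = 5)
  for (e in seq_len(0.3 * nEpochs)) spiky30[(e - 1) * elen + 7] <- 200
  spiky20 <- rnorm(n, sd = 5)
  for (e in seq_len(0.2 * nEpochs)) spiky20[(e - 1) * elen + 7] <- 200
  rec <- tinyRecording(rbind(clean, spiky30, spiky20), fs = fs,
                       chans = c("ok", "bad", "boundary"))
  res <- rejectChannels(rec, epochLen = 2, amplitude = 100, fraction = 0.20)
  expect_identical(res$rejected, "bad")
  expect_identical(channelNames(res$recording), c("ok", "boundary"))

  allZero <- tinyRecording(matrix(0, 3, n), fs = fs)
  expect_length(rejectChannels(allZero)$rejected, 0)

  allBad <- tinyRecording(matrix(500, 2, n), fs = fs)
  expect_error(rejectChannels(allBad), "all channels rejected")
})

test_that("baseline correction subtracts the pre-onset window mean", {
  fs <- 500
  nCtx <- 100                               # 200 ms of context at 500 Hz
  seg <- matrix(7, 2, 600)                  # constant +7 uV offset
  out <- baselineCorrect(seg, fs, c(-200, 0), onset = nCtx + 1)
  expect_equal(rowMeans(out[, 1:nCtx]), c(0, 0))
  expect_equal(out, seg - 7)

  # linear ramp: window mean removed, slope untouched
  ramp <- matrix(seq_len(600), 1)
  outR <- baselineCorrect(ramp, fs, c(-200, 0), onset = nCtx + 1)
  expect_equal(mean(outR[, 1:nCtx]), 0)
  expect_equal(diff(outR[1, ]), diff(ramp[1, ]))

  # the (-200, 0) ms window at 500 Hz spans exactly 100 samples
  segNA <- matrix(0, 1, 600)
  segNA[1, 1:100] <- 1                       # only context samples nonzero
  outW <- baselineCorrect(segNA, fs, c(-200, 0), onset = 101)
  expect_equal(outW[1, 101], -1)             # mean of exactly those 100 used

  expect_error(baselineCorrect(seg, fs, c(-200, 0), onset = 50), "outside")
  expect_error(baselineCorrect(seg, fs, c(0, 0), onset = 101), "zero samples")
})

test_that("baseline correction is idempotent", {
  set.seed(3)
  seg <- matrix(rnorm(1200, mean = 4), 2, 600)
  once <- baselineCorrect(seg, 500, c(-200, 0), onset = 101)
  twice <- baselineCorrect(once, 500, c(-200, 0), onset = 101)
  expect_equal(once, twice)
})

test_that("segmentation yields the paradigm's block structure per band", {
  s <- generateSubject(defaultParadigm(), defaultCoupling(), seed = 21)
  blocks <- splitConditionsAndBands(subjectRecording(s))
  bh <- conditionSegments(blocks, "BH", "delta")
  expect_length(bh, 4)                                  # 4 breath-holds
  expect_true(all(vapply(bh, ncol, integer(1)) == 10000))  # 20 s each
  expect_length(blocks@segments$SB, 4)                  # 4 bands emitted
  expect_named(blocks@segments$SB, defaultBands()$name)

  # missing condition errors
  par2 <- ParadigmSpec(data.frame(condition = c("SB", "BH"),
                                  duration = c(50, 20)))
  s2 <- generateSubject(par2, defaultCoupling(), seed = 3)
  expect_error(splitConditionsAndBands(subjectRecording(s2)), "PB")
})

test_that("filtering commutes with segmentation away from block edges", {
  fs <- 250
  set.seed(9)
  data <- matrix(rnorm(2 * 40 * fs), 2)
  rec <- tinyRecording(data, fs = fs, conditions = c("SB", "BH"))
  whole <- recordingData(bandpassFilter(rec, 8, 13))
  blockIdx <- 1:(20 * fs)
  segRec <- tinyRecording(data[, blockIdx], fs = fs)
  segFilt <- recordingData(bandpassFilter(segRec, 8, 13))
  interior <- seq(4 * fs, 16 * fs)
  expect_equal(segFilt[, interior], whole[, interior], tolerance = 1e-6)
})

test_that("channel rejection is deterministic and order-independent", {
  fs <- 100
  set.seed(12)
  n <- 40 * fs
  data <- rbind(rnorm(n, sd = 40), rnorm(n, sd = 60), rnorm(n, sd = 20))
  rec <- tinyRecording(data, fs = fs, chans = c("a", "b", "c"))
  r1 <- rejectChannels(rec)
  r2 <- rejectChannels(rec)
  expect_identical(r1$rejected, r2$rejected)
  perm <- c(3, 1, 2)
  recP <- tinyRecording(data[perm, ], fs = fs, chans = c("c", "a", "b"))
  expect_setequal(rejectChannels(recP)$rejected, r1$rejected)
})
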