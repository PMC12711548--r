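# Analytic-signal phases and phase-locking values.

test_that("instantaneous phase of a cosine advances at the tone frequency", {
  fs <- 500
  t <- (1:5000) / fs
  ph <- instantaneousPhase(cos(2 * pi * 10 * t))[1, ]
  interior <- 500:4500
  slope <- mean(diff(unwrapPhase <- cumsum(c(ph[interior][1],
                     atan2(sin(diff(ph[interior])), cos(diff(ph[interior])))))))
  expect_equal(slope * fs, 2 * pi * 10, tolerance = 0.01 * 2 * pi * 10)
})

test_that("quadrature pair shows a constant pi/2 phase difference", {
  fs <- 500
  t <- (1:5000) / fs
  ph <- instantaneousPhase(rbind(cos(2 * pi * 8 * t), sin(2 * pi * 8 * t)))
  d <- ph[1, 500:4500] - ph[2, 500:4500]
  d <- atan2(sin(d), cos(d))
  expect_equal(mean(d), pi / 2, tolerance = 0.01)
  expect_lt(sd(d), 0.05)
})

test_that("instantaneous frequency tracks a linear chirp", {
  fs <- 500
  n <- 10000
  tt <- (1:n) / fs
  f0 <- 5; k <- 1                  # 5 Hz + 1 Hz/s sweep
  phase <- 2 * pi * (f0 * tt + k * tt^2 / 2)
  ph <- instantaneousPhase(cos(phase))[1, ]
  d <- diff(ph)
  d <- atan2(sin(d), cos(d))
  instF <- d * fs / (2 * pi)
  interior <- 1000:9000
  expected <- f0 + k * tt[interior]
  expect_lt(max(abs(instF[interior] - expected) / expected), 0.02)
})

test_that("constant channels are rejected for phase extraction", {
  expect_error(instantaneousPhase(rbind(rnorm(100), rep(1, 100))), "constant")
})

test_that("plvPair identities: locking, cancellation, input checks", {
  ph <- runif(1000, -pi, pi)
  expect_equal(plvPair(ph, ph), 1)
  a <- rep(0, 4000)
  b <- rep(c(0, pi / 2, pi, 3 * pi / 2), 1000)
  expect_equal(plvPair(a, b), 0, tolerance = 1e-12)
  expect_error(plvPair(1:10, 1:9), "mismatch")
  expect_error(plvPair(1, 1), "2 samples")
})

test_that("PLV is invariant to common phase offsets and amplitude scaling", {
  set.seed(14)
  fs <- 250
  t <- (1:2500) / fs
  x <- sin(2 * pi * 10 * t) + 0.3 * rnorm(length(t))
  y <- sin(2 * pi * 10 * t + 0.7) + 0.3 * rnorm(length(t))
  base <- plvPair(instantaneousPhase(x)[1, ], instantaneousPhase(y)[1, ])
  shifted <- plvPair(instantaneousPhase(x)[1, ] + 1.3,
                     instantaneousPhase(y)[1, ])
  scaled <- plvPair(instantaneousPhase(5 * x)[1, ],
                    instantaneousPhase(0.2 * y)[1, ])
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(scaled, base, tolerance = 1e-6)
})

test_that("null PLV matches the Rayleigh mean resultant length", {
  # independent uniform phases: E[PLV] ~ sqrt(pi) / (2 sqrt(N))
  set.seed(15)
  N <- 2000; reps <- 300
  plvs <- replicate(reps, plvPair(runif(N, -pi, pi), runif(N, -pi, pi)))
  expected <- sqrt(pi / (4 * N))
  se <- sd(plvs) / sqrt(reps)
  expect_lt(abs(mean(plvs) - expected), 3 * se)
})

test_that("plvMatrix averages epochs and keeps the matrix well-formed", {
  setup <- singleBandSetup(0.5, duration = 8)
  s <- generateSubject(setup$paradigm, setup$coupling, seed = 7)
  blocks <- splitConditionsAndBands(subjectRecording(s), bands = setup$bands,
                                    requireConditions = "SB")
  cm <- plvMatrix(blocks, "SB", "b", subjectId = "X1")
  v <- plvValues(cm)
  expect_equal(v, t(v))
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(diag(v), setNames(rep(1, 3), rownames(v)))
  expect_error(plvMatrix(blocks, "PB", "b"), "PB")

  # epoch averaging is the arithmetic mean of per-segment PLV matrices
  par2 <- ParadigmSpec(data.frame(condition = c("SB", "SB"), duration = c(8, 8)),
                       channelNames = c("C3", "C4", "P3"))
  s2 <- generateSubject(par2, setup$coupling, seed = 8)
  blocks2 <- splitConditionsAndBands(subjectRecording(s2), bands = setup$bands,
                                     requireConditions = "SB")
  cm2 <- plvMatrix(blocks2, "SB", "b")
  segs <- conditionSegments(blocks2, "SB", "b")
  perSeg <- lapply(segs, function(seg) {
    ph <- instantaneousPhase(seg)
    n <- ncol(ph)
    trim <- floor(0.05 * n)
    ph <- ph[, (trim + 1):(n - trim)]
    plvPair(ph[1, ], ph[2, ])
  })
  expect_equal(plvValues(cm2)[1, 2], mean(unlist(perSeg)), tolerance = 1e-12)
})

test_that("edge vectorization produces named unique and full layouts", {
  chans <- defaultMontage()
  expect_length(edgeNames(chans, "unique"), 120)
  expect_length(edgeNames(chans, "full"), 256)
  m <- matrix(runif(16), 4, 4, dimnames = list(chans[1:4], chans[1:4]))
  m <- (m + t(m)) / 2; diag(m) <- 1
  v <- edgeVector(m, "unique")
  expect_length(v, 6)
  expect_equal(unname(v[1]), m[1, 2])
  expect_equal(names(v)[1], "Fp1-FP2")
  expect_length(edgeVector(m, "full"), 16)
})
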