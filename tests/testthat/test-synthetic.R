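# Synthetic cohort generator: paradigm arithmetic, coupling -> PLV ground
# truth, FVC covariate calibration, determinism.

test_that("default paradigm reproduces the 330-s block design", {
  p <- defaultParadigm()
  expect_equal(paradigmDuration(p), 330)
  expect_equal(paradigmSamples(p), 165000)
  expect_length(p@channelNames, 16)
  # four 20-s breath-hold blocks interleaved with 50-s breathing blocks
  expect_equal(sum(p@blocks$condition == "BH"), 4)
  expect_true(all(p@blocks$duration[p@blocks$condition == "BH"] == 20))
  s <- generateSubject(p, defaultCoupling(), seed = 11)
  expect_equal(ncol(recordingData(subjectRecording(s))), 165000)
  ann <- annotations(subjectRecording(s))
  expect_equal(nrow(ann), 9)
  expect_equal(ann$end[9], 165000)
})

test_that("paradigm and coupling invariants are enforced", {
  expect_error(ParadigmSpec(data.frame(condition = "SB", duration = -1)),
               "duration")
  expect_error(ParadigmSpec(data.frame(condition = "XX", duration = 10)),
               "condition")
  expect_error(ParadigmSpec(data.frame(condition = "SB", duration = 10),
                            channelNames = c("C3", "C3")), "unique")
  chans <- c("C3", "C4")
  k <- matrix(c(0, 0.5, 0.7, 0), 2, 2, dimnames = list(chans, chans))
  expect_error(CouplingSpec(list(SB = list(alpha = k)),
                            bands = data.frame(name = "alpha", lo = 8, hi = 13),
                            amplitudes = c(alpha = 1), channelNames = chans),
               "symmetric")
  # channel count mismatch between paradigm and coupling
  setup <- singleBandSetup(0.5)
  par2 <- ParadigmSpec(data.frame(condition = "SB", duration = 5),
                       channelNames = c("A", "B"))
  expect_error(generateSubject(par2, setup$coupling, seed = 1), "mismatch")
  # condition absent from the coupling spec
  parPB <- ParadigmSpec(data.frame(condition = "PB", duration = 5),
                        channelNames = c("C3", "C4", "P3"))
  expect_error(generateSubject(parPB, setup$coupling, seed = 1), "condition")
})

test_that("identical seeds give bit-identical recordings, different seeds differ", {
  setup <- singleBandSetup(0.5, duration = 4)
  a <- generateSubject(setup$paradigm, setup$coupling, seed = 42)
  b <- generateSubject(setup$paradigm, setup$coupling, seed = 42)
  c <- generateSubject(setup$paradigm, setup$coupling, seed = 43)
  expect_identical(recordingData(subjectRecording(a)),
                   recordingData(subjectRecording(b)))
  expect_false(identical(recordingData(subjectRecording(a)),
                         recordingData(subjectRecording(c))))
})

test_that("full coupling without noise yields perfect phase locking", {
  plv <- empiricalPairPlv(1, seed = 5)
  expect_equal(plv, 1, tolerance = 1e-9)
})

test_that("uncoupled channels fall to near-null PLV", {
  # kappa = 0: channels ride independent oscillators; the narrowband
  # Rayleigh-null floor is well below any coupled level
  plvs <- vapply(1:10, function(s) empiricalPairPlv(0, seed = s), numeric(1))
  expect_lt(mean(plvs), 0.25)
  expect_gt(mean(vapply(1:5, function(s) empiricalPairPlv(0.5, seed = s),
                        numeric(1))),
            mean(plvs))
})

test_that("empirical PLV is monotone in the planted coupling", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  seeds <- 1:20
  means <- vapply(grid, function(k)
    mean(vapply(seeds, function(s)
      empiricalPairPlv(k, seed = s, duration = 10), numeric(1))), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_gt(suppressWarnings(cor(grid, means, method = "spearman")), 0.95)
})

test_that("band-limited components place their Welch peak inside the band", {
  for (band in list(c(lo = 4, hi = 8), c(lo = 8, hi = 13), c(lo = 13, hi = 30))) {
    setup <- singleBandSetup(0.6, band = band, duration = 30)
    s <- generateSubject(setup$paradigm, setup$coupling, seed = 2)
    x <- recordingData(subjectRecording(s))[1, , drop = FALSE]
    psd <- welchPsd(x, 500, windowLen = 1024, nfft = 2048)
    peak <- psdFrequencies(psd)[which.max(psdPower(psd)[1, ])]
    expect_gte(peak, band[["lo"]])
    expect_lt(peak, band[["hi"]])
  }
})

test_that("FVC calibration hits the target population correlation", {
  # null association
  set.seed(101)
  d0 <- sampleFvcCouplings(200, targetR = 0)
  expect_lt(abs(cor(d0$kappa, d0$fvc)), 0.15)
  # replicate cohorts at the study size: mean empirical r within +-0.05
  set.seed(202)
  rs <- replicate(500, {
    d <- sampleFvcCouplings(35, targetR = 0.5)
    cor(d$kappa, d$fvc)
  })
  expect_lt(abs(mean(rs) - 0.5), 0.05)
})

test_that("generateCohort plants the FVC association at the requested edge", {
  chans <- defaultMontage()
  expect_error(generateCohort(5, fvcAssoc = list(edge = c("C4", "ZZ"),
                                                 band = "theta",
                                                 condition = "PB",
                                                 targetR = 0.5), seed = 1),
               "edge")
  expect_error(generateCohort(2, seed = 1), "nSubjects")
  par <- ParadigmSpec(data.frame(condition = c("PB"), duration = 4))
  coup <- defaultCoupling()
  cohort <- generateCohort(4, par, coup,
                           fvcAssoc = list(edge = c("C4", "T8"),
                                           band = "theta", condition = "PB",
                                           targetR = 0.5), seed = 9)
  expect_length(cohort, 4)
  fvc <- vapply(cohort, subjectFvc, numeric(1))
  expect_true(all(fvc > 0))
  kap <- vapply(cohort, function(s)
    s@groundTruth@kappa$PB$theta["C4", "T8"], numeric(1))
  expect_gt(sd(kap), 0)        # edge coupling varies across subjects
  other <- vapply(cohort, function(s)
    s@groundTruth@kappa$PB$theta["C3", "P3"], numeric(1))
  expect_equal(sd(other), 0)   # other edges fixed
  man <- cohortManifest(cohort)
  expect_equal(nrow(man), 4)
  expect_false(anyDuplicated(man$seed) > 0)
})
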