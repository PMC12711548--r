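# Small in-code fixtures shared across test files.

# single-band, single-condition generator setup with uniform coupling
singleBandSetup <- function(kappa, chans = c("C3", "C4", "P3"),
                            duration = 20, band = c(lo = 8, hi = 13),
                            noiseSd = 0, condition = "SB") {
  bands <- data.frame(name = "b", lo = band[["lo"]], hi = band[["hi"]])
  paradigm <- ParadigmSpec(data.frame(condition = condition, duration = duration),
                           channelNames = chans)
  kap <- list(uniformCoupling(kappa, chans))
  names(kap) <- "b"
  coupling <- CouplingSpec(stats::setNames(list(kap), condition), bands = bands,
                           amplitudes = c(b = 10), noiseSd = noiseSd,
                           channelNames = chans)
  list(paradigm = paradigm, coupling = coupling, bands = bands)
}

# empirical pairwise PLV between the first two channels for one seed
empiricalPairPlv <- function(kappa, seed, ...) {
  setup <- singleBandSetup(kappa, ...)
  s <- generateSubject(setup$paradigm, setup$coupling, seed = seed)
  blocks <- splitConditionsAndBands(subjectRecording(s), bands = setup$bands,
                                    requireConditions = character())
  cond <- setup$paradigm@blocks$condition[1]
  plvValues(plvMatrix(blocks, cond, "b"))[1, 2]
}

# tiny annotated recording from explicit data
tinyRecording <- function(data, fs = 100,
                          chans = paste0("ch", seq_len(nrow(data))),
                          conditions = "SB") {
  n <- ncol(data)
  k <- length(conditions)
  bounds <- round(seq(0, n, length.out = k + 1))
  ann <- data.frame(condition = conditions, start = bounds[-(k + 1)],
                    end = bounds[-1], stringsAsFactors = FALSE)
  EegRecording(data, fs, chans, ann)
}
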