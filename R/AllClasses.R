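#' Default 16-channel montage
#'
#' The fixed montage used throughout: Fp1, FP2, F3, F4, F7, F8, T7, T8, C3,
#' C4, P3, P4, P7, P8, O1, O2.
#'
#' @return Character vector of 16 channel labels.
#' @export
defaultMontage <- function() {
  c("Fp1", "FP2", "F3", "F4", "F7", "F8", "T7", "T8",
    "C3", "C4", "P3", "P4", "P7", "P8", "O1", "O2")
}

#' Canonical EEG band table
#'
#' Delta (1-4 Hz), theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz). Band
#' edges are lower-inclusive and upper-exclusive so the four bands partition
#' 1-30 Hz; the gamma band (31-45 Hz) is excluded by design.
#'
#' @return A `data.frame` with columns `name`, `lo`, `hi` (Hz).
#' @export
defaultBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             lo = c(1, 4, 8, 13),
             hi = c(4, 8, 13, 30),
             stringsAsFactors = FALSE)
}

#' Validate a band table
#'
#' @param bands A band table as returned by [defaultBands()].
#' @param fs Sampling rate in Hz (bands must lie below Nyquist).
#' @return The validated band table, invisibly.
#' @export
validateBands <- function(bands, fs = Inf) {
  stopifnot(is.data.frame(bands), all(c("name", "lo", "hi") %in% names(bands)))
  if (anyDuplicated(bands$name)) stop("band names must be unique")
  ok <- bands$lo > 0 & bands$lo < bands$hi & bands$hi <= fs / 2
  if (!all(ok)) {
    stop("invalid band(s): ", paste(bands$name[!ok], collapse = ", "),
         " (need 0 < lo < hi <= fs/2)")
  }
  invisible(bands)
}

# ---------------------------------------------------------------------------
# ParadigmSpec

#' @rdname ParadigmSpec-class
#' @export
setClass("ParadigmSpec",
         representation(blocks = "data.frame",
                        samplingRate = "numeric",
                        channelNames = "character"))

setValidity("ParadigmSpec", function(object) {
  b <- object@blocks
  msg <- character()
  if (!all(c("condition", "duration") %in% names(b)))
    msg <- c(msg, "blocks needs columns 'condition' and 'duration'")
  else {
    if (!all(b$condition %in% CONDITIONS))
      msg <- c(msg, sprintf("unknown condition label(s): %s",
                            paste(setdiff(b$condition, CONDITIONS), collapse = ", ")))
    if (any(b$duration <= 0)) msg <- c(msg, "all block durations must be > 0")
  }
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (length(object@channelNames) < 2)
    msg <- c(msg, "at least 2 channels required")
  if (length(msg)) msg else TRUE
})

#' Block paradigm specification
#'
#' Describes the ordered condition blocks of one recording run, the sampling
#' rate and the montage. The default paradigm is a single continuous 330-s
#' run: 50 s SB, then four cycles of 20 s BH followed by 50 s of breathing
#' (alternating PB and SB), i.e. 50 SB + 4 x (20 BH + 50 breathing) = 330 s.
#'
#' @param blocks `data.frame` with columns `condition` (one of `"SB"`,
#'   `"BH"`, `"PB"`) and `duration` (seconds).
#' @param samplingRate Sampling rate in Hz (default 500).
#' @param channelNames Channel labels (default [defaultMontage()]).
#' @return A `ParadigmSpec` object.
#' @examples
#' p <- defaultParadigm()
#' paradigmDuration(p)  # 330
#' @export
ParadigmSpec <- function(blocks, samplingRate = 500,
                         channelNames = defaultMontage()) {
  new("ParadigmSpec", blocks = blocks, samplingRate = samplingRate,
      channelNames = channelNames)
}

#' @rdname ParadigmSpec-class
#' @export
defaultParadigm <- function(samplingRate = 500, channelNames = defaultMontage()) {
  blocks <- data.frame(
    condition = c("SB", "BH", "PB", "BH", "SB", "BH", "PB", "BH", "SB"),
    duration = c(50, 20, 50, 20, 50, 20, 50, 20, 50),
    stringsAsFactors = FALSE)
  ParadigmSpec(blocks, samplingRate, channelNames)
}

#' Total paradigm duration in seconds
#' @param paradigm A `ParadigmSpec`.
#' @export
paradigmDuration <- function(paradigm) sum(paradigm@blocks$duration)

#' @describeIn ParadigmSpec-class number of samples in one run
#' @param paradigm A `ParadigmSpec`.
#' @export
paradigmSamples <- function(paradigm) {
  sum(round(paradigm@blocks$duration * paradigm@samplingRate))
}

#' @name ParadigmSpec-class
#' @title Block paradigm class
#' @aliases ParadigmSpec-class
#' @description S4 container for the block design (see [ParadigmSpec()]).
NULL

setMethod("show", "ParadigmSpec", function(object) {
  cat(sprintf("ParadigmSpec: %d blocks, %.0f s total, fs = %g Hz, %d channels\n",
              nrow(object@blocks), paradigmDuration(object),
              object@samplingRate, length(object@channelNames)))
  cat("  ", paste(sprintf("%s(%gs)", object@blocks$condition,
                          object@blocks$duration), collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# CouplingSpec

#' @rdname CouplingSpec
#' @export
setClass("CouplingSpec",
         representation(kappa = "list",        # [[condition]][[band]] -> matrix
                        bands = "data.frame",
                        amplitudes = "numeric", # uV, named per band
                        phaseJitter = "numeric",
                        noiseSd = "numeric",
                        channelNames = "character"))

setValidity("CouplingSpec", function(object) {
  msg <- character()
  nch <- length(object@channelNames)
  for (cond in names(object@kappa)) {
    for (band in names(object@kappa[[cond]])) {
      k <- object@kappa[[cond]][[band]]
      if (!is.matrix(k) || nrow(k) != nch || ncol(k) != nch) {
        msg <- c(msg, sprintf("kappa[%s][%s] must be %dx%d", cond, band, nch, nch))
        next
      }
      if (max(abs(k - t(k))) > 1e-12)
        msg <- c(msg, sprintf("kappa[%s][%s] not symmetric", cond, band))
      if (any(k < 0 | k > 1))
        msg <- c(msg, sprintf("kappa[%s][%s] outside [0,1]", cond, band))
      if (any(diag(k) != 0))
        msg <- c(msg, sprintf("kappa[%s][%s] diagonal must be zero", cond, band))
    }
  }
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@phaseJitter < 0) msg <- c(msg, "phaseJitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground-truth coupling specification for the synthetic generator
#'
#' Holds, for each (condition, band), a symmetric pairwise coupling matrix
#' `kappa` with entries in \[0, 1\] and zero diagonal, plus per-band
#' oscillation amplitudes (uV), a private phase-jitter scale (rad per sqrt
#' sample) and the additive sensor-noise SD (uV).
#'
#' The default encodes the qualitative condition effects the pipeline is
#' meant to recover: stronger low-frequency (delta/theta) coupling among
#' frontal channels during SB than BH or PB, and stronger broad alpha/beta
#' coupling during BH than PB.
#'
#' @param kappa Nested list `kappa[[condition]][[band]]` of coupling
#'   matrices; missing (condition, band) entries default to the background
#'   level.
#' @param bands Band table (see [defaultBands()]).
#' @param amplitudes Named numeric vector of band amplitudes in uV.
#' @param phaseJitter Private phase-jitter innovation scale (rad/sqrt sample).
#' @param noiseSd Additive white sensor-noise SD in uV.
#' @param channelNames Channel labels.
#' @return A `CouplingSpec` object.
#' @export
CouplingSpec <- function(kappa, bands = defaultBands(),
                         amplitudes = c(delta = 20, theta = 10, alpha = 15, beta = 8),
                         phaseJitter = 0, noiseSd = 2,
                         channelNames = defaultMontage()) {
  new("CouplingSpec", kappa = kappa, bands = bands,
      amplitudes = amplitudes[bands$name], phaseJitter = phaseJitter,
      noiseSd = noiseSd, channelNames = channelNames)
}

#' Uniform coupling matrix
#'
#' All off-diagonal pairs coupled at `level`.
#'
#' @param level Coupling strength in \[0, 1\].
#' @param channelNames Channel labels.
#' @export
uniformCoupling <- function(level, channelNames = defaultMontage()) {
  n <- length(channelNames)
  k <- matrix(level, n, n, dimnames = list(channelNames, channelNames))
  diag(k) <- 0
  k
}

#' Coupling matrix elevated within a channel block
#'
#' Background coupling everywhere, `level` among the channels in `members`.
#'
#' @param members Channel labels forming the coupled block.
#' @param level Within-block coupling.
#' @param background Coupling outside the block.
#' @param channelNames Channel labels.
#' @export
blockCoupling <- function(members, level, background = 0.15,
                          channelNames = defaultMontage()) {
  k <- uniformCoupling(background, channelNames)
  if (!all(members %in% channelNames))
    stop("unknown channel(s): ", paste(setdiff(members, channelNames), collapse = ", "))
  k[members, members] <- level
  diag(k) <- 0
  k
}

#' @rdname CouplingSpec
#' @export
defaultCoupling <- function(channelNames = defaultMontage()) {
  frontal <- c("Fp1", "FP2", "F3", "F4", "F7", "F8")
  frontal <- intersect(frontal, channelNames)
  kappa <- list(
    SB = list(delta = blockCoupling(frontal, 0.60, 0.15, channelNames),
              theta = blockCoupling(frontal, 0.50, 0.15, channelNames),
              alpha = uniformCoupling(0.40, channelNames),
              beta  = uniformCoupling(0.35, channelNames)),
    BH = list(delta = blockCoupling(frontal, 0.30, 0.15, channelNames),
              theta = blockCoupling(frontal, 0.30, 0.15, channelNames),
              alpha = uniformCoupling(0.55, channelNames),
              beta  = uniformCoupling(0.50, channelNames)),
    PB = list(delta = blockCoupling(frontal, 0.35, 0.15, channelNames),
              theta = blockCoupling(frontal, 0.35, 0.15, channelNames),
              alpha = uniformCoupling(0.30, channelNames),
              beta  = uniformCoupling(0.25, channelNames)))
  CouplingSpec(kappa, channelNames = channelNames)
}

setMethod("show", "CouplingSpec", function(object) {
  cat(sprintf("CouplingSpec: %d conditions x %d bands, %d channels, noiseSd = %g uV\n",
              length(object@kappa), nrow(object@bands),
              length(object@channelNames), object@noiseSd))
})

# ---------------------------------------------------------------------------
# EegRecording

#' @rdname EegRecording
#' @export
setClass("EegRecording",
         representation(data = "matrix",        # channels x samples, uV
                        samplingRate = "numeric",
                        channelNames = "character",
                        annotations = "data.frame")) # condition, start, end (0-based half-open)

setValidity("EegRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "row count of data must match channelNames")
  a <- object@annotations
  if (nrow(a)) {
    if (!all(c("condition", "start", "end") %in% names(a)))
      msg <- c(msg, "annotations need columns condition, start, end")
    else {
      if (any(a$start < 0) || any(a$end > ncol(object@data)))
        msg <- c(msg, "annotations out of bounds")
      if (any(a$end <= a$start)) msg <- c(msg, "annotation end must exceed start")
      if (is.unsorted(a$start)) msg <- c(msg, "annotations must be sorted")
      if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)]))
        msg <- c(msg, "annotations must not overlap")
    }
  }
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (length(msg)) msg else TRUE
})

#' Multichannel EEG recording
#'
#' Channels x samples matrix (uV) with sampling rate, channel labels and
#' block annotations. Annotations use 0-based, half-open sample intervals
#' `[start, end)`.
#'
#' @param data Numeric matrix, channels x samples.
#' @param samplingRate Sampling rate in Hz.
#' @param channelNames Channel labels (length = `nrow(data)`).
#' @param annotations `data.frame` with columns `condition`, `start`, `end`.
#' @return An `EegRecording` object.
#' @export
EegRecording <- function(data, samplingRate, channelNames = rownames(data),
                         annotations = data.frame(condition = character(),
                                                  start = integer(),
                                                  end = integer())) {
  if (is.null(channelNames)) stop("channelNames required")
  rownames(data) <- channelNames
  new("EegRecording", data = data, samplingRate = samplingRate,
      channelNames = channelNames, annotations = annotations)
}

#' @describeIn EegRecording channels x samples signal matrix
#' @param x An `EegRecording`.
#' @export
recordingData <- function(x) x@data

#' @describeIn EegRecording sampling rate in Hz
#' @export
samplingRate <- function(x) x@samplingRate

#' @describeIn EegRecording channel labels
#' @export
channelNames <- function(x) x@channelNames

#' @describeIn EegRecording block annotation table
#' @export
annotations <- function(x) x@annotations

setMethod("show", "EegRecording", function(object) {
  cat(sprintf("EegRecording: %d channels x %d samples (%.1f s at %g Hz), %d annotated blocks\n",
              nrow(object@data), ncol(object@data),
              ncol(object@data) / object@samplingRate,
              object@samplingRate, nrow(object@annotations)))
})

# ---------------------------------------------------------------------------
# SyntheticSubject

#' @rdname generateSubject
#' @export
setClass("SyntheticSubject",
         representation(recording = "EegRecording",
                        fvc = "numeric",
                        subjectId = "character",
                        groundTruth = "CouplingSpec",
                        seed = "numeric"))

setValidity("SyntheticSubject", function(object) {
  if (!is.na(object@fvc) && object@fvc <= 0) "fvc must be > 0" else TRUE
})

#' @describeIn generateSubject the subject's recording
#' @param x A `SyntheticSubject`.
#' @export
subjectRecording <- function(x) x@recording

#' @describeIn generateSubject forced vital capacity (litres; may be `NA`)
#' @export
subjectFvc <- function(x) x@fvc

#' @describeIn generateSubject subject identifier
#' @export
subjectId <- function(x) x@subjectId

setMethod("show", "SyntheticSubject", function(object) {
  cat(sprintf("SyntheticSubject %s: FVC = %s L, seed = %s\n  ", object@subjectId,
              ifelse(is.na(object@fvc), "NA", format(object@fvc, digits = 3)),
              format(object@seed)))
  show(object@recording)
})

# ---------------------------------------------------------------------------
# ConditionBlocks

#' @rdname splitConditionsAndBands
#' @export
setClass("ConditionBlocks",
         representation(segments = "list",   # [[condition]][[band]] -> list of matrices
                        broadband = "list",  # [[condition]] -> list of matrices
                        samplingRate = "numeric",
                        channelNames = "character",
                        bands = "data.frame",
                        provenance = "list"))

setValidity("ConditionBlocks", function(object) {
  msg <- character()
  nch <- length(object@channelNames)
  for (cond in names(object@segments))
    for (band in names(object@segments[[cond]]))
      for (seg in object@segments[[cond]][[band]])
        if (nrow(seg) != nch) {
          msg <- c(msg, "segment channel count mismatch")
          break
        }
  if (length(msg)) msg else TRUE
})

#' @describeIn splitConditionsAndBands band-filtered segments for one
#'   condition/band (list of channels x samples matrices)
#' @param x A `ConditionBlocks` object.
#' @param condition,band Condition and band names.
#' @export
conditionSegments <- function(x, condition, band) {
  segs <- x@segments[[condition]]
  if (is.null(segs)) stop("no segments for condition ", condition)
  if (!band %in% names(segs)) stop("unknown band ", band)
  segs[[band]]
}

#' @describeIn splitConditionsAndBands broadband (unsplit) segments for one
#'   condition
#' @export
broadbandSegments <- function(x, condition) {
  segs <- x@broadband[[condition]]
  if (is.null(segs)) stop("no segments for condition ", condition)
  segs
}

setMethod("show", "ConditionBlocks", function(object) {
  counts <- vapply(object@segments, function(s) length(s[[1]]), integer(1))
  cat(sprintf("ConditionBlocks: %s; %d bands, %d channels\n",
              paste(sprintf("%s x%d", names(counts), counts), collapse = ", "),
              nrow(object@bands), length(object@channelNames)))
})

# ---------------------------------------------------------------------------
# ConnectivityMatrix

#' @rdname plvMatrix
#' @export
setClass("ConnectivityMatrix",
         representation(values = "matrix",
                        band = "character",
                        condition = "character",
                        subjectId = "character",
                        nSamples = "numeric"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  else {
    if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "values must be symmetric")
    if (any(v < -1e-12 | v > 1 + 1e-12)) msg <- c(msg, "values must lie in [0,1]")
    if (any(abs(diag(v) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn plvMatrix the symmetric PLV matrix (unit diagonal)
#' @param x A `ConnectivityMatrix`.
#' @export
plvValues <- function(x) x@values

setMethod("show", "ConnectivityMatrix", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("ConnectivityMatrix %dx%d [%s / %s / %s]: mean off-diagonal PLV = %.3f (n = %d samples)\n",
              nrow(object@values), ncol(object@values),
              object@subjectId, object@condition, object@band,
              mean(off), object@nSamples))
})
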