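# Deterministic cleaning and band decomposition of annotated recordings.

# Zero-phase Butterworth band-pass applied per channel (forward-backward, so
# the effective attenuation is the squared magnitude response).
butterBandpass <- function(lo, hi, fs, order = 4) {
  signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
}

#' Zero-phase band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel. Signal length is preserved.
#'
#' @param recording An [EegRecording()].
#' @param lo,hi Band edges in Hz; `hi` must not exceed Nyquist.
#' @param order Butterworth order (default 4; applied twice by filtfilt).
#' @return A filtered [EegRecording()] with unchanged annotations.
#' @export
bandpassFilter <- function(recording, lo, hi, order = 4) {
  fs <- recording@samplingRate
  if (!(lo > 0 && lo < hi && hi <= fs / 2))
    stop(sprintf("band [%g, %g] Hz outside (0, Nyquist = %g]", lo, hi, fs / 2))
  bf <- butterBandpass(lo, hi, fs, order)
  out <- t(apply(recording@data, 1, function(ch) signal::filtfilt(bf, ch)))
  dimnames(out) <- dimnames(recording@data)
  EegRecording(out, fs, recording@channelNames, recording@annotations)
}

#' Amplitude-based channel rejection
#'
#' The recording is tiled into non-overlapping epochs of `epochLen` seconds;
#' a channel is discarded when the share of epochs containing any sample with
#' `|x| > amplitude` uV strictly exceeds `fraction`. No interpolation is
#' applied; surviving channels are returned unchanged.
#'
#' @param recording An [EegRecording()].
#' @param epochLen Epoch length in seconds (default 2).
#' @param amplitude Amplitude threshold in uV (default 100).
#' @param fraction Maximum tolerated share of violating epochs (default 0.20,
#'   strict `>`).
#' @return List with elements `recording` (channels removed) and `rejected`
#'   (character vector of dropped channel labels).
#' @export
rejectChannels <- function(recording, epochLen = 2, amplitude = 100,
                           fraction = 0.20) {
  if (epochLen <= 0) stop("epochLen must be > 0")
  fs <- recording@samplingRate
  n <- ncol(recording@data)
  elen <- round(epochLen * fs)
  nEpochs <- n %/% elen
  if (nEpochs < 1) stop("recording shorter than one epoch")
  share <- vapply(seq_len(nrow(recording@data)), function(i) {
    ch <- recording@data[i, seq_len(nEpochs * elen)]
    viol <- matrix(abs(ch) > amplitude, elen, nEpochs)
    mean(apply(viol, 2, any))
  }, numeric(1))
  rejected <- recording@channelNames[share > fraction]
  keep <- setdiff(recording@channelNames, rejected)
  if (!length(keep)) stop("all channels rejected")
  out <- EegRecording(recording@data[keep, , drop = FALSE], fs, keep,
                      recording@annotations)
  list(recording = out, rejected = rejected)
}

#' Baseline correction by pre-onset mean subtraction
#'
#' Subtracts, per channel, the mean over the baseline window from the whole
#' segment. The window is given in milliseconds relative to the block onset
#' sample (`onset`, 1-based index within `segment`); the default
#' `c(-200, 0)` uses the 200 ms immediately preceding onset.
#'
#' @param segment Channels x samples matrix containing enough pre-onset
#'   context to cover the window.
#' @param fs Sampling rate in Hz.
#' @param window Length-2 numeric, window in ms relative to onset
#'   (half-open: samples with `window[1] <= t < window[2]`).
#' @param onset 1-based sample index of the block onset within `segment`.
#' @return The corrected matrix, same dimensions as `segment`.
#' @export
baselineCorrect <- function(segment, fs, window = c(-200, 0), onset = 1) {
  if (!is.matrix(segment)) segment <- matrix(segment, nrow = 1)
  i0 <- onset + floor(window[1] / 1000 * fs)
  i1 <- onset + ceiling(window[2] / 1000 * fs) - 1
  if (i1 < i0) stop("baseline window contains zero samples")
  if (i0 < 1 || i1 > ncol(segment))
    stop(sprintf("baseline window [%d, %d] outside segment (1..%d)",
                 i0, i1, ncol(segment)))
  mu <- rowMeans(segment[, i0:i1, drop = FALSE])
  segment - mu
}

#' Split an annotated recording into per-condition, per-band segments
#'
#' For each annotated block the segment is extracted, baseline-corrected
#' (mean over the pre-onset window subtracted; for a block starting at sample
#' 0 with no pre-onset context the window is mirrored to the first
#' `|window|` ms of the block, which is noted in the provenance) and
#' band-filtered once per band. Band filtering is performed on the full
#' recording before segmentation so that block-interior samples carry no
#' per-segment filter transients.
#'
#' @param recording An [EegRecording()] with annotations (normally already
#'   broadband-filtered and channel-rejected).
#' @param bands Band table (default [defaultBands()]; gamma excluded).
#' @param baselineWindow Baseline window in ms relative to block onset.
#' @param filterOrder Butterworth order for the band filters.
#' @param requireConditions Conditions that must be present; an error is
#'   raised if any has zero blocks. Defaults to all three paradigm
#'   conditions; pass a subset (or `character()`) for partial recordings.
#' @return A `ConditionBlocks` object.
#' @export
splitConditionsAndBands <- function(recording, bands = defaultBands(),
                                    baselineWindow = c(-200, 0),
                                    filterOrder = 4,
                                    requireConditions = CONDITIONS) {
  fs <- recording@samplingRate
  validateBands(bands, fs)
  ann <- recording@annotations
  if (!nrow(ann)) stop("recording has no annotations")
  conds <- unique(ann$condition)
  missing <- setdiff(requireConditions, conds)
  if (length(missing))
    stop("condition(s) with zero blocks: ", paste(missing, collapse = ", "))
  nBase <- ceiling(abs(diff(baselineWindow)) / 1000 * fs)

  # full-recording band filtering, then per-block extraction
  filtered <- lapply(seq_len(nrow(bands)), function(b)
    bandpassFilter(recording, bands$lo[b], bands$hi[b], filterOrder)@data)
  names(filtered) <- bands$name

  fallback <- logical(nrow(ann))
  extract <- function(data, blk) {
    s <- ann$start[blk]; e <- ann$end[blk]
    seg <- data[, (s + 1):e, drop = FALSE]
    if (s >= nBase) {
      ctx <- cbind(data[, (s - nBase + 1):s, drop = FALSE], seg)
      seg <- baselineCorrect(ctx, fs, baselineWindow,
                             onset = nBase + 1)[, (nBase + 1):ncol(ctx), drop = FALSE]
    } else {
      # no pre-onset context: use the first |window| ms of the block itself
      fallback[blk] <<- TRUE
      seg <- seg - rowMeans(seg[, seq_len(min(nBase, ncol(seg))), drop = FALSE])
    }
    seg
  }

  segments <- list(); broadband <- list()
  for (cond in conds) {
    blks <- which(ann$condition == cond)
    segments[[cond]] <- lapply(seq_len(nrow(bands)), function(b)
      lapply(blks, function(blk) extract(filtered[[b]], blk)))
    names(segments[[cond]]) <- bands$name
    broadband[[cond]] <- lapply(blks, function(blk) extract(recording@data, blk))
  }

  new("ConditionBlocks", segments = segments, broadband = broadband,
      samplingRate = fs, channelNames = recording@channelNames, bands = bands,
      provenance = list(filter = sprintf("butterworth order %d, zero-phase", filterOrder),
                        bands = bands, baselineWindow = baselineWindow,
                        baselineFallbackBlocks = which(fallback)))
}

#' Standard preprocessing chain
#'
#' Broadband 1-45 Hz zero-phase band-pass, amplitude-based channel rejection,
#' then per-condition/band segmentation with baseline correction.
#'
#' @param recording An annotated [EegRecording()].
#' @param bands Band table.
#' @param broadband Length-2 numeric, broadband filter edges in Hz.
#' @param ... Passed to [rejectChannels()].
#' @return A `ConditionBlocks` object; rejected channels are recorded in the
#'   provenance.
#' @export
preprocessRecording <- function(recording, bands = defaultBands(),
                                broadband = c(1, 45), ...) {
  filt <- bandpassFilter(recording, broadband[1], broadband[2])
  rej <- rejectChannels(filt, ...)
  blocks <- splitConditionsAndBands(rej$recording, bands)
  blocks@provenance$broadband <- broadband
  blocks@provenance$rejectedChannels <- rej$rejected
  blocks
}
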