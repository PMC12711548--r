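# Welch power spectral density and band-averaged log power.

#' @rdname welchPsd
#' @export
setClass("PsdEstimate",
         representation(frequencies = "numeric",
                        power = "matrix",       # channels x frequencies, uV^2/Hz
                        params = "list"))

setValidity("PsdEstimate", function(object) {
  msg <- character()
  if (ncol(object@power) != length(object@frequencies))
    msg <- c(msg, "power columns must match frequency grid")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PsdEstimate", function(object) {
  cat(sprintf("PsdEstimate: %d channels x %d frequencies (0..%.4g Hz), %d-sample %s window, %d averaged segments\n",
              nrow(object@power), length(object@frequencies),
              max(object@frequencies), object@params$windowLen,
              object@params$window, object@params$nSegments))
})

#' @describeIn welchPsd one-sided frequency grid (Hz)
#' @param x A `PsdEstimate`.
#' @export
psdFrequencies <- function(x) x@frequencies

#' @describeIn welchPsd channels x frequencies power matrix (uV^2/Hz)
#' @export
psdPower <- function(x) x@power

#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is split into overlapping
#' windowed segments (128-sample Hamming window, 50% overlap by default),
#' each segment is zero-padded to `nfft` points, and the one-sided power
#' densities are averaged. One-sided density scaling conserves total power:
#' the integral of the PSD over frequency estimates the signal variance.
#'
#' With `windowLen` equal to the signal length, one segment and a
#' rectangular window, the estimate degenerates to the raw periodogram.
#'
#' @param segment Channels x samples matrix (a vector is treated as one
#'   channel).
#' @param fs Sampling rate in Hz.
#' @param windowLen Window length in samples (default 128).
#' @param overlap Overlap proportion in \[0, 1) (default 0.5).
#' @param nfft FFT length; segments are zero-padded to this (default 256).
#' @param window `"hamming"` (default) or `"rectangular"`.
#' @return A `PsdEstimate`.
#' @export
welchPsd <- function(segment, fs, windowLen = 128, overlap = 0.5, nfft = 256,
                     window = c("hamming", "rectangular")) {
  window <- match.arg(window)
  if (!is.matrix(segment)) segment <- matrix(segment, nrow = 1)
  n <- ncol(segment)
  if (n < windowLen)
    stop(sprintf("segment (%d samples) shorter than one window (%d)", n, windowLen))
  if (nfft < windowLen) stop("nfft must be >= windowLen")
  w <- if (window == "hamming") as.numeric(signal::hamming(windowLen)) else rep(1, windowLen)
  step <- max(1L, round(windowLen * (1 - overlap)))
  starts <- seq(1L, n - windowLen + 1L, by = step)
  U <- sum(w^2)
  nf <- nfft %/% 2 + 1L
  acc <- matrix(0, nrow(segment), nf)
  for (s in starts) {
    seg <- segment[, s:(s + windowLen - 1L), drop = FALSE] * rep(w, each = nrow(segment))
    padded <- cbind(seg, matrix(0, nrow(segment), nfft - windowLen))
    F <- mvfft(t(padded))[seq_len(nf), , drop = FALSE]
    acc <- acc + t(Mod(F)^2)
  }
  P <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC and (for even nfft) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nf] <- 1
  P <- P * rep(dbl, each = nrow(segment))
  freqs <- (seq_len(nf) - 1) * fs / nfft
  rownames(P) <- rownames(segment)
  new("PsdEstimate", frequencies = freqs, power = P,
      params = list(windowLen = windowLen, overlap = overlap, nfft = nfft,
                    window = window, fs = fs, nSegments = length(starts),
                    resolutionHz = fs / nfft))
}

#' Band-averaged log power
#'
#' Mean power over the frequency bins falling in the band (lower-inclusive,
#' upper-exclusive), log-transformed.
#'
#' @param psd A `PsdEstimate`.
#' @param band One-row band table (or list) with `lo` and `hi` in Hz.
#' @param log Apply the log transform (default `TRUE`).
#' @param base Logarithm base (default 10).
#' @return Named per-channel numeric vector.
#' @export
bandLogPower <- function(psd, band, log = TRUE, base = 10) {
  sel <- psd@frequencies >= band$lo & psd@frequencies < band$hi
  if (!any(sel))
    stop(sprintf("no frequency bins in band [%g, %g) Hz (grid step %g Hz)",
                 band$lo, band$hi, psd@params$resolutionHz))
  p <- rowMeans(psd@power[, sel, drop = FALSE])
  if (log) log(p, base = base) else p
}

#' Band log-power table for one subject
#'
#' Welch PSD is computed per broadband block segment, power is averaged
#' across segments (epochs) of the same condition, and the band means are
#' log-transformed afterwards.
#'
#' @param blocks A `ConditionBlocks` object.
#' @param subjectId Subject label for the output table.
#' @param ... Passed to [welchPsd()].
#' @return Long `data.frame` with columns `subject`, `condition`, `band`,
#'   `channel`, `log_power`.
#' @export
bandPowerTable <- function(blocks, subjectId = "S1", ...) {
  fs <- blocks@samplingRate
  bands <- blocks@bands
  out <- list()
  for (cond in names(blocks@broadband)) {
    segs <- blocks@broadband[[cond]]
    psds <- lapply(segs, welchPsd, fs = fs, ...)
    avg <- psds[[1]]
    if (length(psds) > 1) {
      pw <- Reduce(`+`, lapply(psds, psdPower)) / length(psds)
      avg <- new("PsdEstimate", frequencies = psds[[1]]@frequencies,
                 power = pw, params = psds[[1]]@params)
    }
    for (b in seq_len(nrow(bands))) {
      lp <- bandLogPower(avg, bands[b, ])
      out[[length(out) + 1L]] <- data.frame(
        subject = subjectId, condition = cond, band = bands$name[b],
        channel = blocks@channelNames, log_power = unname(lp),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
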