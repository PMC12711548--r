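# Phase-locking-value connectivity from analytic-signal phases.

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation: negative frequencies are zeroed, positive frequencies
#' doubled, DC (and Nyquist for even lengths) kept.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @return Complex vector/matrix of the same shape.
#' @export
analyticSignal <- function(x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(t(x)) * h
  z <- t(mvfft(X, inverse = TRUE)) / n
  if (vec) z[1, ] else z
}

#' Instantaneous phase of band-limited signals
#'
#' Per channel, the phase is the argument of the analytic signal, in
#' (-pi, pi]. Meaningful only for band-limited input; run the band filters
#' first.
#'
#' @param segment Numeric vector or channels x samples matrix.
#' @return Phase matrix (rad), channels x samples.
#' @export
instantaneousPhase <- function(segment) {
  if (!is.matrix(segment)) segment <- matrix(segment, nrow = 1)
  v <- apply(segment, 1, var)
  if (any(v == 0))
    stop("constant (zero-variance) channel(s): ",
         paste(which(v == 0), collapse = ", "))
  ph <- Arg(analyticSignal(segment))
  dimnames(ph) <- dimnames(segment)
  ph
}

#' Phase-locking value of one channel pair
#'
#' `PLV = | mean_t exp(i (phi_a(t) - phi_b(t))) |`: the modulus of the mean
#' resultant vector of the sample-by-sample phase differences. 0 means no
#' phase coupling, 1 perfect locking.
#'
#' @param phaseA,phaseB Phase series in radians, equal lengths >= 2.
#' @return Scalar in \[0, 1\].
#' @export
plvPair <- function(phaseA, phaseB) {
  if (length(phaseA) != length(phaseB)) stop("phase series length mismatch")
  if (length(phaseA) < 2) stop("need at least 2 samples")
  Mod(mean(exp(1i * (phaseA - phaseB))))
}

# All-pairs PLV of a phase matrix (channels x samples): |Z Z^H| / N with
# Z = exp(i phi).
plvAllPairs <- function(phase) {
  Z <- exp(1i * phase)
  M <- Mod(Z %*% Conj(t(Z))) / ncol(phase)
  pmin(M, 1)
}

#' Band-specific PLV connectivity matrix
#'
#' For one condition and band, the PLV is computed for every channel pair
#' within each segment (epoch) and averaged across segments. To suppress
#' Hilbert edge effects the first and last `edgeTrim` share of each
#' segment's phase series is discarded before the PLV. The diagonal is 1 by
#' definition.
#'
#' @param blocks A `ConditionBlocks` object.
#' @param condition Condition label.
#' @param band Band name.
#' @param edgeTrim Share of samples trimmed from each segment end
#'   (default 0.05).
#' @param subjectId Subject label carried into the result.
#' @return A `ConnectivityMatrix`.
#' @export
plvMatrix <- function(blocks, condition, band, edgeTrim = 0.05,
                      subjectId = "S1") {
  segs <- conditionSegments(blocks, condition, band)
  if (!length(segs)) stop("no segments for condition ", condition)
  nUsed <- 0L
  acc <- NULL
  for (seg in segs) {
    ph <- instantaneousPhase(seg)
    n <- ncol(ph)
    trim <- floor(edgeTrim * n)
    keep <- (trim + 1):(n - trim)
    ph <- ph[, keep, drop = FALSE]
    m <- plvAllPairs(ph)
    acc <- if (is.null(acc)) m else acc + m
    nUsed <- nUsed + length(keep)
  }
  m <- acc / length(segs)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(blocks@channelNames, blocks@channelNames)
  new("ConnectivityMatrix", values = m, band = band, condition = condition,
      subjectId = subjectId, nSamples = as.numeric(nUsed))
}

#' Edge names of a square connectivity matrix
#'
#' @param channels Channel labels.
#' @param mode `"unique"` for the strictly-upper-triangle (120 edges for 16
#'   channels) or `"full"` for all n^2 matrix entries by column
#'   (256 for 16 channels, diagonal included).
#' @return Character vector of edge labels `"A-B"`.
#' @export
edgeNames <- function(channels, mode = c("unique", "full")) {
  mode <- match.arg(mode)
  n <- length(channels)
  if (mode == "unique") {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  } else {
    idx <- cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))
  }
  paste0(channels[idx[, 1]], "-", channels[idx[, 2]])
}

#' Vectorize a connectivity matrix
#'
#' @param x A `ConnectivityMatrix` or plain square matrix.
#' @param mode `"unique"` (strictly-upper-triangle) or `"full"` (all
#'   entries, column order).
#' @return Named numeric vector of edge values.
#' @export
edgeVector <- function(x, mode = c("unique", "full")) {
  mode <- match.arg(mode)
  m <- if (is(x, "ConnectivityMatrix")) x@values else x
  chans <- rownames(m)
  if (is.null(chans)) chans <- as.character(seq_len(nrow(m)))
  v <- if (mode == "unique") m[upper.tri(m)] else as.numeric(m)
  names(v) <- edgeNames(chans, mode)
  v
}

#' Stack edge vectors of several subjects
#'
#' @param cms List of `ConnectivityMatrix` objects (one per subject, same
#'   condition/band).
#' @param mode Vectorization mode, see [edgeVector()].
#' @return Subjects x edges numeric matrix with edge names as columns and
#'   subject ids as rows.
#' @export
stackEdgeVectors <- function(cms, mode = c("unique", "full")) {
  mode <- match.arg(mode)
  m <- do.call(rbind, lapply(cms, edgeVector, mode = mode))
  rownames(m) <- vapply(cms, function(x) x@subjectId, character(1))
  m
}

#' Long-format edge table
#'
#' @param cm A `ConnectivityMatrix`.
#' @return `data.frame` with columns `subject`, `condition`, `band`, `ch_i`,
#'   `ch_j`, `plv` (unique pairs).
#' @export
plvEdgeTable <- function(cm) {
  n <- nrow(cm@values)
  idx <- which(upper.tri(cm@values), arr.ind = TRUE)
  chans <- rownames(cm@values)
  data.frame(subject = cm@subjectId, condition = cm@condition, band = cm@band,
             ch_i = chans[idx[, 1]], ch_j = chans[idx[, 2]],
             plv = cm@values[idx], stringsAsFactors = FALSE)
}
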