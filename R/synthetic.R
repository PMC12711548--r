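# Synthetic block-design EEG with known band-specific phase coupling.
#
# Mechanism: per band one shared oscillator phase Theta(t) evolves as a
# random-frequency walk confined to the band; every channel additionally
# carries an independent private oscillator Psi_i(t) with the same law.
# A channel's phase is the argument of the circular mixture
#   sqrt(lambda_i) e^{i Theta} + sqrt(1 - lambda_i) e^{i Psi_i},
# so lambda_i in [0,1] is the shared-phase fraction. Pairwise coupling
# kappa_ij is realised through per-channel loadings lambda_i with
# lambda_i * lambda_j ~ kappa_ij; the factorisation is exact for uniform and
# block-constant kappa (the default regimes) and an upper envelope otherwise.
# The empirical kappa -> PLV map is monotone but not the identity.

# Band-confined random-frequency walk; returns phase vector (rad).
# Instantaneous frequency is an AR(1) (mean band centre, time constant ~0.5 s)
# clipped to the band interior.
bandOscillator <- function(n, fs, lo, hi) {
  fc <- (lo + hi) / 2
  half <- (hi - lo) / 2
  rho <- exp(-1 / (0.5 * fs))
  eps <- rnorm(n)
  x <- as.numeric(stats::filter(eps * sqrt(1 - rho^2), rho,
                                method = "recursive", init = rnorm(1)))
  f <- pmin(pmax(fc + 0.5 * half * x, lo + 0.05 * half), hi - 0.05 * half)
  runif(1, -pi, pi) + 2 * pi * cumsum(f) / fs
}

# Per-channel shared-phase loadings from a pairwise coupling matrix.
channelLoadings <- function(kappa) {
  lam <- apply(kappa, 1, max)
  sqrt(pmax(lam, 0))
}

#' Generate one synthetic subject
#'
#' Simulates a block-design multichannel EEG run under a [ParadigmSpec()]
#' with ground-truth phase coupling from a [CouplingSpec()], plus an optional
#' FVC covariate. The output is deterministic given `seed`.
#'
#' Per band, a shared band-limited oscillator and per-channel private
#' oscillators are mixed with condition-specific shared-phase fractions
#' derived from the coupling matrices; the signal is the amplitude-weighted
#' sum of the band cosines plus white sensor noise.
#'
#' @param paradigm A [ParadigmSpec()].
#' @param coupling A [CouplingSpec()]; its channel set must match the
#'   paradigm's.
#' @param seed Integer seed; fixes the subject completely.
#' @param fvc Forced vital capacity in litres (`NA` if not measured).
#' @param subjectId Subject identifier.
#' @return A `SyntheticSubject` holding an annotated [EegRecording()].
#' @examples
#' paradigm <- ParadigmSpec(data.frame(condition = "SB", duration = 4),
#'                          channelNames = c("C3", "C4"))
#' coupling <- CouplingSpec(list(SB = list(alpha = uniformCoupling(1, c("C3", "C4")))),
#'                          bands = data.frame(name = "alpha", lo = 8, hi = 13),
#'                          amplitudes = c(alpha = 10), noiseSd = 0,
#'                          channelNames = c("C3", "C4"))
#' subj <- generateSubject(paradigm, coupling, seed = 1)
#' @export
generateSubject <- function(paradigm, coupling, seed, fvc = NA_real_,
                            subjectId = sprintf("S%06d", seed)) {
  validObject(paradigm)
  validObject(coupling)
  if (!identical(paradigm@channelNames, coupling@channelNames))
    stop("channel set mismatch between paradigm and coupling")
  bad <- setdiff(paradigm@blocks$condition, names(coupling@kappa))
  if (length(bad))
    stop("coupling has no entry for condition(s): ", paste(bad, collapse = ", "))

  fs <- paradigm@samplingRate
  chans <- paradigm@channelNames
  nch <- length(chans)
  lens <- round(paradigm@blocks$duration * fs)
  N <- sum(lens)
  starts <- cumsum(c(0, lens[-length(lens)]))  # 0-based
  bands <- coupling@bands

  set.seed(seed)
  x <- matrix(0, nch, N, dimnames = list(chans, NULL))
  for (b in seq_len(nrow(bands))) {
    bn <- bands$name[b]
    amp <- coupling@amplitudes[[bn]]
    theta <- bandOscillator(N, fs, bands$lo[b], bands$hi[b])
    psi <- matrix(0, nch, N)
    for (i in seq_len(nch)) psi[i, ] <- bandOscillator(N, fs, bands$lo[b], bands$hi[b])
    jit <- NULL
    if (coupling@phaseJitter > 0) {
      rho <- exp(-1 / (0.2 * fs))
      jit <- matrix(0, nch, N)
      for (i in seq_len(nch))
        jit[i, ] <- as.numeric(stats::filter(rnorm(N, sd = coupling@phaseJitter),
                                             rho, method = "recursive"))
    }
    for (blk in seq_along(lens)) {
      cond <- paradigm@blocks$condition[blk]
      kap <- coupling@kappa[[cond]][[bn]]
      if (is.null(kap)) kap <- uniformCoupling(0, chans)
      lam <- channelLoadings(kap)
      idx <- (starts[blk] + 1):(starts[blk] + lens[blk])
      zc <- exp(1i * theta[idx])
      for (i in seq_len(nch)) {
        phi <- Arg(sqrt(lam[i]) * zc + sqrt(1 - lam[i]) * exp(1i * psi[i, idx]))
        if (!is.null(jit)) phi <- phi + (1 - lam[i]) * jit[i, idx]
        x[i, idx] <- x[i, idx] + amp * cos(phi)
      }
    }
  }
  if (coupling@noiseSd > 0)
    x <- x + matrix(rnorm(nch * N, sd = coupling@noiseSd), nch, N)

  ann <- data.frame(condition = paradigm@blocks$condition,
                    start = starts, end = starts + lens,
                    stringsAsFactors = FALSE)
  rec <- EegRecording(x, fs, chans, ann)
  new("SyntheticSubject", recording = rec, fvc = fvc, subjectId = subjectId,
      groundTruth = coupling, seed = as.numeric(seed))
}

#' Sample per-subject edge couplings with a planted FVC association
#'
#' Linear-Gaussian construction: the planted edge's coupling for subject s is
#' `kappa0 + kappaSd * z_s` (clipped to \[0.02, 0.98\]) and
#' `FVC_s = fvcMean + targetR * fvcSd * z_s + fvcSd * sqrt(1 - targetR^2) * e_s`
#' with independent standard normal `z_s`, `e_s`, so the population
#' correlation between FVC and the latent coupling equals `targetR` exactly
#' (clipping is rare for the default `kappa0 = 0.5`, `kappaSd = 0.1`).
#'
#' @param n Number of subjects.
#' @param targetR Target population correlation, `|targetR| < 1`.
#' @param kappa0 Mean coupling at the planted edge.
#' @param kappaSd SD of the per-subject coupling (default 0.1).
#' @param fvcMean,fvcSd FVC population mean and SD in litres.
#' @return `data.frame` with columns `kappa`, `fvc`.
#' @export
sampleFvcCouplings <- function(n, targetR, kappa0 = 0.5, kappaSd = 0.1,
                               fvcMean = 4.0, fvcSd = 0.8) {
  if (abs(targetR) >= 1) stop("|targetR| must be < 1")
  z <- rnorm(n)
  e <- rnorm(n)
  kappa <- pmin(pmax(kappa0 + kappaSd * z, 0.02), 0.98)
  fvc <- fvcMean + targetR * fvcSd * z + fvcSd * sqrt(1 - targetR^2) * e
  fvc <- pmax(fvc, 0.5)  # FVC is physically positive
  data.frame(kappa = kappa, fvc = fvc)
}

#' Generate a synthetic cohort
#'
#' Produces `nSubjects` independent subjects under a common paradigm and
#' coupling specification. When `fvcAssoc` is supplied, the coupling of one
#' chosen (edge, band, condition) varies across subjects and FVC is drawn so
#' that its population correlation with that coupling equals `targetR` (see
#' [sampleFvcCouplings()]); all other edges are independent of FVC.
#'
#' @param nSubjects Number of subjects (>= 3).
#' @param paradigm A [ParadigmSpec()].
#' @param coupling A [CouplingSpec()].
#' @param fvcAssoc `NULL`, or a list with elements `edge` (two channel
#'   labels), `band`, `condition`, `targetR`, and optionally `kappa0`
#'   (default: the coupling spec's value at that edge), `kappaSd` (0.1),
#'   `fvcMean` (4.0), `fvcSd` (0.8).
#' @param seed Integer seed for the whole cohort.
#' @return List of `SyntheticSubject`s.
#' @export
generateCohort <- function(nSubjects, paradigm = defaultParadigm(),
                           coupling = defaultCoupling(), fvcAssoc = NULL,
                           seed = 1) {
  if (nSubjects < 3) stop("nSubjects must be >= 3")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nSubjects)
  draw <- NULL
  if (!is.null(fvcAssoc)) {
    chans <- paradigm@channelNames
    if (!all(fvcAssoc$edge %in% chans))
      stop("fvcAssoc edge not in channel set: ",
           paste(setdiff(fvcAssoc$edge, chans), collapse = ", "))
    if (abs(fvcAssoc$targetR) >= 1) stop("|targetR| must be < 1")
    kappa0 <- fvcAssoc$kappa0
    if (is.null(kappa0))
      kappa0 <- coupling@kappa[[fvcAssoc$condition]][[fvcAssoc$band]][fvcAssoc$edge[1], fvcAssoc$edge[2]]
    draw <- sampleFvcCouplings(nSubjects, fvcAssoc$targetR, kappa0,
                               kappaSd = fvcAssoc$kappaSd %||% 0.1,
                               fvcMean = fvcAssoc$fvcMean %||% 4.0,
                               fvcSd = fvcAssoc$fvcSd %||% 0.8)
  } else {
    draw <- data.frame(kappa = NA_real_,
                       fvc = pmax(rnorm(nSubjects, 4.0, 0.8), 0.5))
  }
  lapply(seq_len(nSubjects), function(s) {
    coup <- coupling
    if (!is.null(fvcAssoc)) {
      k <- coup@kappa[[fvcAssoc$condition]][[fvcAssoc$band]]
      k[fvcAssoc$edge[1], fvcAssoc$edge[2]] <- draw$kappa[s]
      k[fvcAssoc$edge[2], fvcAssoc$edge[1]] <- draw$kappa[s]
      coup@kappa[[fvcAssoc$condition]][[fvcAssoc$band]] <- k
    }
    generateSubject(paradigm, coup, seed = seeds[s], fvc = draw$fvc[s],
                    subjectId = sprintf("S%03d", s))
  })
}

#' Cohort manifest table
#'
#' @param subjects List of `SyntheticSubject`s.
#' @return `data.frame` with columns `subject_id`, `fvc`, `seed`.
#' @export
cohortManifest <- function(subjects) {
  data.frame(subject_id = vapply(subjects, subjectId, character(1)),
             fvc = vapply(subjects, subjectFvc, numeric(1)),
             seed = vapply(subjects, function(s) s@seed, numeric(1)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
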