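# End-to-end orchestration: simulate/ingest -> preprocess -> PSD -> PLV ->
# graph metrics -> group statistics -> FVC correlation -> classification.

#' Pipeline configuration
#'
#' Assembles the configuration for [runPipeline()] with the standard
#' defaults. Any element can be overridden; the configuration can also be
#' stored as, and read back from, a YAML file ([readPipelineConfig()]).
#'
#' @param outDir Output directory for all artifacts.
#' @param nSubjects Cohort size for the simulate stage.
#' @param paradigm [ParadigmSpec()] for the simulate stage.
#' @param coupling [CouplingSpec()] for the simulate stage.
#' @param seed Master seed; independent stage seeds are derived from it.
#' @param fvcAssoc Planted FVC association (see [generateCohort()]), or
#'   `NULL`.
#' @param bands Band table.
#' @param broadband Broadband filter edges (Hz).
#' @param psd Welch settings (`windowLen`, `overlap`, `nfft`).
#' @param plv PLV settings (`edgeTrim`).
#' @param stats Group-statistics settings (`fweMethod`, `alphaFwe`,
#'   `alphaFdr`, `nPerm`, `paired`, `corMode`).
#' @param classifier Classification settings (`folds`, `repeats`,
#'   `kNeighbors`, `band`, `spec`).
#' @param inputPrefixes Optional character vector of recording path
#'   prefixes to ingest instead of simulating; FVC values are then taken
#'   from `fvc`.
#' @param fvc Optional per-subject FVC vector for ingested recordings.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(outDir = tempfile("breathnet_run_"),
                           nSubjects = 12, paradigm = defaultParadigm(),
                           coupling = defaultCoupling(), seed = 1,
                           fvcAssoc = list(edge = c("C4", "T8"),
                                           band = "theta", condition = "PB",
                                           targetR = 0.5),
                           bands = defaultBands(), broadband = c(1, 45),
                           psd = list(windowLen = 128, overlap = 0.5, nfft = 256),
                           plv = list(edgeTrim = 0.05),
                           stats = list(fweMethod = "maxT", alphaFwe = 0.01,
                                        alphaFdr = 0.01, nPerm = 1000,
                                        paired = FALSE, corMode = "full"),
                           classifier = list(folds = 10, repeats = 10,
                                             kNeighbors = 10, band = "alpha",
                                             spec = classifierSpec()),
                           inputPrefixes = NULL, fvc = NULL) {
  structure(list(outDir = outDir, nSubjects = nSubjects,
                 paradigm = paradigm, coupling = coupling, seed = seed,
                 fvcAssoc = fvcAssoc, bands = bands, broadband = broadband,
                 psd = psd, plv = plv, stats = stats, classifier = classifier,
                 inputPrefixes = inputPrefixes, fvc = fvc),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; recognised top-level keys match the arguments of
#'   [pipelineConfig()] (the band table as a list of `name`/`lo`/`hi`
#'   records).
#' @return A `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (key in c("outDir", "nSubjects", "seed", "broadband", "inputPrefixes", "fvc"))
    if (!is.null(raw[[key]])) args[[key]] <- unlist(raw[[key]])
  if (!is.null(raw$bands))
    args$bands <- do.call(rbind, lapply(raw$bands, as.data.frame))
  for (key in c("fvcAssoc", "psd", "plv", "stats", "classifier"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  if (!is.null(args$fvcAssoc$edge)) args$fvcAssoc$edge <- unlist(args$fvcAssoc$edge)
  if (!is.null(args$classifier$spec)) args$classifier$spec <- do.call(classifierSpec, args$classifier$spec)
  else if (!is.null(args$classifier)) args$classifier$spec <- classifierSpec()
  do.call(pipelineConfig, args)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest), preprocessing, Welch band power, PLV
#' connectivity, weighted network metrics, pairwise condition contrasts with
#' FWE control (band power, PLV edges and network metrics), FVC-edge
#' correlation with BH-FDR, and the three-way condition classification.
#' All artifacts are written to `config$outDir` as delimited tables and a
#' manifest with per-file checksums; identical configurations and seeds
#' reproduce identical outputs.
#'
#' @param config A [pipelineConfig()].
#' @return List with elements `manifest` (data.frame of files, checksums,
#'   stages), `bandPower`, `edges` (per band/condition subject x edge
#'   matrices), `metrics`, `contrasts`, `correlation`, `classification`,
#'   `rejected`, `timings`.
#' @export
runPipeline <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = character(), stage = character(),
                         stringsAsFactors = FALSE)
  addFile <- function(path, stage) {
    manifest <<- rbind(manifest, data.frame(file = path, stage = stage,
                                            stringsAsFactors = FALSE))
  }
  timings <- numeric(0)
  lastT <- t0
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[stage] <<- t1 - lastT
    lastT <<- t1
  }

  # --- simulate or ingest -------------------------------------------------
  if (is.null(config$inputPrefixes)) {
    subjects <- generateCohort(config$nSubjects, config$paradigm,
                               config$coupling, fvcAssoc = config$fvcAssoc,
                               seed = config$seed)
    recs <- lapply(subjects, subjectRecording)
    fvc <- vapply(subjects, subjectFvc, numeric(1))
    ids <- vapply(subjects, subjectId, character(1))
    addFile(writeTsv(cohortManifest(subjects),
                     file.path(config$outDir, "cohort_manifest.tsv")), "simulate")
  } else {
    recs <- lapply(config$inputPrefixes, readRecording)
    ids <- sprintf("S%03d", seq_along(recs))
    fvc <- config$fvc %||% rep(NA_real_, length(recs))
  }
  tick("simulate")

  # --- preprocess ---------------------------------------------------------
  blocks <- vector("list", length(recs))
  rejected <- list()
  for (s in seq_along(recs)) {
    blocks[[s]] <- preprocessRecording(recs[[s]], bands = config$bands,
                                       broadband = config$broadband)
    rejected[[ids[s]]] <- blocks[[s]]@provenance$rejectedChannels
  }
  tick("preprocess")

  # --- PSD ----------------------------------------------------------------
  bandPower <- do.call(rbind, lapply(seq_along(blocks), function(s)
    bandPowerTable(blocks[[s]], subjectId = ids[s],
                   windowLen = config$psd$windowLen,
                   overlap = config$psd$overlap, nfft = config$psd$nfft)))
  addFile(writeTsv(bandPower, file.path(config$outDir, "band_power.tsv")), "psd")
  tick("psd")

  # --- PLV ----------------------------------------------------------------
  bands <- config$bands$name
  conds <- intersect(CONDITIONS, names(blocks[[1]]@segments))
  cms <- list()   # [[band]][[condition]] -> list over subjects
  for (band in bands) for (cond in conds) {
    cms[[band]][[cond]] <- lapply(seq_along(blocks), function(s)
      plvMatrix(blocks[[s]], cond, band, edgeTrim = config$plv$edgeTrim,
                subjectId = ids[s]))
    for (cm in cms[[band]][[cond]])
      addFile(writeConnectivityMatrix(cm, file.path(config$outDir,
              sprintf("plv_%s_%s_%s.tsv", cm@subjectId, cond, band))), "plv")
  }
  tick("plv")

  # --- network metrics ----------------------------------------------------
  metrics <- do.call(rbind, lapply(bands, function(band)
    do.call(rbind, lapply(conds, function(cond)
      do.call(rbind, lapply(cms[[band]][[cond]], function(cm) {
        m <- networkMetrics(cm)
        data.frame(subject = cm@subjectId, condition = cond, band = band,
                   cc = m$cc, le = m$le, ge = m$ge, dc = m$dc,
                   stringsAsFactors = FALSE)
      }))))))
  addFile(writeTsv(metrics, file.path(config$outDir, "network_metrics.tsv")),
          "graph")
  tick("graph")

  # --- group statistics ---------------------------------------------------
  contrastPairs <- list(c("SB", "BH"), c("PB", "BH"), c("SB", "PB"))
  contrastPairs <- Filter(function(p) all(p %in% conds), contrastPairs)
  statsSeed <- config$seed + 7919L
  contrasts <- list()
  for (band in bands) {
    edgesByCond <- lapply(cms[[band]], stackEdgeVectors, mode = "unique")
    for (pair in contrastPairs) {
      lab <- paste(pair, collapse = "-")
      # PLV edge contrast
      fwe <- fweCorrect(edgesByCond[[pair[1]]], edgesByCond[[pair[2]]],
                        alpha = config$stats$alphaFwe,
                        method = config$stats$fweMethod,
                        nPerm = config$stats$nPerm, seed = statsSeed,
                        paired = config$stats$paired, label = lab)
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        band = band, contrast = lab, featureType = "plv_edge",
        feature = fwe$features, t = fwe$t, p = fwe$p,
        significant = fwe$mask, stringsAsFactors = FALSE)
      # band-power contrast per channel
      pw <- lapply(pair, function(cond) {
        sub <- bandPower[bandPower$band == band & bandPower$condition == cond, ]
        m <- matrix(sub$log_power, nrow = length(unique(sub$subject)),
                    byrow = TRUE)
        colnames(m) <- sub$channel[seq_len(ncol(m))]
        m
      })
      fweP <- fweCorrect(pw[[1]], pw[[2]], alpha = config$stats$alphaFwe,
                         method = config$stats$fweMethod,
                         nPerm = config$stats$nPerm, seed = statsSeed,
                         paired = config$stats$paired, label = lab)
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        band = band, contrast = lab, featureType = "psd_channel",
        feature = fweP$features, t = fweP$t, p = fweP$p,
        significant = fweP$mask, stringsAsFactors = FALSE)
      # network-metric contrast
      mm <- lapply(pair, function(cond)
        as.matrix(metrics[metrics$band == band & metrics$condition == cond,
                          c("cc", "le", "ge", "dc")]))
      ct <- contrastTtest(mm[[1]], mm[[2]], paired = config$stats$paired,
                          label = lab)
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        band = band, contrast = lab, featureType = "network_metric",
        feature = ct$features, t = ct$t, p = ct$p,
        significant = ct$p < config$stats$alphaFwe, stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, contrasts)
  addFile(writeTsv(contrasts, file.path(config$outDir, "contrasts.tsv")),
          "stats")
  tick("stats")

  # --- FVC correlation ----------------------------------------------------
  correlation <- NULL
  if (all(is.na(fvc))) {
    warning("no FVC values available; correlation stage skipped")
  } else {
    correlation <- do.call(rbind, lapply(bands, function(band) {
      em <- lapply(cms[[band]], stackEdgeVectors, mode = config$stats$corMode)
      fvcCorrelation(em, fvc, alpha = config$stats$alphaFdr,
                     mode = config$stats$corMode, band = band)
    }))
    addFile(writeTsv(correlation,
                     file.path(config$outDir, "fvc_correlation.tsv")), "correlate")
  }
  tick("correlate")

  # --- classification -----------------------------------------------------
  clBand <- config$classifier$band
  Xlist <- lapply(conds, function(cond) stackEdgeVectors(cms[[clBand]][[cond]],
                                                         mode = "unique"))
  X <- do.call(rbind, Xlist)
  yLab <- rep(conds, times = vapply(Xlist, nrow, integer(1)))
  classification <- crossValidate(X, yLab, spec = config$classifier$spec,
                                  folds = config$classifier$folds,
                                  repeats = config$classifier$repeats,
                                  seed = config$seed + 104729L,
                                  kNeighbors = config$classifier$kNeighbors)
  report <- data.frame(band = clBand,
                       accuracy = classification$accuracy,
                       kappa = classification$kappa)
  addFile(writeTsv(report, file.path(config$outDir, "classification.tsv")),
          "classify")
  tick("classify")

  manifest$md5 <- unname(tools::md5sum(manifest$file))
  writeTsv(manifest, file.path(config$outDir, "manifest.tsv"))
  list(manifest = manifest, bandPower = bandPower, edges = cms,
       metrics = metrics, contrasts = contrasts, correlation = correlation,
       classification = classification, rejected = rejected,
       timings = timings)
}
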