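# Delimited-matrix + structured-sidecar reader/writer for recordings.
#
# One recording is a pair of files: <prefix>_data.tsv (samples x channels,
# tab-delimited with a header row of channel names) and <prefix>_sidecar.yaml
# carrying sampling_rate, channel names and block annotations as a
# (condition, start_s, end_s) table.

#' Write a recording to disk
#'
#' @param recording An [EegRecording()].
#' @param prefix Path prefix; `<prefix>_data.tsv` and
#'   `<prefix>_sidecar.yaml` are written.
#' @param digits Significant digits for the data file (default 8).
#' @return Invisibly, the two file paths.
#' @export
writeRecording <- function(recording, prefix, digits = 8) {
  dataPath <- paste0(prefix, "_data.tsv")
  sidecarPath <- paste0(prefix, "_sidecar.yaml")
  df <- as.data.frame(signif(t(recording@data), digits))
  names(df) <- recording@channelNames
  write.table(df, dataPath, sep = "\t", row.names = FALSE, quote = FALSE)
  fs <- recording@samplingRate
  ann <- recording@annotations
  yaml::write_yaml(list(
    sampling_rate = fs,
    channels = as.list(recording@channelNames),
    annotations = lapply(seq_len(nrow(ann)), function(i)
      list(condition = ann$condition[i],
           start_s = ann$start[i] / fs,
           end_s = ann$end[i] / fs))), sidecarPath)
  invisible(c(dataPath, sidecarPath))
}

#' Read a recording from disk
#'
#' Counterpart of [writeRecording()]; validates that the sidecar names the
#' sampling rate, channels and annotations, and that the channel set matches
#' the data file.
#'
#' @param prefix Path prefix used at write time.
#' @return An [EegRecording()].
#' @export
readRecording <- function(prefix) {
  dataPath <- paste0(prefix, "_data.tsv")
  sidecarPath <- paste0(prefix, "_sidecar.yaml")
  if (!file.exists(dataPath)) stop("missing data file: ", dataPath)
  if (!file.exists(sidecarPath)) stop("missing sidecar: ", sidecarPath)
  side <- yaml::read_yaml(sidecarPath)
  for (field in c("sampling_rate", "channels", "annotations"))
    if (is.null(side[[field]]))
      stop("sidecar is missing required field '", field, "'")
  fs <- side$sampling_rate
  if (!is.numeric(fs) || fs <= 0)
    stop("sidecar field 'sampling_rate' must be a positive number")
  chans <- unlist(side$channels)
  df <- read.table(dataPath, header = TRUE, sep = "\t", check.names = FALSE)
  if (!identical(names(df), chans))
    stop(sprintf("channel mismatch: sidecar lists %d channels, data file has %d (%s)",
                 length(chans), ncol(df),
                 paste(head(setdiff(chans, names(df))), collapse = ", ")))
  ann <- do.call(rbind, lapply(side$annotations, function(a) {
    for (field in c("condition", "start_s", "end_s"))
      if (is.null(a[[field]]))
        stop("annotation entry missing field '", field, "'")
    data.frame(condition = a$condition,
               start = round(a$start_s * fs), end = round(a$end_s * fs),
               stringsAsFactors = FALSE)
  }))
  EegRecording(t(as.matrix(df)), fs, chans, ann)
}

#' Write a connectivity matrix as a delimited square table
#'
#' @param cm A `ConnectivityMatrix`.
#' @param path Output path (tab-delimited, channel names as header and
#'   row names).
#' @export
writeConnectivityMatrix <- function(cm, path) {
  write.table(format(cm@values, digits = 10), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' Read a connectivity matrix written by [writeConnectivityMatrix()]
#'
#' @param path File path.
#' @param band,condition,subjectId Metadata to attach.
#' @export
readConnectivityMatrix <- function(path, band = "", condition = "",
                                   subjectId = "") {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  new("ConnectivityMatrix", values = m, band = band, condition = condition,
      subjectId = subjectId, nSamples = NA_real_)
}
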