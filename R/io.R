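#' Write a trial set to a plain-text dataset container
#'
#' Lays the dataset out as a directory: `meta.json` (sampling rate, channel
#' names, labels, segment lengths and, when present, the ground-truth
#' coherence matrices of a simulated set) plus one tab-separated
#' channels x samples file per trial (rest and MI segments concatenated).
#'
#' @param trials A `trial_set`.
#' @param path Directory to create (must not already contain a dataset
#'   unless `overwrite = TRUE`).
#' @param overwrite Replace an existing container.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(trials, path, overwrite = FALSE) {
  stopifnot(inherits(trials, "trial_set"))
  if (dir.exists(path) && !overwrite && length(list.files(path)))
    stop("'", path, "' exists and is not empty; use overwrite = TRUE")
  dir.create(file.path(path, "trials"), recursive = TRUE,
             showWarnings = FALSE)
  gt <- attr(trials, "ground_truth")
  meta <- list(fs = attr(trials, "fs"),
               channel_names = attr(trials, "channel_names"),
               labels = trial_labels(trials),
               n_rest = vapply(trials, function(t) ncol(t$rest), integer(1)),
               n_mi = vapply(trials, function(t) ncol(t$mi), integer(1)),
               band = unclass(trials[[1]]$band))
  if (!is.null(gt)) meta$ground_truth <- lapply(gt, unclass)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  for (i in seq_along(trials)) {
    utils::write.table(
      cbind(trials[[i]]$rest, trials[[i]]$mi),
      file.path(path, "trials", sprintf("trial_%04d.tsv", i)),
      sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a trial set from a plain-text dataset container
#'
#' @param path Directory written by [write_dataset()].
#' @return A `trial_set` (with the `ground_truth` attribute if stored).
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  band <- frequency_band(meta$band$lo, meta$band$hi, meta$band$name)
  files <- sort(list.files(file.path(path, "trials"), full.names = TRUE))
  trials <- lapply(seq_along(files), function(i) {
    m <- as.matrix(utils::read.table(files[i], sep = "\t"))
    dimnames(m) <- NULL
    rownames(m) <- meta$channel_names
    mi_trial(meta$labels[i], m[, seq_len(meta$n_rest[i]), drop = FALSE],
             m[, meta$n_rest[i] + seq_len(meta$n_mi[i]), drop = FALSE],
             band, meta$fs, meta$channel_names)
  })
  ts <- new_trial_set(trials, meta$channel_names, meta$fs)
  if (!is.null(meta$ground_truth))
    attr(ts, "ground_truth") <- lapply(meta$ground_truth, function(m) {
      m <- as.matrix(m)
      dimnames(m) <- list(meta$channel_names, meta$channel_names)
      m
    })
  ts
}

#' Export a coherence matrix as TSV
#'
#' Tab-separated n x n matrix with a header row (and first column) of
#' channel names.
#'
#' @param W A `coherence_matrix` (or plain named matrix).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coherence_tsv <- function(W, path) {
  utils::write.table(format(unclass(W), digits = 10), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a coherence matrix from TSV
#'
#' @param path File written by [write_coherence_tsv()].
#' @param band Optional [frequency_band()] to attach.
#' @return A `coherence_matrix`.
#' @export
read_coherence_tsv <- function(path, band = NULL) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  structure(m, band = band, class = c("coherence_matrix", "matrix"))
}

#' Read a montage file
#'
#' Plain text, one electrode name per line; blank lines and `#` comments
#' are ignored.
#'
#' @param path Montage file.
#' @return Character vector of channel names.
#' @export
read_montage <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x)) stop("montage file contains duplicate names")
  x
}

#' Write a recording to EDF
#'
#' Minimal European Data Format writer: 16-bit samples, one-second data
#' records, per-channel physical scaling from the data range.  Plain EDF
#' has no annotation stream, so event markers are not stored (use the text
#' dataset container for labelled trials).  A trailing partial second is
#' dropped.
#'
#' @param rec An [eeg_recording()].
#' @param path Output `.edf` file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  if (n_rec * fs < ncol(rec$samples))
    warning("dropping trailing partial second (",
            ncol(rec$samples) - n_rec * fs, " samples)")
  ns <- nrow(rec$samples)
  X <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(X, 1, min)
  pmax_ <- apply(X, 1, max)
  span <- pmax_ - pmin_
  pmin_[span == 0] <- pmin_[span == 0] - 1
  pmax_[span == 0] <- pmax_[span == 0] + 1
  dmin <- -32768
  dmax <- 32767
  pad <- function(x, w) formatC(substr(as.character(x), 1, w), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8), pad(1, 8),
    pad(ns, 4)), con, eos = NULL)
  fields <- list(c(16, rec$channel_names), c(80, rep("", ns)),
                 c(8, rep("uV", ns)),
                 c(8, formatC(pmin_, digits = 5, format = "g")),
                 c(8, formatC(pmax_, digits = 5, format = "g")),
                 c(8, rep(dmin, ns)), c(8, rep(dmax, ns)),
                 c(80, rep("", ns)), c(8, rep(fs, ns)), c(32, rep("", ns)))
  for (f in fields) {
    w <- as.integer(f[1])
    for (v in f[-1]) writeChar(pad(v, w), con, eos = NULL)
  }
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      v <- X[ch, ((r - 1) * fs + 1):(r * fs)]
      d <- as.integer(round((v - pmin_[ch]) * scale[ch] + dmin))
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Minimal European Data Format reader for 16-bit continuous EDF files
#' with a common sampling rate across channels.  Annotation channels
#' (EDF+) are not interpreted.
#'
#' @param path `.edf` file.
#' @return An [eeg_recording()] with empty events.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                   endian = "little")
      out[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (d - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  eeg_recording(out, labels, fs)
}

#' Save / load a fitted model
#'
#' Single-file checkpoint holding the fitted parameters, pooling
#' hierarchy, graph, configuration and training history.
#'
#' @param object A fitted [cgcn()] model.
#' @param path Checkpoint file.
#' @return `path` invisibly; `read_model()` returns the `cgcn` object.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "cgcn"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "cgcn")) stop("'", path, "' is not a cgcn checkpoint")
  obj
}

#' Write evaluation metrics as JSON
#'
#' @param metrics A `cgcn_metrics` or `cgcn_cv` object.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  if (inherits(metrics, "cgcn_metrics")) {
    out <- list(accuracy = metrics$accuracy, f1 = metrics$f1,
                loss = metrics$loss, n = metrics$n,
                confusion = unclass(as.matrix(metrics$confusion)))
  } else if (inherits(metrics, "cgcn_cv")) {
    out <- list(summary = metrics$summary,
                folds = lapply(metrics$folds, function(m)
                  list(accuracy = m$accuracy, f1 = m$f1, loss = m$loss,
                       n = m$n)))
  } else stop("unsupported metrics object")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
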