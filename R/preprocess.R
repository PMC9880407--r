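#' Standard 21-electrode 10-20 montage
#'
#' Electrode names of the 21-channel international 10-20 layout used for
#' scalp-level connectivity analysis (frontal-polar through occipital rows).
#'
#' @format Character vector of 21 channel names.
#' @export
montage_1020 <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                  "T7", "C3", "Cz", "C4", "T8",
                  "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")

#' Frequency band definition
#'
#' @param lo Lower edge in Hz (exclusive of 0).
#' @param hi Upper edge in Hz; must exceed `lo`.
#' @param name Band label, e.g. `"mu"`, `"beta"`, `"mu_beta"`, `"broadband"`.
#' @return An object of class `frequency_band`.
#' @export
frequency_band <- function(lo, hi, name = "band") {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1, length(hi) == 1)
  if (!(lo >= 0 && hi > lo))
    stop("invalid frequency band: need 0 <= lo < hi, got [", lo, ", ", hi, "]")
  structure(list(lo = lo, hi = hi, name = name), class = "frequency_band")
}

#' Sensorimotor rhythm bands
#'
#' The mu (8-13 Hz), beta (13-30 Hz) and combined mu+beta (8-30 Hz) bands
#' conventionally used for motor-imagery analysis.  Boundaries are
#' configurable by constructing [frequency_band()] objects directly.
#'
#' @param which Optional subset of band names.
#' @return Named list of `frequency_band` objects.
#' @export
rhythm_bands <- function(which = c("mu", "beta", "mu_beta")) {
  all <- list(mu      = frequency_band(8, 13, "mu"),
              beta    = frequency_band(13, 30, "beta"),
              mu_beta = frequency_band(8, 30, "mu_beta"))
  all[match.arg(which, names(all), several.ok = TRUE)]
}

#' Multichannel EEG recording
#'
#' Container for a continuous multichannel recording: a channels-by-time
#' sample matrix, ordered channel names, sampling rate and event markers
#' (motor-imagery onsets with class labels).
#'
#' @param samples Numeric matrix, channels x time samples.
#' @param channel_names Character vector, one unique name per row.
#' @param fs Sampling rate in Hz.
#' @param events Optional data.frame with columns `sample` (1-based MI onset
#'   index) and `label` (class label).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, channel_names, fs, events = NULL) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), fs > 0)
  if (length(channel_names) != nrow(samples))
    stop("channel_names length must equal the number of rows of samples")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), label = character(0))
  } else {
    events <- as.data.frame(events)
    stopifnot(all(c("sample", "label") %in% names(events)))
    if (nrow(events) && (min(events$sample) < 1 ||
                         max(events$sample) > ncol(samples)))
      stop("event sample indices fall outside the recording")
  }
  rownames(samples) <- channel_names
  structure(list(samples = samples, channel_names = channel_names,
                 fs = fs, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$events)))
  invisible(x)
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each time sample has zero mean over the montage.  This stands in for
#' reference-free transformations that require a head model.
#'
#' @param rec An [eeg_recording()].
#' @return A re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2)
    stop("average re-referencing needs at least 2 channels")
  rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  rec
}

# Butterworth band-pass design (transfer-function form), shared by the
# preprocessing and simulation code so analysis and generation use one filter.
butter_bandpass <- function(band, fs, order = 5) {
  stopifnot(inherits(band, "frequency_band"))
  if (band$hi >= fs / 2)
    stop("band edge ", band$hi, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  if (band$lo <= 0)
    stop("band-pass low edge must be > 0 Hz")
  signal::butter(order, c(band$lo, band$hi) / (fs / 2), type = "pass")
}

# Single-pass complex frequency response H(f) of an ARMA filter.
filter_response <- function(filt, f, fs) {
  z <- exp(-2i * pi * f / fs)
  num <- outer(z, seq_along(filt$b) - 1, `^`) %*% filt$b
  den <- outer(z, seq_along(filt$a) - 1, `^`) %*% filt$a
  as.vector(num / den)
}

#' Magnitude response of the zero-phase band-pass filter
#'
#' Returns the amplitude gain of the forward-backward Butterworth band-pass
#' at the requested frequencies, i.e. the squared single-pass magnitude
#' response |H(f)|^2 (zero-phase filtering applies the filter twice).
#'
#' @param f Frequencies in Hz.
#' @param band A [frequency_band()].
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order (per pass) of the underlying design.
#' @return Numeric vector of amplitude gains.
#' @export
bandpass_gain <- function(f, band, fs, order = 5) {
  Mod(filter_response(butter_bandpass(band, fs, order), f, fs))^2
}

# Single-pass IIR filtering started in steady state with respect to the
# first sample: the difference equation is seeded as if the input had been
# x[1] forever, so a constant input yields its steady-state output from
# sample one with no startup transient.  Linear in x.
iir_filter <- function(filt, x) {
  b <- filt$b / filt$a[1]
  a <- filt$a / filt$a[1]
  nb <- length(b)
  xx <- c(rep(x[1], nb - 1L), x)
  u <- stats::filter(xx, b, method = "convolution", sides = 1)
  u <- as.numeric(u[nb:length(xx)])
  y0 <- x[1] * sum(b) / sum(a)
  as.numeric(stats::filter(u, -a[-1], method = "recursive",
                           init = rep(y0, length(a) - 1L)))
}

# Zero-phase filtering with odd-reflection edge padding; operates on a
# vector or on each row of a matrix.
filtfilt_pad <- function(filt, x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, function(r) filtfilt_pad(filt, r)))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  npad <- 3L * (length(filt$a) - 1L)
  if (n <= npad)
    stop("signal too short for zero-phase filtering (need > ", npad,
         " samples, got ", n, ")")
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  ext <- c(head_pad, x, tail_pad)
  y <- iir_filter(filt, ext)
  y <- rev(iir_filter(filt, rev(y)))
  as.numeric(y[(npad + 1):(npad + n)])
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel of a recording.  The effective amplitude response is the squared
#' single-pass response, so attenuation at the -3 dB edges is -6 dB.
#'
#' @param rec An [eeg_recording()].
#' @param band A [frequency_band()]; edges must lie below Nyquist.
#' @param order Butterworth order, default 5.
#' @return The filtered `eeg_recording`.
#' @export
bandpass <- function(rec, band, order = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  filt <- butter_bandpass(band, rec$fs, order)
  rec$samples <- filtfilt_pad(filt, rec$samples)
  rec
}

#' Select and reorder channels
#'
#' @param rec An [eeg_recording()].
#' @param montage Ordered character vector of channel names to keep; every
#'   name must be present in the recording.
#' @return The recording restricted to `montage`, in montage order.
#' @export
select_channels <- function(rec, montage) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(montage, rec$channel_names)
  if (length(missing))
    stop("channels not present in recording: ",
         paste(missing, collapse = ", "))
  idx <- match(montage, rec$channel_names)
  eeg_recording(rec$samples[idx, , drop = FALSE], montage, rec$fs, rec$events)
}

#' Single labelled motor-imagery trial
#'
#' @param label Class label (e.g. `"left"` or `"right"`).
#' @param rest Channels x samples matrix of the pre-cue rest segment.
#' @param mi Channels x samples matrix of the motor-imagery segment.
#' @param band The [frequency_band()] the trial is filtered to
#'   (`"broadband"` for raw trials).
#' @param fs Sampling rate in Hz.
#' @param channel_names Ordered channel names.
#' @return An object of class `mi_trial`.
#' @export
mi_trial <- function(label, rest, mi, band, fs, channel_names) {
  stopifnot(nrow(rest) == nrow(mi), nrow(mi) == length(channel_names))
  structure(list(label = label, rest = rest, mi = mi, band = band,
                 fs = fs, channel_names = channel_names),
            class = "mi_trial")
}

new_trial_set <- function(trials, channel_names, fs) {
  structure(trials, channel_names = channel_names, fs = fs,
            class = "trial_set")
}

#' @export
`[.trial_set` <- function(x, i) {
  new_trial_set(unclass(x)[i], attr(x, "channel_names"), attr(x, "fs"))
}

#' Trial labels of a trial set
#' @param trials A `trial_set`.
#' @return Character vector of labels.
#' @export
trial_labels <- function(trials) {
  vapply(trials, function(t) as.character(t$label), character(1))
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %d channels @ %g Hz; labels: %s\n",
              length(x), length(attr(x, "channel_names")), attr(x, "fs"),
              paste(sprintf("%s=%d", names(table(trial_labels(x))),
                            table(trial_labels(x))), collapse = ", ")))
  invisible(x)
}

#' Cut a recording into labelled trials
#'
#' Each event marks a motor-imagery onset; the trial consists of `rest_dur`
#' seconds immediately before the onset and `mi_dur` seconds from the onset.
#' Events too close to the recording edges are skipped with a warning
#' rather than zero-padded.
#'
#' @param rec An [eeg_recording()] with labelled events.
#' @param rest_dur Rest-segment duration in seconds (default 3).
#' @param mi_dur Motor-imagery segment duration in seconds (default 4).
#' @param band Band descriptor attached to the trials (default broadband).
#' @return A `trial_set`.
#' @export
segment_trials <- function(rec, rest_dur = 3, mi_dur = 4, band = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!nrow(rec$events)) stop("recording has no events to segment on")
  if (is.null(band)) band <- frequency_band(0, rec$fs / 2, "broadband")
  n_rest <- round(rest_dur * rec$fs)
  n_mi <- round(mi_dur * rec$fs)
  n <- ncol(rec$samples)
  trials <- list()
  skipped <- 0L
  for (k in seq_len(nrow(rec$events))) {
    s <- rec$events$sample[k]
    if (s - n_rest < 1 || s + n_mi - 1 > n) {
      skipped <- skipped + 1L
      next
    }
    trials[[length(trials) + 1L]] <- mi_trial(
      label = rec$events$label[k],
      rest = rec$samples[, (s - n_rest):(s - 1), drop = FALSE],
      mi = rec$samples[, s:(s + n_mi - 1), drop = FALSE],
      band = band, fs = rec$fs, channel_names = rec$channel_names)
  }
  if (skipped)
    warning(skipped, " trial(s) skipped: too close to the recording edge")
  new_trial_set(trials, rec$channel_names, rec$fs)
}

#' Split a broadband trial into rhythm-band copies
#'
#' Filters the trial (rest and MI segments as one continuous stretch, to
#' avoid an artificial filter edge at the cue) into each requested band
#' with the same zero-phase Butterworth design used throughout.
#'
#' @param trial An [mi_trial()].
#' @param bands Named list of [frequency_band()] objects
#'   (default [rhythm_bands()]).
#' @param order Butterworth order.
#' @return Named list of band-filtered `mi_trial` objects.
#' @export
split_rhythms <- function(trial, bands = rhythm_bands(), order = 5) {
  stopifnot(inherits(trial, "mi_trial"))
  n_rest <- ncol(trial$rest)
  joint <- cbind(trial$rest, trial$mi)
  out <- lapply(bands, function(b) {
    filt <- butter_bandpass(b, trial$fs, order)
    y <- filtfilt_pad(filt, joint)
    mi_trial(trial$label, y[, seq_len(n_rest), drop = FALSE],
             y[, (n_rest + 1):ncol(y), drop = FALSE],
             b, trial$fs, trial$channel_names)
  })
  names(out) <- names(bands)
  out
}

#' Band-filter every trial of a set
#'
#' @param trials A `trial_set`.
#' @param band A [frequency_band()].
#' @param order Butterworth order.
#' @return A `trial_set` filtered to `band`.
#' @export
filter_trials <- function(trials, band, order = 5) {
  out <- lapply(trials, function(tr)
    split_rhythms(tr, list(b = band), order = order)[[1]])
  new_trial_set(out, attr(trials, "channel_names"), attr(trials, "fs"))
}
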