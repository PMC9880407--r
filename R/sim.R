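#' Simulation configuration for coupled-source EEG
#'
#' Describes a synthetic two-class motor-imagery dataset: during the MI
#' segment, the "hub" channels of the active class share one band-limited
#' latent source on top of private white noise, so their in-band coherence
#' is known in closed form; all other channels (and the rest segment) carry
#' independent noise only.
#'
#' `coupling_snr` is the in-band power-spectral-density ratio of the shared
#' source to the private noise on a hub channel: at the source-band centre
#' the source PSD equals `coupling_snr` times the white-noise floor, so two
#' hub channels have mid-band coherence
#' `coupling_snr^2 / (1 + coupling_snr)^2` (0.25 at `coupling_snr = 1`).
#'
#' @param channel_names Montage (default the 21-channel 10-20 set).
#' @param fs Sampling rate in Hz (default 250; any rate comfortably above
#'   twice the source-band upper edge works).
#' @param rest_dur,mi_dur Rest and MI segment durations in seconds
#'   (defaults 3 and 4, i.e. 7 s trials).
#' @param n_trials_per_class Trials per class (default 40).
#' @param source_band [frequency_band()] of the shared source
#'   (default 8-30 Hz).
#' @param coupling_snr In-band source-to-noise PSD ratio (>= 0).
#' @param hub_map Named list mapping each class label to the channel names
#'   that share the source.  Default: right-hemisphere sensorimotor hub for
#'   left-hand imagery and vice versa.
#' @param filter_order Butterworth order used to band-limit the source
#'   (same design as the preprocessing filter).
#' @param seed Integer master seed; each trial derives its own substream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(channel_names = montage_1020,
                       fs = 250,
                       rest_dur = 3, mi_dur = 4,
                       n_trials_per_class = 40,
                       source_band = frequency_band(8, 30, "mu_beta"),
                       coupling_snr = 1,
                       hub_map = list(left  = c("C4", "T8", "P4"),
                                      right = c("C3", "T7", "P3")),
                       filter_order = 5,
                       seed = 1L) {
  stopifnot(fs > 2 * source_band$hi, coupling_snr >= 0,
            n_trials_per_class >= 1, rest_dur > 0, mi_dur > 0)
  if (source_band$lo <= 0 || source_band$lo >= source_band$hi ||
      source_band$hi >= fs / 2)
    stop("invalid source band for fs = ", fs)
  if (!all(unlist(hub_map) %in% channel_names))
    stop("hub_map names channels absent from the montage")
  if (abs(rest_dur * fs - round(rest_dur * fs)) > 1e-9 ||
      abs(mi_dur * fs - round(mi_dur * fs)) > 1e-9)
    stop("segment durations must give integer sample counts at fs = ", fs)
  structure(list(channel_names = channel_names, fs = fs,
                 rest_dur = rest_dur, mi_dur = mi_dur,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 source_band = source_band, coupling_snr = coupling_snr,
                 hub_map = hub_map, filter_order = as.integer(filter_order),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Counter-based substream: trial i is reproducible independent of the order
# in which trials are generated.  Kept below 2^31 - 1.
trial_substream_seed <- function(seed, index, label) {
  label_code <- sum(utf8ToInt(as.character(label)))
  (as.numeric(seed) %% 65521 * 32452843 +
      as.numeric(index) * 49979687 +
      as.numeric(label_code) * 86028121) %% 2147483647
}

#' Simulate one labelled trial
#'
#' The rest segment is independent unit-variance white noise on every
#' channel.  During the MI segment the hub channels of `label` additionally
#' receive `sqrt(coupling_snr)` times a shared band-limited source (white
#' noise zero-phase filtered to the source band).  Generation is a pure
#' function of `(cfg$seed, index, label)`.
#'
#' @param cfg A [sim_config()].
#' @param label Class label; must be a name of `cfg$hub_map`.
#' @param index Trial counter used for the per-trial random substream.
#' @return An [mi_trial()] (broadband, unfiltered).
#' @export
simulate_trial <- function(cfg, label, index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  label <- as.character(label)
  if (!label %in% names(cfg$hub_map))
    stop("unknown class label '", label, "'")
  n_ch <- length(cfg$channel_names)
  n_rest <- round(cfg$rest_dur * cfg$fs)
  n_mi <- round(cfg$mi_dur * cfg$fs)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(trial_substream_seed(cfg$seed, index, label))

  pad <- round(cfg$fs)  # 1 s guard against filter edge transients
  filt <- butter_bandpass(cfg$source_band, cfg$fs, cfg$filter_order)
  src <- filtfilt_pad(filt, stats::rnorm(n_mi + 2 * pad))
  src <- src[(pad + 1):(pad + n_mi)]

  noise <- matrix(stats::rnorm(n_ch * (n_rest + n_mi)), nrow = n_ch)
  rest <- noise[, seq_len(n_rest), drop = FALSE]
  mi <- noise[, (n_rest + 1):(n_rest + n_mi), drop = FALSE]
  hubs <- match(cfg$hub_map[[label]], cfg$channel_names)
  if (cfg$coupling_snr > 0)
    mi[hubs, ] <- mi[hubs, ] +
      matrix(sqrt(cfg$coupling_snr) * src, nrow = length(hubs),
             ncol = n_mi, byrow = TRUE)
  rownames(rest) <- rownames(mi) <- cfg$channel_names
  mi_trial(label, rest, mi,
           frequency_band(0, cfg$fs / 2, "broadband"),
           cfg$fs, cfg$channel_names)
}

#' Theoretical in-band coherence of a hub pair
#'
#' Closed form for the magnitude-squared coherence between two channels
#' sharing the band-limited source: with in-band source-to-noise PSD ratio
#' `r(f) = coupling_snr * |H(f)|^4` (H the single-pass Butterworth response;
#' zero-phase filtering squares it, PSD squares it again), the coherence is
#' `r^2 / (1 + r)^2`, averaged over the requested band.
#'
#' @param cfg A [sim_config()].
#' @param band Band over which to average (default the source band).
#' @param freqs Optional frequency grid; default is a fine grid over `band`.
#' @return Scalar theoretical band-averaged coherence in [0, 1].
#' @export
ground_truth_msc <- function(cfg, band = cfg$source_band, freqs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(freqs))
    freqs <- seq(band$lo, band$hi, length.out = 512)
  else
    freqs <- freqs[freqs >= band$lo & freqs <= band$hi]
  if (!length(freqs)) stop("no frequencies inside the band")
  g2 <- bandpass_gain(freqs, cfg$source_band, cfg$fs, cfg$filter_order)
  r <- cfg$coupling_snr * g2^2
  mean(r^2 / (1 + r)^2)
}

#' Ground-truth coherence matrices per class
#'
#' @param cfg A [sim_config()].
#' @param band Band over which the theoretical coherence is averaged.
#' @param freqs Optional frequency grid (e.g. the Welch grid).
#' @return Named list (one per class) of symmetric channels x channels
#'   matrices: the closed-form band coherence on within-hub pairs, 0
#'   elsewhere off-diagonal, 1 on the diagonal.
#' @export
ground_truth_matrix <- function(cfg, band = cfg$source_band, freqs = NULL) {
  n <- length(cfg$channel_names)
  val <- ground_truth_msc(cfg, band, freqs)
  out <- lapply(cfg$hub_map, function(hub) {
    m <- diag(n)
    dimnames(m) <- list(cfg$channel_names, cfg$channel_names)
    idx <- match(hub, cfg$channel_names)
    for (i in idx) for (j in idx) if (i != j) m[i, j] <- val
    m
  })
  out
}

#' Generate a balanced labelled dataset
#'
#' Produces `2 * n_trials_per_class` trials with alternating class labels
#' and attaches the closed-form ground-truth coherence matrices as the
#' `ground_truth` attribute.
#'
#' @param cfg A [sim_config()].
#' @return A `trial_set` with attributes `ground_truth` (per-class
#'   matrices from [ground_truth_matrix()]) and `sim_config`.
#' @export
make_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  labels <- rep(names(cfg$hub_map), times = cfg$n_trials_per_class)
  trials <- lapply(seq_along(labels), function(i)
    simulate_trial(cfg, labels[i], index = i))
  ts <- new_trial_set(trials, cfg$channel_names, cfg$fs)
  attr(ts, "ground_truth") <- ground_truth_matrix(cfg)
  attr(ts, "sim_config") <- cfg
  ts
}

#' Concatenate a trial set into a continuous recording
#'
#' Rebuilds an event-marked continuous recording from a trial set (trials
#' laid end to end, MI onset markers at each rest/MI boundary), mainly so
#' that the segmentation step can be exercised round-trip.
#'
#' @param trials A `trial_set`.
#' @return An [eeg_recording()] with one event per trial.
#' @export
dataset_as_recording <- function(trials) {
  stopifnot(inherits(trials, "trial_set"), length(trials) > 0)
  fs <- attr(trials, "fs")
  mats <- lapply(trials, function(tr) cbind(tr$rest, tr$mi))
  widths <- vapply(mats, ncol, integer(1))
  offsets <- cumsum(c(0, widths[-length(widths)]))
  onset <- offsets + vapply(trials, function(tr) ncol(tr$rest), integer(1)) + 1L
  eeg_recording(do.call(cbind, mats), attr(trials, "channel_names"), fs,
                events = data.frame(sample = onset,
                                    label = trial_labels(trials)))
}
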