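#' Welch cross-spectral density
#'
#' Windowed, overlapped, averaged cross-periodogram of two equally long
#' signals on a one-sided frequency grid.  Each segment is mean-detrended,
#' tapered with a periodic Hann window and Fourier transformed; the
#' cross-spectrum is the average of `Conj(X) * Y` over segments, scaled to
#' a density (1 / (fs * sum(w^2))) with one-sided doubling of all bins
#' except DC and Nyquist.
#'
#' @param x,y Numeric vectors of equal length.
#' @param fs Sampling rate in Hz.
#' @param window_len Segment length in samples (default 1 s).
#' @param overlap Fractional overlap between consecutive segments in
#'   [0, 1), default 0.5.
#' @return An object of class `cross_spectrum` with fields `frequencies`,
#'   `Pxy` (complex), `n_segments`, `window_len`, `overlap`.
#' @export
welch_cross_spectrum <- function(x, y, fs, window_len = round(fs),
                                 overlap = 0.5) {
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  sf <- welch_segment_ffts(rbind(x, y), fs, window_len, overlap)
  S <- welch_scale(fs, window_len)
  Pxy <- rowMeans(Conj(sf$fft[, , 1]) * sf$fft[, , 2]) * S$scale
  Pxy <- Pxy * S$one_sided
  structure(list(frequencies = S$frequencies, Pxy = Pxy,
                 n_segments = sf$n_segments, window_len = window_len,
                 overlap = overlap),
            class = "cross_spectrum")
}

#' Welch power spectral density
#'
#' @inheritParams welch_cross_spectrum
#' @return A `cross_spectrum` whose `Pxy` is the real nonnegative PSD of `x`.
#' @export
welch_psd <- function(x, fs, window_len = round(fs), overlap = 0.5) {
  cs <- welch_cross_spectrum(x, x, fs, window_len, overlap)
  cs$Pxy <- Re(cs$Pxy)
  cs
}

# Segment start indices for Welch averaging.
welch_starts <- function(n, window_len, overlap) {
  step <- max(1L, round(window_len * (1 - overlap)))
  starts <- seq(1L, n - window_len + 1L, by = step)
  if (length(starts) < 2)
    stop("fewer than 2 Welch segments fit (single-segment coherence is ",
         "identically 1); shorten the window or lengthen the signal")
  starts
}

# One-sided grid, density scaling and doubling factors shared by the
# cross-spectrum and coherence paths.
welch_scale <- function(fs, window_len) {
  w <- hann_window(window_len)
  nf <- floor(window_len / 2) + 1L
  one_sided <- rep(2, nf)
  one_sided[1] <- 1
  if (window_len %% 2 == 0) one_sided[nf] <- 1
  list(frequencies = (seq_len(nf) - 1) * fs / window_len,
       scale = 1 / (fs * sum(w^2)),
       one_sided = one_sided)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# FFTs of detrended, Hann-tapered segments for a channels x time matrix.
# Returns the one-sided bins as an array (n_freq x n_segments x n_channels).
welch_segment_ffts <- function(mat, fs, window_len, overlap) {
  n <- ncol(mat)
  starts <- welch_starts(n, window_len, overlap)
  w <- hann_window(window_len)
  nf <- floor(window_len / 2) + 1L
  out <- array(0i, dim = c(nf, length(starts), nrow(mat)))
  for (ch in seq_len(nrow(mat))) {
    seg <- vapply(starts, function(s) {
      v <- mat[ch, s:(s + window_len - 1L)]
      (v - mean(v)) * w
    }, numeric(window_len))
    out[, , ch] <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
  }
  list(fft = out, n_segments = length(starts), frequencies =
         (seq_len(nf) - 1) * fs / window_len)
}

#' Magnitude-squared coherence spectrum
#'
#' Estimates `C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))` from Welch-averaged
#' spectra.  Frequencies at which either auto-spectrum is numerically zero
#' (dead channel) are assigned coherence 0.  Values are clipped into
#' [0, 1] after a tolerance check.
#'
#' @inheritParams welch_cross_spectrum
#' @return An object of class `coherence_spectrum` with fields
#'   `frequencies`, `Cxy`, `n_segments`.
#' @export
msc <- function(x, y, fs, window_len = round(fs), overlap = 0.5) {
  stopifnot(length(x) == length(y))
  sf <- welch_segment_ffts(rbind(x, y), fs, window_len, overlap)
  Fx <- sf$fft[, , 1]
  Fy <- sf$fft[, , 2]
  Pxy <- rowMeans(Conj(Fx) * Fy)
  Pxx <- rowMeans(Mod(Fx)^2)
  Pyy <- rowMeans(Mod(Fy)^2)
  den <- Pxx * Pyy
  C <- ifelse(den <= .Machine$double.eps^2, 0, Mod(Pxy)^2 / den)
  if (any(C > 1 + 1e-8))
    stop("coherence estimate exceeds 1 beyond numerical tolerance")
  C <- pmin(pmax(C, 0), 1)
  structure(list(frequencies = sf$frequencies, Cxy = C,
                 n_segments = sf$n_segments),
            class = "coherence_spectrum")
}

#' Band-averaged coherence
#'
#' Unweighted mean of the coherence spectrum over grid frequencies inside
#' the band (closed on both edges).
#'
#' @param cs A `coherence_spectrum` (or any list with `frequencies`/`Cxy`).
#' @param band A [frequency_band()].
#' @return Scalar in [0, 1].
#' @export
band_average <- function(cs, band) {
  keep <- cs$frequencies >= band$lo & cs$frequencies <= band$hi
  if (!any(keep))
    stop("no frequency-grid point inside band [", band$lo, ", ", band$hi, "]")
  mean(cs$Cxy[keep])
}

#' Coherence adjacency matrix of a multichannel segment
#'
#' Band-averaged magnitude-squared coherence for every unordered channel
#' pair, assembled into a symmetric weighting matrix.  The diagonal is set
#' to 0 by convention (self-coherence is trivially 1 and the matrix is used
#' as a graph adjacency without self-loops).
#'
#' @param mat Channels x samples numeric matrix (the MI segment).
#' @param fs Sampling rate in Hz.
#' @param band A [frequency_band()] to average over.
#' @param window_len,overlap Welch parameters (default 1 s Hann, 50%).
#' @param channel_names Optional channel names (default rownames).
#' @return An n x n matrix of class `coherence_matrix` with attributes
#'   `band` and `n_segments`.
#' @export
coherence_matrix <- function(mat, fs, band, window_len = round(fs),
                             overlap = 0.5, channel_names = rownames(mat)) {
  mat <- as.matrix(mat)
  n_ch <- nrow(mat)
  if (n_ch < 2) stop("need at least 2 channels")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  sf <- welch_segment_ffts(mat, fs, window_len, overlap)
  keep <- which(sf$frequencies >= band$lo & sf$frequencies <= band$hi)
  if (!length(keep))
    stop("no frequency-grid point inside band [", band$lo, ", ", band$hi, "]")
  acc <- matrix(0, n_ch, n_ch)
  for (f in keep) {
    M <- sf$fft[f, , ]                      # n_segments x n_channels
    P <- crossprod(Conj(M), M) / nrow(M)   # cross-spectral matrix at f
    p <- Re(diag(P))
    den <- outer(p, p)
    Cf <- ifelse(den <= .Machine$double.eps^2, 0, Mod(P)^2 / den)
    acc <- acc + Cf
  }
  W <- acc / length(keep)
  W <- (W + t(W)) / 2
  W <- pmin(pmax(W, 0), 1)
  diag(W) <- 0
  dimnames(W) <- list(channel_names, channel_names)
  structure(W, band = band, n_segments = sf$n_segments,
            class = c("coherence_matrix", "matrix"))
}

#' Per-trial coherence matrix
#'
#' Computes the [coherence_matrix()] of a trial's motor-imagery segment
#' (the rest segment is not used for connectivity).
#'
#' @param trial An [mi_trial()].
#' @param band Band to average over.
#' @param window_len,overlap Welch parameters.
#' @return A `coherence_matrix`.
#' @export
trial_coherence <- function(trial, band, window_len = round(trial$fs),
                            overlap = 0.5) {
  stopifnot(inherits(trial, "mi_trial"))
  coherence_matrix(trial$mi, trial$fs, band, window_len, overlap,
                   trial$channel_names)
}

#' Coherence graphs from a trial set
#'
#' Builds the connectivity graph(s) used by the classifier.  Coherence is
#' amplitude-invariant, so trials may be raw or band-filtered; the band
#' argument selects which Welch bins are averaged.
#'
#' @param trials A `trial_set`.
#' @param band A [frequency_band()].
#' @param mode `"train_average"` (one matrix from all trials pooled, the
#'   leakage-safe default when the trials are a training split),
#'   `"class_average"` (one matrix per class) or `"per_trial"` (a list of
#'   matrices).
#' @param window_len,overlap Welch parameters.
#' @return A `coherence_matrix`, a named list of them (class_average), or a
#'   list of per-trial matrices.
#' @export
trial_graph <- function(trials, band,
                        mode = c("train_average", "class_average",
                                 "per_trial"),
                        window_len = round(attr(trials, "fs")),
                        overlap = 0.5) {
  mode <- match.arg(mode)
  if (!length(trials)) stop("empty trial set")
  mats <- lapply(trials, trial_coherence, band = band,
                 window_len = window_len, overlap = overlap)
  if (mode == "per_trial") return(mats)
  if (mode == "train_average") return(average_coherence(mats, band))
  labs <- trial_labels(trials)
  out <- lapply(split(mats, labs), average_coherence, band = band)
  if (any(!lengths(split(mats, labs)))) stop("empty class in trial set")
  out
}

average_coherence <- function(mats, band) {
  stopifnot(length(mats) >= 1)
  W <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  structure(W, band = band, n_segments = attr(mats[[1]], "n_segments"),
            class = c("coherence_matrix", "matrix"))
}

#' @export
print.coherence_matrix <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<coherence_matrix> %d x %d, band %s [%g, %g] Hz\n",
              nrow(x), ncol(x), b$name, b$lo, b$hi))
  invisible(x)
}
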