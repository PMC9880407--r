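test_that("Welch cross-spectrum matches the direct-DFT oracle", {
  fs <- 250
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  set.seed(11)
  x <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 25 * t + 1) + rnorm(length(t), sd = 0.3)
  y <- sin(2 * pi * 10 * t + 0.7) + rnorm(length(t), sd = 0.3)
  cs <- welch_cross_spectrum(x, y, fs, window_len = fs, overlap = 0.5)
  or <- oracle_welch_cross(x, y, fs, fs, 0.5)
  expect_equal(cs$frequencies, or$frequencies)
  expect_lt(max(Mod(cs$Pxy - or$Pxy)) / max(Mod(or$Pxy)), 1e-10)
  # x = y gives the real, nonnegative Welch PSD
  ps <- welch_cross_spectrum(x, x, fs)
  expect_true(all(abs(Im(ps$Pxy)) < 1e-12 * max(Mod(ps$Pxy))))
  expect_true(all(Re(ps$Pxy) >= 0))
  # swapping arguments conjugates every bin
  sw <- welch_cross_spectrum(y, x, fs)
  expect_equal(sw$Pxy, Conj(cs$Pxy))
})

test_that("magnitude-squared coherence behaves as Eq-defined", {
  fs <- 200
  set.seed(12)
  x <- rnorm(1600)
  # perfect linear dependence -> coherence 1 wherever power is nonzero
  cs <- msc(x, 3 * x, fs)
  expect_true(all(abs(cs$Cxy - 1) < 1e-10))
  # invariance to per-channel rescaling
  y <- rnorm(1600)
  c1 <- msc(x, y, fs)
  c2 <- msc(0.02 * x, -40 * y, fs)
  expect_lt(max(abs(c1$Cxy - c2$Cxy)), 1e-10)
  # matches the oracle's MSC exactly
  or <- oracle_welch_cross(x, y, fs, fs, 0.5)
  expect_lt(max(abs(c1$Cxy - or$msc)), 1e-10)
  expect_true(all(c1$Cxy >= 0 & c1$Cxy <= 1))
})

test_that("independent noise sits at the 1/L coherence bias floor", {
  fs <- 128
  L <- 8
  set.seed(13)
  means <- replicate(60, {
    x <- rnorm(fs * L)
    y <- rnorm(fs * L)
    mean(msc(x, y, fs, window_len = fs, overlap = 0)$Cxy)
  })
  # E[MSC] for independent signals with L non-overlapping segments ~ 1/L
  expect_lt(abs(mean(means) - 1 / L), 0.03)
})

test_that("band averaging is the arithmetic mean over included bins", {
  freqs <- 0:50
  band <- frequency_band(8, 30)
  ramp <- list(frequencies = freqs, Cxy = freqs / 100)
  keep <- freqs >= 8 & freqs <= 30
  expect_equal(band_average(ramp, band), mean(freqs[keep] / 100))
  expect_equal(band_average(list(frequencies = freqs,
                                 Cxy = rep(0.4, 51)), band), 0.4)
  ind <- list(frequencies = freqs, Cxy = as.numeric(keep))
  expect_equal(band_average(ind, band), 1)
  expect_error(band_average(ramp, frequency_band(60, 70)), "no frequency")
})

test_that("coherence matrix equals the naive per-pair double loop", {
  fs <- 250
  set.seed(14)
  mat <- matrix(rnorm(6 * 1000), 6)
  rownames(mat) <- paste0("ch", 1:6)
  band <- frequency_band(8, 30)
  W <- coherence_matrix(mat, fs, band)
  ref <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) if (i != j)
    ref[i, j] <- band_average(msc(mat[i, ], mat[j, ], fs), band)
  expect_lt(max(abs(unclass(W) - ref)), 1e-12)
  expect_equal(unclass(W), t(unclass(W)))
  expect_true(all(diag(W) == 0))
  # a duplicated channel has coherence 1 with its clone
  mat2 <- rbind(mat, clone = mat[1, ])
  W2 <- coherence_matrix(mat2, fs, band)
  expect_equal(unname(W2["ch1", "clone"]), 1, tolerance = 1e-10)
})

test_that("21-channel trials give 21 x 21 matrices with hub maxima", {
  cfg <- sim_config(n_trials_per_class = 1, coupling_snr = 4, seed = 15)
  tr <- simulate_trial(cfg, "left", 1)
  W <- trial_coherence(tr, cfg$source_band)
  expect_equal(dim(W), c(21L, 21L))
  expect_equal(sum(upper.tri(W)), 210)
  top <- which(unclass(W) == max(W), arr.ind = TRUE)
  expect_true(all(rownames(W)[top] %in% cfg$hub_map$left))
})

test_that("trial_graph modes average as stated", {
  ds <- small_dataset(n_per_class = 2, seed = 16)
  band <- frequency_band(8, 30)
  per <- trial_graph(ds, band, "per_trial")
  expect_length(per, 4)
  avg <- trial_graph(ds, band, "train_average")
  expect_equal(unclass(avg),
               Reduce(`+`, lapply(per, unclass)) / 4, tolerance = 1e-12)
  cls <- trial_graph(ds, band, "class_average")
  labs <- trial_labels(ds)
  expect_equal(unclass(cls$left),
               Reduce(`+`, lapply(per[labs == "left"], unclass)) / 2)
  # averaging preserves symmetry and range
  expect_true(all(avg >= 0 & avg <= 1))
  expect_equal(unclass(avg), t(unclass(avg)))
  # single trial: every mode reduces to that trial's matrix
  one <- ds[1]
  expect_equal(unclass(trial_graph(one, band, "train_average")),
               unclass(per[[1]]))
})

test_that("estimation error shrinks as segments accumulate", {
  # convergence toward the closed-form hub coherence with longer MI data
  err <- sapply(c(4, 16), function(dur) {
    mean(sapply(1:5, function(s) {
      cfg <- sim_config(mi_dur = dur, coupling_snr = 1, seed = 300 + s,
                        n_trials_per_class = 1)
      tr <- simulate_trial(cfg, "left")
      est <- band_average(msc(tr$mi["C4", ], tr$mi["T8", ], cfg$fs),
                          cfg$source_band)
      abs(est - ground_truth_msc(cfg))
    }))
  })
  expect_lt(err[2], err[1])
})

test_that("degenerate inputs are rejected or guarded", {
  expect_error(msc(rnorm(100), rnorm(100), fs = 250, window_len = 100),
               "fewer than 2")
  expect_error(coherence_matrix(matrix(rnorm(100), 1), 250,
                                frequency_band(8, 30)), "2 channels")
  # dead channel: coherence defined as 0
  x <- rnorm(1000)
  dead <- rep(0, 1000)
  expect_true(all(msc(x, dead, 250)$Cxy == 0))
})
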