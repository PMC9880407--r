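test_that("forward pass yields proper probabilities", {
  tn <- tiny_net()
  fw <- cgcn:::cgcn_forward(tn$params, tn$laps, tn$hier, tn$X)
  expect_equal(colSums(fw$prob), rep(1, 4), tolerance = 1e-10)
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # all-zero weights and bias: symmetric logits, probabilities 1/2
  zero <- cgcn:::map_params(tn$params, tn$params, function(a, b) a * 0)
  fw0 <- cgcn:::cgcn_forward(zero, tn$laps, tn$hier, tn$X)
  expect_equal(as.vector(fw0$prob), rep(0.5, 8))
  # inference is deterministic (no dropout outside training)
  fw2 <- cgcn:::cgcn_forward(tn$params, tn$laps, tn$hier, tn$X)
  expect_identical(fw$prob, fw2$prob)
})

test_that("loss matches hand-evaluated cross-entropy with L2 penalty", {
  tn <- tiny_net()
  zero <- cgcn:::map_params(tn$params, tn$params, function(a, b) a * 0)
  # perfect prediction, zero weights: loss 0
  expect_equal(cgcn:::cgcn_loss(tn$P, tn$P, zero, 0.001)$total, 0,
               tolerance = 1e-9)
  # maximal uncertainty: both-class binary cross-entropy is 2 ln 2
  q <- matrix(0.5, 2, 4)
  expect_equal(cgcn:::cgcn_loss(q, tn$P, zero, 0.001)$total, 2 * log(2))
  # growing any weight strictly increases the penalized loss
  bigger <- cgcn:::map_params(tn$params, tn$params, function(a, b) a * 2)
  l1 <- cgcn:::cgcn_loss(q, tn$P, tn$params, 0.001)$total
  l2_ <- cgcn:::cgcn_loss(q, tn$P, bigger, 0.001)$total
  expect_gt(l2_, l1)
})

test_that("analytic gradients match central finite differences", {
  tn <- tiny_net(n = 5, K = 3, filters = c(3, 4), f0 = 6, B = 4, seed = 3)
  loss_of <- function(params) {
    fw <- cgcn:::cgcn_forward(params, tn$laps, tn$hier, tn$X)
    cgcn:::cgcn_loss(fw$prob, tn$P, params, tn$l2)$total
  }
  fw <- cgcn:::cgcn_forward(tn$params, tn$laps, tn$hier, tn$X)
  grads <- cgcn:::cgcn_backward(fw, tn$P, tn$params, tn$laps, tn$hier,
                                tn$l2)
  h <- 1e-5
  check_block <- function(get, set, ganalytic) {
    vals <- get(tn$params)
    gnum <- vals * 0
    for (i in seq_along(vals)) {
      up <- vals; up[i] <- up[i] + h
      dn <- vals; dn[i] <- dn[i] - h
      gnum[i] <- (loss_of(set(tn$params, up)) -
                    loss_of(set(tn$params, dn))) / (2 * h)
    }
    rel <- abs(ganalytic - gnum) / pmax(abs(ganalytic) + abs(gnum), 1e-6)
    expect_lt(max(rel), 1e-5)
  }
  for (l in 1:2) {
    check_block(function(p) p$conv[[l]]$theta,
                function(p, v) { p$conv[[l]]$theta <- v; p },
                grads$conv[[l]]$theta)
    check_block(function(p) p$conv[[l]]$bias,
                function(p, v) { p$conv[[l]]$bias <- v; p },
                grads$conv[[l]]$bias)
  }
  check_block(function(p) p$fc$W, function(p, v) { p$fc$W <- v; p },
              grads$fc$W)
  check_block(function(p) p$fc$b, function(p, v) { p$fc$b <- v; p },
              grads$fc$b)
})

test_that("node features are standardized, decimated and deterministic", {
  ds <- small_dataset(n_per_class = 1, seed = 20)
  tr <- filter_trials(ds, frequency_band(8, 30, "mu_beta"))[[1]]
  X <- build_features(tr, n_features = 200)
  expect_equal(dim(X), c(21L, 200L))
  expect_lt(max(abs(rowMeans(X))), 1e-10)
  expect_equal(apply(X, 1, var), rep(1, 21), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(X, build_features(tr, n_features = 200))
  # degenerate constant channel maps to zeros
  tr0 <- tr
  tr0$mi[3, ] <- 5
  expect_equal(unname(build_features(tr0)[3, ]), rep(0, 200))
  # psd features cover the band grid
  Xp <- build_features(tr, feature_type = "psd")
  expect_equal(nrow(Xp), 21)
  expect_gt(ncol(Xp), 10)
  # coherence features: one standardized connectivity profile per channel
  Xc <- build_features(tr, feature_type = "coherence")
  expect_equal(dim(Xc), c(21L, 21L))
  expect_lt(max(abs(rowMeans(Xc))), 1e-10)
  W <- unclass(trial_coherence(tr, tr$band))
  expect_equal(cor(Xc[4, ], W[4, ]), 1, tolerance = 1e-10)
})

test_that("training descends on separable data, reproducibly", {
  ds <- small_dataset(n_per_class = 10, snr = 2, seed = 30)
  band <- frequency_band(8, 30, "mu_beta")
  ft <- filter_trials(ds, band)
  g <- trial_graph(ft, band, "train_average")
  cfg <- cgcn_config(epochs = 8, seed = 4)
  m <- cgcn(ft, g, cfg)
  expect_lt(m$history$loss[8], m$history$loss[1])
  expect_equal(nrow(m$history), 8)
  m2 <- cgcn(ft, g, cfg)
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
  # untrained model: empty history but a working forward pass
  m0 <- cgcn(ft, g, cgcn_config(epochs = 0, seed = 4))
  expect_equal(nrow(m0$history), 0)
  p <- predict(m0, ft, type = "prob")
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-10,
               ignore_attr = TRUE)
  # single-class data are rejected
  expect_error(cgcn(ft[trial_labels(ft) == "left"], g, cfg),
               "single class")
})

test_that("classification metrics match hand arithmetic and caret", {
  # confusion [[3,1],[2,4]]: accuracy 0.7, macro-F1 hand-computed
  truth <- c(rep("a", 4), rep("b", 6))
  pred <- c("a", "a", "a", "b", "a", "a", "b", "b", "b", "b")
  m <- classification_metrics(truth, pred)
  expect_equal(m$accuracy, 0.7)
  f1a <- 2 * (3 / 5) * (3 / 4) / ((3 / 5) + (3 / 4))
  f1b <- 2 * (4 / 5) * (4 / 6) / ((4 / 5) + (4 / 6))
  expect_equal(m$f1_macro, (f1a + f1b) / 2)
  # all-correct predictions
  m1 <- classification_metrics(truth, truth)
  expect_equal(m1$accuracy, 1)
  expect_equal(m1$f1_macro, 1)
  # against an independent reference implementation
  skip_if_not_installed("caret")
  set.seed(5)
  for (rep in 1:3) {
    tr <- sample(c("l", "r"), 200, replace = TRUE)
    pr <- ifelse(runif(200) < 0.3, sample(c("l", "r"), 200, TRUE), tr)
    ours <- classification_metrics(tr, pr, classes = c("l", "r"))
    cm <- caret::confusionMatrix(factor(pr, c("l", "r")),
                                 factor(tr, c("l", "r")),
                                 mode = "everything")
    expect_equal(unname(ours$accuracy),
                 unname(cm$overall["Accuracy"]))
    f1_l <- cm$byClass["F1"]
    cm_r <- caret::confusionMatrix(factor(pr, c("r", "l")),
                                   factor(tr, c("r", "l")),
                                   mode = "everything")
    expect_equal(unname(ours$f1_macro),
                 unname((f1_l + cm_r$byClass["F1"]) / 2))
  }
})

test_that("cross-validation folds partition the data with stratification", {
  ds <- small_dataset(n_per_class = 10, seed = 40)
  labels <- trial_labels(ds)
  id <- cgcn:::stratified_folds(labels, folds = 5, seed = 7)
  expect_length(id, 20)
  expect_equal(sort(unique(id)), 1:5)
  for (k in 1:5) {
    expect_equal(sum(id == k), 4)
    expect_equal(sum(id == k & labels == "left"), 2)   # 2 per class
  }
  # pure function of labels and seed
  expect_identical(id, cgcn:::stratified_folds(labels, 5, 7))
  expect_false(identical(id, cgcn:::stratified_folds(labels, 5, 8)))
})

test_that("cross-validation evaluates held-out folds per band", {
  ds <- small_dataset(n_per_class = 5, snr = 3, seed = 50)
  cfg <- cgcn_config(epochs = 4, seed = 6)
  cv <- cgcn_cv(ds, frequency_band(8, 30, "mu_beta"), cfg, folds = 5)
  expect_length(cv$folds, 5)
  ns <- vapply(cv$folds, `[[`, numeric(1), "n")
  expect_equal(sum(ns), 10)                 # union of folds = full set
  expect_equal(unname(ns), rep(2, 5))       # stratified 2-trial folds
  expect_true(all(cv$summary$mean >= 0))
  expect_error(cgcn_cv(ds, frequency_band(8, 30), cfg, folds = 6),
               "at least")
})

test_that("model checkpoints and prediction survive a save/load cycle", {
  ds <- small_dataset(n_per_class = 4, seed = 60)
  band <- frequency_band(8, 30, "mu_beta")
  ft <- filter_trials(ds, band)
  g <- trial_graph(ft, band, "train_average")
  m <- cgcn(ft, g, cgcn_config(epochs = 2, seed = 8))
  f <- tempfile(fileext = ".rds")
  write_model(m, f)
  m2 <- read_model(f)
  expect_identical(predict(m, ft), predict(m2, ft))
  expect_identical(predict(m, ft, type = "class"),
                   predict(m2, ft, type = "class"))
  unlink(f)
})
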