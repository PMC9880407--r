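#' C-GCN model configuration
#'
#' Hyperparameters of the coherence-based graph convolutional classifier.
#' Defaults follow the published training setup (100 epochs, batch size
#' 512, L2 regularization 0.001, dropout 0.50, learning rate 0.01); batch
#' size acts as an upper bound, the effective batch is
#' `min(batch_size, n_train)`.
#'
#' @param K Chebyshev polynomial order (number of terms) per conv layer.
#' @param filters Feature-map counts per graph-conv layer; its length sets
#'   the number of conv/pool levels.
#' @param pool_factor Nodes merged per pooling step (pairwise, 2).
#' @param n_classes Number of classes (2).
#' @param epochs Training epochs.
#' @param batch_size Upper bound on the mini-batch size.
#' @param l2_lambda Weight of the L2 penalty on conv and FC weights
#'   (biases excluded).
#' @param dropout Dropout rate applied to the flattened features before the
#'   fully connected layer (training mode only).
#' @param learning_rate Step size of the optimizer.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param n_features Node-feature length: the band-filtered MI time series
#'   is decimated to this many samples per channel.
#' @param feature_type `"timeseries"` (default), `"psd"` (log Welch PSD
#'   over the band grid) or `"coherence"` (each channel's row of the
#'   trial's band-averaged coherence matrix).
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and fold assignment.
#' @return An object of class `cgcn_config`.
#' @export
cgcn_config <- function(K = 3, filters = c(32, 64), pool_factor = 2,
                        n_classes = 2, epochs = 100, batch_size = 512,
                        l2_lambda = 0.001, dropout = 0.50,
                        learning_rate = 0.01,
                        optimizer = c("adam", "sgd"),
                        n_features = 200,
                        feature_type = c("timeseries", "psd", "coherence"),
                        seed = 1L) {
  stopifnot(K >= 1, all(filters >= 1), n_classes >= 2, epochs >= 0,
            batch_size >= 1, l2_lambda >= 0, dropout >= 0, dropout < 1,
            learning_rate > 0, n_features >= 1)
  structure(list(K = as.integer(K), filters = as.integer(filters),
                 pool_factor = as.integer(pool_factor),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 l2_lambda = l2_lambda, dropout = dropout,
                 learning_rate = learning_rate,
                 optimizer = match.arg(optimizer),
                 n_features = as.integer(n_features),
                 feature_type = match.arg(feature_type),
                 seed = as.integer(seed)),
            class = "cgcn_config")
}

#' Node features of a trial
#'
#' Default "timeseries" features: the band-filtered MI segment decimated to
#' `n_features` evenly spaced samples per channel, then per-channel
#' standardized to zero mean and unit variance.  (The signal is band-limited
#' well below the decimated Nyquist at the default settings.)  The "psd"
#' alternative uses the standardized log Welch PSD over the trial band's
#' frequency bins.  The "coherence" alternative uses each channel's row of
#' the trial's own band-averaged coherence matrix (its connectivity profile
#' to every other channel), which carries the pairwise-synchronization
#' structure that per-channel features cannot express.  A constant
#' (degenerate) channel is left as zeros.
#'
#' @param trial An [mi_trial()] (band-filtered).
#' @param n_features Feature length for the timeseries mode.
#' @param feature_type `"timeseries"`, `"psd"` or `"coherence"`.
#' @param window_len,overlap Welch parameters for the psd and coherence
#'   modes.
#' @return Channels x features numeric matrix.
#' @export
build_features <- function(trial, n_features = 200,
                           feature_type = c("timeseries", "psd",
                                            "coherence"),
                           window_len = round(trial$fs), overlap = 0.5) {
  stopifnot(inherits(trial, "mi_trial"))
  feature_type <- match.arg(feature_type)
  if (feature_type == "timeseries") {
    idx <- round(seq(1, ncol(trial$mi), length.out = n_features))
    X <- trial$mi[, idx, drop = FALSE]
  } else if (feature_type == "coherence") {
    X <- unclass(trial_coherence(trial, trial$band, window_len, overlap))
  } else {
    band <- trial$band
    X <- t(vapply(seq_len(nrow(trial$mi)), function(ch) {
      p <- welch_psd(trial$mi[ch, ], trial$fs, window_len, overlap)
      keep <- p$frequencies >= band$lo & p$frequencies <= band$hi
      log10(pmax(p$Pxy[keep], 1e-20))
    }, numeric(sum({
      p0 <- welch_scale(trial$fs, window_len)
      p0$frequencies >= trial$band$lo & p0$frequencies <= trial$band$hi
    }))))
  }
  X <- X - rowMeans(X)
  s <- sqrt(rowSums(X^2) / (ncol(X) - 1))
  degen <- s < 1e-12
  s[degen] <- 1
  X <- X / s
  X[degen, ] <- 0
  rownames(X) <- trial$channel_names
  X
}

# Stack per-trial features into an n_nodes x n_features x n_trials array.
features_array <- function(trials, config) {
  mats <- lapply(trials, build_features, n_features = config$n_features,
                 feature_type = config$feature_type)
  n <- nrow(mats[[1]])
  f <- ncol(mats[[1]])
  arr <- array(0, dim = c(n, f, length(mats)))
  for (b in seq_along(mats)) arr[, , b] <- mats[[b]]
  arr
}

## ---- internal forward / backward machinery ------------------------------
## Batch activations travel through the layers as 3-D arrays laid out as
## (nodes x samples x features): with the feature index last, both
## matricizations used by the Chebyshev products -- n x (B*F) for Laplacian
## products and (n*B) x F for coefficient products -- are plain `dim<-`
## reshapes of the same memory, so every heavy operation is a single BLAS
## matrix multiply with no transposition copies.

conv_forward <- function(H, Lt, theta, bias) {
  d <- dim(H)                               # n, B, Fin
  K <- dim(theta)[1]
  Fout <- dim(theta)[3]
  Hm <- H
  dim(Hm) <- c(d[1], d[2] * d[3])           # n x (B*Fin)
  Tk <- vector("list", K)
  Tk[[1]] <- Hm
  if (K >= 2) Tk[[2]] <- Lt %*% Hm
  if (K >= 3) for (k in 3:K)
    Tk[[k]] <- 2 * (Lt %*% Tk[[k - 1]]) - Tk[[k - 2]]
  Z <- matrix(0, d[1] * d[2], Fout)
  for (k in seq_len(K)) {
    dim(Tk[[k]]) <- c(d[1] * d[2], d[3])    # (n*B) x Fin
    th_k <- matrix(theta[k, , ], dim(theta)[2], dim(theta)[3])
    Z <- Z + Tk[[k]] %*% th_k
  }
  Z <- sweep(Z, 2, bias, `+`)
  dim(Z) <- c(d[1], d[2], Fout)
  list(out = Z, cache = list(Tmat = Tk, dims = d, K = K))
}

conv_backward <- function(dY, Lt, theta, cache) {
  d <- cache$dims                           # n, B, Fin
  K <- cache$K
  Fout <- dim(theta)[3]
  dZ <- dY
  dim(dZ) <- c(d[1] * d[2], Fout)           # (n*B) x Fout
  dtheta <- array(0, dim = dim(theta))
  for (k in seq_len(K))
    dtheta[k, , ] <- crossprod(cache$Tmat[[k]], dZ)
  dbias <- colSums(dZ)
  # cotangents of the Chebyshev basis, reverse three-term recursion
  cot <- vector("list", K)
  for (k in seq_len(K)) {
    th_k <- matrix(theta[k, , ], dim(theta)[2], dim(theta)[3])
    Mk <- dZ %*% t(th_k)                    # (n*B) x Fin
    dim(Mk) <- c(d[1], d[2] * d[3])
    cot[[k]] <- Mk
  }
  if (K >= 3) for (k in K:3) {
    cot[[k - 1]] <- cot[[k - 1]] + 2 * (Lt %*% cot[[k]])
    cot[[k - 2]] <- cot[[k - 2]] - cot[[k]]
  }
  dX <- cot[[1]]
  if (K >= 2) dX <- dX + Lt %*% cot[[2]]
  dim(dX) <- d
  list(dX = dX, dtheta = dtheta, dbias = dbias)
}

pool_forward <- function(H, groups) {
  d <- dim(H)
  nc <- length(groups)
  out <- array(0, dim = c(nc, d[2], d[3]))
  winners <- vector("list", nc)
  for (i in seq_len(nc)) {
    idx <- groups[[i]]
    if (length(idx) == 1L) {
      out[i, , ] <- H[idx, , ]
    } else {
      a <- H[idx[1], , ]
      b <- H[idx[2], , ]
      win <- a >= b
      out[i, , ] <- a * win + b * !win
      winners[[i]] <- win
    }
  }
  list(out = out, winners = winners)
}

pool_backward <- function(dY, groups, winners, n_fine) {
  d <- dim(dY)
  dH <- array(0, dim = c(n_fine, d[2], d[3]))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    if (length(idx) == 1L) {
      dH[idx, , ] <- dY[i, , ]
    } else {
      g <- dY[i, , ]
      win <- winners[[i]]
      dH[idx[1], , ] <- g * win
      dH[idx[2], , ] <- g * (!win)
    }
  }
  dH
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), `/`)
}

# Full forward pass; P (one-hot C x B) optional, dropout_mask optional.
cgcn_forward <- function(params, laplacians, hierarchy, X,
                         train_mode = FALSE, dropout = 0,
                         dropout_mask = NULL) {
  n_layers <- length(params$conv)
  H <- aperm(X, c(1, 3, 2))                 # (n, F, B) -> (n, B, F)
  caches <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    cv <- conv_forward(H, laplacians[[l]], params$conv[[l]]$theta,
                       params$conv[[l]]$bias)
    relu_mask <- cv$out > 0
    A <- cv$out * relu_mask
    pl <- pool_forward(A, hierarchy$groups[[l]])
    caches[[l]] <- list(conv = cv$cache, relu = relu_mask,
                        winners = pl$winners,
                        n_fine = dim(A)[1])
    H <- pl$out
  }
  d <- dim(H)                               # n_coarse, B, F
  Hflat <- aperm(H, c(1, 3, 2))             # back to node-major flatten
  dim(Hflat) <- c(d[1] * d[3], d[2])
  if (train_mode && dropout > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(
        (stats::runif(length(Hflat)) >= dropout) / (1 - dropout),
        nrow(Hflat), ncol(Hflat))
    Hdrop <- Hflat * dropout_mask
  } else {
    dropout_mask <- NULL
    Hdrop <- Hflat
  }
  logits <- params$fc$W %*% Hdrop + params$fc$b
  q <- softmax_cols(logits)
  list(prob = q, caches = caches, Hdrop = Hdrop, Hflat_dim = d,
       dropout_mask = dropout_mask)
}

# Both-class binary cross-entropy (summed over the two class terms,
# averaged over the batch) plus the L2 penalty on weights.
cgcn_loss <- function(q, P, params, l2_lambda) {
  qc <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  data_loss <- -sum(P * log(qc) + (1 - P) * log(1 - qc)) / ncol(P)
  penalty <- 0
  if (l2_lambda > 0) {
    penalty <- sum(params$fc$W^2)
    for (cv in params$conv) penalty <- penalty + sum(cv$theta^2)
    penalty <- l2_lambda * penalty
  }
  list(total = data_loss + penalty, data = data_loss, penalty = penalty)
}

cgcn_backward <- function(fw, P, params, laplacians, hierarchy, l2_lambda) {
  q <- fw$prob
  B <- ncol(P)
  qc <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  g <- -(P / qc - (1 - P) / (1 - qc)) / B          # dL/dq
  dlogits <- q * sweep(g, 2, colSums(g * q))       # softmax Jacobian
  grads <- list(conv = vector("list", length(params$conv)), fc = NULL)
  grads$fc <- list(W = dlogits %*% t(fw$Hdrop) + 2 * l2_lambda * params$fc$W,
                   b = rowSums(dlogits))
  dHflat <- crossprod(params$fc$W, dlogits)
  if (!is.null(fw$dropout_mask)) dHflat <- dHflat * fw$dropout_mask
  d <- fw$Hflat_dim                         # n_coarse, B, F
  dH <- aperm(array(dHflat, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  for (l in rev(seq_along(params$conv))) {
    ca <- fw$caches[[l]]
    dA <- pool_backward(dH, hierarchy$groups[[l]], ca$winners, ca$n_fine)
    dA <- dA * ca$relu
    bk <- conv_backward(dA, laplacians[[l]], params$conv[[l]]$theta, ca$conv)
    grads$conv[[l]] <- list(
      theta = bk$dtheta + 2 * l2_lambda * params$conv[[l]]$theta,
      bias = bk$dbias)
    dH <- bk$dX
  }
  grads
}

init_params <- function(config, n_nodes_per_level, n_in_features) {
  n_layers <- length(config$filters)
  conv <- vector("list", n_layers)
  fin <- n_in_features
  for (l in seq_len(n_layers)) {
    fout <- config$filters[l]
    lim <- sqrt(6 / (config$K * fin + fout))
    conv[[l]] <- list(
      theta = array(stats::runif(config$K * fin * fout, -lim, lim),
                    dim = c(config$K, fin, fout)),
      bias = rep(0, fout))
    fin <- fout
  }
  n_flat <- n_nodes_per_level[n_layers + 1] * fin
  lim <- sqrt(6 / (n_flat + config$n_classes))
  list(conv = conv,
       fc = list(W = matrix(stats::runif(config$n_classes * n_flat,
                                         -lim, lim),
                            config$n_classes, n_flat),
                 b = rep(0, config$n_classes)))
}

# Walk two parallel parameter structures applying f elementwise.
map_params <- function(p, g, f) {
  for (l in seq_along(p$conv)) {
    p$conv[[l]]$theta <- f(p$conv[[l]]$theta, g$conv[[l]]$theta)
    p$conv[[l]]$bias <- f(p$conv[[l]]$bias, g$conv[[l]]$bias)
  }
  p$fc$W <- f(p$fc$W, g$fc$W)
  p$fc$b <- f(p$fc$b, g$fc$b)
  p
}

zero_like <- function(p) map_params(p, p, function(a, b) a * 0)

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- map_params(state$m, grads, function(m, g) beta1 * m +
                          (1 - beta1) * g)
  state$v <- map_params(state$v, grads, function(v, g) beta2 * v +
                          (1 - beta2) * g^2)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- map_params(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map_params(params, upd, `-`)
  list(params = params, state = state)
}

## ---- fitting ------------------------------------------------------------

#' Fit a coherence-based graph convolutional network
#'
#' Trains the C-GCN classifier on labelled motor-imagery trials: the
#' coherence matrix defines a weighted graph over electrodes, node features
#' are built per trial, and the network — one Chebyshev graph-conv layer,
#' ReLU and max pooling per entry of `config$filters`, then dropout and a
#' fully connected softmax head — is trained by mini-batch gradient descent
#' (Adam by default) on the both-class cross-entropy plus an L2 weight
#' penalty.  Training is fully reproducible from `config$seed`.
#'
#' @param trials A `trial_set` of band-filtered labelled trials.
#' @param graph A [coherence_matrix()] (or any symmetric nonnegative
#'   adjacency) over the same channels; typically built from training
#'   trials only via [trial_graph()].
#' @param config A [cgcn_config()].
#' @param approx_lmax Optional fixed largest-eigenvalue value (e.g. 2) for
#'   the Laplacian rescaling; by default it is computed per level.
#' @return An object of class `cgcn` with the fitted parameters, pooling
#'   hierarchy, per-level Laplacians, class labels, config and per-epoch
#'   training history (`loss`, `data_loss`, `accuracy`).
#' @export
cgcn <- function(trials, graph, config = cgcn_config(),
                 approx_lmax = NULL) {
  stopifnot(inherits(trials, "trial_set"), length(trials) > 0)
  labels <- trial_labels(trials)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training data contain a single class")
  if (length(classes) != config$n_classes)
    stop("data have ", length(classes), " classes but config expects ",
         config$n_classes)
  g <- eeg_graph(graph)
  ch <- attr(trials, "channel_names")
  if (!identical(g$node_names, ch))
    stop("graph nodes do not match trial channels")

  n_layers <- length(config$filters)
  hierarchy <- coarsen_graph(g, levels = n_layers,
                             pool_factor = config$pool_factor)
  laplacians <- lapply(hierarchy$graphs[seq_len(n_layers)], function(gl) {
    Ln <- laplacian_normalized(gl)
    lmax <- if (is.null(approx_lmax)) lambda_max(Ln) else approx_lmax
    scale_laplacian(Ln, lmax)
  })
  n_nodes <- vapply(hierarchy$graphs, function(gl)
    length(gl$node_names), integer(1))

  X <- features_array(trials, config)
  P <- t(stats::model.matrix(~ factor(labels, levels = classes) - 1))
  B <- length(trials)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  params <- init_params(config, n_nodes, dim(X)[2])
  state <- list(m = zero_like(params), v = zero_like(params))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        data_loss = numeric(0), accuracy = numeric(0))
  bs <- min(config$batch_size, B)
  t_step <- 0
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(B)
    ep_loss <- ep_data <- 0
    correct <- 0
    for (start in seq(1, B, by = bs)) {
      idx <- ord[start:min(start + bs - 1, B)]
      Xb <- X[, , idx, drop = FALSE]
      Pb <- P[, idx, drop = FALSE]
      fw <- cgcn_forward(params, laplacians, hierarchy, Xb,
                         train_mode = TRUE, dropout = config$dropout)
      ls <- cgcn_loss(fw$prob, Pb, params, config$l2_lambda)
      grads <- cgcn_backward(fw, Pb, params, laplacians, hierarchy,
                             config$l2_lambda)
      t_step <- t_step + 1
      if (config$optimizer == "adam") {
        st <- adam_step(params, grads, state, config$learning_rate, t_step)
        params <- st$params
        state <- st$state
      } else {
        params <- map_params(params, grads, function(p, g)
          p - config$learning_rate * g)
      }
      ep_loss <- ep_loss + ls$total * length(idx)
      ep_data <- ep_data + ls$data * length(idx)
      correct <- correct + sum(apply(fw$prob, 2, which.max) ==
                                 apply(Pb, 2, which.max))
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep_loss / B, data_loss = ep_data / B,
      accuracy = correct / B))
  }
  structure(list(params = params, hierarchy = hierarchy,
                 laplacians = laplacians, graph = g, classes = classes,
                 config = config, history = history,
                 channel_names = ch),
            class = "cgcn")
}

#' @export
print.cgcn <- function(x, ...) {
  cfg <- x$config
  n_nodes <- vapply(x$hierarchy$graphs, function(g)
    length(g$node_names), integer(1))
  cat("Coherence-based graph convolutional network\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = " vs ")))
  cat(sprintf("  graph: %d electrodes; pooling %s\n", n_nodes[1],
              paste(n_nodes, collapse = " -> ")))
  cat(sprintf("  conv layers: K = %d, filters = %s; dropout %.2f, L2 %.4g\n",
              cfg$K, paste(cfg$filters, collapse = ", "), cfg$dropout,
              cfg$l2_lambda))
  if (nrow(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs: loss %.4f, training accuracy %.3f\n",
                h$epoch, h$loss, h$accuracy))
  } else cat("  untrained (0 epochs)\n")
  invisible(x)
}

#' @export
summary.cgcn <- function(object, ...) {
  print(object)
  np <- sum(vapply(object$params$conv, function(cv)
    length(cv$theta) + length(cv$bias), numeric(1))) +
    length(object$params$fc$W) + length(object$params$fc$b)
  cat(sprintf("  parameters: %d\n", as.integer(np)))
  if (nrow(object$history) > 1) {
    cat("  loss trajectory (first/last 3 epochs):\n")
    h <- object$history
    show <- unique(c(seq_len(min(3, nrow(h))),
                     seq(max(1, nrow(h) - 2), nrow(h))))
    print(h[show, ], row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.cgcn <- function(object, ...) object$params

#' @export
plot.cgcn <- function(x, ...) {
  if (!nrow(x$history)) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "C-GCN training", ...)
  plot(x$history$epoch, x$history$accuracy, type = "l", xlab = "epoch",
       ylab = "training accuracy", ylim = c(0, 1), main = "", ...)
  invisible(x)
}

#' Predict class probabilities or labels
#'
#' @param object A fitted [cgcn()] model.
#' @param newdata A `trial_set` over the same montage.
#' @param type `"prob"` for a trials x classes probability matrix or
#'   `"class"` for predicted labels.
#' @param ... Unused.
#' @return Probability matrix or character vector of labels.
#' @export
predict.cgcn <- function(object, newdata,
                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "trial_set"))
  X <- features_array(newdata, object$config)
  fw <- cgcn_forward(object$params, object$laplacians, object$hierarchy,
                     X, train_mode = FALSE)
  probs <- t(fw$prob)
  colnames(probs) <- object$classes
  if (type == "prob") probs
  else object$classes[max.col(probs, ties.method = "first")]
}

#' Classification metrics
#'
#' Accuracy, per-class precision/recall/F1, macro-averaged F1 and the
#' confusion matrix for a set of predictions.
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param classes Class levels (default: sorted union).
#' @return List with `accuracy`, `f1_macro`, `per_class` (data.frame) and
#'   `confusion` (truth in rows, predictions in columns).
#' @export
classification_metrics <- function(truth, pred,
                                   classes = sort(unique(c(truth, pred)))) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  conf <- table(truth = truth, pred = pred)
  acc <- sum(diag(conf)) / sum(conf)
  per <- lapply(seq_along(classes), function(i) {
    tp <- conf[i, i]
    prec <- if (sum(conf[, i]) > 0) tp / sum(conf[, i]) else 0
    rec <- if (sum(conf[i, ]) > 0) tp / sum(conf[i, ]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = classes[i], precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(accuracy = acc, f1_macro = mean(per$f1), per_class = per,
       confusion = conf)
}

#' Evaluate a fitted model on labelled trials
#'
#' Computes accuracy, macro-F1, the evaluation loss (both-class
#' cross-entropy without the regularization penalty) and the confusion
#' matrix.
#'
#' @param object A fitted [cgcn()].
#' @param trials A labelled `trial_set`.
#' @return An object of class `cgcn_metrics`.
#' @export
evaluate_cgcn <- function(object, trials) {
  stopifnot(inherits(object, "cgcn"), length(trials) > 0)
  probs <- predict(object, trials, type = "prob")
  truth <- trial_labels(trials)
  pred <- object$classes[max.col(probs, ties.method = "first")]
  m <- classification_metrics(truth, pred, object$classes)
  P <- t(stats::model.matrix(~ factor(truth, levels = object$classes) - 1))
  ls <- cgcn_loss(t(probs), P, object$params, l2_lambda = 0)
  structure(list(accuracy = m$accuracy, f1 = m$f1_macro,
                 loss = ls$data, confusion = m$confusion,
                 per_class = m$per_class, n = length(trials)),
            class = "cgcn_metrics")
}

#' @export
print.cgcn_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro-F1 %.4f | loss %.4f (n = %d)\n",
              x$accuracy, x$f1, x$loss, x$n))
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validation of the C-GCN pipeline
#'
#' Splits trials into stratified folds (a pure function of the labels and
#' `config$seed`), band-filters the trials, and for each fold recomputes
#' the coherence graph from that fold's TRAINING trials only (both classes
#' pooled) before fitting and evaluating — so no label or validation
#' information leaks into the graph.
#'
#' @param trials A raw (broadband) `trial_set`.
#' @param band The [frequency_band()] to analyse.
#' @param config A [cgcn_config()].
#' @param folds Number of folds (default 10, i.e. 90/10 splits).
#' @param window_len,overlap Welch parameters for the coherence graphs.
#' @param approx_lmax Passed to [cgcn()].
#' @return An object of class `cgcn_cv`: per-fold `cgcn_metrics` and a
#'   `summary` data.frame of mean and sd for accuracy, F1 and loss.
#' @export
cgcn_cv <- function(trials, band, config = cgcn_config(), folds = 10,
                    window_len = round(attr(trials, "fs")), overlap = 0.5,
                    approx_lmax = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  labels <- trial_labels(trials)
  if (min(table(labels)) < folds)
    stop("need at least ", folds, " trials per class for ", folds, " folds")
  fold_id <- stratified_folds(labels, folds, config$seed)
  ftrials <- filter_trials(trials, band)
  mats <- trial_graph(ftrials, band, mode = "per_trial",
                      window_len = window_len, overlap = overlap)
  fold_metrics <- vector("list", folds)
  for (k in seq_len(folds)) {
    tr <- which(fold_id != k)
    va <- which(fold_id == k)
    gk <- average_coherence(mats[tr], band)
    model <- cgcn(ftrials[tr], gk, config, approx_lmax = approx_lmax)
    fold_metrics[[k]] <- evaluate_cgcn(model, ftrials[va])
  }
  acc <- vapply(fold_metrics, `[[`, numeric(1), "accuracy")
  f1 <- vapply(fold_metrics, `[[`, numeric(1), "f1")
  loss <- vapply(fold_metrics, `[[`, numeric(1), "loss")
  structure(list(
    folds = fold_metrics, fold_id = fold_id, band = band, config = config,
    summary = data.frame(metric = c("accuracy", "f1", "loss"),
                         mean = c(mean(acc), mean(f1), mean(loss)),
                         sd = c(stats::sd(acc), stats::sd(f1),
                                stats::sd(loss)))),
    class = "cgcn_cv")
}

# Deterministic stratified fold assignment.
stratified_folds <- function(labels, folds, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  fold_id
}

#' @export
print.cgcn_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV, band %s\n", length(x$folds),
              x$band$name))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
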