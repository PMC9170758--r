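# Convolutional network for pseudouridylation site classification.
#
# The network is implemented directly in base R matrix algebra. Convolutions
# are "valid" (no padding) cross-correlations computed by im2col: sliding
# windows of the input are gathered into a tall matrix and multiplied against
# the filter bank with one BLAS call. Layout convention used throughout: a
# batch of N encoded sequences is an N x (4 * L) matrix whose columns are the
# column-major flattening of the L x 4 one-hot matrix (position fastest
# within each channel). Gathered window matrices have rows ordered sample-
# fastest within window position, so `dim<-` reshapes between the matmul view
# and the (N, positions, filters) array view without copying semantics
# getting in the way.

# ---- configuration ----------------------------------------------------------

#' Network and optimizer configuration
#'
#' Defaults reproduce the published architecture: a first convolution of 64
#' filters spanning 8 positions x 4 channels, a second convolution of 32
#' filters spanning 8 positions x 64 channels, width-2 non-overlapping max
#' pooling after each convolution, and a 64-64-1 fully-connected head with a
#' logistic output. PReLU activations follow each convolution and each hidden
#' dense layer; batch normalization sits between each convolution and its
#' activation; dropout acts on the hidden dense layers.
#'
#' For the default 101-nt input the feature-map lengths are
#' 94 -> 47 -> 40 -> 20 and the flattened width is 20 x 32 = 640; the
#' constructor rejects configurations whose arithmetic collapses below one
#' position.
#'
#' @param conv1_filters,conv2_filters Filter counts (64, 32).
#' @param conv1_len,conv2_len Filter window lengths (8, 8).
#' @param pool_len Pooling width and stride (2).
#' @param fc_units Hidden dense layer widths (c(64, 64)).
#' @param learning_rate SGD learning rate (0.01).
#' @param dropout_p Dropout probability on hidden dense layers, in `[0, 1)`.
#' @param momentum SGD momentum in `[0, 1)` (0.9).
#' @param batch_size Minibatch size (64).
#' @param max_epochs Epoch cap (100).
#' @param early_stop_patience Epochs without validation-loss improvement
#'   tolerated before stopping (10); 0 stops at the first non-improving epoch.
#' @param seed Integer seed controlling initialization and training RNG.
#' @param input_len Input window length (101).
#' @return Object of class `model_config`.
#' @export
model_config <- function(conv1_filters = 64L, conv1_len = 8L,
                         conv2_filters = 32L, conv2_len = 8L,
                         pool_len = 2L, fc_units = c(64L, 64L),
                         learning_rate = 0.01, dropout_p = 0.25,
                         momentum = 0.9, batch_size = 64L,
                         max_epochs = 100L, early_stop_patience = 10L,
                         seed = 1L, input_len = 101L) {
  cfg <- list(conv1_filters = as.integer(conv1_filters),
              conv1_len = as.integer(conv1_len),
              conv2_filters = as.integer(conv2_filters),
              conv2_len = as.integer(conv2_len),
              pool_len = as.integer(pool_len),
              fc_units = as.integer(fc_units),
              learning_rate = learning_rate,
              dropout_p = dropout_p,
              momentum = momentum,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              early_stop_patience = as.integer(early_stop_patience),
              seed = as.integer(seed),
              input_len = as.integer(input_len),
              bn_eps = 1e-5, bn_momentum = 0.9)
  stopifnot(cfg$pool_len >= 1L, length(cfg$fc_units) >= 1L,
            cfg$dropout_p >= 0, cfg$dropout_p < 1,
            cfg$momentum >= 0, cfg$momentum < 1,
            cfg$learning_rate > 0, cfg$batch_size >= 1L,
            cfg$max_epochs >= 1L, cfg$early_stop_patience >= 0L)
  dims <- feature_map_dims(cfg)   # validates the architecture arithmetic
  cfg$dims <- dims
  structure(cfg, class = "model_config")
}

#' Closed-form feature-map sizes for a configuration
#'
#' Pure arithmetic, independent of the network code: with no-padding
#' convolutions and floor division by the pool width,
#' `conv1 = input - k1 + 1`, `pool1 = conv1 %/% pool`,
#' `conv2 = pool1 - k2 + 1`, `pool2 = conv2 %/% pool`,
#' `flatten = pool2 * conv2_filters`.
#'
#' @param config A `model_config` (or plain list with the same fields).
#' @return List with `conv1`, `pool1`, `conv2`, `pool2`, `flatten`.
#' @export
feature_map_dims <- function(config) {
  l1 <- config$input_len - config$conv1_len + 1L
  if (l1 < 1L) stop("conv1: kernel length ", config$conv1_len,
                    " exceeds input length ", config$input_len)
  p1 <- l1 %/% config$pool_len
  if (p1 < 1L) stop("pool1: feature map collapses to zero length")
  l2 <- p1 - config$conv2_len + 1L
  if (l2 < 1L) stop("conv2: kernel length ", config$conv2_len,
                    " exceeds pooled length ", p1)
  p2 <- l2 %/% config$pool_len
  if (p2 < 1L) stop("pool2: feature map collapses to zero length")
  list(conv1 = l1, pool1 = p1, conv2 = l2, pool2 = p2,
       flatten = p2 * config$conv2_filters)
}

# ---- construction -----------------------------------------------------------

#' Build an untrained network from a configuration
#'
#' Weights are He-initialized from the configuration seed; PReLU slopes start
#' at 0.25; batch-norm scale/shift at 1/0 with running statistics at 0/1.
#'
#' @param config A [model_config()].
#' @return Object of class `psicnn_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d <- config$dims
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  fan1 <- 4L * config$conv1_len
  fan2 <- config$conv1_filters * config$conv2_len
  params <- list(
    W1 = he(fan1, config$conv1_filters), b1 = numeric(config$conv1_filters),
    a1 = rep(0.25, config$conv1_filters),
    g1 = rep(1, config$conv1_filters), be1 = numeric(config$conv1_filters),
    W2 = he(fan2, config$conv2_filters), b2 = numeric(config$conv2_filters),
    a2 = rep(0.25, config$conv2_filters),
    g2 = rep(1, config$conv2_filters), be2 = numeric(config$conv2_filters))
  widths <- c(d$flatten, config$fc_units)
  for (i in seq_along(config$fc_units)) {
    params[[paste0("Wf", i)]] <- he(widths[i], widths[i + 1])
    params[[paste0("bf", i)]] <- numeric(widths[i + 1])
    params[[paste0("af", i)]] <- rep(0.25, widths[i + 1])
  }
  nf <- length(config$fc_units)
  params[[paste0("Wf", nf + 1)]] <- he(widths[nf + 1], 1L)
  params[[paste0("bf", nf + 1)]] <- 0

  running <- list(m1 = numeric(config$conv1_filters),
                  v1 = rep(1, config$conv1_filters),
                  m2 = numeric(config$conv2_filters),
                  v2 = rep(1, config$conv2_filters))

  model <- structure(list(config = config, params = params, running = running,
                          history = NULL, stopped_epoch = NA_integer_),
                     class = "psicnn_model")
  model$cache <- .build_index_cache(config)
  model
}

# Precompute the im2col gather indices and the col2im scatter matrix; these
# depend only on the architecture, never on the batch.
.build_index_cache <- function(config) {
  d <- config$dims
  L <- config$input_len; K1 <- config$conv1_len
  # idx1[p, (ch-1)*K1 + j] = column of the encoded matrix holding channel ch,
  # position p + j - 1
  idx1 <- matrix(0L, d$conv1, 4L * K1)
  for (ch in 1:4) for (j in seq_len(K1)) {
    idx1[, (ch - 1L) * K1 + j] <- (ch - 1L) * L + seq_len(d$conv1) + j - 1L
  }
  K2 <- config$conv2_len; F1 <- config$conv1_filters
  idx2 <- matrix(0L, d$conv2, F1 * K2)
  for (ch in seq_len(F1)) for (j in seq_len(K2)) {
    idx2[, (ch - 1L) * K2 + j] <- (ch - 1L) * d$pool1 + seq_len(d$conv2) + j - 1L
  }
  # sparse 0/1 scatter matrix: rows index the gathered conv2 columns
  # (position fastest within filter-window column), columns index pool1 cells
  S2 <- Matrix::sparseMatrix(i = seq_len(length(idx2)), j = as.vector(idx2),
                             x = 1, dims = c(length(idx2), d$pool1 * F1))
  list(idx1 = as.vector(idx1), idx2 = as.vector(idx2), S2 = S2)
}

# ---- layer helpers ----------------------------------------------------------

.addcol <- function(M, b) M + rep(b, each = nrow(M))

.prelu <- function(Z, a) pmax(Z, 0) + .addcol_mul(pmin(Z, 0), a)
.addcol_mul <- function(M, a) M * rep(a, each = nrow(M))

.bn_forward <- function(Z, gamma, beta, eps, train, rmean, rvar) {
  if (train) {
    mu <- colMeans(Z)
    v <- colMeans(Z * Z) - mu * mu
  } else {
    mu <- rmean; v <- rvar
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- .addcol_mul(.addcol(Z, -mu), inv)
  list(out = .addcol(.addcol_mul(xhat, gamma), beta),
       xhat = xhat, mu = mu, v = v, inv = inv)
}

.bn_backward <- function(dY, bn, gamma) {
  dgamma <- colSums(dY * bn$xhat)
  dbeta <- colSums(dY)
  dxhat <- .addcol_mul(dY, gamma)
  # standard batch-norm gradient (biased batch variance), per column:
  # dZ = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  dZ <- .addcol_mul(
    .addcol(dxhat, -colMeans(dxhat)) -
      .addcol_mul(bn$xhat, colMeans(dxhat * bn$xhat)),
    bn$inv)
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# ---- forward pass -----------------------------------------------------------

# X: N x (4*input_len) encoded batch. Returns list(prob, cache) in training
# mode; plain probabilities otherwise. Dropout masks are drawn from the
# current RNG stream when train = TRUE.
.forward <- function(model, X, train = FALSE) {
  cfg <- model$config; d <- cfg$dims; p <- model$params; ch <- model$cache
  N <- nrow(X)
  F1 <- cfg$conv1_filters; F2 <- cfg$conv2_filters

  M1 <- X[, ch$idx1, drop = FALSE]; dim(M1) <- c(N * d$conv1, 4L * cfg$conv1_len)
  Z1 <- .addcol(M1 %*% p$W1, p$b1)
  bn1 <- .bn_forward(Z1, p$g1, p$be1, cfg$bn_eps, train, model$running$m1, model$running$v1)
  A1 <- .prelu(bn1$out, p$a1)
  dim(A1) <- c(N, d$conv1, F1)
  i1 <- seq(1L, 2L * d$pool1, by = 2L); i2 <- i1 + 1L
  Xa <- A1[, i1, , drop = FALSE]; Xb <- A1[, i2, , drop = FALSE]
  mask1 <- Xa >= Xb                       # ties resolve to the earlier cell
  P1 <- Xa * mask1 + Xb * (!mask1)          # N x pool1 x F1

  Hm <- P1; dim(Hm) <- c(N, d$pool1 * F1)
  M2 <- Hm[, ch$idx2, drop = FALSE]; dim(M2) <- c(N * d$conv2, F1 * cfg$conv2_len)
  Z2 <- .addcol(M2 %*% p$W2, p$b2)
  bn2 <- .bn_forward(Z2, p$g2, p$be2, cfg$bn_eps, train, model$running$m2, model$running$v2)
  A2 <- .prelu(bn2$out, p$a2)
  dim(A2) <- c(N, d$conv2, F2)
  j1 <- seq(1L, 2L * d$pool2, by = 2L); j2 <- j1 + 1L
  Ya <- A2[, j1, , drop = FALSE]; Yb <- A2[, j2, , drop = FALSE]
  mask2 <- Ya >= Yb
  P2 <- Ya * mask2 + Yb * (!mask2)
  Fm <- P2; dim(Fm) <- c(N, d$flatten)

  nf <- length(cfg$fc_units)
  U <- vector("list", nf); D <- vector("list", nf); drop <- vector("list", nf)
  H <- Fm
  for (i in seq_len(nf)) {
    U[[i]] <- .addcol(H %*% p[[paste0("Wf", i)]], p[[paste0("bf", i)]])
    D[[i]] <- .prelu(U[[i]], p[[paste0("af", i)]])
    if (train && cfg$dropout_p > 0) {
      drop[[i]] <- (matrix(stats::runif(length(D[[i]])), nrow(D[[i]])) >=
                      cfg$dropout_p) / (1 - cfg$dropout_p)
      D[[i]] <- D[[i]] * drop[[i]]
    }
    H <- D[[i]]
  }
  logit <- .addcol(H %*% p[[paste0("Wf", nf + 1)]], p[[paste0("bf", nf + 1)]])
  prob <- stats::plogis(as.vector(logit))

  if (!train) return(prob)
  list(prob = prob,
       cache = list(M1 = M1, Z1 = Z1, bn1 = bn1, mask1 = mask1,
                    M2 = M2, Z2 = Z2, bn2 = bn2, mask2 = mask2,
                    Fm = Fm, U = U, D = D, drop = drop, N = N))
}

# ---- backward pass ----------------------------------------------------------

# Mean binary cross-entropy loss gradient through the whole stack.
.backward <- function(model, cache, y) {
  cfg <- model$config; d <- cfg$dims; p <- model$params; ch <- model$cache
  N <- cache$N; F1 <- cfg$conv1_filters; F2 <- cfg$conv2_filters
  nf <- length(cfg$fc_units)
  g <- list()

  dlogit <- matrix((cache$prob - y) / N, ncol = 1)
  H_last <- if (nf > 0) cache$D[[nf]] else cache$Fm
  g[[paste0("Wf", nf + 1)]] <- crossprod(H_last, dlogit)
  g[[paste0("bf", nf + 1)]] <- sum(dlogit)
  dH <- dlogit %*% t(p[[paste0("Wf", nf + 1)]])

  for (i in rev(seq_len(nf))) {
    if (!is.null(cache$drop[[i]])) dH <- dH * cache$drop[[i]]
    Ui <- cache$U[[i]]; ai <- p[[paste0("af", i)]]
    neg <- Ui < 0
    g[[paste0("af", i)]] <- colSums(dH * Ui * neg)
    dU <- dH * (!neg) + .addcol_mul(dH * neg, ai)
    H_prev <- if (i > 1) cache$D[[i - 1]] else cache$Fm
    g[[paste0("Wf", i)]] <- crossprod(H_prev, dU)
    g[[paste0("bf", i)]] <- colSums(dU)
    dH <- dU %*% t(p[[paste0("Wf", i)]])
  }

  # dH is d(loss)/d(flatten): route back through pool2 / PReLU2 / BN2 / conv2
  dP2 <- dH; dim(dP2) <- c(N, d$pool2, F2)
  dA2 <- array(0, c(N, d$conv2, F2))
  j1 <- seq(1L, 2L * d$pool2, by = 2L); j2 <- j1 + 1L
  dA2[, j1, ] <- dP2 * cache$mask2
  dA2[, j2, ] <- dP2 * (!cache$mask2)
  dim(dA2) <- c(N * d$conv2, F2)
  Z2n <- cache$bn2$out                            # BN output (pre-PReLU)
  neg2 <- Z2n < 0
  g$a2 <- colSums(dA2 * Z2n * neg2)
  dZ2n <- dA2 * (!neg2) + .addcol_mul(dA2 * neg2, p$a2)
  bb2 <- .bn_backward(dZ2n, cache$bn2, p$g2)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  g$W2 <- crossprod(cache$M2, bb2$dZ)
  g$b2 <- colSums(bb2$dZ)

  dM2 <- bb2$dZ %*% t(p$W2)                      # (N*conv2) x (F1*K2)
  dim(dM2) <- c(N, d$conv2 * F1 * cfg$conv2_len)
  dHm <- as.matrix(dM2 %*% ch$S2)                # scatter-add back to pool1
  dP1 <- dHm; dim(dP1) <- c(N, d$pool1, F1)
  dA1 <- array(0, c(N, d$conv1, F1))
  i1 <- seq(1L, 2L * d$pool1, by = 2L); i2 <- i1 + 1L
  dA1[, i1, ] <- dP1 * cache$mask1
  dA1[, i2, ] <- dP1 * (!cache$mask1)
  dim(dA1) <- c(N * d$conv1, F1)
  Z1n <- cache$bn1$out
  neg1 <- Z1n < 0
  g$a1 <- colSums(dA1 * Z1n * neg1)
  dZ1n <- dA1 * (!neg1) + .addcol_mul(dA1 * neg1, p$a1)
  bb1 <- .bn_backward(dZ1n, cache$bn1, p$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  g$W1 <- crossprod(cache$M1, bb1$dZ)
  g$b1 <- colSums(bb1$dZ)
  g
}

.bce <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

# ---- training ---------------------------------------------------------------

#' Train the network by minibatch SGD with momentum
#'
#' Minimizes binary cross-entropy. When validation samples are supplied,
#' training stops once the validation loss has failed to improve for
#' `early_stop_patience` consecutive epochs and the best-epoch weights are
#' restored; otherwise training runs for `max_epochs`. Batch-norm running
#' statistics are updated during training and used for all prediction, so
#' prediction is batch-size invariant. Fully deterministic for a fixed
#' configuration seed.
#'
#' @param config A [model_config()].
#' @param train_samples data.frame with `sequence` and `label` columns (as
#'   produced by the sample builders or [generate_dataset()]).
#' @param validation_samples Optional data.frame of the same shape used for
#'   early stopping.
#' @param model Optional pre-built [build_model()] object to continue from;
#'   defaults to a fresh build from `config`.
#' @param verbose Print per-epoch losses.
#' @return A trained `psicnn_model` with `history` (per-epoch train and
#'   validation loss) and `stopped_epoch`.
#' @export
train_model <- function(config, train_samples, validation_samples = NULL,
                        model = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  y <- as.numeric(train_samples$label)
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; both labels are required")
  }
  X <- .encode_batch(train_samples$sequence)
  if (ncol(X) != 4L * config$input_len) {
    stop("training sequences are not of length ", config$input_len)
  }
  has_val <- !is.null(validation_samples)
  if (has_val) {
    Xv <- .encode_batch(validation_samples$sequence)
    yv <- as.numeric(validation_samples$label)
  }
  if (is.null(model)) model <- build_model(config)
  p <- model$params
  vel <- lapply(p, function(x) x * 0)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 1L)

  n <- nrow(X)
  best_loss <- Inf; best <- NULL; patience_left <- config$early_stop_patience
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  stopped <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      model$params <- p
      fw <- .forward(model, X[idx, , drop = FALSE], train = TRUE)
      fw$cache$prob <- fw$prob
      # running batch-norm statistics (biased variance, exponential average)
      bm <- config$bn_momentum
      model$running$m1 <- bm * model$running$m1 + (1 - bm) * fw$cache$bn1$mu
      model$running$v1 <- bm * model$running$v1 + (1 - bm) * fw$cache$bn1$v
      model$running$m2 <- bm * model$running$m2 + (1 - bm) * fw$cache$bn2$mu
      model$running$v2 <- bm * model$running$v2 + (1 - bm) * fw$cache$bn2$v
      g <- .backward(model, fw$cache, y[idx])
      for (nm in names(g)) {
        vel[[nm]] <- config$momentum * vel[[nm]] - config$learning_rate * g[[nm]]
        p[[nm]] <- p[[nm]] + vel[[nm]]
      }
      ep_loss <- ep_loss + .bce(fw$prob, y[idx]) * length(idx)
    }
    model$params <- p
    train_loss <- ep_loss / n
    val_loss <- NA_real_
    if (has_val) {
      val_loss <- .bce(.predict_encoded(model, Xv), yv)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  val %s", epoch, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    }
    if (has_val) {
      if (val_loss < best_loss - 1e-12) {
        best_loss <- val_loss
        best <- list(params = p, running = model$running)
        patience_left <- config$early_stop_patience
      } else {
        if (patience_left == 0L) { stopped <- epoch; break }
        patience_left <- patience_left - 1L
      }
    }
    stopped <- epoch
  }
  if (has_val && !is.null(best)) {
    model$params <- best$params
    model$running <- best$running
  }
  model$history <- hist
  model$stopped_epoch <- stopped
  model
}

# ---- prediction -------------------------------------------------------------

.predict_encoded <- function(model, X, chunk = 1024L) {
  n <- nrow(X)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[idx] <- .forward(model, X[idx, , drop = FALSE], train = FALSE)
  }
  out
}

#' Predict pseudouridylation scores for encoded windows
#'
#' Accepts a character vector of fixed-length sequences, a data.frame with a
#' `sequence` column, a single `L x 4` one-hot matrix, or an `N x 4L` encoded
#' batch matrix. Scores are in `[0, 1]`, one per input, order preserved, and
#' independent of how the inputs are batched (inference uses running
#' batch-norm statistics).
#'
#' @param object A trained `psicnn_model`.
#' @param newdata Sequences or encoded matrices (see Details).
#' @param ... Ignored.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict.psicnn_model <- function(object, newdata, ...) {
  L <- object$config$input_len
  if (is.data.frame(newdata)) newdata <- newdata$sequence
  if (is.character(newdata)) {
    if (!all(nchar(newdata) == L)) {
      stop("input sequences must all have length ", L)
    }
    X <- .encode_batch(newdata)
  } else if (is.matrix(newdata)) {
    if (ncol(newdata) == 4L && nrow(newdata) == L) {
      X <- matrix(as.vector(newdata), nrow = 1L)   # single L x 4 one-hot
    } else if (ncol(newdata) == 4L * L) {
      X <- newdata
    } else {
      stop("encoded input must be ", L, " x 4 (single window) or N x ", 4L * L)
    }
  } else {
    stop("`newdata` must be sequences or an encoded matrix")
  }
  .predict_encoded(object, X)
}

#' @export
print.psicnn_model <- function(x, ...) {
  d <- x$config$dims
  cat("psiCNN model: input", x$config$input_len, "nt;",
      x$config$conv1_filters, "+", x$config$conv2_filters, "conv filters;",
      "feature maps", d$conv1, "->", d$pool1, "->", d$conv2, "->", d$pool2,
      "; flatten", d$flatten, "\n")
  if (!is.null(x$history)) {
    cat("trained", nrow(x$history), "epochs (stopped at", x$stopped_epoch, ")\n")
  }
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

.MODEL_FORMAT <- "psicnn-model"
.MODEL_VERSION <- 1L

.pack_num <- function(x) {
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       data = jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L)))
}
.unpack_num <- function(p) {
  v <- readBin(jsonlite::base64_dec(p$data), numeric(), n = prod(unlist(p$dim)),
               size = 8L)
  if (length(p$dim) == 2L) matrix(v, p$dim[[1]], p$dim[[2]]) else v
}

#' Save a trained model to a single versioned file
#'
#' The file is JSON: configuration plus base64-encoded IEEE-754 weight blobs,
#' so a load/save round trip reproduces predictions bit-for-bit.
#'
#' @param model A `psicnn_model`.
#' @param path Output file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "psicnn_model"))
  cfg <- unclass(model$config); cfg$dims <- NULL
  obj <- list(format = .MODEL_FORMAT, version = .MODEL_VERSION,
              config = cfg,
              params = lapply(model$params, .pack_num),
              running = lapply(model$running, .pack_num),
              stopped_epoch = model$stopped_epoch,
              history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Model file.
#' @return A `psicnn_model` whose predictions equal those of the saved model
#'   exactly.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("corrupt or unreadable model file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, .MODEL_FORMAT)) {
    stop("corrupt model file: unrecognized format", call. = FALSE)
  }
  if (!identical(as.integer(obj$version), .MODEL_VERSION)) {
    stop("model file version ", obj$version, " is not supported", call. = FALSE)
  }
  cfg <- obj$config
  config <- model_config(conv1_filters = cfg$conv1_filters,
                         conv1_len = cfg$conv1_len,
                         conv2_filters = cfg$conv2_filters,
                         conv2_len = cfg$conv2_len,
                         pool_len = cfg$pool_len,
                         fc_units = unlist(cfg$fc_units),
                         learning_rate = cfg$learning_rate,
                         dropout_p = cfg$dropout_p,
                         momentum = cfg$momentum,
                         batch_size = cfg$batch_size,
                         max_epochs = cfg$max_epochs,
                         early_stop_patience = cfg$early_stop_patience,
                         seed = cfg$seed, input_len = cfg$input_len)
  model <- build_model(config)
  if (!setequal(names(obj$params), names(model$params))) {
    stop("corrupt model file: parameter set mismatch", call. = FALSE)
  }
  model$params <- lapply(obj$params, .unpack_num)[names(model$params)]
  model$running <- lapply(obj$running, .unpack_num)[names(model$running)]
  model$stopped_epoch <- if (is.null(obj$stopped_epoch)) NA_integer_ else
    as.integer(obj$stopped_epoch)
  if (!is.null(obj$history)) {
    model$history <- do.call(rbind, lapply(obj$history, function(r) {
      data.frame(epoch = as.integer(r$epoch),
                 train_loss = as.numeric(r$train_loss),
                 val_loss = if (is.null(r$val_loss)) NA_real_ else
                   as.numeric(r$val_loss))
    }))
  }
  model
}
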