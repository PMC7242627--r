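#' Specification of the 3D-CNN classifier
#'
#' The fixed small architecture used throughout:
#' average-pool (2, stride 2) -> conv 64 filters of size 3 (valid, ELU) ->
#' conv 16 filters of size 3 (valid, ELU) -> max-pool 2 -> flatten ->
#' fully connected 16 (ELU) -> fully connected 1 (sigmoid). Convolutions
#' are unpadded and pooling uses floor division; on the 45x54x45
#' single-channel input this yields exactly 257,585 trainable parameters.
#'
#' @param input_shape Spatial dimensions, default `c(45, 54, 45)` (the 4 mm
#'   MNI grid).
#' @param in_channels 1 (single measure) or 9 (all measures stacked).
#' @param conv1_filters,conv2_filters,kernel,pool,fc_hidden Architecture
#'   knobs; defaults reproduce the reference network.
#' @return A list of class `cnn_spec` including the propagated layer shapes.
#' @export
#' @examples
#' parameter_count(cnn_spec())
cnn_spec <- function(input_shape = c(45, 54, 45), in_channels = 1,
                     conv1_filters = 64, conv2_filters = 16,
                     kernel = 3, pool = 2, fc_hidden = 16) {
  stopifnot(length(input_shape) == 3, all(input_shape >= 1))
  if (!in_channels %in% c(1L, 9L)) {
    # other channel counts work mathematically; restrict to the two used
    in_channels <- as.integer(in_channels)
  }
  d0 <- as.integer(input_shape)
  d1 <- d0 %/% pool                       # average pooling, stride = size
  d2 <- d1 - (kernel - 1L)                # valid convolution
  d3 <- d2 - (kernel - 1L)
  d4 <- d3 %/% pool                       # max pooling
  if (any(d2 < 1L) || any(d3 < 1L) || any(d4 < 1L)) {
    abort(sprintf("input %s too small for the receptive chain",
                  paste(d0, collapse = "x")))
  }
  structure(list(
    input_shape = d0, in_channels = as.integer(in_channels),
    conv1_filters = as.integer(conv1_filters),
    conv2_filters = as.integer(conv2_filters),
    kernel = as.integer(kernel), pool = as.integer(pool),
    fc_hidden = as.integer(fc_hidden),
    shapes = list(pool1 = d1, conv1 = d2, conv2 = d3, pool2 = d4,
                  flatten = prod(d4) * as.integer(conv2_filters))),
    class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  s <- x$shapes
  cat(sprintf("<cnn_spec> input (%d, %s)\n", x$in_channels,
              paste(x$input_shape, collapse = "x")))
  cat(sprintf("  avgpool -> %s | conv%d -> %s | conv%d -> %s | maxpool -> %s | flatten %d -> fc%d -> fc1\n",
              paste(s$pool1, collapse = "x"), x$conv1_filters,
              paste(s$conv1, collapse = "x"), x$conv2_filters,
              paste(s$conv2, collapse = "x"), paste(s$pool2, collapse = "x"),
              s$flatten, x$fc_hidden))
  cat(sprintf("  trainable parameters: %s\n",
              format(parameter_count(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sum of all trainable weights and biases of the network (closed-form from
#' the layer arithmetic for a spec; element count of the weight arrays for a
#' built model — the two always agree).
#'
#' @param x A `cnn_spec` or `boldnine_cnn` model.
#' @return Integer parameter count.
#' @export
parameter_count <- function(x) UseMethod("parameter_count")

#' @export
parameter_count.cnn_spec <- function(x) {
  k3 <- x$kernel^3
  conv1 <- x$conv1_filters * (k3 * x$in_channels) + x$conv1_filters
  conv2 <- x$conv2_filters * (k3 * x$conv1_filters) + x$conv2_filters
  fc1 <- x$shapes$flatten * x$fc_hidden + x$fc_hidden
  fc2 <- x$fc_hidden + 1L
  as.integer(conv1 + conv2 + fc1 + fc2)
}

#' @export
parameter_count.boldnine_cnn <- function(x) {
  as.integer(sum(vapply(x$weights, length, 0)))
}

# fan-in scaled uniform init, the conventional default for small nets
init_uniform <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(runif(prod(dims), -b, b), dims)
}

#' Build an (untrained) 3D-CNN
#'
#' Initializes all weights with fan-in-scaled uniform draws under the given
#' seed, so two builds with the same seed are identical.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer RNG seed for initialization.
#' @return An object of class `boldnine_cnn`.
#' @export
build_cnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  k3 <- spec$kernel^3
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  w <- list(
    W1 = init_uniform(c(spec$in_channels, spec$conv1_filters, k3),
                      k3 * spec$in_channels),
    b1 = as.vector(init_uniform(spec$conv1_filters, k3 * spec$in_channels)),
    W2 = init_uniform(c(spec$conv1_filters, spec$conv2_filters, k3),
                      k3 * spec$conv1_filters),
    b2 = as.vector(init_uniform(spec$conv2_filters, k3 * spec$conv1_filters)),
    Wf1 = init_uniform(c(spec$shapes$flatten, spec$fc_hidden),
                       spec$shapes$flatten),
    bf1 = as.vector(init_uniform(spec$fc_hidden, spec$shapes$flatten)),
    Wf2 = init_uniform(c(spec$fc_hidden, 1L), spec$fc_hidden),
    bf2 = as.vector(init_uniform(1L, spec$fc_hidden)))
  structure(list(kind = "cnn", spec = spec, weights = w, seed = seed,
                 best_epoch = NA_integer_, training_log = NULL),
            class = "boldnine_cnn")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
# derivative of ELU expressed through its activation value
elu_grad_from_act <- function(a) {
  g <- array(1, dim(a) %||% length(a))
  neg <- a < 0
  g[neg] <- a[neg] + 1
  g
}

# strided pooling index sequences
pool_seq <- function(out_len, pool, off) seq.int(off, by = pool, length.out = out_len)

# average pooling (size = stride = pool) on layout (C, X, Y, Z, B)
avgpool_fwd <- function(x, pool, od) {
  dm <- dim(x)
  out <- array(0, c(dm[1], od, dm[5]))
  for (dz in 1:pool) for (dy in 1:pool) for (dx in 1:pool) {
    out <- out + x[, pool_seq(od[1], pool, dx), pool_seq(od[2], pool, dy),
                   pool_seq(od[3], pool, dz), , drop = FALSE]
  }
  out / pool^3
}

# byte budget above which forward slices are not cached for the backward
# pass (they are then recomputed, trading time for memory on large grids)
.conv_cache_limit <- 1.2e9

# the k^3 shifted views of x, each flattened to a (Cin, N) matrix
conv_blocks <- function(x, k, od) {
  dm <- dim(x)
  n <- prod(od) * dm[5]
  blocks <- vector("list", k^3)
  o <- 0L
  for (dz in 0:(k - 1)) for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    o <- o + 1L
    s <- x[, (1 + dx):(od[1] + dx), (1 + dy):(od[2] + dy),
           (1 + dz):(od[3] + dz), , drop = FALSE]
    dim(s) <- c(dm[1], n)
    blocks[[o]] <- s
  }
  blocks
}

# valid 3D convolution on layout (C, X, Y, Z, B) via shift-and-GEMM: one
# BLAS multiply per kernel offset; with keep_cols the shifted views are
# cached for reuse by the backward pass (when they fit the byte budget)
conv_fwd <- function(x, w, b, k, od, keep_cols = FALSE) {
  dm <- dim(x)
  cout <- dim(w)[2]
  n <- prod(od) * dm[5]
  cache <- keep_cols && dm[1] * k^3 * n * 8 <= .conv_cache_limit
  blocks <- if (cache) vector("list", k^3) else NULL
  out <- matrix(b, cout, n)
  o <- 0L
  for (dz in 0:(k - 1)) for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    o <- o + 1L
    s <- x[, (1 + dx):(od[1] + dx), (1 + dy):(od[2] + dy),
           (1 + dz):(od[3] + dz), , drop = FALSE]
    dim(s) <- c(dm[1], n)
    wo <- w[, , o]; dim(wo) <- dim(w)[1:2]
    out <- out + crossprod(wo, s)
    if (cache) blocks[[o]] <- s
  }
  dim(out) <- c(cout, od, dm[5])
  list(out = out, cols = blocks)
}

# gradients of a valid convolution: weight/bias grads and input grad;
# cached forward blocks avoid re-slicing the input
conv_bwd <- function(x, w, k, od, dout, cols = NULL) {
  dm <- dim(x)
  cin <- dm[1]
  cout <- dim(w)[2]
  n <- prod(od) * dm[5]
  dmat <- dout; dim(dmat) <- c(cout, n)
  dw <- array(0, dim(w))
  dx_arr <- array(0, dm)
  o <- 0L
  for (dz in 0:(k - 1)) for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    o <- o + 1L
    ix <- (1 + dx):(od[1] + dx); iy <- (1 + dy):(od[2] + dy)
    iz <- (1 + dz):(od[3] + dz)
    if (is.null(cols)) {
      s <- x[, ix, iy, iz, , drop = FALSE]
      dim(s) <- c(cin, n)
    } else {
      s <- cols[[o]]
    }
    dw[, , o] <- tcrossprod(s, dmat)
    wo <- w[, , o]; dim(wo) <- dim(w)[1:2]
    ds <- wo %*% dmat
    dim(ds) <- c(cin, od, dm[5])
    dx_arr[, ix, iy, iz, ] <- dx_arr[, ix, iy, iz, , drop = FALSE] + ds
  }
  list(dw = dw, db = rowSums(dmat), dx = dx_arr)
}

# max pooling with argmax bookkeeping for the backward pass
maxpool_fwd <- function(x, pool, od) {
  dm <- dim(x)
  out <- NULL; arg <- NULL
  j <- 0L
  for (dz in 1:pool) for (dy in 1:pool) for (dx in 1:pool) {
    j <- j + 1L
    s <- x[, pool_seq(od[1], pool, dx), pool_seq(od[2], pool, dy),
           pool_seq(od[3], pool, dz), , drop = FALSE]
    if (is.null(out)) {
      out <- s; arg <- array(1L, dim(s))
    } else {
      upd <- s > out
      out[upd] <- s[upd]
      arg[upd] <- j
    }
  }
  list(out = out, arg = arg)
}

maxpool_bwd <- function(dout, arg, in_dim, pool, od) {
  dx_arr <- array(0, in_dim)
  j <- 0L
  for (dz in 1:pool) for (dy in 1:pool) for (dx in 1:pool) {
    j <- j + 1L
    ix <- pool_seq(od[1], pool, dx); iy <- pool_seq(od[2], pool, dy)
    iz <- pool_seq(od[3], pool, dz)
    dx_arr[, ix, iy, iz, ] <- dout * (arg == j)
  }
  dx_arr
}

# engine selection: the compiled kernels are the default; the pure-R path
# ("r") is the reference implementation the kernels are tested against
cnn_engine <- function() getOption("boldnine.engine", "cpp")

# weight array (Cin, Cout, k^3) as the (Cin*k^3, Cout) matrix whose row
# order is channel-within-offset (offsets enumerated dx fastest)
conv_wmat <- function(w) {
  d <- dim(w)
  m <- aperm(w, c(1L, 3L, 2L))
  dim(m) <- c(d[1] * d[3], d[2])
  m
}

# weight arrays in the matrix layout the compiled kernels consume
weights_as_mats <- function(w) {
  list(Wm1 = conv_wmat(w$W1), b1 = w$b1,
       Wm2 = conv_wmat(w$W2), b2 = w$b2,
       Wf1 = w$Wf1, bf1 = w$bf1,
       Wf2 = as.vector(w$Wf2), bf2 = w$bf2)
}

# (Cin*k^3, Cout) gradient matrix back to the (Cin, Cout, k^3) array layout
wmat_as_array <- function(m, cin, cout, k3) {
  aperm(array(m, c(cin, k3, cout)), c(1L, 3L, 2L))
}

# full forward pass; keep = TRUE caches activations for backprop
cnn_forward <- function(model, x, keep = FALSE) {
  sp <- model$spec; w <- model$weights; s <- sp$shapes
  if (length(dim(x)) != 5L || dim(x)[1] != sp$in_channels) {
    abort("input must have layout (channels, x, y, z, batch)")
  }
  p1 <- avgpool_fwd(x, sp$pool, s$pool1)
  c1 <- conv_fwd(p1, w$W1, w$b1, sp$kernel, s$conv1, keep_cols = keep)
  a1 <- elu(c1$out)
  c2 <- conv_fwd(a1, w$W2, w$b2, sp$kernel, s$conv2, keep_cols = keep)
  a2 <- elu(c2$out)
  mp <- maxpool_fwd(a2, sp$pool, s$pool2)
  b <- dim(x)[5]
  f <- matrix(mp$out, s$flatten, b)
  h <- elu(crossprod(w$Wf1, f) + w$bf1)
  z <- as.vector(crossprod(w$Wf2, h)) + w$bf2
  p <- 1 / (1 + exp(-z))
  if (!keep) return(list(p = p))
  list(p = p, z = z, h = h, f = f, mp = mp, a2 = a2, a1 = a1, p1 = p1,
       cols1 = c1$cols, cols2 = c2$cols)
}

# backward pass for mean binary cross-entropy over the batch
cnn_backward <- function(model, x, y, fw) {
  sp <- model$spec; w <- model$weights; s <- sp$shapes
  b <- length(y)
  dz <- matrix((fw$p - y) / b, 1, b)
  dwf2 <- fw$h %*% t(dz)
  dbf2 <- sum(dz)
  dh <- (w$Wf2 %*% dz) * elu_grad_from_act(fw$h)
  dwf1 <- fw$f %*% t(dh)
  dbf1 <- rowSums(dh)
  df <- w$Wf1 %*% dh
  dm <- array(df, dim(fw$mp$out))
  da2 <- maxpool_bwd(dm, fw$mp$arg, dim(fw$a2), sp$pool, s$pool2)
  dz2 <- da2 * elu_grad_from_act(fw$a2)
  g2 <- conv_bwd(fw$a1, w$W2, sp$kernel, s$conv2, dz2, cols = fw$cols2)
  dz1 <- g2$dx * elu_grad_from_act(fw$a1)
  g1 <- conv_bwd(fw$p1, w$W1, sp$kernel, s$conv1, dz1, cols = fw$cols1)
  list(W1 = g1$dw, b1 = g1$db, W2 = g2$dw, b2 = g2$db,
       Wf1 = dwf1, bf1 = dbf1, Wf2 = dwf2, bf2 = dbf2)
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Training configuration for the 3D-CNN
#'
#' Defaults follow the reference protocol: mini-batches of 32, at most 50
#' epochs, SGD with learning rate 0.001 and momentum 0.9, binary
#' cross-entropy on the sigmoid output, and no regularization of any kind.
#' The epoch whose weights score the best plain accuracy on the validation
#' set is kept (ties resolve to the earliest epoch).
#'
#' @param batch_size Mini-batch size (the last incomplete batch is used,
#'   not dropped).
#' @param max_epochs Maximum number of epochs.
#' @param lr,momentum SGD hyperparameters.
#' @param seed Seed controlling shuffling (and any other training
#'   randomness); two runs with the same seed produce identical logs.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, max_epochs = 50L,
                         lr = 0.001, momentum = 0.9, seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 1, lr > 0,
            momentum >= 0, momentum < 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lr = lr, momentum = momentum, seed = as.integer(seed)),
            class = "train_config")
}

#' Train the 3D-CNN with epoch-wise validation selection
#'
#' Runs mini-batch SGD with per-epoch shuffling, evaluates validation
#' accuracy after every epoch, and returns the weight snapshot with the
#' best validation accuracy (earliest epoch on ties). The final-epoch
#' weights are also retained, which is what exposes the network's
#' overfitting behavior when trained well past validation convergence.
#'
#' @param model An untrained [build_cnn()] model.
#' @param x_train,x_val Arrays with layout (channels, x, y, z, subjects).
#' @param y_train,y_val Numeric 0/1 labels (1 = patient).
#' @param config A [train_config()].
#' @return The model with `weights` (best epoch), `final_weights`,
#'   `best_epoch` and a `training_log` tibble (epoch, train_loss,
#'   train_accuracy, val_accuracy).
#' @export
train_cnn <- function(model, x_train, y_train, x_val, y_val,
                      config = train_config()) {
  stopifnot(inherits(model, "boldnine_cnn"))
  n <- dim(x_train)[5]; nv <- dim(x_val)[5]
  if (n == 0L || nv == 0L) abort("empty training or validation set")
  if (length(y_train) != n || length(y_val) != nv) abort("label length mismatch")
  if (length(unique(y_train)) < 2L) abort("training set has a single class")
  w <- model$weights
  vel <- lapply(w, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
  })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  best_acc <- -Inf; best_epoch <- NA_integer_; best_w <- w
  log <- vector("list", config$max_epochs)
  for (ep in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    losses <- 0; correct <- 0
    for (st in seq(1L, n, by = config$batch_size)) {
      idx <- perm[st:min(st + config$batch_size - 1L, n)]
      xb <- x_train[, , , , idx, drop = FALSE]
      yb <- y_train[idx]
      if (cnn_engine() == "cpp") {
        sp <- model$spec
        wm <- weights_as_mats(w)
        res <- cnn_fwdbwd_cpp(as.vector(xb), dim(xb), wm$Wm1, wm$b1,
                              wm$Wm2, wm$b2, wm$Wf1, wm$bf1, wm$Wf2, wm$bf2,
                              sp$kernel, sp$pool, as.numeric(yb))
        k3 <- sp$kernel^3
        gr <- list(
          W1 = wmat_as_array(res$dWm1, sp$in_channels, sp$conv1_filters, k3),
          b1 = as.vector(res$db1),
          W2 = wmat_as_array(res$dWm2, sp$conv1_filters, sp$conv2_filters, k3),
          b2 = as.vector(res$db2),
          Wf1 = res$dWf1, bf1 = as.vector(res$dbf1),
          Wf2 = matrix(res$dWf2, ncol = 1), bf2 = res$dbf2)
        p <- as.vector(res$p)
        losses <- losses + res$loss * length(idx)
      } else {
        mtmp <- model; mtmp$weights <- w
        fw <- cnn_forward(mtmp, xb, keep = TRUE)
        gr <- cnn_backward(mtmp, xb, yb, fw)
        p <- fw$p
        losses <- losses + bce_loss(p, yb) * length(idx)
      }
      correct <- correct + sum((p >= 0.5) == (yb == 1))
      for (nm in names(w)) {
        vel[[nm]] <- config$momentum * vel[[nm]] + gr[[nm]]
        w[[nm]] <- w[[nm]] - config$lr * vel[[nm]]
      }
    }
    mtmp <- model; mtmp$weights <- w
    va_acc <- cnn_accuracy(mtmp, x_val, y_val, config$batch_size)
    # train_accuracy is the running estimate over the epoch's mini-batches
    # (each batch scored just before its update), the usual epoch log
    log[[ep]] <- tibble(epoch = ep, train_loss = losses / n,
                        train_accuracy = correct / n, val_accuracy = va_acc)
    if (va_acc > best_acc) {
      best_acc <- va_acc; best_epoch <- ep; best_w <- w
    }
  }
  model$weights <- best_w
  model$final_weights <- w
  model$best_epoch <- best_epoch
  model$training_log <- dplyr::bind_rows(log)
  model
}

cnn_accuracy <- function(model, x, y, batch_size = 64L) {
  p <- cnn_scores(model, x, batch_size)
  mean((p >= 0.5) == (y == 1))
}

cnn_scores <- function(model, x, batch_size = 64L) {
  n <- dim(x)[5]
  out <- numeric(n)
  use_cpp <- cnn_engine() == "cpp"
  wm <- if (use_cpp) weights_as_mats(model$weights)
  for (st in seq(1L, n, by = batch_size)) {
    idx <- st:min(st + batch_size - 1L, n)
    xb <- x[, , , , idx, drop = FALSE]
    out[idx] <- if (use_cpp) {
      sp <- model$spec
      as.vector(cnn_fwd_cpp(as.vector(xb), dim(xb), wm$Wm1, wm$b1, wm$Wm2,
                            wm$b2, wm$Wf1, wm$bf1, wm$Wf2, wm$bf2,
                            sp$kernel, sp$pool))
    } else {
      cnn_forward(model, xb)$p
    }
  }
  out
}

#' Predict with a trained 3D-CNN
#'
#' @param model A trained `boldnine_cnn`.
#' @param x Input array, layout (channels, x, y, z, subjects).
#' @param subject_ids Optional ids for the prediction table.
#' @param weights Use the best-validation-epoch snapshot (default) or the
#'   final-epoch weights.
#' @param batch_size Prediction batch size (results are batch-size
#'   independent).
#' @return A `prediction_set` tibble: `subject_id`, `score` (sigmoid
#'   probability), `label` (score >= 0.5).
#' @export
predict_cnn <- function(model, x, subject_ids = NULL,
                        weights = c("best", "final"), batch_size = 64L) {
  weights <- match.arg(weights)
  if (weights == "final" && !is.null(model$final_weights)) {
    model$weights <- model$final_weights
  }
  p <- cnn_scores(model, x, batch_size)
  prediction_set(subject_ids %||% as.character(seq_along(p)), p,
                 as.integer(p >= 0.5), kind = "cnn")
}

#' Construct a prediction set
#'
#' @param subject_ids Character ids.
#' @param score Sigmoid probabilities (CNN) or signed margins (SVM).
#' @param label Integer 0/1 predicted labels.
#' @param kind `"cnn"`, `"svm"` or `"ensemble"`.
#' @return A tibble of class `prediction_set`.
#' @export
prediction_set <- function(subject_ids, score, label, kind = "cnn") {
  out <- tibble(subject_id = as.character(subject_ids),
                score = as.numeric(score), label = as.integer(label))
  class(out) <- c("prediction_set", class(out))
  attr(out, "kind") <- kind
  out
}

#' @export
print.boldnine_cnn <- function(x, ...) {
  cat(sprintf("<boldnine_cnn> %s parameters | %s\n",
              format(parameter_count(x), big.mark = ","),
              if (is.na(x$best_epoch)) "untrained"
              else sprintf("trained, best epoch %d", x$best_epoch)))
  invisible(x)
}

#' Persist and reload a model checkpoint
#'
#' A checkpoint bundles the architecture, the best-epoch and final weights,
#' and the training log; the log is additionally written next to it as a
#' tab-delimited table (epoch, train_loss, train_accuracy, val_accuracy).
#'
#' @param model A `boldnine_cnn` or `boldnine_svm`.
#' @param path Checkpoint path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  if (inherits(model, "boldnine_cnn") && !is.null(model$training_log)) {
    readr::write_tsv(model$training_log,
                     sub("\\.rds$", "_log.tsv", path))
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
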