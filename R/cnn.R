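# Inception-style convolutional classifier of presented vs non-presented
# peptides, one model per allele.
#
# Architecture: the 11 x 21 one-hot input is read by three parallel
# convolutional branches with 8 two-dimensional kernels each. Kernels span
# all 21 residue columns and 2, 3 or 4 consecutive positions (a multi-scale
# reading of 2-/3-/4-residue windows, stride 1, no padding), activated by
# Leaky ReLU. Because the kernels cover the full residue axis, each branch
# output collapses to (12 - h) positions x 8 kernels; the three branches are
# flattened, concatenated (216 features at the defaults), passed through a
# 100-unit dense layer with Leaky ReLU and inverted dropout, and a 2-node
# softmax gives the presented / not-presented probabilities.
#
# Training is mini-batch Adam on cross-entropy with early stopping on
# validation loss. Everything is plain vectorized R: the convolution is an
# im2col expansion followed by one matrix product per branch, which is fast
# at these tiny spatial extents and keeps the package free of compiled or
# framework dependencies.

#' Configuration of the presentation classifier
#'
#' Defaults follow the published architecture where stated (three parallel
#' branches of eight 2-D kernels, 100 dense units, Leaky ReLU alpha = 0.2,
#' two-node softmax output, Adam with canonical parameters, dropout and
#' early stopping); kernel heights, dropout rate, batch size and the epoch
#' budget are declared package choices, all overridable.
#'
#' @param branch_kernel_heights integer vector of exactly three kernel
#'   heights (rows spanned); kernels always span all 21 columns.
#' @param kernels_per_branch kernels per branch (default 8).
#' @param dense_units hidden units in the dense layer (default 100).
#' @param leaky_relu_alpha negative-slope of the Leaky ReLU (default 0.2).
#' @param dropout_rate dropout after the dense layer, in [0, 1) (default 0.4).
#' @param learning_rate,beta1,beta2,epsilon Adam parameters (canonical
#'   defaults).
#' @param batch_size mini-batch size (default 128).
#' @param max_epochs epoch budget (default 200).
#' @param early_stopping_patience consecutive non-improving validation
#'   epochs tolerated before halting (default 10; 0 halts at the first).
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @return list with class `model_config`.
#' @export
model_config <- function(branch_kernel_heights = c(2L, 3L, 4L),
                         kernels_per_branch = 8L,
                         dense_units = 100L,
                         leaky_relu_alpha = 0.2,
                         dropout_rate = 0.4,
                         learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         batch_size = 128L,
                         max_epochs = 200L,
                         early_stopping_patience = 10L,
                         seed = 1L) {
  if (length(branch_kernel_heights) != 3L)
    cond_stop("exactly three convolutional branches are required",
              "hlapresent_config_error")
  if (any(branch_kernel_heights < 1L | branch_kernel_heights > PEP_MAX))
    cond_stop("branch kernel heights must lie in [1, 11]",
              "hlapresent_config_error")
  if (dropout_rate < 0 || dropout_rate >= 1)
    cond_stop("dropout_rate must lie in [0, 1)", "hlapresent_config_error")
  structure(list(
    branch_kernel_heights = as.integer(branch_kernel_heights),
    kernels_per_branch = as.integer(kernels_per_branch),
    dense_units = as.integer(dense_units),
    leaky_relu_alpha = leaky_relu_alpha,
    dropout_rate = dropout_rate,
    learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
    epsilon = epsilon,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    early_stopping_patience = as.integer(early_stopping_patience),
    seed = as.integer(seed)), class = "model_config")
}

# column indices of the flat 231-vector touched by a kernel of height h at
# vertical offset p (1-based): rows p..p+h-1, all 21 columns
conv_cols <- function(h, p) {
  as.vector(vapply(p:(p + h - 1L), function(r)
    (r - 1L) * ENC_COLS + seq_len(ENC_COLS), integer(ENC_COLS)))
}

#' Build an untrained presentation classifier
#'
#' Initializes weights (He-scaled Gaussian) under `config$seed` and returns
#' a model handle; [n_parameters()] reports the total trainable parameter
#' count.
#'
#' @param config a [model_config()].
#' @param allele optional allele name stored with the model.
#' @return object of class `hla_cnn`.
#' @export
build_model <- function(config = model_config(), allele = NULL) {
  if (!inherits(config, "model_config")) config <- do.call(model_config, config)
  rng <- local_rng(config$seed)
  k <- config$kernels_per_branch
  heights <- config$branch_kernel_heights
  conv_w <- list(); conv_b <- list(); positions <- list(); colsets <- list()
  for (b in seq_along(heights)) {
    h <- heights[b]
    fan_in <- h * ENC_COLS
    conv_w[[b]] <- matrix(stats::rnorm(fan_in * k, sd = sqrt(2 / fan_in)),
                          fan_in, k)
    conv_b[[b]] <- rep(0, k)
    p <- PEP_MAX - h + 1L
    positions[[b]] <- p
    colsets[[b]] <- lapply(seq_len(p), function(pp) conv_cols(h, pp))
  }
  n_flat <- sum(unlist(positions) * k)
  w1 <- matrix(stats::rnorm(n_flat * config$dense_units, sd = sqrt(2 / n_flat)),
               n_flat, config$dense_units)
  b1 <- rep(0, config$dense_units)
  w2 <- matrix(stats::rnorm(config$dense_units * 2, sd = sqrt(2 / config$dense_units)),
               config$dense_units, 2)
  b2 <- rep(0, 2)
  rng()
  structure(list(
    config = config, allele = allele,
    alphabet = enc_alphabet(),
    params = list(conv_w = conv_w, conv_b = conv_b, w1 = w1, b1 = b1,
                  w2 = w2, b2 = b2),
    colsets = colsets, positions = unlist(positions),
    trained = FALSE, history = NULL), class = "hla_cnn")
}

#' Total trainable parameter count of a model
#'
#' @param model an `hla_cnn`.
#' @export
n_parameters <- function(model) length(flatten_params(model$params))

leaky <- function(x, alpha) ifelse(x > 0, x, alpha * x)
leaky_grad <- function(x, alpha) ifelse(x > 0, 1, alpha)

# im2col: stack the per-position input slices of branch b vertically;
# rows are ordered position-major ((p-1)*N + n).
im2col <- function(X, colset) {
  do.call(rbind, lapply(colset, function(cols) X[, cols, drop = FALSE]))
}

# Forward pass. Returns softmax probabilities and, when `keep = TRUE`, the
# intermediate activations needed for backpropagation.
cnn_forward <- function(model, X, dropmask = NULL, keep = FALSE) {
  cfg <- model$config
  p <- model$params
  n <- nrow(X)
  branches <- vector("list", length(p$conv_w))
  caches <- if (keep) vector("list", length(p$conv_w))
  for (b in seq_along(p$conv_w)) {
    xh <- im2col(X, model$colsets[[b]])
    z <- sweep(xh %*% p$conv_w[[b]], 2, p$conv_b[[b]], "+")
    a <- leaky(z, cfg$leaky_relu_alpha)
    np <- model$positions[b]
    flat <- matrix(a, nrow = n)          # columns ordered (p fastest, then k)
    branches[[b]] <- flat
    if (keep) caches[[b]] <- list(xh = xh, z = z)
  }
  concat <- do.call(cbind, branches)
  z1 <- sweep(concat %*% p$w1, 2, p$b1, "+")
  h1 <- leaky(z1, cfg$leaky_relu_alpha)
  hd <- if (is.null(dropmask)) h1 else h1 * dropmask
  z2 <- sweep(hd %*% p$w2, 2, p$b2, "+")
  zmax <- apply(z2, 1, max)
  ez <- exp(z2 - zmax)
  probs <- ez / rowSums(ez)
  out <- list(probs = probs)
  if (keep) out <- c(out, list(concat = concat, z1 = z1, hd = hd,
                               caches = caches))
  out
}

# Backward pass: gradients of mean cross-entropy w.r.t. all parameters
# (and optionally the input, for attribution).
cnn_backward <- function(model, X, y01, fwd, dropmask = NULL,
                         want_dx = FALSE) {
  cfg <- model$config
  p <- model$params
  n <- nrow(X)
  y <- cbind(1 - y01, y01)
  dz2 <- (fwd$probs - y) / n
  g <- list(w2 = crossprod(fwd$hd, dz2), b2 = colSums(dz2))
  dhd <- dz2 %*% t(p$w2)
  if (!is.null(dropmask)) dhd <- dhd * dropmask
  dz1 <- dhd * leaky_grad(fwd$z1, cfg$leaky_relu_alpha)
  g$w1 <- crossprod(fwd$concat, dz1)
  g$b1 <- colSums(dz1)
  dconcat <- dz1 %*% t(p$w1)
  g$conv_w <- list(); g$conv_b <- list()
  if (want_dx) dX <- matrix(0, n, ncol(X))
  offset <- 0L
  k <- cfg$kernels_per_branch
  for (b in seq_along(p$conv_w)) {
    np <- model$positions[b]
    dflat <- dconcat[, offset + seq_len(np * k), drop = FALSE]
    offset <- offset + np * k
    dz <- dflat
    dim(dz) <- c(n * np, k)              # inverse of the forward reshape
    dz <- dz * leaky_grad(fwd$caches[[b]]$z, cfg$leaky_relu_alpha)
    g$conv_w[[b]] <- crossprod(fwd$caches[[b]]$xh, dz)
    g$conv_b[[b]] <- colSums(dz)
    if (want_dx) {
      dxh <- dz %*% t(p$conv_w[[b]])
      for (pp in seq_len(np)) {
        rows <- (pp - 1L) * n + seq_len(n)
        cols <- model$colsets[[b]][[pp]]
        dX[, cols] <- dX[, cols] + dxh[rows, , drop = FALSE]
      }
    }
  }
  if (want_dx) g$dX <- dX
  g
}

flatten_params <- function(p) c(unlist(p$conv_w), unlist(p$conv_b),
                                p$w1, p$b1, p$w2, p$b2)

relist_params <- function(vec, template) {
  out <- template
  i <- 0L
  take <- function(x) {
    v <- vec[i + seq_along(unlist(x))]
    i <<- i + length(unlist(x))
    if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
  }
  out$conv_w <- lapply(template$conv_w, take)
  out$conv_b <- lapply(template$conv_b, take)
  out$w1 <- take(template$w1); out$b1 <- take(template$b1)
  out$w2 <- take(template$w2); out$b2 <- take(template$b2)
  out
}

cross_entropy <- function(probs, y01) {
  eps <- 1e-12
  p1 <- pmin(pmax(probs[, 2], eps), 1 - eps)
  -mean(y01 * log(p1) + (1 - y01) * log(1 - p1))
}

# chunked loss evaluation (keeps memory flat on large validation sets)
eval_loss <- function(model, X, y01, chunk = 4096L) {
  n <- nrow(X)
  total <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    f <- cnn_forward(model, X[idx, , drop = FALSE])
    total <- total + cross_entropy(f$probs, y01[idx]) * length(idx)
  }
  total / n
}

#' Train the presentation classifier
#'
#' Mini-batch Adam on cross-entropy. After every epoch the validation loss
#' is computed; training halts at the epoch budget or when validation loss
#' has failed to improve for `early_stopping_patience` consecutive epochs,
#' and the weights from the best validation epoch are restored. Dropout is
#' active only during training. Fully deterministic under `config$seed` in
#' single-threaded R.
#'
#' @param model an untrained (or warm) `hla_cnn` from [build_model()].
#' @param train_set,validation_set data.frames with `peptide` and `label`
#'   columns (labels 0/1), or lists `list(x = <n x 231 matrix>, y = <0/1>)`.
#' @param verbose print per-epoch losses.
#' @return the trained model; `$history` is a data.frame of per-epoch train
#'   and validation loss, `$best_epoch` the epoch whose weights were kept.
#' @export
train_model <- function(model, train_set, validation_set, verbose = FALSE) {
  cfg <- model$config
  tr <- as_xy(train_set)
  va <- as_xy(validation_set)
  if (!nrow(tr$x) || !nrow(va$x))
    cond_stop("training and validation sets must be nonempty",
              "hlapresent_size_error")
  if (length(unique(va$y)) < 2L)
    warning("validation set contains a single class; early stopping uses loss only")
  rng <- local_rng(cfg$seed + 1L)
  on.exit(rng())
  n <- nrow(tr$x)
  theta <- flatten_params(model$params)
  m_t <- numeric(length(theta)); v_t <- numeric(length(theta))
  step <- 0L
  best_loss <- Inf; best_theta <- theta; best_epoch <- 0L
  since_improve <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  keep_prob <- 1 - cfg$dropout_rate
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (s in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      xb <- tr$x[idx, , drop = FALSE]
      yb <- tr$y[idx]
      dropmask <- if (cfg$dropout_rate > 0)
        matrix(stats::rbinom(length(idx) * cfg$dense_units, 1L, keep_prob) / keep_prob,
               length(idx), cfg$dense_units)
      fwd <- cnn_forward(model, xb, dropmask = dropmask, keep = TRUE)
      epoch_loss <- epoch_loss + cross_entropy(fwd$probs, yb) * length(idx)
      grad <- cnn_backward(model, xb, yb, fwd, dropmask = dropmask)
      gvec <- flatten_params(grad[c("conv_w", "conv_b", "w1", "b1", "w2", "b2")])
      step <- step + 1L
      m_t <- cfg$beta1 * m_t + (1 - cfg$beta1) * gvec
      v_t <- cfg$beta2 * v_t + (1 - cfg$beta2) * gvec^2
      mhat <- m_t / (1 - cfg$beta1^step)
      vhat <- v_t / (1 - cfg$beta2^step)
      theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$epsilon)
      model$params <- relist_params(theta, model$params)
    }
    val_loss <- eval_loss(model, va$x, va$y)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / n, val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      epoch_loss / n, val_loss))
    if (val_loss < best_loss - 1e-9) {
      best_loss <- val_loss; best_theta <- theta; best_epoch <- epoch
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve > cfg$early_stopping_patience) break
    }
  }
  model$params <- relist_params(best_theta, model$params)
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best_epoch
  model
}

as_xy <- function(set) {
  if (is.list(set) && !is.data.frame(set) && all(c("x", "y") %in% names(set)))
    return(list(x = set$x, y = as.numeric(set$y)))
  if (!all(c("peptide", "label") %in% names(set)))
    cond_stop("expected a data.frame with 'peptide' and 'label' columns",
              "hlapresent_format_error")
  list(x = encode_matrix(set$peptide), y = as.numeric(set$label))
}

#' Predict presentation probabilities for peptides
#'
#' @param object a trained `hla_cnn`.
#' @param peptides character vector of 8-11mer peptides.
#' @param threshold positive-class probability above which a peptide is
#'   called presented (default 0.5).
#' @param ... unused.
#' @return data.frame with one row per input peptide, in order: `peptide`,
#'   `score` (probability of presentation, in [0, 1]) and `call` (0/1).
#' @export
predict.hla_cnn <- function(object, peptides, threshold = 0.5, ...) {
  X <- encode_matrix(peptides)
  n <- nrow(X)
  scores <- numeric(n)
  for (s in seq(1L, n, by = 4096L)) {
    idx <- s:min(s + 4095L, n)
    scores[idx] <- cnn_forward(object, X[idx, , drop = FALSE])$probs[, 2]
  }
  data.frame(peptide = peptides, score = scores,
             call = as.integer(scores >= threshold),
             stringsAsFactors = FALSE)
}

#' Per-position input attribution of the presentation score
#'
#' Gradient of the positive-class logit margin with respect to the one-hot
#' input, summarized as mean absolute gradient per peptide position. High
#' values flag positions the model relies on -- anchor residues in a
#' well-trained model.
#'
#' @param model trained `hla_cnn`.
#' @param peptides character vector.
#' @return numeric vector of length 11 (mean |gradient| per position).
#' @export
input_saliency <- function(model, peptides) {
  X <- encode_matrix(peptides)
  fwd <- cnn_forward(model, X, keep = TRUE)
  g <- cnn_backward(model, X, rep(1, nrow(X)), fwd, want_dx = TRUE)
  gx <- abs(g$dX)
  pos_mean <- vapply(seq_len(PEP_MAX), function(i)
    mean(gx[, (i - 1L) * ENC_COLS + seq_len(ENC_COLS)]), numeric(1))
  stats::setNames(pos_mean, paste0("P", seq_len(PEP_MAX)))
}

#' Percentile ranks of query peptides against a background population
#'
#' The rank of a query is `100 * (1 + b) / (1 + B)` where `b` is the number
#' of background peptides scoring strictly above it and `B` the background
#' size; lower is stronger, and ranks of at most `threshold` (default 2)
#' constitute a binder call, mirroring the conventional top-2% rule.
#'
#' @param model trained `hla_cnn`.
#' @param query_peptides,background_peptides character vectors; the
#'   background must be nonempty.
#' @return data.frame `peptide`, `score`, `percentile_rank`, `call`.
#' @export
percentile_ranks <- function(model, query_peptides, background_peptides,
                             threshold = 2.0) {
  if (!length(background_peptides))
    cond_stop("background must be nonempty", "hlapresent_size_error")
  bg <- predict(model, background_peptides)$score
  qs <- predict(model, query_peptides)$score
  ranks <- vapply(qs, function(s) 100 * (1 + sum(bg > s)) / (1 + length(bg)),
                  numeric(1))
  data.frame(peptide = query_peptides, score = qs, percentile_rank = ranks,
             call = as.integer(ranks <= threshold), stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with tie correction; the standard summary
#' for a score that should separate MS hits from decoys.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 truth.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Save / load a trained model as plain JSON
#'
#' The checkpoint embeds the configuration, the alphabet-to-column mapping
#' and the seed, so a reloaded model reproduces its scores exactly.
#'
#' @param model an `hla_cnn`.
#' @param path file path (JSON).
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config), allele = model$allele,
              alphabet = model$alphabet,
              params = list(conv_w = model$params$conv_w,
                            conv_b = model$params$conv_b,
                            w1 = model$params$w1, b1 = model$params$b1,
                            w2 = model$params$w2, b2 = model$params$b2),
              trained = model$trained, best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config[names(obj$config) %in%
                                          names(formals(model_config))])
  model <- build_model(cfg, allele = obj$allele)
  model$params$conv_w <- lapply(obj$params$conv_w, as.matrix)
  model$params$conv_b <- lapply(seq_along(obj$params$conv_b), function(i)
    as.numeric(obj$params$conv_b[[i]]))
  model$params$w1 <- as.matrix(obj$params$w1)
  model$params$b1 <- as.numeric(obj$params$b1)
  model$params$w2 <- as.matrix(obj$params$w2)
  model$params$b2 <- as.numeric(obj$params$b2)
  model$trained <- isTRUE(obj$trained)
  model$best_epoch <- obj$best_epoch
  model
}

#' @export
print.hla_cnn <- function(x, ...) {
  cat(sprintf("<hla_cnn%s: 3 branches (heights %s) x %d kernels, %d dense units, %s, %d parameters>\n",
              if (is.null(x$allele)) "" else paste0(" ", x$allele),
              paste(x$config$branch_kernel_heights, collapse = "/"),
              x$config$kernels_per_branch, x$config$dense_units,
              if (x$trained) "trained" else "untrained",
              n_parameters(x)))
  invisible(x)
}
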