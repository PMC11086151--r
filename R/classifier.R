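#' Training configuration
#'
#' Hyperparameters of the two-class image classifier. The training recipe
#' is plain minibatch stochastic gradient descent (no momentum, weight
#' decay or schedule) at learning rate 0.05 with batch size 32 and a
#' categorical cross-entropy loss; after every epoch the validation loss
#' is evaluated and the weights with the lowest validation loss seen are
#' the ones returned.
#'
#' Two backbones are available. `"mobilenet_v2_pretrained"` is the
#' transfer-learning backbone (inverted residual bottleneck network with a
#' two-node dense head, all weights fine-tuned); it requires pretrained
#' weights on disk and errors when they are unavailable.  `"tiny_cnn"` is
#' a small CPU-scale convolutional network trained from random
#' initialisation: the RGB input is reduced to an ink-density map (one
#' minus mean brightness), bilinearly pooled to 32 x 32, passed through
#' one 5 x 5 convolution with 8 filters and ReLU, 2 x 2 mean pooling, and
#' a dense two-node softmax head.
#'
#' @param backbone `"tiny_cnn"` or `"mobilenet_v2_pretrained"`.
#' @param learning_rate SGD learning rate.
#' @param batch_size Minibatch size.
#' @param input_px Expected input image side length.
#' @param max_epochs Number of training epochs scanned by the
#'   lowest-validation-loss checkpoint rule.
#' @param seed Seed for weight initialisation and batch shuffling.
#' @param fine_tune_all If `TRUE` all weights are trainable.
#' @param pool_px Side length of the tiny backbone's pooled ink-density
#'   map; 64 keeps individual channel lanes a few pixels tall so ictal
#'   band structure survives pooling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(backbone = c("tiny_cnn", "mobilenet_v2_pretrained"),
                         learning_rate = 0.05, batch_size = 32,
                         input_px = 224, max_epochs = 30, seed = 1L,
                         fine_tune_all = TRUE, pool_px = 64) {
  backbone <- match.arg(backbone)
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(backbone = backbone, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 input_px = as.integer(input_px),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 fine_tune_all = isTRUE(fine_tune_all),
                 pool_px = as.integer(pool_px), kernel_px = 5L,
                 n_filters = 8L),
            class = "train_config")
}

# Geometry of the tiny backbone, derived once from the config.
tiny_geometry <- function(cfg) {
  p <- cfg$pool_px                       # pooled input side
  k <- cfg$kernel_px
  o <- p - k + 1L                        # conv output side (valid)
  q <- o %/% 2L                          # after 2x2 mean pooling
  # im2col index matrix: one row per conv output position, one column per
  # kernel tap, containing linear (column-major) indices into the p x p map
  pos <- expand.grid(i = seq_len(o), j = seq_len(o))
  tap <- expand.grid(di = 0:(k - 1), dj = 0:(k - 1))
  idx <- matrix(0L, nrow(pos), nrow(tap))
  for (t in seq_len(nrow(tap)))
    idx[, t] <- (pos$j + tap$dj[t] - 1L) * p + pos$i + tap$di[t]
  # 2x2 mean-pool group per conv output position
  group <- (ceiling(pos$j / 2) - 1L) * q + ceiling(pos$i / 2)
  list(p = p, k = k, o = o, q = q, idx = idx, group = as.integer(group),
       n_features = q * q * cfg$n_filters)
}

#' Build a classifier model
#'
#' @param cfg A [train_config()].
#' @return An object of class `eeg_cnn`: the backbone geometry plus a
#'   seeded random weight initialisation. For
#'   `"mobilenet_v2_pretrained"` an error is raised when no pretrained
#'   weights are available offline, suggesting the `"tiny_cnn"` backbone.
#' @export
build_model <- function(cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  if (cfg$backbone == "mobilenet_v2_pretrained")
    stop("pretrained MobileNetV2 weights are not available offline; ",
         "use train_config(backbone = \"tiny_cnn\")")
  geom <- tiny_geometry(cfg)
  nf <- cfg$n_filters
  k2 <- cfg$kernel_px^2
  params <- with_seed(cfg$seed, list(
    W1 = matrix(stats::rnorm(k2 * nf, 0, sqrt(2 / k2)), k2, nf),
    b1 = rep(0, nf),
    W2 = matrix(stats::rnorm(geom$n_features * 2, 0,
                             sqrt(2 / geom$n_features)),
                geom$n_features, 2),
    b2 = rep(0, 2)))
  structure(list(cfg = cfg, geom = geom, params = params),
            class = "eeg_cnn")
}

#' @export
print.eeg_cnn <- function(x, ...) {
  cat(sprintf("<eeg_cnn> backbone %s: %d conv filters %dx%d, %d features, 2-node softmax head\n",
              x$cfg$backbone, x$cfg$n_filters, x$cfg$kernel_px,
              x$cfg$kernel_px, x$geom$n_features))
  invisible(x)
}

# Preprocess one normalised RGB tensor ([0,1], h x w x 3) into the tiny
# backbone's pooled ink-density map (p x p matrix).
tiny_preprocess <- function(tensor, geom) {
  ink <- 1 - (tensor[, , 1] + tensor[, , 2] + tensor[, , 3]) / 3
  if (nrow(ink) != geom$p || ncol(ink) != geom$p) {
    eb <- EBImage::resize(EBImage::Image(t(ink)), w = geom$p, h = geom$p)
    ink <- t(EBImage::imageData(eb))
  }
  ink
}

softmax2 <- function(l) {
  e <- exp(l - max(l))
  e / sum(e)
}

# Forward pass from an im2col matrix; returns activations needed by the
# backward pass.
tiny_forward <- function(params, xcol, geom) {
  z1 <- sweep(xcol %*% params$W1, 2, params$b1, "+")
  h <- pmax(z1, 0)
  pooled <- rowsum(h, geom$group) / 4
  f <- as.vector(pooled)
  logits <- drop(f %*% params$W2) + params$b2
  list(h = h, f = f, p = softmax2(logits))
}

tiny_backward <- function(params, xcol, fwd, y, geom) {
  dlogits <- fwd$p - y
  dW2 <- fwd$f %o% dlogits
  df <- drop(params$W2 %*% dlogits)
  dpool <- matrix(df, geom$q * geom$q, ncol(params$W1))
  dh <- dpool[geom$group, , drop = FALSE] / 4
  dh[fwd$h <= 0] <- 0
  list(W1 = crossprod(xcol, dh), b1 = colSums(dh),
       W2 = dW2, b2 = dlogits)
}

# One-hot with ES as class 1.
onehot <- function(label) if (label == "ES") c(1, 0) else c(0, 1)

dataset_xcols <- function(images, model) {
  lapply(images, function(tensor) {
    ink <- tiny_preprocess(tensor, model$geom)
    matrix(as.vector(ink)[model$geom$idx], nrow(model$geom$idx))
  })
}

mean_ce_loss <- function(model, xcols, labels) {
  eps <- 1e-12
  mean(vapply(seq_along(xcols), function(i) {
    p <- tiny_forward(model$params, xcols[[i]], model$geom)$p
    -log(max(p[if (labels[i] == "ES") 1 else 2], eps))
  }, numeric(1)))
}

#' Train the classifier
#'
#' Runs minibatch SGD for `cfg$max_epochs` epochs, evaluating the
#' categorical cross-entropy on the validation set after each epoch, and
#' returns the weights from the epoch with the lowest validation loss.
#'
#' @param model An [build_model()] handle.
#' @param train_images,val_images Lists of normalised `[0,1]` RGB tensors
#'   (from [resize_and_normalize()]).
#' @param train_labels,val_labels Character/factor vectors of `"ES"` /
#'   `"PNES"`, one per image. Training and validation sets must be
#'   disjoint at the event level (checked upstream by the pipeline).
#' @param cfg A [train_config()]; defaults to the model's own.
#' @return An object of class `eeg_cnn_fit`: `model` (weights of the best
#'   epoch), `history` (data.frame epoch / train_loss / val_loss),
#'   `best_epoch`.
#' @export
train_classifier <- function(model, train_images, train_labels,
                             val_images, val_labels, cfg = model$cfg) {
  stopifnot(inherits(model, "eeg_cnn"))
  if (length(train_images) == 0L || length(val_images) == 0L)
    stop("training and validation sets must be non-empty")
  train_labels <- as.character(train_labels)
  val_labels <- as.character(val_labels)
  if (length(unique(train_labels)) < 2L)
    stop("training set must contain both classes")

  xtr <- dataset_xcols(train_images, model)
  xva <- dataset_xcols(val_images, model)
  ytr <- lapply(train_labels, onehot)
  n <- length(xtr)
  lr <- cfg$learning_rate
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(cfg$seed + epoch, sample(n))
    epoch_loss <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1, n)]
      grad <- NULL
      for (i in batch) {
        fwd <- tiny_forward(model$params, xtr[[i]], model$geom)
        epoch_loss <- epoch_loss -
          log(max(fwd$p[if (train_labels[i] == "ES") 1 else 2], 1e-12))
        g <- tiny_backward(model$params, xtr[[i]], fwd, ytr[[i]], model$geom)
        grad <- if (is.null(grad)) g else
          Map(`+`, grad, g)
      }
      scale <- lr / length(batch)
      model$params <- Map(function(p, g) p - scale * g, model$params, grad)
    }
    val_loss <- mean_ce_loss(model, xva, val_labels)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / n, val_loss = val_loss))
    if (val_loss < best$loss)
      best <- list(loss = val_loss, params = model$params, epoch = epoch)
  }
  model$params <- best$params
  structure(list(model = model, history = history,
                 best_epoch = best$epoch, best_val_loss = best$loss),
            class = "eeg_cnn_fit")
}

#' @export
print.eeg_cnn_fit <- function(x, ...) {
  cat(sprintf("<eeg_cnn_fit> %d epochs; best epoch %d (val loss %.4f)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict class probabilities
#'
#' Deterministic, order-preserving softmax scores for a batch of
#' preprocessed images.
#'
#' @param model An `eeg_cnn` or `eeg_cnn_fit`.
#' @param images List of normalised `[0,1]` RGB tensors.
#' @return data.frame with columns `p_es`, `p_pnes` (rows sum to 1).
#' @export
predict_scores <- function(model, images) {
  if (inherits(model, "eeg_cnn_fit")) model <- model$model
  stopifnot(inherits(model, "eeg_cnn"))
  xcols <- dataset_xcols(images, model)
  p <- t(vapply(xcols,
                function(x) tiny_forward(model$params, x, model$geom)$p,
                numeric(2)))
  data.frame(p_es = p[, 1], p_pnes = p[, 2])
}

#' Hard classification from softmax scores
#'
#' Arg-max over the two-node softmax; the exact tie (0.5, 0.5) resolves to
#' PNES, the conservative default (no seizure called without evidence).
#'
#' @param scores data.frame with columns `p_es`, `p_pnes`.
#' @return Character vector of `"ES"` / `"PNES"`.
#' @export
classify_scores <- function(scores) {
  ifelse(scores$p_es > 0.5, "ES", "PNES")
}
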