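#' CNN architecture specification
#'
#' The fixed compact classifier: five 3x3 'same'-padded convolution stages
#' (ReLU, 20% dropout, 2x2 max pooling with stride 2 after each), a 50%
#' dropout after the last pooling, then fully connected layers of sizes 512
#' and 3 with a 50% dropout between them and a softmax output. At the default
#' 180-pixel input the spatial trace is 180-90-45-22-11-5 (odd sizes pool with
#' floor) and the flattened width is 5*5*128 = 3200.
#'
#' @param input_side input image side; must survive five halvings (>= 32).
#' @param conv_filters filter counts of the five convolution stages.
#' @param fc_sizes sizes of the two dense layers (last must be 3).
#' @param conv_dropout,post_pool_dropout,post_fc_dropout dropout rates.
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(input_side = 180L,
                     conv_filters = c(32L, 64L, 128L, 128L, 128L),
                     fc_sizes = c(512L, 3L),
                     conv_dropout = 0.20, post_pool_dropout = 0.50,
                     post_fc_dropout = 0.50) {
  if (length(conv_filters) != 5L) stop_pocusda("exactly five conv stages required")
  if (fc_sizes[length(fc_sizes)] != 3L) stop_pocusda("final layer width must be 3")
  trace <- spatial_trace(input_side)
  if (trace[length(trace)] < 1L) {
    stop_pocusda("input_side %d too small for five 2x2 poolings", input_side)
  }
  structure(list(input_side = as.integer(input_side),
                 conv_filters = as.integer(conv_filters),
                 fc_sizes = as.integer(fc_sizes),
                 conv_dropout = conv_dropout,
                 post_pool_dropout = post_pool_dropout,
                 post_fc_dropout = post_fc_dropout),
            class = "cnn_spec")
}

#' Spatial sizes through the five pooling stages
#' @param input_side input side in pixels.
#' @return Integer vector of length 6: input side and the five pooled sides.
#' @export
spatial_trace <- function(input_side) {
  out <- integer(6)
  out[1] <- as.integer(input_side)
  for (i in 2:6) out[i] <- out[i - 1] %/% 2L
  out
}

#' Analytic trainable-parameter count of a [cnn_spec()]
#' @param spec a `cnn_spec`.
#' @return Total number of trainable parameters.
#' @export
cnn_param_count <- function(spec) {
  cin <- c(1L, spec$conv_filters[-5])
  conv <- sum(9 * cin * spec$conv_filters + spec$conv_filters)
  side5 <- spatial_trace(spec$input_side)[6]
  flat <- side5^2 * spec$conv_filters[5]
  ins <- c(flat, spec$fc_sizes[-length(spec$fc_sizes)])
  conv + sum(ins * spec$fc_sizes + spec$fc_sizes)
}

#' Build the CNN
#'
#' @param spec a [cnn_spec()].
#' @param seed seed for weight initialisation.
#' @return A `pocus_cnn` model object (untrained). The network outputs logits;
#'   [predict_scores()] applies the softmax.
#' @export
build_cnn <- function(spec = cnn_spec(), seed = 1L) {
  net <- with_seed(seed, {
    layers <- list()
    cin <- 1L
    for (f in spec$conv_filters) {
      layers <- c(layers, list(
        layer_conv(3L, cin, f, stride = 1L, pad = 1L),
        layer_relu(),
        layer_dropout(spec$conv_dropout),
        layer_maxpool2()
      ))
      cin <- f
    }
    side5 <- spatial_trace(spec$input_side)[6]
    flat <- side5^2 * spec$conv_filters[5]
    layers <- c(layers, list(
      layer_dropout(spec$post_pool_dropout),
      layer_flatten(),
      layer_dense(flat, spec$fc_sizes[1]),
      layer_relu(),
      layer_dropout(spec$post_fc_dropout),
      layer_dense(spec$fc_sizes[1], spec$fc_sizes[2])
    ))
    layers
  })
  structure(list(net = net, spec = spec, classes = CLASS_LEVELS,
                 seed = seed, history = NULL),
            class = "pocus_cnn")
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)` with `K = 3` classes, so every class has equal total
#' impact on the loss: `sum_c w_c * n_c = N`.
#'
#' @param labels character vector of class labels.
#' @return Named numeric weights over the three classes.
#' @export
class_weights <- function(labels) {
  n_c <- table(factor(labels, levels = CLASS_LEVELS))
  if (any(n_c == 0)) {
    stop_pocusda("class '%s' absent from the training labels",
                 names(n_c)[which(n_c == 0)[1]])
  }
  w <- length(labels) / (length(CLASS_LEVELS) * as.numeric(n_c))
  setNames(w, names(n_c))
}

#' Class-weighted categorical cross-entropy
#'
#' Batch average of `-w_true * log(p_true)`; probabilities on the true class
#' are floored at 1e-7 before the log.
#'
#' @param probabilities matrix (n x 3), columns in class order
#'   normal/benign/malignant, rows summing to 1.
#' @param true_class character vector of length n.
#' @param weights named class weights (default all 1).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probabilities, true_class,
                                   weights = setNames(rep(1, 3), CLASS_LEVELS)) {
  idx <- match(true_class, CLASS_LEVELS)
  if (anyNA(idx)) stop_pocusda("unknown class label in true_class")
  p <- probabilities[cbind(seq_along(idx), idx)]
  if (any(p < -1e-9) || any(abs(rowSums(probabilities) - 1) > 1e-6)) {
    stop_pocusda("probabilities must be non-negative rows summing to 1")
  }
  mean(-weights[true_class] * log(pmax(p, 1e-7)))
}

#' Training configuration for the classifier
#'
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param seed seed controlling initialisation, shuffling, dropout and
#'   augmentation.
#' @param augment_policy optional [augment_policy()] applied per image per
#'   epoch; `NULL` disables augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, epochs = 50L, batch_size = 32L,
                         seed = 1L, augment_policy = NULL) {
  if (lr <= 0) stop_pocusda("learning rate must be positive")
  if (epochs < 1) stop_pocusda("epochs must be >= 1")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment_policy = augment_policy),
            class = "train_config")
}

#' Train the classifier
#'
#' Shuffled mini-batch training with Adam and the class-weighted categorical
#' cross-entropy; class weights are computed on the full assembled training
#' set. Pixel inputs are scaled to [0, 1]. Fresh augmented views are drawn per
#' image per epoch when a policy is set; stored images are never modified.
#'
#' @param cohort a `us_cohort` whose images match `spec$input_side`.
#' @param spec a [cnn_spec()].
#' @param config a [train_config()].
#' @return A trained `pocus_cnn` with a per-epoch `history` data frame.
#' @export
train_classifier <- function(cohort, spec = cnn_spec(),
                             config = train_config()) {
  labels <- cohort$meta$class
  w <- class_weights(labels)
  y_idx <- match(labels, CLASS_LEVELS)
  n <- length(labels)
  model <- build_cnn(spec, seed = config$seed)
  stream <- augment_stream(cohort$images, config$augment_policy,
                           seed = derive_seed(config$seed, "augment"))
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_)

  with_seed(derive_seed(config$seed, "train"), {
    opt <- adam_state(model$net, lr = config$lr)
    for (epoch in seq_len(config$epochs)) {
      views <- stream(epoch)
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        x <- stack_images(views[idx], scale = 1 / 255)
        z <- net_forward(model$net, x, training = TRUE)   # (3, B)
        p <- softmax_cols(z)
        bidx <- cbind(y_idx[idx], seq_along(idx))
        wb <- w[labels[idx]]
        loss <- mean(-wb * log(pmax(p[bidx], 1e-7)))
        if (!is.finite(loss)) {
          stop_pocusda("training diverged (non-finite loss at epoch %d)", epoch)
        }
        losses <- c(losses, loss)
        dz <- p
        dz[bidx] <- dz[bidx] - 1
        dz <- sweep(dz, 2, wb, "*") / length(idx)
        net_backward(model$net, dz)
        adam_step(opt)
      }
      history$loss[epoch] <- mean(losses)
    }
  })
  model$history <- history
  model$train_config <- config
  model$class_weights <- w
  model
}

#' Predict class probabilities for a cohort
#'
#' Inference is deterministic (dropout inactive). Returns one probability
#' triple per record together with the true label and patient id: a score set.
#'
#' @param model a trained `pocus_cnn`.
#' @param cohort a `us_cohort` with images matching the model input side.
#' @param batch_size inference batch size.
#' @return A `score_set` data frame with columns `patient_id`, `true_class`,
#'   `p_normal`, `p_benign`, `p_malignant`.
#' @export
predict_scores <- function(model, cohort, batch_size = 64L) {
  n <- n_images(cohort)
  probs <- matrix(NA_real_, n, 3)
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    x <- stack_images(cohort$images[idx], scale = 1 / 255)
    z <- net_forward(model$net, x, training = FALSE)
    probs[idx, ] <- t(softmax_cols(z))
  }
  out <- data.frame(
    patient_id = cohort$meta$patient_id,
    true_class = cohort$meta$class,
    p_normal = probs[, 1], p_benign = probs[, 2], p_malignant = probs[, 3],
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_set", "data.frame")
  out
}

#' Read/write score sets as CSV
#' @param scores a `score_set`.
#' @param path CSV path.
#' @return `read_score_set` returns a `score_set`.
#' @export
write_score_set <- function(scores, path) {
  write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_set
#' @export
read_score_set <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("score_set", "data.frame")
  out
}
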