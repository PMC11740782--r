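#' Configuration for cycle-consistent domain translation
#'
#' Architecture and optimisation settings for the two-generator,
#' two-discriminator translation model: ResNet-style generators (7x7 stem,
#' strided downsampling, residual blocks, nearest-neighbour upsampling, tanh
#' output), patch discriminators, least-squares adversarial loss, L1 cycle
#' consistency weighted by `lambda_cycle` and an identity term at
#' `lambda_identity * lambda_cycle`. The default is a desk-scale preset
#' (64-pixel single-channel images, narrow widths, few epochs); full-scale
#' training uses wider networks and 200 epochs.
#'
#' @param image_side input/output image side.
#' @param generator_width base filter count of the generators.
#' @param n_residual_blocks residual blocks at the bottleneck.
#' @param n_downsample strided downsampling stages (and matching upsampling).
#' @param discriminator_width base filter count of the discriminators.
#' @param lambda_cycle cycle-consistency weight.
#' @param lambda_identity identity-loss multiplier on `lambda_cycle`.
#' @param lr Adam learning rate.
#' @param epochs training epochs (>= 1); 200 at full scale.
#' @param batch_size images per step.
#' @param replay_buffer use a 50-image history of generated images for
#'   discriminator updates.
#' @param lr_decay linearly decay the learning rate to zero over the second
#'   half of training.
#' @param seed integer seed.
#' @return A `cyclegan_config` list.
#' @export
cyclegan_config <- function(image_side = 64L, generator_width = 8L,
                            n_residual_blocks = 1L, n_downsample = 2L,
                            discriminator_width = 8L,
                            lambda_cycle = 10, lambda_identity = 0.5,
                            lr = 2e-4, epochs = 3L, batch_size = 1L,
                            replay_buffer = TRUE, lr_decay = TRUE,
                            seed = 0L) {
  if (lambda_cycle <= 0) stop_pocusda("lambda_cycle must be positive")
  if (epochs < 1) stop_pocusda("epochs must be >= 1")
  structure(list(image_side = as.integer(image_side),
                 generator_width = as.integer(generator_width),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 n_downsample = as.integer(n_downsample),
                 discriminator_width = as.integer(discriminator_width),
                 lambda_cycle = lambda_cycle,
                 lambda_identity = lambda_identity, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 replay_buffer = isTRUE(replay_buffer),
                 lr_decay = isTRUE(lr_decay), seed = as.integer(seed)),
            class = "cyclegan_config")
}

#' Least-squares adversarial loss
#'
#' Mean squared deviation of the discriminator outputs from the target label
#' (1 for real, 0 for fake).
#'
#' @param discriminator_outputs numeric array of patch logits.
#' @param is_real logical target.
#' @return Scalar loss.
#' @export
adversarial_loss <- function(discriminator_outputs, is_real) {
  if (!all(is.finite(discriminator_outputs))) {
    stop_pocusda("non-finite discriminator outputs")
  }
  target <- if (isTRUE(is_real)) 1 else 0
  mean((discriminator_outputs - target)^2)
}

#' L1 cycle-consistency loss
#'
#' @param original,reconstructed arrays of identical shape.
#' @param lambda_cycle weight.
#' @return `lambda_cycle * mean(|original - reconstructed|)`.
#' @export
cycle_loss <- function(original, reconstructed, lambda_cycle = 10) {
  if (!identical(dim(original) %||% length(original),
                 dim(reconstructed) %||% length(reconstructed))) {
    stop_pocusda("cycle_loss: shape mismatch between original and reconstruction")
  }
  lambda_cycle * mean(abs(original - reconstructed))
}

build_generator <- function(cfg) {
  f <- cfg$generator_width
  layers <- list(layer_conv(7L, 1L, f, pad = 3L), layer_instnorm(f),
                 layer_relu())
  w <- f
  for (i in seq_len(cfg$n_downsample)) {
    layers <- c(layers, list(layer_conv(3L, w, 2L * w, stride = 2L, pad = 1L),
                             layer_instnorm(2L * w), layer_relu()))
    w <- 2L * w
  }
  for (i in seq_len(cfg$n_residual_blocks)) {
    layers <- c(layers, list(layer_resblock(3L, w)))
  }
  for (i in seq_len(cfg$n_downsample)) {
    layers <- c(layers, list(layer_upsample2(),
                             layer_conv(3L, w, w %/% 2L, pad = 1L),
                             layer_instnorm(w %/% 2L), layer_relu()))
    w <- w %/% 2L
  }
  c(layers, list(layer_conv(7L, w, 1L, pad = 3L), layer_tanh()))
}

build_discriminator <- function(cfg) {
  f <- cfg$discriminator_width
  list(
    layer_conv(4L, 1L, f, stride = 2L, pad = 1L), layer_lrelu(0.2),
    layer_conv(4L, f, 2L * f, stride = 2L, pad = 1L),
    layer_instnorm(2L * f), layer_lrelu(0.2),
    layer_conv(4L, 2L * f, 1L, stride = 1L, pad = 1L)
  )
}

net_zero_grads <- function(net) {
  for (l in net_param_layers(net)) {
    l$grads <- lapply(l$params, function(p) p * 0)
  }
  invisible(net)
}

# backward pass that ACCUMULATES into existing grads (the engine's
# layer_backward overwrites; generators receive gradients from several loss
# paths per step, so snapshots are summed here).
net_backward_acc <- function(net, dy) {
  layers <- net_param_layers(net)
  old <- lapply(layers, function(l) l$grads)
  dx <- net_backward(net, dy)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(l$grads)) {
      prev <- old[[i]][[nm]]
      if (!is.null(prev)) l$grads[[nm]] <- l$grads[[nm]] + prev
    }
  }
  dx
}

to_gan_scale <- function(images) {
  x <- stack_images(images, scale = 1 / 127.5)
  x - 1
}

from_gan_scale <- function(x) {
  n <- dim(x)[4]
  lapply(seq_len(n), function(i) quantize8((x[, , 1, i] + 1) / 2))
}

replay_sample <- function(buffer, x, max_size = 50L) {
  # Returns the image shown to the discriminator and the updated buffer.
  if (length(buffer) < max_size) {
    buffer[[length(buffer) + 1L]] <- x
    return(list(x = x, buffer = buffer))
  }
  if (runif(1) < 0.5) {
    j <- sample.int(length(buffer), 1)
    old <- buffer[[j]]
    buffer[[j]] <- x
    list(x = old, buffer = buffer)
  } else {
    list(x = x, buffer = buffer)
  }
}

#' Train a cycle-consistent translation model between two image domains
#'
#' Alternates generator and discriminator Adam updates on the least-squares
#' adversarial, L1 cycle and identity losses. Images enter on the 0–255 scale
#' and are internally mapped to [-1, 1]; generators are tanh-bounded so
#' outputs are always in the valid range. Deterministic given
#' `config$seed`.
#'
#' @param source_images list of matrices (source domain, e.g. standard).
#' @param target_images list of matrices (target domain, e.g. POCUS).
#' @param config a [cyclegan_config()].
#' @return A `translator_pair`: generators `g_st` (source to target) and
#'   `g_ts`, discriminators, the config and a per-epoch loss `history`.
#' @export
train_cyclegan <- function(source_images, target_images,
                           config = cyclegan_config()) {
  if (length(source_images) == 0 || length(target_images) == 0) {
    stop_pocusda("both domains must be non-empty")
  }
  side <- config$image_side
  ok <- function(imgs) all(vapply(imgs, function(m) {
    nrow(m) == side && ncol(m) == side
  }, TRUE))
  if (!ok(source_images) || !ok(target_images)) {
    stop_pocusda("images must be preprocessed to %dx%d", side, side)
  }

  with_seed(config$seed, {
    g_st <- build_generator(config)
    g_ts <- build_generator(config)
    d_s <- build_discriminator(config)
    d_t <- build_discriminator(config)
    opt_g <- list(adam_state(g_st, lr = config$lr),
                  adam_state(g_ts, lr = config$lr))
    opt_d <- list(adam_state(d_s, lr = config$lr),
                  adam_state(d_t, lr = config$lr))
    buf_s <- list(); buf_t <- list()
    lam <- config$lambda_cycle
    lam_id <- config$lambda_identity * lam
    hist <- data.frame(epoch = seq_len(config$epochs), g_loss = NA_real_,
                       d_loss = NA_real_, cycle = NA_real_)

    # one epoch sweeps the larger domain once; the smaller one is recycled
    n_iter <- max(length(source_images), length(target_images))
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr
      if (config$lr_decay && epoch > config$epochs / 2) {
        lr <- config$lr *
          (config$epochs - epoch + 1) / (config$epochs - config$epochs / 2 + 1)
      }
      ia <- rep(sample(seq_along(source_images)), length.out = n_iter)
      ib <- rep(sample(seq_along(target_images)), length.out = n_iter)
      gl <- dl <- cl <- 0
      steps <- seq(1, n_iter, by = config$batch_size)
      for (s0 in steps) {
        idx <- s0:min(s0 + config$batch_size - 1, n_iter)
        x <- to_gan_scale(source_images[ia[idx]])
        y <- to_gan_scale(target_images[ib[idx]])
        nb <- length(idx)

        # ---- generator update -------------------------------------------
        net_zero_grads(g_st); net_zero_grads(g_ts)
        g_total <- 0; cyc_total <- 0

        one_direction <- function(g, f, d, src) {
          # adversarial + forward-cycle contribution of one direction
          fake <- net_forward(g, src, training = TRUE)
          dout <- net_forward(d, fake, training = TRUE)
          adv <- mean((dout - 1)^2)
          dfake_adv <- net_backward(d, 2 * (dout - 1) / length(dout))
          rec <- net_forward(f, fake, training = TRUE)
          cyc <- lam * mean(abs(rec - src))
          drec <- lam * sign(rec - src) / length(rec)
          dfake_cyc <- net_backward_acc(f, drec)
          net_backward_acc(g, dfake_adv + dfake_cyc)
          list(adv = adv, cyc = cyc, fake = fake)
        }
        st <- one_direction(g_st, g_ts, d_t, x)
        ts <- one_direction(g_ts, g_st, d_s, y)
        g_total <- st$adv + ts$adv + st$cyc + ts$cyc
        cyc_total <- st$cyc + ts$cyc
        if (lam_id > 0) {
          idy <- net_forward(g_st, y, training = TRUE)
          g_total <- g_total + lam_id * mean(abs(idy - y))
          net_backward_acc(g_st, lam_id * sign(idy - y) / length(idy))
          idx2 <- net_forward(g_ts, x, training = TRUE)
          g_total <- g_total + lam_id * mean(abs(idx2 - x))
          net_backward_acc(g_ts, lam_id * sign(idx2 - x) / length(idx2))
        }
        adam_step(opt_g[[1]], lr = lr)
        adam_step(opt_g[[2]], lr = lr)

        # ---- discriminator updates --------------------------------------
        upd_d <- function(d, opt, real, fake_new, buf) {
          net_zero_grads(d)
          rb <- replay_sample(buf, fake_new)
          dr <- net_forward(d, real, training = TRUE)
          lr_loss <- 0.5 * mean((dr - 1)^2)
          net_backward_acc(d, (dr - 1) / length(dr))
          df <- net_forward(d, rb$x, training = TRUE)
          lf_loss <- 0.5 * mean(df^2)
          net_backward_acc(d, df / length(df))
          adam_step(opt, lr = lr)
          list(loss = lr_loss + lf_loss, buffer = rb$buffer)
        }
        fake_t <- if (config$replay_buffer) st$fake else st$fake
        r1 <- upd_d(d_t, opt_d[[2]], y, fake_t, if (config$replay_buffer) buf_t else list())
        buf_t <- if (config$replay_buffer) r1$buffer else buf_t
        r2 <- upd_d(d_s, opt_d[[1]], x, ts$fake, if (config$replay_buffer) buf_s else list())
        buf_s <- if (config$replay_buffer) r2$buffer else buf_s

        if (!is.finite(g_total) || !is.finite(r1$loss + r2$loss)) {
          stop_pocusda("translation training diverged at epoch %d", epoch)
        }
        gl <- gl + g_total; dl <- dl + r1$loss + r2$loss; cl <- cl + cyc_total
      }
      hist$g_loss[epoch] <- gl / length(steps)
      hist$d_loss[epoch] <- dl / length(steps)
      hist$cycle[epoch] <- cl / length(steps)
    }
    structure(list(g_st = g_st, g_ts = g_ts, d_s = d_s, d_t = d_t,
                   config = config, history = hist),
              class = "translator_pair")
  })
}

#' Translate images with a trained generator
#'
#' @param pair a `translator_pair`.
#' @param images list of matrices on the 0–255 scale.
#' @param direction `"st"` (source to target, the default) or `"ts"`.
#' @param batch_size images per forward pass.
#' @return List of translated matrices on the 0–255 scale.
#' @export
translate_images <- function(pair, images, direction = "st",
                             batch_size = 16L) {
  g <- if (direction == "st") pair$g_st else pair$g_ts
  out <- vector("list", length(images))
  for (b0 in seq(1, length(images), by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, length(images))
    y <- net_forward(g, to_gan_scale(images[idx]), training = FALSE)
    out[idx] <- from_gan_scale(y)
  }
  out
}

#' Train translators under a regime
#'
#' `"cyclegan1"` trains one model on all classes and maps it to every class;
#' `"cyclegan3"` trains one independent model per class.
#'
#' @param source_cohort,target_cohort `us_cohort`s (e.g. standard and POCUS
#'   training sets).
#' @param config a [cyclegan_config()].
#' @param regime `"cyclegan1"` or `"cyclegan3"`.
#' @return Named list mapping each class to a `translator_pair`.
#' @export
train_regime <- function(source_cohort, target_cohort,
                         config = cyclegan_config(),
                         regime = c("cyclegan1", "cyclegan3")) {
  regime <- match.arg(regime)
  if (regime == "cyclegan1") {
    pair <- train_cyclegan(source_cohort$images, target_cohort$images, config)
    return(setNames(rep(list(pair), 3), CLASS_LEVELS))
  }
  pairs <- list()
  for (cl in CLASS_LEVELS) {
    src <- source_cohort$images[source_cohort$meta$class == cl]
    tgt <- target_cohort$images[target_cohort$meta$class == cl]
    if (length(src) == 0 || length(tgt) == 0) {
      stop_pocusda("class '%s' missing from a domain; cyclegan3 needs all classes in both domains", cl)
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, regime, cl)
    pairs[[cl]] <- train_cyclegan(src, tgt, cfg)
  }
  pairs
}

#' Translate a source-domain cohort into the target domain
#'
#' Every record keeps its class label and patient id (the labelling
#' assumption for generated images); domain becomes `"translated"` and
#' provenance names the regime. A per-image mean-darkening statistic
#' (mean original minus mean translated, 0–255 scale) is attached as the
#' `darkening` column, a cheap monitor for collapsed dark outputs.
#'
#' @param cohort a `us_cohort` of source-domain images.
#' @param translators named class-to-`translator_pair` map from
#'   [train_regime()].
#' @param provenance tag recorded on translated records (e.g. `"cyclegan1"`).
#' @return A `us_cohort` of translated records.
#' @export
translate_cohort <- function(cohort, translators, provenance = "cyclegan") {
  missing <- setdiff(unique(cohort$meta$class), names(translators))
  if (length(missing)) {
    stop_pocusda("no translator for class '%s'", missing[1])
  }
  out <- cohort
  if (n_images(cohort) > 0) {
    for (cl in unique(cohort$meta$class)) {
      idx <- which(cohort$meta$class == cl)
      out$images[idx] <- translate_images(translators[[cl]],
                                          cohort$images[idx])
    }
  }
  out$meta$domain <- rep("translated", n_images(cohort))
  out$meta$provenance <- rep(provenance, n_images(cohort))
  out$meta$darkening <- vapply(seq_len(n_images(cohort)), function(i) {
    mean(cohort$images[[i]]) - mean(out$images[[i]])
  }, 0)
  out
}
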