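#' Augmentation policy
#'
#' Random per-image, per-epoch augmentation. The spatial group applies a
#' single composed affine (zoom, shear, rotation, shift, optional horizontal
#' flip) with bilinear interpolation and zero fill; the brightness/noise group
#' scales the [0,1]-normalized image by a uniform brightness factor and adds
#' i.i.d. Gaussian noise. A factor above 1 brightens (plain convention; the
#' sampled factor distribution is symmetric about 1, so an inverted convention
#' is statistically equivalent).
#'
#' @param zoom_range zoom half-range as a fraction (factor drawn from
#'   `U(1 - z, 1 + z)`).
#' @param shear_range shear-factor half-range.
#' @param shift_range shift half-range as a fraction of the image side.
#' @param horizontal_flip flip with probability 0.5 when `TRUE`.
#' @param rotation_range rotation half-range in degrees.
#' @param brightness_range `c(low, high)` brightness factors.
#' @param noise_variance Gaussian noise variance on the [0, 1] scale.
#' @param enabled_groups subset of `c("spatial", "brightness_noise")`.
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(zoom_range = 0.10, shear_range = 0.10,
                           shift_range = 0.10, horizontal_flip = TRUE,
                           rotation_range = 30,
                           brightness_range = c(0.7, 1.3),
                           noise_variance = 0.01,
                           enabled_groups = "spatial") {
  if (any(c(zoom_range, shear_range, shift_range, rotation_range,
            noise_variance) < 0)) {
    stop_pocusda("augmentation ranges must be non-negative")
  }
  if (brightness_range[1] > brightness_range[2]) {
    stop_pocusda("brightness_range must be ordered (low, high)")
  }
  bad <- setdiff(enabled_groups, c("spatial", "brightness_noise"))
  if (length(bad)) stop_pocusda("unknown augmentation group '%s'", bad[1])
  structure(
    list(zoom_range = zoom_range, shear_range = shear_range,
         shift_range = shift_range, horizontal_flip = horizontal_flip,
         rotation_range = rotation_range, brightness_range = brightness_range,
         noise_variance = noise_variance, enabled_groups = enabled_groups),
    class = "augment_policy"
  )
}

#' Apply a fully specified spatial transform
#'
#' Deterministic core of [spatial_augment()]: a single affine composed as
#' zoom then shear then rotation, applied about the image centre, followed by
#' the shift; bilinear interpolation, zero fill.
#'
#' @param pixels matrix on the 0–255 scale.
#' @param zoom scale factor.
#' @param shear shear factor (row displaced proportionally to column).
#' @param rotation rotation in degrees.
#' @param shift_r,shift_c shifts in pixels (rows, columns).
#' @param flip reverse columns (horizontal flip) before the affine.
#' @return Transformed matrix, same shape, clipped to [0, 255].
#' @export
apply_spatial_transform <- function(pixels, zoom = 1, shear = 0, rotation = 0,
                                    shift_r = 0, shift_c = 0, flip = FALSE) {
  if (flip) pixels <- pixels[, ncol(pixels):1, drop = FALSE]
  if (zoom == 1 && shear == 0 && rotation == 0 && shift_r == 0 && shift_c == 0) {
    return(pixels)
  }
  th <- rotation * pi / 180
  a_rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  a_shear <- rbind(c(1, shear), c(0, 1))
  a <- (zoom * diag(2)) %*% a_shear %*% a_rot
  ctr <- c((nrow(pixels) + 1) / 2, (ncol(pixels) + 1) / 2)
  offset <- ctr + c(shift_r, shift_c) - a %*% ctr
  m <- rbind(t(a), as.numeric(offset))
  out <- EBImage::imageData(
    EBImage::affine(EBImage::as.Image(pixels), m, filter = "bilinear",
                    bg.col = 0)
  )
  matrix(pmin(pmax(out, 0), 255), nrow(pixels), ncol(pixels))
}

#' Random spatial augmentation
#'
#' Draws zoom, shear, shifts, flip and rotation independently from the policy
#' ranges and applies them as one composed affine.
#'
#' @param pixels matrix on the 0–255 scale.
#' @param policy an [augment_policy()].
#' @param seed optional seed (`NULL`: current RNG stream).
#' @return Augmented matrix, same shape and range.
#' @export
spatial_augment <- function(pixels, policy = augment_policy(), seed = NULL) {
  with_seed(seed, {
    side <- nrow(pixels)
    apply_spatial_transform(
      pixels,
      zoom = runif(1, 1 - policy$zoom_range, 1 + policy$zoom_range),
      shear = runif(1, -policy$shear_range, policy$shear_range),
      rotation = runif(1, -policy$rotation_range, policy$rotation_range),
      shift_r = runif(1, -policy$shift_range, policy$shift_range) * side,
      shift_c = runif(1, -policy$shift_range, policy$shift_range) * side,
      flip = policy$horizontal_flip && runif(1) < 0.5
    )
  })
}

#' Random brightness and noise augmentation
#'
#' Scales the [0,1]-normalized image by a factor drawn from
#' `U(brightness_range)`, adds zero-mean Gaussian noise with the policy
#' variance, clips to [0, 1] and rescales to 0–255.
#'
#' @inheritParams spatial_augment
#' @return Augmented matrix, same shape and range.
#' @export
brightness_noise_augment <- function(pixels, policy = augment_policy(),
                                     seed = NULL) {
  with_seed(seed, {
    x <- pixels / 255
    f <- runif(1, policy$brightness_range[1], policy$brightness_range[2])
    x <- x * f
    if (policy$noise_variance > 0) {
      x <- x + rnorm(length(x), sd = sqrt(policy$noise_variance))
    }
    matrix(pmin(pmax(x, 0), 1) * 255, nrow(pixels), ncol(pixels))
  })
}

# Augment one image with every enabled group (spatial first).
augment_image <- function(pixels, policy, seed = NULL) {
  with_seed(seed, {
    if ("spatial" %in% policy$enabled_groups) {
      pixels <- spatial_augment(pixels, policy)
    }
    if ("brightness_noise" %in% policy$enabled_groups) {
      pixels <- brightness_noise_augment(pixels, policy)
    }
    pixels
  })
}

#' Per-epoch augmentation stream
#'
#' Returns a function of the epoch index yielding a freshly augmented view of
#' every stored image. Parameters are drawn independently per image and per
#' epoch; the stored images are never modified. The stream is a pure function
#' of `(images, policy, seed, epoch)`.
#'
#' @param images list of pixel matrices.
#' @param policy an [augment_policy()], or `NULL` to disable augmentation.
#' @param seed integer stream seed.
#' @return `function(epoch)` returning a list of matrices.
#' @export
augment_stream <- function(images, policy, seed = 1L) {
  force(images); force(policy); force(seed)
  function(epoch) {
    if (is.null(policy) || length(policy$enabled_groups) == 0) return(images)
    lapply(seq_along(images), function(i) {
      augment_image(images[[i]], policy, seed = derive_seed(seed, epoch, i))
    })
  }
}
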