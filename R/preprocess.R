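#' Margin crop specification
#'
#' Pixels to strip from each edge, used to remove device metadata margins.
#'
#' @param top,bottom,left,right non-negative pixel counts.
#' @return A `crop_spec` list.
#' @export
crop_spec <- function(top = 0L, bottom = 0L, left = 0L, right = 0L) {
  s <- list(top = as.integer(top), bottom = as.integer(bottom),
            left = as.integer(left), right = as.integer(right))
  if (any(unlist(s) < 0)) stop_pocusda("crop margins must be >= 0")
  structure(s, class = "crop_spec")
}

#' Crop metadata margins from an image
#'
#' @param pixels numeric matrix.
#' @param spec a [crop_spec()].
#' @return The cropped matrix; values inside the kept region are unchanged.
#' @export
crop_margins <- function(pixels, spec = crop_spec()) {
  h <- nrow(pixels); w <- ncol(pixels)
  rows <- seq.int(spec$top + 1L, h - spec$bottom)
  cols <- seq.int(spec$left + 1L, w - spec$right)
  if (spec$top + spec$bottom >= h || spec$left + spec$right >= w) {
    stop_pocusda("over-crop: margins leave an empty image (%dx%d input)", h, w)
  }
  pixels[rows, cols, drop = FALSE]
}

#' Zero-pad an image to a square
#'
#' Pads with zeros to `N = max(height, width)`, centring the original content
#' at offset `floor((N - h) / 2)` top / left. The pixel-value sum is conserved.
#'
#' @param pixels numeric matrix.
#' @return An `N x N` matrix.
#' @export
zero_pad_square <- function(pixels) {
  h <- nrow(pixels); w <- ncol(pixels)
  if (h == w) return(pixels)
  n <- max(h, w)
  out <- matrix(0, n, n)
  r0 <- floor((n - h) / 2)
  c0 <- floor((n - w) / 2)
  out[r0 + seq_len(h), c0 + seq_len(w)] <- pixels
  out
}

#' Resize a square image to the network input side
#'
#' Downscaling by an integer factor uses exact block (area) averaging;
#' all other cases use anti-aliased bilinear interpolation (a Gaussian blur
#' proportional to the downscale factor precedes bilinear sampling).
#'
#' @param pixels square numeric matrix on the 0–255 scale.
#' @param side target side in pixels.
#' @return A `side x side` matrix, values clipped to [0, 255].
#' @export
resize_to_input <- function(pixels, side = 180L) {
  h <- nrow(pixels); w <- ncol(pixels)
  if (h != w) {
    stop_pocusda("resize_to_input expects a square image; run zero_pad_square first")
  }
  if (h == side) return(pixels)
  out <- if (h > side && h %% side == 0) {
    f <- h %/% side
    # exact area averaging over f x f blocks
    m <- matrix(pixels, nrow = f)
    m <- colMeans(m)                          # (side * w) values: rows pooled
    m <- matrix(m, nrow = side)               # side x w
    m2 <- matrix(t(m), nrow = f)              # pool columns
    t(matrix(colMeans(m2), nrow = side))
  } else {
    img <- pixels
    if (h > side) {
      img <- EBImage::imageData(
        EBImage::gblur(EBImage::as.Image(img), sigma = 0.5 * h / side)
      )
    }
    EBImage::imageData(
      EBImage::resize(EBImage::as.Image(img), w = side, h = side,
                      filter = "bilinear")
    )
  }
  matrix(pmin(pmax(out, 0), 255), side, side)
}

#' Preprocess a cohort: crop, zero-pad, resize
#'
#' Applies [crop_margins()], [zero_pad_square()] and [resize_to_input()] to
#' every image. Margins may differ per domain (device-specific).
#'
#' @param cohort a `us_cohort`.
#' @param side target side.
#' @param crop_specs named list mapping domain to [crop_spec()]; missing
#'   domains get zero margins.
#' @return A `us_cohort` with square `side x side` images.
#' @export
preprocess_cohort <- function(cohort, side = 180L, crop_specs = list()) {
  zero <- crop_spec()
  cohort$images <- lapply(seq_len(n_images(cohort)), function(i) {
    spec <- crop_specs[[cohort$meta$domain[i]]]
    if (is.null(spec)) spec <- zero
    resize_to_input(zero_pad_square(crop_margins(cohort$images[[i]], spec)),
                    side)
  })
  cohort
}
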