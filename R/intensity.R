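#' Pooled per-class intensity histogram
#'
#' Sums the 256-bin (0–255) histograms of every image of one class, producing
#' the target distribution used for per-class histogram specification. Targets
#' are built from training images of the darker (POCUS) domain only.
#'
#' @param cohort a `us_cohort` (or plain list of `image_record`s).
#' @param class_label the class to pool.
#' @return A `class_histogram`: list with `class_label`, `bin_counts`
#'   (256 non-negative integers) and `n_pixels`.
#' @export
pooled_class_histogram <- function(cohort, class_label) {
  check_class_label(class_label)
  if (inherits(cohort, "us_cohort")) {
    idx <- which(cohort$meta$class == class_label)
    images <- cohort$images[idx]
  } else {
    images <- lapply(Filter(function(r) r$class_label == class_label, cohort),
                     `[[`, "pixels")
  }
  if (length(images) == 0) {
    stop_pocusda("no images of class '%s' to pool", class_label)
  }
  counts <- integer(256)
  for (img in images) {
    counts <- counts + tabulate(as.integer(img) + 1L, nbins = 256L)
  }
  structure(list(class_label = class_label, bin_counts = counts,
                 n_pixels = sum(counts)),
            class = "class_histogram")
}

#' Build one pooled histogram per class
#' @param cohort a `us_cohort` containing all three classes.
#' @return Named list of `class_histogram` objects.
#' @export
class_histograms <- function(cohort) {
  setNames(lapply(CLASS_LEVELS, function(cl) pooled_class_histogram(cohort, cl)),
           CLASS_LEVELS)
}

#' Write / read a class histogram as CSV (`intensity,count`)
#' @param hist a `class_histogram`.
#' @param path CSV path.
#' @return `write_class_histogram` invisibly returns `path`;
#'   `read_class_histogram` returns a `class_histogram`.
#' @export
write_class_histogram <- function(hist, path) {
  write.csv(data.frame(intensity = 0:255, count = hist$bin_counts,
                       class = hist$class_label),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_class_histogram
#' @export
read_class_histogram <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  structure(list(class_label = d$class[1], bin_counts = d$count,
                 n_pixels = sum(d$count)),
            class = "class_histogram")
}

# Right-continuous quantile function of a 256-bin histogram: smallest
# intensity whose CDF is >= p.
hist_quantile_lut <- function(bin_counts) {
  cdf <- cumsum(bin_counts) / sum(bin_counts)
  function(p) {
    idx <- findInterval(p, cdf, left.open = TRUE) + 1L
    pmin(idx, 256L) - 1L
  }
}

#' Histogram specification (matching) of an image to a target histogram
#'
#' Maps each pixel through `Q_target(F_image(v))`: the image's empirical CDF
#' followed by the target's right-continuous quantile function (smallest
#' intensity whose target CDF reaches the probability). The mapping is
#' monotone non-decreasing; a degenerate single-intensity image maps entirely
#' to the target median.
#'
#' @param pixels matrix on the 0–255 scale.
#' @param target a `class_histogram`.
#' @return Matrix of the same shape on the 0–255 scale.
#' @export
match_image_to_histogram <- function(pixels, target) {
  if (!inherits(target, "class_histogram") || target$n_pixels <= 0) {
    stop_pocusda("invalid target histogram")
  }
  v <- as.integer(pixels)
  src_counts <- tabulate(v + 1L, nbins = 256L)
  q_target <- hist_quantile_lut(target$bin_counts)
  if (sum(src_counts > 0) == 1L) {
    out <- rep(q_target(0.5), length(v))
    return(matrix(out, nrow(pixels), ncol(pixels)))
  }
  src_cdf <- cumsum(src_counts) / sum(src_counts)
  lut <- q_target(src_cdf)        # one output level per source intensity
  matrix(lut[v + 1L], nrow(pixels), ncol(pixels))
}

#' Histogram equalization
#'
#' Spreads intensities via the image's own empirical CDF:
#' `out = round(255 * F(v))`. Monotone; a constant image maps to 255
#' (its CDF is 1 everywhere).
#'
#' @param pixels matrix on the 0–255 scale.
#' @return Matrix of the same shape on the 0–255 scale.
#' @export
equalize <- function(pixels) {
  v <- as.integer(pixels)
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts) / sum(counts)
  lut <- round(255 * cdf)
  matrix(lut[v + 1L], nrow(pixels), ncol(pixels))
}

#' Apply per-class histogram matching to a cohort
#'
#' Each image is matched to the pooled target histogram of its own class
#' (one target per class). Provenance is tagged `"hist_match"`.
#'
#' @param cohort a `us_cohort`.
#' @param targets named list from [class_histograms()].
#' @return A `us_cohort`.
#' @export
match_cohort <- function(cohort, targets) {
  missing <- setdiff(unique(cohort$meta$class), names(targets))
  if (length(missing)) {
    stop_pocusda("no target histogram for class '%s'", missing[1])
  }
  cohort$images <- lapply(seq_len(n_images(cohort)), function(i) {
    match_image_to_histogram(cohort$images[[i]],
                             targets[[cohort$meta$class[i]]])
  })
  cohort$meta$provenance <- "hist_match"
  cohort
}

#' Apply histogram equalization to every image of a cohort
#' @param cohort a `us_cohort`.
#' @return A `us_cohort` with provenance `"hist_eq"`.
#' @export
equalize_cohort <- function(cohort) {
  cohort$images <- lapply(cohort$images, equalize)
  cohort$meta$provenance <- "hist_eq"
  cohort
}
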