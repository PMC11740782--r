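#' Reduce a three-class score set to the malignant-vs-rest problem
#'
#' The score is the malignant probability; the label is 1 for malignant truth
#' and 0 for normal or benign (cancerous vs non-cancerous).
#'
#' @param score_set a `score_set` data frame.
#' @return List with numeric `scores` and integer `labels`, order preserved.
#' @export
binarize_malignant <- function(score_set) {
  list(scores = score_set$p_malignant,
       labels = as.integer(score_set$true_class == "malignant"))
}

#' Area under the ROC curve (Mann–Whitney form)
#'
#' Equals the probability that a random positive outscores a random negative,
#' with ties counted half; computed from midranks.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels 0/1 labels; both values must be present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) {
    stop_pocusda("auc needs both positive and negative labels")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

#' ROC curve over all distinct thresholds
#'
#' Positive calls are `score >= threshold`. The curve includes -Inf and +Inf
#' endpoints, so the operating points (sensitivity 1, specificity 0) and
#' (0, 1) are always present; sensitivity is non-increasing in the threshold.
#'
#' @inheritParams auc
#' @return A `roc_curve` data frame with columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop_pocusda("roc_curve needs both positive and negative labels")
  }
  thr <- c(-Inf, sort(unique(scores)), Inf)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  out <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), 0),
    specificity = vapply(thr, function(t) mean(neg < t), 0)
  )
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Sensitivity-constrained Youden operating point
#'
#' Maximises the Youden statistic `J = sensitivity + specificity - 1` among
#' thresholds whose sensitivity reaches `min_sensitivity`; ties break toward
#' higher specificity, then higher threshold. With at least one positive the
#' floor is always feasible (the -Inf endpoint has sensitivity 1); with no
#' feasible threshold the unconstrained maximiser is returned.
#'
#' @param roc a [roc_curve()].
#' @param min_sensitivity sensitivity floor (default 0.90).
#' @return An `operating_point` list: `threshold`, `sensitivity`,
#'   `specificity`, `j`.
#' @export
constrained_youden <- function(roc, min_sensitivity = 0.90) {
  if (!nrow(roc)) stop_pocusda("empty ROC curve")
  cand <- roc[roc$sensitivity >= min_sensitivity, , drop = FALSE]
  if (!nrow(cand)) cand <- roc
  j <- cand$sensitivity + cand$specificity - 1
  best <- order(-j, -cand$specificity, -cand$threshold)[1]
  structure(list(threshold = cand$threshold[best],
                 sensitivity = cand$sensitivity[best],
                 specificity = cand$specificity[best],
                 j = j[best]),
            class = "operating_point")
}

#' Percentile bootstrap confidence interval for a score-set metric
#'
#' Resamples test images with replacement `B` times at the original size and
#' takes the 2.5/97.5 percentiles of the metric. Resamples on which the
#' metric is not computable (e.g. a single class drawn) are redrawn; the
#' redraw count is attached as attribute `n_redrawn`. Patient-level
#' resampling (all images of a drawn patient enter together) is available
#' since test images share patients.
#'
#' @param score_set a `score_set`.
#' @param metric_fn function of a `score_set` returning a scalar.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level confidence level.
#' @param unit `"image"` (default) or `"patient"`.
#' @return Numeric `c(lower, upper)` with attributes `n_redrawn` and `values`.
#' @export
bootstrap_ci <- function(score_set, metric_fn, B = 1000L, seed = 1L,
                         level = 0.95, unit = c("image", "patient")) {
  unit <- match.arg(unit)
  if (B < 1) stop_pocusda("B must be >= 1")
  n <- nrow(score_set)
  pats <- unique(score_set$patient_id)
  vals <- with_seed(seed, {
    out <- numeric(B)
    redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- if (unit == "image") {
          sample.int(n, n, replace = TRUE)
        } else {
          unlist(lapply(sample(pats, length(pats), replace = TRUE),
                        function(p) which(score_set$patient_id == p)))
        }
        v <- tryCatch(metric_fn(score_set[idx, , drop = FALSE]),
                      error = function(e) NA_real_)
        if (is.finite(v)) break
        redrawn <- redrawn + 1L
        if (redrawn > 50L * B) stop_pocusda("bootstrap cannot find valid resamples")
      }
      out[b] <- v
    }
    attr(out, "n_redrawn") <- redrawn
    out
  })
  a <- (1 - level) / 2
  ci <- unname(quantile(vals, c(a, 1 - a)))
  attr(ci, "n_redrawn") <- attr(vals, "n_redrawn")
  attr(ci, "values") <- as.numeric(vals)
  ci
}

#' Malignant-vs-rest AUC of a score set
#' @param score_set a `score_set`.
#' @return Scalar AUC.
#' @export
metric_auc <- function(score_set) {
  b <- binarize_malignant(score_set)
  auc(b$scores, b$labels)
}

#' Balanced accuracy of a score set (argmax predictions)
#' @param score_set a `score_set`.
#' @return Scalar balanced accuracy.
#' @export
metric_balanced_accuracy <- function(score_set) {
  p <- as.matrix(score_set[, c("p_normal", "p_benign", "p_malignant")])
  pred <- CLASS_LEVELS[max.col(p, ties.method = "first")]
  balanced_accuracy(pred, score_set$true_class)
}

#' Balanced accuracy: unweighted mean of per-class recalls
#'
#' @param predicted_classes,true_classes character vectors; all three classes
#'   must appear in the truth.
#' @return Scalar in [0, 1].
#' @export
balanced_accuracy <- function(predicted_classes, true_classes) {
  recalls <- vapply(CLASS_LEVELS, function(cl) {
    idx <- true_classes == cl
    if (!any(idx)) {
      stop_pocusda("class '%s' missing from the true labels", cl)
    }
    mean(predicted_classes[idx] == cl)
  }, 0)
  mean(recalls)
}

#' Bootstrap CIs for sensitivity and specificity at a fixed threshold
#'
#' The threshold (chosen on the full test set before resampling) is held
#' fixed across resamples.
#'
#' @param score_set a `score_set`.
#' @param threshold malignant-probability threshold (positive iff
#'   `score >= threshold`).
#' @param B,seed,level as in [bootstrap_ci()].
#' @return List with point estimates `sensitivity`, `specificity` and their
#'   CIs `sens_ci`, `spec_ci`.
#' @export
sens_spec_at_threshold_ci <- function(score_set, threshold, B = 1000L,
                                      seed = 1L, level = 0.95) {
  sens_fn <- function(s) {
    b <- binarize_malignant(s)
    if (!any(b$labels == 1)) stop("no positives")
    mean(b$scores[b$labels == 1] >= threshold)
  }
  spec_fn <- function(s) {
    b <- binarize_malignant(s)
    if (!any(b$labels == 0)) stop("no negatives")
    mean(b$scores[b$labels == 0] < threshold)
  }
  list(
    sensitivity = sens_fn(score_set),
    specificity = spec_fn(score_set),
    sens_ci = bootstrap_ci(score_set, sens_fn, B, derive_seed(seed, "sens"),
                           level),
    spec_ci = bootstrap_ci(score_set, spec_fn, B, derive_seed(seed, "spec"),
                           level)
  )
}

#' Gaussian moments of a feature matrix
#' @param features numeric matrix, one row per observation.
#' @return A `gaussian_stats` list with mean vector `mu` and covariance
#'   `sigma`.
#' @export
gaussian_stats <- function(features) {
  features <- as.matrix(features)
  structure(list(mu = colMeans(features), sigma = cov(features)),
            class = "gaussian_stats")
}

# Symmetric PSD matrix square root by eigendecomposition; small negative
# eigenvalues (numerical noise) are clipped at zero and the clip magnitude
# returned.
sym_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  clip <- max(0, -min(e$values))
  v <- pmax(e$values, 0)
  list(sqrt = e$vectors %*% (sqrt(v) * t(e$vectors)), clip = clip)
}

#' Fréchet distance between two Gaussians
#'
#' `||mu_a - mu_b||^2 + Tr(Sigma_a + Sigma_b - 2 (Sigma_a Sigma_b)^{1/2})`,
#' computed through the symmetrized product
#' `Sigma_a^{1/2} Sigma_b Sigma_a^{1/2}`. Negative eigenvalue noise in the
#' square roots is clipped; the total clip magnitude is attached as attribute
#' `clip`.
#'
#' @param stats_a,stats_b `gaussian_stats` of matching dimension.
#' @return Non-negative scalar.
#' @export
frechet_distance <- function(stats_a, stats_b) {
  if (length(stats_a$mu) != length(stats_b$mu)) {
    stop_pocusda("feature dimensions differ (%d vs %d)",
                 length(stats_a$mu), length(stats_b$mu))
  }
  ra <- sym_sqrt(stats_a$sigma)
  inner <- ra$sqrt %*% stats_b$sigma %*% ra$sqrt
  ri <- sym_sqrt(inner)
  d <- sum((stats_a$mu - stats_b$mu)^2) +
    sum(diag(stats_a$sigma)) + sum(diag(stats_b$sigma)) -
    2 * sum(diag(ri$sqrt))
  structure(max(d, 0), clip = ra$clip + ri$clip)
}

#' Fixed random-convolution feature extractor
#'
#' A three-stage strided convolution network with ReLU activations and global
#' average pooling, weights drawn once from a fixed seed. It requires no
#' pretrained weights; distances are comparable only within one extractor,
#' identified by `extractor_id`.
#'
#' @param dim feature dimension (width of the last stage).
#' @param seed seed fixing the random weights.
#' @return A `fid_extractor` object.
#' @export
fid_extractor <- function(dim = 64L, seed = 1234L) {
  net <- with_seed(seed, list(
    layer_conv(3L, 1L, 8L, stride = 2L, pad = 1L), layer_relu(),
    layer_conv(3L, 8L, 16L, stride = 2L, pad = 1L), layer_relu(),
    layer_conv(3L, 16L, as.integer(dim), stride = 2L, pad = 1L), layer_relu()
  ))
  structure(list(net = net, dim = as.integer(dim),
                 extractor_id = sprintf("randconv%d-seed%d", dim, seed)),
            class = "fid_extractor")
}

#' Extract pooled features from a list of images
#' @param extractor a [fid_extractor()].
#' @param images list of matrices on the 0–255 scale (equal sizes).
#' @param batch_size images per forward pass.
#' @return Matrix `length(images) x dim`.
#' @export
extract_features <- function(extractor, images, batch_size = 32L) {
  out <- matrix(NA_real_, length(images), extractor$dim)
  for (b0 in seq(1, length(images), by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, length(images))
    z <- net_forward(extractor$net, stack_images(images[idx], scale = 1 / 255))
    d <- dim(z)
    zm <- z
    dim(zm) <- c(d[1] * d[2], d[3] * d[4])
    gap <- matrix(colMeans(zm), d[3], d[4])   # (dim, batch)
    out[idx, ] <- t(gap)
  }
  out
}

#' Fréchet distance between the feature Gaussians of two image sets
#'
#' @param images_a,images_b lists of matrices on the 0–255 scale.
#' @param extractor a [fid_extractor()] (default: the fixed random-convolution
#'   embedding). Any object with the same interface — for instance a wrapper
#'   around a pretrained deep feature backend — can be plugged in.
#' @return Non-negative scalar with attribute `extractor_id`. Sides with
#'   fewer images than `dim + 1` are allowed but flagged with a warning (the
#'   covariance is then singular).
#' @export
fid <- function(images_a, images_b, extractor = fid_extractor()) {
  if (length(images_a) < 2 || length(images_b) < 2) {
    stop_pocusda("fid needs at least 2 images on each side")
  }
  if (min(length(images_a), length(images_b)) < extractor$dim + 1) {
    warning(sprintf(
      "fewer than dim+1 = %d images on one side; covariance is singular",
      extractor$dim + 1
    ), call. = FALSE)
  }
  fa <- gaussian_stats(extract_features(extractor, images_a))
  fb <- gaussian_stats(extract_features(extractor, images_b))
  d <- frechet_distance(fa, fb)
  attr(d, "extractor_id") <- extractor$extractor_id
  d
}

# Placement values (structural components) of one score vector: V10 per
# positive, V01 per negative, ties half-weighted.
placement_values <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' Single-model AUC variance (DeLong structural components)
#' @inheritParams auc
#' @return Estimated variance of the empirical AUC.
#' @export
delong_auc_variance <- function(scores, labels) {
  pv <- placement_values(scores, as.integer(labels))
  var(pv$v10) / length(pv$v10) + var(pv$v01) / length(pv$v01)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both models are scored on the same labelled test set. Placement values
#' give the 2x2 covariance of the AUC estimates; the difference is compared
#' to a standard normal. A zero variance with equal AUCs (e.g. identical
#' score vectors) yields p = 1 by convention.
#'
#' @param scores_a,scores_b score vectors on the same records.
#' @param labels shared 0/1 labels.
#' @return List `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop_pocusda("delong_paired needs both label values")
  }
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop_pocusda("score vectors must match the label vector")
  }
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(v)
  }
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p)
}

#' Holm–Bonferroni stepdown adjustment
#'
#' Sorted p-values are multiplied by decreasing factors with a cumulative
#' maximum and capped at 1 (the classical stepdown, as in
#' `stats::p.adjust(method = "holm")`, which performs the computation).
#'
#' @param p_values numeric vector in [0, 1].
#' @param alpha family-wise error level.
#' @return List with `adjusted` p-values (input order) and logical `reject`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1)) {
    stop_pocusda("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "holm")
  list(adjusted = adj, reject = adj < alpha)
}

#' Pairwise significance matrix across evaluated classifiers
#'
#' All pairwise paired DeLong tests on the shared test set, jointly
#' Holm-adjusted (family size `choose(k, 2)`); cells are `**` when the
#' adjusted p is below 0.01, `*` below `alpha`, else `ns`.
#'
#' @param score_sets named list of `score_set`s on identical test records.
#' @param alpha significance level (default 0.05).
#' @return A `significance_matrix` list: character `stars` matrix, numeric
#'   `p_raw` and `p_adjusted` matrices, and `alpha`.
#' @export
significance_matrix <- function(score_sets, alpha = 0.05) {
  k <- length(score_sets)
  if (k < 2) stop_pocusda("need at least two score sets")
  ids <- names(score_sets) %||% as.character(seq_len(k))
  truth <- score_sets[[1]]$true_class
  for (s in score_sets) {
    if (!identical(s$true_class, truth)) {
      stop_pocusda("score sets were not evaluated on identical test records")
    }
  }
  labels <- as.integer(truth == "malignant")
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  p_raw <- apply(pairs, 1, function(ij) {
    delong_paired(score_sets[[ij[1]]]$p_malignant,
                  score_sets[[ij[2]]]$p_malignant, labels)$p
  })
  adj <- holm_bonferroni(p_raw, alpha)$adjusted
  mk <- function(vals, init) {
    m <- matrix(init, k, k, dimnames = list(ids, ids))
    m[pairs] <- vals
    m[pairs[, 2:1, drop = FALSE]] <- vals
    m
  }
  stars <- mk(ifelse(adj < 0.01, "**", ifelse(adj < alpha, "*", "ns")), "ns")
  structure(list(stars = stars, p_raw = mk(p_raw, NA_real_),
                 p_adjusted = mk(adj, NA_real_), alpha = alpha),
            class = "significance_matrix")
}
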