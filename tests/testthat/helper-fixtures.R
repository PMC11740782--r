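# Shared fixtures. Expensive artifacts (trained models, study runs) are
# memoized so several test files can assert on one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_phantom_config <- function(side = 32L, ...) {
  phantom_config(image_side = side, ...)
}

# small three-class cohort for transform/classifier tests
tiny_cohort <- function(domain = "standard", n_patients = 12L, side = 32L,
                        seed = 42L) {
  cached(sprintf("cohort-%s-%d-%d-%d", domain, n_patients, side, seed), {
    generate_cohort(n_patients, c(2L, 3L),
                    class_mix = c(normal = 1 / 3, benign = 1 / 3,
                                  malignant = 1 / 3),
                    domain = domain, config = tiny_phantom_config(side),
                    seed = seed)
  })
}

# random score set with a given separation between malignant and the rest
random_score_set <- function(n = 60L, delta = 1, seed = 1L) {
  set.seed(seed)
  cls <- sample(c("normal", "benign", "malignant"), n, replace = TRUE)
  s <- rnorm(n) + delta * (cls == "malignant")
  p_mal <- 1 / (1 + exp(-s))
  rest <- (1 - p_mal)
  p_norm <- rest * runif(n, 0.3, 0.7)
  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)), true_class = cls,
    p_normal = p_norm, p_benign = rest - p_norm, p_malignant = p_mal,
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_set", "data.frame")
  out
}

# exhaustive pair-counting AUC oracle
auc_oracle <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# brute-force constrained-Youden oracle over every threshold interval
youden_oracle <- function(scores, labels, floor = 0.9) {
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), 0)
  ok <- sens >= floor
  if (!any(ok)) ok <- rep(TRUE, length(thr))
  j <- sens + spec - 1
  cand <- which(ok)
  best <- cand[order(-j[cand], -spec[cand], -thr[cand])[1]]
  list(threshold = thr[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}

# classical Holm stepdown done by hand
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[o] <- stepped
  out
}

# matrix square root by eigendecomposition of the (generally non-symmetric)
# product, the independent route for the Frechet-distance check
frechet_oracle <- function(a, b) {
  e <- eigen(a$sigma %*% b$sigma)
  sq <- e$vectors %*% diag(sqrt(as.complex(e$values))) %*% solve(e$vectors)
  sum((a$mu - b$mu)^2) +
    sum(diag(a$sigma)) + sum(diag(b$sigma)) - 2 * Re(sum(diag(sq)))
}

random_spd <- function(d, seed) {
  set.seed(seed)
  m <- matrix(rnorm(d * d), d)
  crossprod(m) / d + diag(d) * 0.1
}

# Kolmogorov-Smirnov distance between the 256-bin histograms of two images
ks_to_target <- function(pixels, target) {
  f1 <- cumsum(tabulate(as.integer(pixels) + 1L, 256L)) / length(pixels)
  f2 <- cumsum(target$bin_counts) / target$n_pixels
  max(abs(f1 - f2))
}

desk_smoke_spec <- function(side = 32L) {
  cnn_spec(side, conv_filters = c(8L, 16L, 32L, 32L, 32L),
           fc_sizes = c(64L, 3L), conv_dropout = 0.05,
           post_pool_dropout = 0.25, post_fc_dropout = 0.25)
}

# The three seeded desk-scale study runs shared by the end-to-end tests.
desk_study_runs <- function() {
  cached("desk-study-runs", {
    lapply(1:3, function(s) {
      run_study(study_config("desk", seed = s,
                             combinations = c(1, 2, 6, 10, 14),
                             bootstrap_B = 200L, fid_dim = 16L),
                quiet = TRUE)
    })
  })
}

# The three seeded desk-scale translation trainings shared by the
# domain-translation tests: one model per seed on the desk cohorts.
desk_translation_runs <- function() {
  cached("desk-translation-runs", {
    cfg <- study_config("desk")
    std <- generate_cohort(cfg$n_patients_standard,
                           cfg$images_per_patient_standard,
                           cfg$class_mix_standard, "standard", cfg$phantom,
                           seed = 101L)
    poc <- patient_split(
      generate_cohort(cfg$n_patients_pocus, cfg$images_per_patient_pocus,
                      cfg$class_mix_pocus, "pocus", cfg$phantom, seed = 102L),
      cfg$test_fraction, seed = 103L
    )
    ptr <- cohort_subset(poc, poc$meta$split == "train")
    ex <- fid_extractor(dim = 16L)
    fid_source <- as.numeric(fid(std$images, ptr$images, ex))
    runs <- lapply(0:2, function(s) {
      gc <- cfg$cyclegan
      gc$seed <- s
      pair <- train_cyclegan(std$images, ptr$images, gc)
      translated <- translate_images(pair, std$images)
      list(pair = pair,
           fid_translated = as.numeric(fid(translated, ptr$images, ex)))
    })
    list(fid_source = fid_source, runs = runs)
  })
}
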