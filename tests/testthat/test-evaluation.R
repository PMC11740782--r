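# ROC/AUC, constrained Youden, bootstrap, balanced accuracy, Frechet/FID,
# DeLong, Holm-Bonferroni, significance matrix.

test_that("binarize_malignant extracts malignant probability and label", {
  s <- data.frame(patient_id = c("a", "b", "c"),
                  true_class = c("malignant", "benign", "normal"),
                  p_normal = c(0.1, 0.5, 0.6), p_benign = c(0.2, 0.3, 0.3),
                  p_malignant = c(0.7, 0.2, 0.1))
  b <- binarize_malignant(s)
  expect_identical(b$scores, c(0.7, 0.2, 0.1))
  expect_identical(b$labels, c(1L, 0L, 0L))
})

test_that("auc equals pair counting on closed-form and random cases", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.2, 0.9, 0.3, 0.8), c(1, 1, 0, 0)), 0.5)
  expect_equal(auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both")
  set.seed(11)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(seq(0, 1, by = 0.05), n, TRUE)  # many ties
    expect_equal(auc(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("roc curves are monotone with both endpoints", {
  set.seed(12)
  scores <- runif(40); labels <- sample(0:1, 40, TRUE)
  labels[1:2] <- 0:1
  roc <- roc_curve(scores, labels)
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 0))
  expect_true(any(roc$sensitivity == 0 & roc$specificity == 1))
})

test_that("the sensitivity floor overrides the unconstrained Youden optimum", {
  scores <- c(0.9, 0.6, 0.2, 0.5, 0.4, 0.3)
  labels <- c(1, 1, 1, 0, 0, 0)
  roc <- roc_curve(scores, labels)
  op <- constrained_youden(roc, 0.9)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 0)
  expect_equal(op$j, 0)
  expect_equal(op$threshold, 0.2)
  free <- constrained_youden(roc, 0)
  expect_equal(free$sensitivity, 2 / 3)
  expect_equal(free$specificity, 1)
  expect_equal(free$j, 2 / 3)

  perfect <- constrained_youden(roc_curve(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0.9)
  expect_equal(perfect$j, 1)
  expect_equal(perfect$sensitivity, 1)
})

test_that("constrained Youden equals exhaustive search on random instances", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), 2)
    floor <- sample(c(0, 0.5, 0.9, 1), 1)
    got <- constrained_youden(roc_curve(scores, labels), floor)
    want <- youden_oracle(scores, labels, floor)
    expect_equal(got$j, want$j)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("bootstrap CIs are seeded, degenerate on constants, and image-level", {
  s <- random_score_set(50L, seed = 2L)
  ci1 <- bootstrap_ci(s, metric_auc, B = 50L, seed = 4L)
  ci2 <- bootstrap_ci(s, metric_auc, B = 50L, seed = 4L)
  expect_identical(ci1, ci2)
  const <- bootstrap_ci(s, function(x) 0.42, B = 20L, seed = 1L)
  expect_equal(unname(const), c(0.42, 0.42), ignore_attr = TRUE)
  expect_error(bootstrap_ci(s, metric_auc, B = 0L), "B must be")
  pat <- bootstrap_ci(s, metric_auc, B = 20L, seed = 1L, unit = "patient")
  expect_true(pat[1] <= pat[2])
})

test_that("fixed-threshold sensitivity/specificity CIs behave at the extremes", {
  s <- random_score_set(40L, delta = 50, seed = 3L)   # perfectly separated
  b <- binarize_malignant(s)
  thr <- min(b$scores[b$labels == 1])
  out <- sens_spec_at_threshold_ci(s, thr, B = 50L, seed = 1L)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$specificity, 1)
  expect_equal(unname(out$sens_ci), c(1, 1), ignore_attr = TRUE)
  expect_equal(unname(out$spec_ci), c(1, 1), ignore_attr = TRUE)
})

test_that("balanced accuracy averages per-class recalls", {
  truth <- rep(c("normal", "benign", "malignant"), times = c(4, 4, 4))
  expect_equal(balanced_accuracy(truth, truth), 1)
  pred <- truth
  pred[5:6] <- "normal"     # benign recall 0.5
  pred[9] <- "benign"       # malignant recall 0.75
  expect_equal(balanced_accuracy(pred, truth), mean(c(1, 0.5, 0.75)))
  expect_equal(balanced_accuracy(rep("normal", 12), truth), 1 / 3)
  expect_error(balanced_accuracy(pred[1:8], truth[1:8]), "malignant")
})

test_that("Frechet distance matches closed forms and the eigen-sqrt oracle", {
  g1 <- structure(list(mu = c(0, 0), sigma = diag(2)), class = "gaussian_stats")
  expect_equal(as.numeric(frechet_distance(g1, g1)), 0)

  a1 <- structure(list(mu = 0, sigma = matrix(1)), class = "gaussian_stats")
  b1 <- structure(list(mu = 2, sigma = matrix(1)), class = "gaussian_stats")
  expect_equal(as.numeric(frechet_distance(a1, b1)), 4)
  c1 <- structure(list(mu = 0, sigma = matrix(4)), class = "gaussian_stats")
  expect_equal(as.numeric(frechet_distance(a1, c1)), 1)  # (sd 1 vs 2)^2

  for (i in 1:10) {
    a <- structure(list(mu = rnorm(5), sigma = random_spd(5, i)),
                   class = "gaussian_stats")
    b <- structure(list(mu = rnorm(5), sigma = random_spd(5, i + 100)),
                   class = "gaussian_stats")
    expect_lt(abs(as.numeric(frechet_distance(a, b)) - frechet_oracle(a, b)),
              1e-8)
    expect_lt(abs(as.numeric(frechet_distance(a, b)) -
                    as.numeric(frechet_distance(b, a))), 1e-8)
    expect_gte(as.numeric(frechet_distance(a, b)), 0)
  }
  expect_error(frechet_distance(g1, a1), "dimensions differ")
})

test_that("fid is zero on identical sets, symmetric, and separates domains", {
  poc <- tiny_cohort("pocus", n_patients = 8L, seed = 21L)
  std <- tiny_cohort("standard", n_patients = 8L, seed = 22L)
  ex <- fid_extractor(dim = 8L)
  expect_lt(as.numeric(fid(poc$images, poc$images, ex)), 1e-12)
  ab <- as.numeric(fid(std$images, poc$images, ex))
  ba <- as.numeric(fid(poc$images, std$images, ex))
  expect_lt(abs(ab - ba), 1e-10)

  # between-domain exceeds within-domain resampling distance
  n <- length(poc$images)
  set.seed(30)
  i1 <- sample(n, n %/% 2); i2 <- setdiff(seq_len(n), i1)
  within <- as.numeric(fid(poc$images[i1], poc$images[i2], ex))
  expect_gt(ab, within)
  expect_error(fid(poc$images[1], poc$images, ex), "at least 2")
  expect_warning(fid(std$images[1:3], poc$images[1:3], ex), "singular")
})

test_that("paired DeLong: identical scores give p = 1; pROC agrees", {
  s <- random_score_set(80L, seed = 6L)
  b <- binarize_malignant(s)
  same <- delong_paired(b$scores, b$scores, b$labels)
  expect_equal(same$p, 1)
  expect_equal(same$auc_a, same$auc_b)

  set.seed(7)
  other <- b$scores * 0.5 + rnorm(80, sd = 0.3)
  got <- delong_paired(b$scores, other, b$labels)
  skip_if_not_installed("pROC")
  r1 <- pROC::roc(b$labels, b$scores, quiet = TRUE)
  r2 <- pROC::roc(b$labels, other, quiet = TRUE)
  ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(got$p, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(got$auc_a, as.numeric(pROC::auc(r1)), tolerance = 1e-12)
  expect_error(delong_paired(b$scores, other, rep(1, 80)), "both label")
})

test_that("single-model DeLong variance is close to a bootstrap variance", {
  set.seed(8)
  y <- rep(c(0, 1), each = 100)
  sc <- rnorm(200) + y
  vd <- delong_auc_variance(sc, y)
  vb <- var(replicate(500, {
    i <- sample(200, 200, TRUE)
    if (length(unique(y[i])) < 2) NA_real_ else auc(sc[i], y[i])
  }), na.rm = TRUE)
  expect_lt(abs(vd - vb) / vb, 0.3)
})

test_that("Holm-Bonferroni matches the hand stepdown and flags rejections", {
  got <- holm_bonferroni(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(got$adjusted, c(0.03, 0.06, 0.06))
  expect_identical(got$reject, c(TRUE, FALSE, FALSE))
  expect_equal(holm_bonferroni(0.2)$adjusted, 0.2)
  all1 <- holm_bonferroni(rep(1, 5))
  expect_true(all(all1$adjusted == 1) && !any(all1$reject))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(14)
  for (i in 1:25) {
    p <- runif(sample(2:12, 1))
    adj <- holm_bonferroni(p)$adjusted
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(!is.unsorted(adj[order(p)]))
  }
})

test_that("the significance matrix is symmetric with an ns diagonal", {
  s1 <- random_score_set(100L, delta = 0.4, seed = 9L)
  s2 <- s1; s3 <- s1
  set.seed(10)
  s2$p_malignant <- pmin(pmax(s1$p_malignant + rnorm(100, sd = 0.05), 0), 1)
  s3$p_malignant <- runif(100)   # uninformative scores
  m <- significance_matrix(list(a = s1, b = s2, c = s3), alpha = 0.05)
  expect_identical(unname(diag(m$stars)), rep("ns", 3))
  expect_identical(m$stars, t(m$stars))
  expect_equal(m$p_adjusted, t(m$p_adjusted))
  expect_true(all(m$stars %in% c("ns", "*", "**")))

  same <- significance_matrix(list(a = s1, b = s1))
  expect_true(all(same$stars == "ns"))

  s4 <- random_score_set(40L, seed = 11L)
  expect_error(significance_matrix(list(s1, s4)), "identical test records")
})
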