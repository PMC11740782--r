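#' The sixteen canonical training-data combinations
#'
#' Combination 1 is the scarce POCUS training set alone; 2–8 add the standard
#' cohort, its histogram-matched or histogram-equalized version, or its
#' domain-translated version (one shared translation model, `cyclegan1`, or
#' one per class, `cyclegan3`); 9–16 repeat 1–8 with random spatial
#' augmentation during training.
#'
#' @return Data frame with columns `id`, `label`, and logical component flags
#'   `standard`, `hist_match`, `hist_eq`, `cyclegan1`, `cyclegan3`,
#'   `augmented` (every combination includes the POCUS training set).
#' @export
combination_table <- function() {
  base <- data.frame(
    id = 1:8,
    label = c("P", "P + US", "P + US + Hist. Match", "P + US + Hist. Eq.",
              "P + CycleGAN1", "P + CycleGAN3", "P + US + CycleGAN1",
              "P + US + CycleGAN3"),
    standard = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    hist_match = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    hist_eq = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    cyclegan1 = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    cyclegan3 = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    augmented = FALSE,
    stringsAsFactors = FALSE
  )
  aug <- base
  aug$id <- 9:16
  aug$label <- paste(base$label, "+ Aug")
  aug$augmented <- TRUE
  rbind(base, aug)
}

#' Patient-exclusive train/test split
#'
#' Assigns whole patients to the test fold until the requested image fraction
#' is reached, so no patient spans both folds. The assignment is stratified
#' by each patient's finding class (the lesion class of their images, normal
#' otherwise): within every stratum, shuffled patients are added greedily
#' until that stratum's share of test images is met, which keeps all three
#' classes represented in both folds whenever each class has at least two
#' patients.
#'
#' @param cohort a `us_cohort`.
#' @param test_fraction requested test share of images.
#' @param seed integer seed.
#' @return The cohort with a `split` column (`"train"`/`"test"`) in its
#'   manifest.
#' @export
patient_split <- function(cohort, test_fraction = 0.4, seed = 1L) {
  pats <- unique(cohort$meta$patient_id)
  if (length(pats) < 2) stop_pocusda("patient_split needs at least 2 patients")
  # patient stratum: the lesion class if one is present, else normal
  stratum <- vapply(pats, function(p) {
    cls <- cohort$meta$class[cohort$meta$patient_id == p]
    lesions <- setdiff(unique(cls), "normal")
    if (length(lesions)) lesions[1] else "normal"
  }, "")
  split <- with_seed(seed, {
    test_pats <- character(0)
    for (st in unique(stratum)) {
      members <- sample(pats[stratum == st])
      target <- test_fraction *
        sum(cohort$meta$patient_id %in% members)
      got <- 0
      for (p in members) {
        if (got >= target) break
        test_pats <- c(test_pats, p)
        got <- got + sum(cohort$meta$patient_id == p)
      }
    }
    ifelse(cohort$meta$patient_id %in% test_pats, "test", "train")
  })
  if (!any(split == "test") || !any(split == "train")) {
    stop_pocusda("cannot form a non-empty train/test split at fraction %.2f",
                 test_fraction)
  }
  cohort$meta$split <- split
  cohort
}

#' Split a cohort into its train and test folds
#' @param cohort a `us_cohort` carrying a `split` column (see
#'   [patient_split()]).
#' @return List with `us_cohort`s `train` and `test`.
#' @export
split_cohort <- function(cohort) {
  if (is.null(cohort$meta$split)) stop_pocusda("cohort has no split column")
  list(train = cohort_subset(cohort, cohort$meta$split == "train"),
       test = cohort_subset(cohort, cohort$meta$split == "test"))
}

#' Assemble the training set of one combination
#'
#' Concatenates the requested record sets. Sizes follow the arithmetic
#' pattern of the design at any cohort scale: the POCUS set alone gives
#' `n_P` records, each added expanded set contributes `n_S` more.
#' Augmentation is a training flag, not a size change.
#'
#' @param combo one row of [combination_table()].
#' @param parts named list of `us_cohort`s: `pocus` (required) and whichever
#'   of `standard`, `hist_match`, `hist_eq`, `cyclegan1`, `cyclegan3` the
#'   combination requests.
#' @return A `us_cohort`.
#' @export
assemble_combination <- function(combo, parts) {
  pieces <- list(parts$pocus)
  if (is.null(parts$pocus)) stop_pocusda("parts$pocus is required")
  for (comp in c("standard", "hist_match", "hist_eq", "cyclegan1", "cyclegan3")) {
    if (isTRUE(combo[[comp]])) {
      if (is.null(parts[[comp]])) {
        stop_pocusda("combination %d needs component '%s' but it was not provided",
                     combo$id, comp)
      }
      pieces <- c(pieces, list(parts[[comp]]))
    }
  }
  do.call(cohort_bind, pieces)
}

#' Study configuration
#'
#' Bundles cohort, model and evaluation settings. The `desk` preset (48-pixel
#' images, tens of patients per domain, narrow networks, few epochs, reduced
#' dropout) runs the full pipeline on one CPU in minutes with a resolvable
#' scarce-POCUS vs expanded-data signal; the `full` preset uses the
#' full-size network (180-pixel input, the canonical dropout and learning
#' rate, 50 epochs, 200 translation epochs) and clinically realistic cohort
#' sizes.
#'
#' @param scale `"desk"` or `"full"`.
#' @param seed master seed; every stage derives its own stream from it.
#' @param combinations combination ids to run (subset of 1:16).
#' @param image_side override of the preset image side (phantom, CNN and
#'   translation models are all built at this side).
#' @param ... overrides of any configuration field.
#' @return A `study_config` list.
#' @export
study_config <- function(scale = c("desk", "full"), seed = 1L,
                         combinations = 1:16, image_side = NULL, ...) {
  scale <- match.arg(scale)
  side <- as.integer(image_side %||% if (scale == "desk") 48L else 180L)
  cfg <- list(
    scale = scale,
    seed = as.integer(seed),
    combinations = combinations,
    image_side = side,
    n_patients_standard = if (scale == "desk") 40L else 436L,
    n_patients_pocus = if (scale == "desk") 40L else 105L,
    images_per_patient_standard = c(2L, 4L),
    images_per_patient_pocus = if (scale == "desk") c(2L, 4L) else c(10L, 15L),
    class_mix_standard = c(normal = 0.33, benign = 0.22, malignant = 0.45),
    class_mix_pocus = c(normal = 0.57, benign = 0.21, malignant = 0.22),
    test_fraction = if (scale == "desk") 0.7 else 0.4,
    phantom = phantom_config(image_side = side),
    cnn = if (scale == "desk") {
      cnn_spec(side, conv_filters = c(8L, 16L, 32L, 32L, 32L),
               fc_sizes = c(64L, 3L), conv_dropout = 0.05,
               post_pool_dropout = 0.25, post_fc_dropout = 0.25)
    } else {
      cnn_spec(180L)
    },
    train = list(lr = if (scale == "desk") 3e-4 else 1e-4,
                 epochs = if (scale == "desk") 20L else 50L,
                 batch_size = if (scale == "desk") 16L else 32L),
    augment = augment_policy(enabled_groups = "spatial"),
    cyclegan = if (scale == "desk") {
      cyclegan_config(image_side = side)
    } else {
      cyclegan_config(image_side = 180L, generator_width = 64L,
                      n_residual_blocks = 9L, discriminator_width = 64L,
                      epochs = 200L)
    },
    bootstrap_B = 1000L,
    alpha = 0.05,
    min_sensitivity = 0.90,
    fid_dim = if (scale == "desk") 16L else 64L
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "study_config")
}

# Assert that no test image fingerprint entered a fitting input and that no
# patient spans both folds.
audit_leakage <- function(test_cohort, fit_cohorts) {
  test_keys <- vapply(test_cohort$images, image_key, "")
  overlap <- 0L
  for (co in fit_cohorts) {
    keys <- vapply(co$images, image_key, "")
    overlap <- overlap + sum(keys %in% test_keys)
  }
  pat_overlap <- 0L
  for (co in fit_cohorts) {
    pat_overlap <- pat_overlap +
      length(intersect(unique(co$meta$patient_id),
                       unique(test_cohort$meta$patient_id)))
  }
  list(test_image_overlap = overlap, patient_overlap = pat_overlap,
       pass = overlap == 0L && pat_overlap == 0L)
}

#' Run the full comparison study
#'
#' Generates the two phantom cohorts, splits the POCUS cohort patient-wise,
#' trains translation models where requested, assembles each training-data
#' combination, trains one classifier per combination and evaluates all of
#' them on the common POCUS test set: malignant-vs-rest AUC and balanced
#' accuracy with percentile bootstrap CIs, the sensitivity-constrained Youden
#' operating point with fixed-threshold CIs, the feature-Gaussian Fréchet
#' distances of the expanded sets to the POCUS training set, and the pairwise
#' DeLong/Holm significance matrix. In combinations with histogram
#' equalization, the equalization is applied to training and test data.
#'
#' @param config a [study_config()].
#' @param quiet suppress progress messages.
#' @return A `comparison_report` list: `metrics` and `operating_points` data
#'   frames, `significance`, `fid`, per-combination `score_sets` and loss
#'   `histories`, the leakage `audit`, and the `config`.
#' @export
run_study <- function(config = study_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (config$phantom$image_side != config$image_side ||
      config$cnn$input_side != config$image_side ||
      config$cyclegan$image_side != config$image_side) {
    stop_pocusda(paste(
      "inconsistent image sides between phantom/cnn/cyclegan configs;",
      "set image_side through study_config(image_side = ...)"
    ))
  }
  combos <- combination_table()
  combos <- combos[combos$id %in% config$combinations, , drop = FALSE]
  seed <- config$seed

  say("generating cohorts (side %d)", config$image_side)
  standard <- generate_cohort(
    config$n_patients_standard, config$images_per_patient_standard,
    config$class_mix_standard, "standard", config$phantom,
    seed = derive_seed(seed, "standard")
  )
  pocus <- generate_cohort(
    config$n_patients_pocus, config$images_per_patient_pocus,
    config$class_mix_pocus, "pocus", config$phantom,
    seed = derive_seed(seed, "pocus")
  )
  pocus <- patient_split(pocus, config$test_fraction,
                         seed = derive_seed(seed, "split"))
  folds <- split_cohort(pocus)
  pocus_train <- folds$train
  pocus_test <- folds$test

  parts <- list(pocus = pocus_train, standard = standard)
  fit_inputs <- list(pocus_train, standard)

  targets <- NULL
  if (any(combos$hist_match)) {
    targets <- class_histograms(pocus_train)
    parts$hist_match <- match_cohort(standard, targets)
  }
  if (any(combos$hist_eq)) parts$hist_eq <- equalize_cohort(standard)

  translators <- list()
  fids <- data.frame(data = "US", fid = NA_real_, stringsAsFactors = FALSE)
  extractor <- fid_extractor(dim = config$fid_dim,
                             seed = derive_seed(seed, "fid"))
  fids$fid[1] <- as.numeric(fid(standard$images, pocus_train$images, extractor))
  for (regime in c("cyclegan1", "cyclegan3")) {
    if (!any(combos[[regime]])) next
    say("training %s translators", regime)
    cfg <- config$cyclegan
    cfg$seed <- derive_seed(seed, regime)
    translators[[regime]] <- train_regime(standard, pocus_train, cfg, regime)
    parts[[regime]] <- translate_cohort(standard, translators[[regime]],
                                        provenance = regime)
    fids <- rbind(fids, data.frame(
      data = regime,
      fid = as.numeric(fid(parts[[regime]]$images, pocus_train$images,
                           extractor))
    ))
  }

  metrics <- data.frame()
  op_points <- data.frame()
  score_sets <- list()
  histories <- list()
  for (i in seq_len(nrow(combos))) {
    combo <- combos[i, ]
    say("combination %d (%s)", combo$id, combo$label)
    combo_parts <- parts
    test_set <- pocus_test
    if (combo$hist_eq) {
      combo_parts$pocus <- equalize_cohort(pocus_train)
      test_set <- equalize_cohort(pocus_test)
    }
    train_set <- assemble_combination(combo, combo_parts)
    tc <- train_config(
      lr = config$train$lr, epochs = config$train$epochs,
      batch_size = config$train$batch_size,
      seed = derive_seed(seed, "cls", combo$id),
      augment_policy = if (combo$augmented) config$augment else NULL
    )
    model <- train_classifier(train_set, config$cnn, tc)
    scores <- predict_scores(model, test_set)
    ev <- evaluate_scores(scores, B = config$bootstrap_B,
                          seed = derive_seed(seed, "boot", combo$id),
                          min_sensitivity = config$min_sensitivity)
    metrics <- rbind(metrics, data.frame(
      combination = combo$label,
      acc = ev$acc, acc_ci_lo = ev$acc_ci[1], acc_ci_hi = ev$acc_ci[2],
      auc = ev$auc, auc_ci_lo = ev$auc_ci[1], auc_ci_hi = ev$auc_ci[2],
      stringsAsFactors = FALSE
    ))
    op_points <- rbind(op_points, data.frame(
      combination = combo$label,
      sens = ev$sens, sens_ci_lo = ev$sens_ci[1], sens_ci_hi = ev$sens_ci[2],
      spec = ev$spec, spec_ci_lo = ev$spec_ci[1], spec_ci_hi = ev$spec_ci[2],
      stringsAsFactors = FALSE
    ))
    score_sets[[as.character(combo$id)]] <- scores
    histories[[as.character(combo$id)]] <- model$history
    fit_inputs <- c(fit_inputs, list(train_set))
  }

  sig <- if (length(score_sets) >= 2) {
    significance_matrix(score_sets, alpha = config$alpha)
  } else {
    NULL
  }
  audit <- audit_leakage(pocus_test, fit_inputs)

  structure(list(metrics = metrics, operating_points = op_points,
                 significance = sig, fid = fids, score_sets = score_sets,
                 histories = histories, audit = audit,
                 combinations = combos, config = config),
            class = "comparison_report")
}

#' Evaluate one score set
#'
#' AUC and balanced accuracy with percentile bootstrap CIs, plus the
#' sensitivity-constrained Youden operating point and fixed-threshold CIs.
#'
#' @param scores a `score_set`.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param min_sensitivity the sensitivity floor for the operating point.
#' @return List of point estimates and CIs.
#' @export
evaluate_scores <- function(scores, B = 1000L, seed = 1L,
                            min_sensitivity = 0.90) {
  b <- binarize_malignant(scores)
  roc <- roc_curve(b$scores, b$labels)
  op <- constrained_youden(roc, min_sensitivity)
  ss <- sens_spec_at_threshold_ci(scores, op$threshold, B = B,
                                  seed = derive_seed(seed, "ss"))
  list(
    auc = auc(b$scores, b$labels),
    auc_ci = bootstrap_ci(scores, metric_auc, B, derive_seed(seed, "auc")),
    acc = metric_balanced_accuracy(scores),
    acc_ci = bootstrap_ci(scores, metric_balanced_accuracy, B,
                          derive_seed(seed, "acc")),
    threshold = op$threshold, j = op$j,
    sens = ss$sensitivity, sens_ci = ss$sens_ci,
    spec = ss$specificity, spec_ci = ss$spec_ci
  )
}

#' Write the report tables (CSV + JSON)
#'
#' @param report a `comparison_report`.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
report_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    metrics = file.path(dir, "metrics.csv"),
    operating_points = file.path(dir, "operating_points.csv"),
    significance = file.path(dir, "significance.csv"),
    fid = file.path(dir, "fid.csv"),
    json = file.path(dir, "report.json")
  )
  write.csv(report$metrics, paths["metrics"], row.names = FALSE)
  write.csv(report$operating_points, paths["operating_points"],
            row.names = FALSE)
  if (!is.null(report$significance)) {
    write.csv(as.data.frame(report$significance$stars), paths["significance"])
  }
  write.csv(report$fid, paths["fid"], row.names = FALSE)
  jsonlite::write_json(
    list(metrics = report$metrics,
         operating_points = report$operating_points,
         fid = report$fid,
         p_adjusted = if (is.null(report$significance)) NULL else
           report$significance$p_adjusted,
         audit = report$audit),
    paths["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE,
    matrix = "rowmajor"
  )
  invisible(paths)
}
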