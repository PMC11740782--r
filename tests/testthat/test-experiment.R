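# Combination assembly, patient-exclusive splitting, orchestration, reports.

test_that("the sixteen combinations match the canonical design", {
  tab <- combination_table()
  expect_identical(nrow(tab), 16L)
  expect_identical(tab$id, 1:16)
  # spot checks of the design
  c6 <- tab[tab$id == 6, ]
  expect_true(c6$cyclegan3 && !c6$standard && !c6$augmented && !c6$cyclegan1)
  c16 <- tab[tab$id == 16, ]
  expect_true(c16$cyclegan3 && c16$standard && c16$augmented)
  expect_identical(tab$augmented, rep(c(FALSE, TRUE), each = 8))
  # 1-8 and 9-16 share their data components
  expect_equal(tab[1:8, 3:7], tab[9:16, 3:7], ignore_attr = TRUE)
  # one intensity/translation transform at a time
  expect_true(all(rowSums(tab[, c("hist_match", "hist_eq", "cyclegan1",
                                  "cyclegan3")]) <= 1))
})

test_that("patient splits are exclusive, seeded and near the requested fraction", {
  co <- tiny_cohort("pocus", n_patients = 30L, seed = 61L)
  sp <- patient_split(co, 0.4, seed = 1L)
  f <- split_cohort(sp)
  expect_length(intersect(unique(f$train$meta$patient_id),
                          unique(f$test$meta$patient_id)), 0)
  realized <- nrow(f$test$meta) / nrow(sp$meta)
  expect_lt(abs(realized - 0.4), 0.1)

  sp2 <- patient_split(co, 0.4, seed = 1L)
  expect_identical(sp$meta$split, sp2$meta$split)
  expect_false(identical(patient_split(co, 0.4, seed = 2L)$meta$split,
                         sp$meta$split))

  one <- cohort_subset(co, co$meta$patient_id == co$meta$patient_id[1])
  expect_error(patient_split(one, 0.4), "at least 2")
})

test_that("combination sizes follow the n_P / n_P + n_S arithmetic", {
  poc <- tiny_cohort("pocus", n_patients = 6L, seed = 62L)
  std <- tiny_cohort("standard", n_patients = 8L, seed = 63L)
  translated <- std
  translated$meta$domain <- "translated"
  parts <- list(pocus = poc, standard = std, cyclegan3 = translated)
  tab <- combination_table()
  n_p <- nrow(poc$meta); n_s <- nrow(std$meta)

  expect_identical(nrow(assemble_combination(tab[1, ], parts)$meta), n_p)
  expect_identical(nrow(assemble_combination(tab[2, ], parts)$meta), n_p + n_s)
  expect_identical(nrow(assemble_combination(tab[8, ], parts)$meta),
                   n_p + 2L * n_s)
  expect_error(assemble_combination(tab[5, ], parts), "cyclegan1")
  # id 2 concatenates without duplication
  c2 <- assemble_combination(tab[2, ], parts)
  keys <- vapply(c2$images, pocusda:::image_key, "")
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("a reduced study run produces the full report structure", {
  rep1 <- run_study(study_config("desk", seed = 5L, combinations = c(1, 2),
                                 image_side = 32L,
                                 n_patients_standard = 10L,
                                 n_patients_pocus = 18L,
                                 class_mix_pocus = c(normal = 1 / 3,
                                                     benign = 1 / 3,
                                                     malignant = 1 / 3),
                                 test_fraction = 0.5,
                                 bootstrap_B = 50L, fid_dim = 8L,
                                 train = list(lr = 3e-4, epochs = 3L,
                                              batch_size = 8L)),
                    quiet = TRUE)
  expect_s3_class(rep1, "comparison_report")
  expect_identical(nrow(rep1$metrics), 2L)
  expect_identical(nrow(rep1$operating_points), 2L)
  expect_identical(dim(rep1$significance$stars), c(2L, 2L))
  expect_true(all(c("acc", "acc_ci_lo", "acc_ci_hi", "auc", "auc_ci_lo",
                    "auc_ci_hi") %in% names(rep1$metrics)))
  expect_true(all(c("sens", "sens_ci_lo", "sens_ci_hi", "spec", "spec_ci_lo",
                    "spec_ci_hi") %in% names(rep1$operating_points)))
  expect_true(rep1$audit$pass)
  expect_identical(rep1$fid$data, "US")
  expect_true(all(vapply(rep1$histories, function(h) all(is.finite(h$loss)),
                         TRUE)))

  dir <- withr::local_tempdir()
  paths <- report_tables(rep1, dir)
  expect_true(all(file.exists(paths)))
  metrics_back <- read.csv(paths["metrics"])
  expect_equal(metrics_back$auc, rep1$metrics$auc)
  expect_identical(names(metrics_back),
                   c("combination", "acc", "acc_ci_lo", "acc_ci_hi", "auc",
                     "auc_ci_lo", "auc_ci_hi"))
  js <- jsonlite::read_json(paths["json"], simplifyVector = TRUE)
  expect_equal(js$metrics$auc, rep1$metrics$auc)
  expect_true(js$audit$pass)
})

test_that("inconsistent image sides are rejected up front", {
  cfg <- study_config("desk", combinations = 1L)
  cfg$image_side <- 32L   # raw override without rebuilding the model configs
  expect_error(run_study(cfg, quiet = TRUE), "image_side")
})

test_that("desk studies are bit-reproducible under one seed", {
  cfgs <- lapply(1:2, function(i) {
    study_config("desk", seed = 77L, combinations = 1L, image_side = 32L,
                 n_patients_standard = 6L, n_patients_pocus = 15L,
                 class_mix_pocus = c(normal = 1 / 3, benign = 1 / 3,
                                     malignant = 1 / 3),
                 test_fraction = 0.5, bootstrap_B = 20L, fid_dim = 8L,
                 train = list(lr = 3e-4, epochs = 2L, batch_size = 8L))
  })
  r1 <- run_study(cfgs[[1]], quiet = TRUE)
  r2 <- run_study(cfgs[[2]], quiet = TRUE)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$score_sets, r2$score_sets)
})
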