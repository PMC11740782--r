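# Cycle-consistent domain translation: losses, regimes, translation contract.

tiny_gan_config <- function(epochs = 2L, ...) {
  cyclegan_config(image_side = 16L, generator_width = 4L,
                  n_residual_blocks = 1L, discriminator_width = 4L,
                  epochs = epochs, seed = 0L, ...)
}

tiny_domain <- function(domain, seed, n = 6L) {
  cfg <- tiny_phantom_config()
  lapply(seq_len(n), function(i) {
    resize_to_input(generate_phantom("normal", domain, cfg,
                                     seed = seed + i)$pixels, 16L)
  })
}

test_that("least-squares adversarial loss hits its closed forms", {
  expect_equal(adversarial_loss(rep(1, 8), is_real = TRUE), 0)
  expect_equal(adversarial_loss(rep(0.5, 5), is_real = TRUE), 0.25)
  expect_equal(adversarial_loss(rep(0.5, 5), is_real = FALSE), 0.25)
  expect_equal(adversarial_loss(c(0, 1), is_real = TRUE), 0.5)
  expect_error(adversarial_loss(c(1, NaN), TRUE), "non-finite")
})

test_that("cycle loss is a weighted mean absolute difference", {
  x <- array(runif(32), c(4, 4, 1, 2))
  expect_equal(cycle_loss(x, x, 10), 0)
  expect_equal(cycle_loss(array(0, c(2, 2)), array(1, c(2, 2)), 10), 10)
  expect_equal(cycle_loss(x, x + 1, 0), 0)
  expect_error(cycle_loss(array(0, c(2, 2)), array(0, c(2, 3))), "shape")
})

test_that("configuration guards reject degenerate training setups", {
  expect_error(cyclegan_config(epochs = 0L), "epochs")
  expect_error(cyclegan_config(lambda_cycle = 0), "lambda_cycle")
  expect_error(train_cyclegan(list(), tiny_domain("pocus", 1), tiny_gan_config()),
               "non-empty")
  expect_error(
    train_cyclegan(list(matrix(0, 8, 8)), list(matrix(0, 16, 16)),
                   tiny_gan_config()),
    "preprocessed"
  )
})

test_that("desk training yields finite losses and valid-range output", {
  pair <- train_cyclegan(tiny_domain("standard", 100), tiny_domain("pocus", 200),
                         tiny_gan_config())
  expect_true(all(is.finite(unlist(pair$history[, -1]))))
  out <- translate_images(pair, tiny_domain("standard", 300, n = 2L))
  expect_true(all(vapply(out, function(m) {
    all(dim(m) == 16L) && min(m) >= 0 && max(m) <= 255
  }, TRUE)))
  # seeded determinism of the whole training
  pair2 <- train_cyclegan(tiny_domain("standard", 100),
                          tiny_domain("pocus", 200), tiny_gan_config())
  expect_identical(pair$history, pair2$history)
})

test_that("translator checkpoints round-trip with identical translations", {
  pair <- train_cyclegan(tiny_domain("standard", 500), tiny_domain("pocus", 600),
                         tiny_gan_config(epochs = 1L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(pair, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  probe <- tiny_domain("standard", 700, n = 2L)
  expect_identical(translate_images(back, probe), translate_images(pair, probe))
})

test_that("cyclegan1 shares one model across classes; cyclegan3 trains three", {
  cfg <- tiny_phantom_config()
  std <- generate_cohort(6L, c(1L, 2L),
                         class_mix = c(normal = 1 / 3, benign = 1 / 3,
                                       malignant = 1 / 3),
                         domain = "standard", config = cfg, seed = 51L)
  poc <- generate_cohort(6L, c(1L, 2L),
                         class_mix = c(normal = 1 / 3, benign = 1 / 3,
                                       malignant = 1 / 3),
                         domain = "pocus", config = cfg, seed = 52L)
  std$images <- lapply(std$images, resize_to_input, side = 16L)
  poc$images <- lapply(poc$images, resize_to_input, side = 16L)

  one <- train_regime(std, poc, tiny_gan_config(epochs = 1L), "cyclegan1")
  expect_named(one, c("normal", "benign", "malignant"))
  expect_identical(one$normal, one$benign)
  expect_identical(one$normal, one$malignant)

  three <- train_regime(std, poc, tiny_gan_config(epochs = 1L), "cyclegan3")
  expect_false(identical(three$normal, three$benign))
  expect_false(identical(three$normal$history, NULL))

  noben <- cohort_subset(poc, poc$meta$class != "benign")
  expect_error(train_regime(std, noben, tiny_gan_config(epochs = 1L),
                            "cyclegan3"), "benign")
})

test_that("translation conserves labels, patient ids and record count", {
  cfg <- tiny_phantom_config()
  std <- generate_cohort(5L, c(2L, 2L),
                         class_mix = c(normal = 1 / 3, benign = 1 / 3,
                                       malignant = 1 / 3),
                         domain = "standard", config = cfg, seed = 53L)
  std$images <- lapply(std$images, resize_to_input, side = 16L)
  pair <- train_cyclegan(std$images, tiny_domain("pocus", 400),
                         tiny_gan_config(epochs = 1L))
  translators <- setNames(rep(list(pair), 3),
                          c("normal", "benign", "malignant"))
  out <- translate_cohort(std, translators, provenance = "cyclegan1")
  expect_identical(nrow(out$meta), nrow(std$meta))
  expect_identical(out$meta$class, std$meta$class)
  expect_identical(out$meta$patient_id, std$meta$patient_id)
  expect_true(all(out$meta$domain == "translated"))
  expect_true(all(out$meta$provenance == "cyclegan1"))
  expect_true(is.numeric(out$meta$darkening))

  empty <- cohort_subset(std, rep(FALSE, nrow(std$meta)))
  out0 <- translate_cohort(empty, translators)
  expect_identical(nrow(out0$meta), 0L)

  expect_error(translate_cohort(std, translators["normal"]), "no translator")
})
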