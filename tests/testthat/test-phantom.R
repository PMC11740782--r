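# Synthetic two-domain phantom cohorts.

test_that("phantom generation is a pure function of its seed", {
  cfg <- tiny_phantom_config()
  a <- generate_phantom("normal", "standard", cfg, seed = 1L)
  b <- generate_phantom("normal", "standard", cfg, seed = 1L)
  expect_identical(a$pixels, b$pixels)
  expect_null(a$geometry)
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  c2 <- generate_phantom("normal", "standard", cfg, seed = 2L)
  expect_false(identical(a$pixels, c2$pixels))
})

test_that("unknown class or domain is rejected with an explicit message", {
  cfg <- tiny_phantom_config()
  expect_error(generate_phantom("cystic", "standard", cfg), "unknown class")
  expect_error(generate_phantom("normal", "mri", cfg), "unknown domain")
  expect_error(apply_domain_shift(matrix(0.5, 4, 4), "mri", cfg),
               "unknown domain")
})

test_that("the POCUS operator darkens a same-seed render", {
  cfg <- tiny_phantom_config(48L)
  std <- generate_phantom("malignant", "standard", cfg, seed = 7L)
  poc <- generate_phantom("malignant", "pocus", cfg, seed = 7L)
  expect_lt(mean(poc$pixels), mean(std$pixels))
  # same seed renders the same scattering geometry in both domains
  expect_equal(std$geometry, poc$geometry)
})

test_that("domain separation holds on at least 95% of 100 paired renders", {
  cfg <- tiny_phantom_config()
  darker <- vapply(1:100, function(i) {
    mean(generate_phantom("normal", "pocus", cfg, seed = i)$pixels) <
      mean(generate_phantom("normal", "standard", cfg, seed = i)$pixels)
  }, TRUE)
  expect_gte(mean(darker), 0.95)
})

test_that("benign lesions are hypoechoic relative to surrounding tissue", {
  cfg <- tiny_phantom_config(48L)
  rec <- generate_phantom("benign", "standard", cfg, seed = 3L)
  g <- rec$geometry
  n <- cfg$image_side
  row <- matrix(seq_len(n), n, n); col <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt(((col - g$cx) / g$r0)^2 + ((row - g$cy) / (0.7 * g$r0))^2)
  expect_lt(mean(rec$pixels[d < 0.6]), mean(rec$pixels[d > 1.3 & d < 2]))
})

test_that("domain operator: identity parameters, gamma arithmetic, dark mass", {
  cfg0 <- tiny_phantom_config(pocus_gamma = 1, pocus_noise_sigma = 0)
  x <- matrix(runif(16 * 16), 16)
  expect_equal(apply_domain_shift(x, "pocus", cfg0), x)

  cfg2 <- tiny_phantom_config(pocus_gamma = 2, pocus_noise_sigma = 0)
  expect_equal(apply_domain_shift(matrix(0.5, 8, 8), "pocus", cfg2),
               matrix(0.25, 8, 8))

  expect_error(apply_domain_shift(matrix(2, 4, 4), "pocus", cfg2),
               "scaled to \\[0, 1\\]")

  cfg <- tiny_phantom_config()
  set.seed(5)
  field <- matrix(runif(48 * 48, 0.05, 0.95), 48)
  poc <- apply_domain_shift(field, "pocus", cfg, seed = 1L)
  std <- apply_domain_shift(field, "standard", cfg, seed = 1L)
  expect_gte(mean(poc < 0.2), mean(std < 0.2))
})

test_that("cohorts are patient-grouped, seeded and class-balanced to the mix", {
  cfg <- tiny_phantom_config()
  co <- generate_cohort(10L, c(1L, 3L),
                        class_mix = c(normal = 1 / 3, benign = 1 / 3,
                                      malignant = 1 / 3),
                        domain = "pocus", config = cfg, seed = 5L)
  expect_true(nrow(co$meta) >= 10 && nrow(co$meta) <= 30)
  expect_lte(length(unique(co$meta$patient_id)), 10L)
  expect_true(all(co$meta$domain == "pocus"))

  co2 <- generate_cohort(10L, c(1L, 3L),
                         class_mix = c(normal = 1 / 3, benign = 1 / 3,
                                       malignant = 1 / 3),
                         domain = "pocus", config = cfg, seed = 5L)
  expect_identical(co$images, co2$images)
  expect_identical(co$meta, co2$meta)

  mix <- c(normal = 0.57, benign = 0.21, malignant = 0.22)
  big <- generate_cohort(200L, c(1L, 3L), mix, "pocus", cfg, seed = 11L)
  frac <- table(factor(big$meta$class, names(mix))) / nrow(big$meta)
  expect_true(all(abs(frac - mix) < 0.05))
})

test_that("exact image counts per patient honour a degenerate range", {
  co <- generate_cohort(6L, c(2L, 2L),
                        class_mix = c(normal = 1 / 3, benign = 1 / 3,
                                      malignant = 1 / 3),
                        domain = "standard", config = tiny_phantom_config(),
                        seed = 3L)
  expect_identical(nrow(co$meta), 12L)
  expect_true(all(table(co$meta$patient_id) == 2))
})

test_that("a class requested by the mix but given no patients is rejected", {
  expect_error(
    generate_cohort(3L, c(1L, 1L),
                    class_mix = c(normal = 0.9, benign = 0.06,
                                  malignant = 0.04),
                    domain = "pocus", config = tiny_phantom_config(),
                    seed = 1L),
    "receives no patients"
  )
})

test_that("cohorts round-trip through PNG + CSV manifests losslessly", {
  co <- tiny_cohort(n_patients = 4L)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$images, co$images)
  expect_identical(back$meta$patient_id, co$meta$patient_id)
  expect_identical(back$meta$class, co$meta$class)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(names(man)[1:5],
                   c("path", "patient_id", "class", "domain", "provenance"))
})

test_that("phantom configuration invariants are enforced", {
  expect_error(phantom_config(image_side = 16), ">= 32")
  expect_error(phantom_config(pocus_gamma = 0.8), "darkens")
  expect_error(phantom_config(annotation_probability = 1.2), "\\[0, 1\\]")
})
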