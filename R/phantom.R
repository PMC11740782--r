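#' Phantom generator configuration
#'
#' Parameters of the two-domain B-mode speckle phantom. The phantom emulates
#' the statistical structure of a cross-device breast-ultrasound cohort: a
#' brighter, cleaner "standard" (cart-based) domain and a darker, noisier
#' point-of-care (POCUS) domain, with three lesion classes. Speckle is
#' modelled as the squared magnitude of a PSF-smoothed complex Gaussian
#' scattering field (Rayleigh envelope), multiplied by a piecewise echogenicity
#' map and log-compressed; the POCUS operator applies gamma compression
#' (`pocus_gamma` > 1 pushes mass into the dark range) plus additive Gaussian
#' noise.
#'
#' @param image_side output image side in pixels (>= 32).
#' @param background_echogenicity mean background echo level in (0, 1].
#' @param speckle_psf_sigma Gaussian point-spread sigma, pixels.
#' @param lesion_radius_range lesion radius as a fraction of the side,
#'   `c(min, max)`.
#' @param malignant_boundary_harmonics number of sinusoidal harmonics
#'   perturbing the malignant boundary.
#' @param malignant_boundary_amplitude total relative amplitude of the
#'   boundary perturbation.
#' @param benign_intensity_multiplier echogenicity multiplier inside benign
#'   lesions, in (0, 1).
#' @param malignant_intensity_multiplier echogenicity multiplier inside
#'   malignant lesions, in (0, 1).
#' @param posterior_enhancement relative brightening of the column band below
#'   a benign lesion.
#' @param shadow_attenuation relative darkening of the column band below a
#'   malignant lesion, in (0, 1).
#' @param pocus_gamma gamma exponent of the POCUS domain operator (> 1 so the
#'   operator darkens).
#' @param pocus_noise_sigma standard deviation of the additive POCUS noise on
#'   the [0, 1] intensity scale.
#' @param standard_noise_sigma mild acquisition noise of the standard domain.
#' @param annotation_probability probability that caliper-like bright glyphs
#'   are burnt into an image.
#' @param contralateral_probability probability that a lesion patient with
#'   more than one image contributes one normal (contralateral) image.
#' @param seed default seed used when a generator call gives none.
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(image_side = 180L,
                           background_echogenicity = 0.55,
                           speckle_psf_sigma = 1.5,
                           lesion_radius_range = c(0.12, 0.26),
                           malignant_boundary_harmonics = 5L,
                           malignant_boundary_amplitude = 0.25,
                           benign_intensity_multiplier = 0.45,
                           malignant_intensity_multiplier = 0.30,
                           posterior_enhancement = 0.40,
                           shadow_attenuation = 0.55,
                           pocus_gamma = 1.8,
                           pocus_noise_sigma = 0.04,
                           standard_noise_sigma = 0.01,
                           annotation_probability = 0.10,
                           contralateral_probability = 0.10,
                           seed = 1L) {
  cfg <- list(
    image_side = as.integer(image_side),
    background_echogenicity = background_echogenicity,
    speckle_psf_sigma = speckle_psf_sigma,
    lesion_radius_range = lesion_radius_range,
    malignant_boundary_harmonics = as.integer(malignant_boundary_harmonics),
    malignant_boundary_amplitude = malignant_boundary_amplitude,
    benign_intensity_multiplier = benign_intensity_multiplier,
    malignant_intensity_multiplier = malignant_intensity_multiplier,
    posterior_enhancement = posterior_enhancement,
    shadow_attenuation = shadow_attenuation,
    pocus_gamma = pocus_gamma,
    pocus_noise_sigma = pocus_noise_sigma,
    standard_noise_sigma = standard_noise_sigma,
    annotation_probability = annotation_probability,
    contralateral_probability = contralateral_probability,
    seed = as.integer(seed)
  )
  if (cfg$image_side < 32L) stop_pocusda("image_side must be >= 32")
  if (cfg$background_echogenicity <= 0 || cfg$background_echogenicity > 1) {
    stop_pocusda("background_echogenicity must lie in (0, 1]")
  }
  for (p in c("annotation_probability", "contralateral_probability")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_pocusda("%s must lie in [0, 1]", p)
  }
  for (p in c("benign_intensity_multiplier", "malignant_intensity_multiplier",
              "shadow_attenuation")) {
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1) stop_pocusda("%s must lie in (0, 1)", p)
  }
  if (cfg$pocus_gamma < 1) {
    stop_pocusda("pocus_gamma must be >= 1 (the POCUS operator darkens)")
  }
  structure(cfg, class = "phantom_config")
}

# Smooth step used for soft lesion boundaries.
soft_mask <- function(d, edge = 1.5) 1 / (1 + exp((d - 1) / (edge / 10)))

# Echogenicity map: background with low-frequency horizontal banding and the
# class-specific lesion insert. Consumes RNG draws; callers seed.
echogenicity_map <- function(class_label, config) {
  n <- config$image_side
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  period <- n / runif(1, 2.5, 4)
  phase <- runif(1, 0, 2 * pi)
  e <- config$background_echogenicity * (1 + 0.15 * sin(2 * pi * row / period + phase))

  if (class_label == "normal") {
    return(list(map = pmax(e, 1e-3), geometry = NULL))
  }

  cy <- runif(1, 0.30, 0.55) * n
  cx <- runif(1, 0.35, 0.65) * n
  r0 <- runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2]) * n

  if (class_label == "benign") {
    ax <- r0            # wider than tall
    ay <- 0.7 * r0
    d <- sqrt(((col - cx) / ax)^2 + ((row - cy) / ay)^2)
    mask <- soft_mask(d)
    mult <- config$benign_intensity_multiplier
    e <- e * (1 - mask * (1 - mult))
    band <- abs(col - cx) < ax & row > cy + 0.5 * ay
    e[band] <- e[band] * (1 + config$posterior_enhancement)
  } else {
    dy <- row - cy
    dx <- col - cx
    theta <- atan2(dy, dx * 1.0)
    k <- config$malignant_boundary_harmonics
    amp <- config$malignant_boundary_amplitude
    ph <- runif(k, 0, 2 * pi)
    wob <- rep(0, length(theta))
    for (j in seq_len(k)) wob <- wob + sin((j + 1) * theta + ph[j])
    r_theta <- r0 * (1 + amp * wob / k)
    # taller than wide: shrink the horizontal axis
    d <- sqrt((dx / 0.7)^2 + dy^2) / pmax(r_theta, 1e-6)
    mask <- soft_mask(d)
    mult <- config$malignant_intensity_multiplier
    e <- e * (1 - mask * (1 - mult))
    band <- abs(col - cx) < 0.7 * r0 & row > cy + 0.5 * r0
    e[band] <- e[band] * (1 - config$shadow_attenuation)
  }
  list(map = pmax(e, 1e-3),
       geometry = list(cy = cy, cx = cx, r0 = r0, class = class_label))
}

# Rayleigh speckle: squared magnitude of a PSF-smoothed complex Gaussian
# scattering field, normalized to unit mean intensity.
speckle_field <- function(n, psf_sigma) {
  re <- matrix(rnorm(n * n), n, n)
  im <- matrix(rnorm(n * n), n, n)
  re <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(re), sigma = psf_sigma))
  im <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(im), sigma = psf_sigma))
  intensity <- re^2 + im^2
  intensity / mean(intensity)
}

#' Apply the acquisition-domain operator to a [0, 1] image
#'
#' The standard domain is identity plus mild Gaussian acquisition noise; the
#' POCUS domain applies gamma compression with exponent `pocus_gamma`
#' (darkening, pushing histogram mass toward 0) followed by additive zero-mean
#' Gaussian noise with standard deviation `pocus_noise_sigma`, then clips to
#' [0, 1].
#'
#' @param pixels numeric matrix with values in [0, 1].
#' @param domain `"standard"` or `"pocus"`.
#' @param config a [phantom_config()].
#' @param seed optional seed for the noise draw (`NULL`: current RNG stream).
#' @return A matrix of the same shape, values in [0, 1].
#' @export
apply_domain_shift <- function(pixels, domain, config = phantom_config(),
                               seed = NULL) {
  check_domain(domain)
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stop_pocusda("apply_domain_shift expects pixels scaled to [0, 1]")
  }
  with_seed(seed, {
    out <- if (domain == "standard") {
      pixels + rnorm(length(pixels), sd = config$standard_noise_sigma)
    } else {
      pixels^config$pocus_gamma +
        rnorm(length(pixels), sd = config$pocus_noise_sigma)
    }
    matrix(pmin(pmax(out, 0), 1), nrow(pixels), ncol(pixels))
  })
}

# Burn two small caliper-like '+' glyphs near the lesion depth. Grayscale
# only; emulates residual radiologist annotations.
burn_calipers <- function(img01, n) {
  for (i in 1:2) {
    r0 <- round(runif(1, 0.25, 0.75) * n)
    c0 <- round(runif(1, 0.2, 0.8) * n)
    rr <- pmax(1, pmin(n, (r0 - 2):(r0 + 2)))
    cc <- pmax(1, pmin(n, (c0 - 2):(c0 + 2)))
    img01[rr, c0] <- 0.95
    img01[r0, cc] <- 0.95
  }
  img01
}

#' Generate one phantom image
#'
#' Renders an echogenicity map for the requested class, multiplies it by a
#' Rayleigh speckle field, log-compresses, applies the acquisition-domain
#' operator, optionally burns caliper glyphs, and quantizes to 8 bits.
#' Output is a pure function of `(class_label, domain, config, seed)`; the
#' same seed renders the same underlying scattering field in both domains.
#'
#' @param class_label `"normal"`, `"benign"` or `"malignant"`.
#' @param domain `"standard"` or `"pocus"`.
#' @param config a [phantom_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return An `image_record`: list with `pixels` (matrix, values 0–255),
#'   `class_label`, `domain`, `patient_id` (`NA` until assigned by a cohort)
#'   and `provenance = "synthetic"`.
#' @export
generate_phantom <- function(class_label, domain, config = phantom_config(),
                             seed = config$seed) {
  check_class_label(class_label)
  check_domain(domain)
  with_seed(seed, {
    n <- config$image_side
    e <- echogenicity_map(class_label, config)
    s <- e$map * speckle_field(n, config$speckle_psf_sigma)
    cmp <- 30
    img01 <- pmin(log1p(cmp * s) / log1p(cmp * 3), 1)
    img01 <- apply_domain_shift(img01, domain, config)
    if (runif(1) < config$annotation_probability) {
      img01 <- burn_calipers(img01, n)
    }
    rec <- image_record(quantize8(img01), class_label, domain,
                        patient_id = NA_character_, provenance = "synthetic")
    rec$geometry <- e$geometry
    rec
  })
}

#' Construct an image record
#'
#' @param pixels numeric matrix on the 0–255 scale.
#' @param class_label,domain closed-vocabulary labels.
#' @param patient_id opaque patient identifier.
#' @param provenance free-text origin tag (e.g. `"synthetic"`, `"cyclegan1"`).
#' @return A list of class `image_record`.
#' @export
image_record <- function(pixels, class_label, domain, patient_id,
                         provenance = "synthetic") {
  check_class_label(class_label)
  check_domain(domain, allow_translated = TRUE)
  structure(
    list(pixels = pixels, class_label = class_label, domain = domain,
         patient_id = patient_id, provenance = provenance),
    class = "image_record"
  )
}

#' Build a cohort container from image records
#'
#' A `us_cohort` holds the pixel matrices alongside a manifest data frame
#' (`patient_id`, `class`, `domain`, `provenance`, optional `split`).
#'
#' @param records list of `image_record` objects.
#' @return An object of class `us_cohort`.
#' @export
as_cohort <- function(records) {
  meta <- data.frame(
    patient_id = vapply(records, function(r) as.character(r$patient_id), ""),
    class = vapply(records, function(r) r$class_label, ""),
    domain = vapply(records, function(r) r$domain, ""),
    provenance = vapply(records, function(r) r$provenance, ""),
    stringsAsFactors = FALSE
  )
  structure(list(images = lapply(records, `[[`, "pixels"), meta = meta),
            class = "us_cohort")
}

#' @export
print.us_cohort <- function(x, ...) {
  cat(sprintf(
    "us_cohort: %d images, %d patients (%s)\n",
    nrow(x$meta), length(unique(x$meta$patient_id)),
    paste(sprintf("%s=%d", names(table(x$meta$class)), table(x$meta$class)),
          collapse = ", ")
  ))
  invisible(x)
}

n_images <- function(cohort) nrow(cohort$meta)

#' Concatenate cohorts
#' @param ... `us_cohort` objects.
#' @return A single `us_cohort`.
#' @export
cohort_bind <- function(...) {
  parts <- list(...)
  cols <- unique(unlist(lapply(parts, function(p) names(p$meta))))
  meta <- do.call(rbind, lapply(parts, function(p) {
    m <- p$meta
    for (nm in setdiff(cols, names(m))) m[[nm]] <- NA
    m[, cols, drop = FALSE]
  }))
  if (!is.null(meta$split) && all(is.na(meta$split))) meta$split <- NULL
  structure(list(images = do.call(c, lapply(parts, `[[`, "images")),
                 meta = meta), class = "us_cohort")
}

#' Subset a cohort by row index
#' @param cohort a `us_cohort`.
#' @param idx integer or logical index into the manifest rows.
#' @return A `us_cohort`.
#' @export
cohort_subset <- function(cohort, idx) {
  structure(list(images = cohort$images[idx],
                 meta = cohort$meta[idx, , drop = FALSE]),
            class = "us_cohort")
}

#' Generate a patient-grouped phantom cohort
#'
#' Patients are allocated to a primary finding class by largest-remainder
#' apportionment of `class_mix` (so realized fractions track the mix), each
#' patient receives a uniform number of images in `images_per_patient_range`,
#' and lesion patients with at least two images may contribute one normal
#' contralateral image. All randomness derives from `seed`.
#'
#' @param n_patients number of patients (>= 1).
#' @param images_per_patient_range integer `c(min, max)` images per patient.
#' @param class_mix named numeric over `normal`, `benign`, `malignant`,
#'   summing to 1.
#' @param domain `"standard"` or `"pocus"`.
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return A `us_cohort`.
#' @export
generate_cohort <- function(n_patients, images_per_patient_range = c(1L, 3L),
                            class_mix = c(normal = 0.57, benign = 0.21,
                                          malignant = 0.22),
                            domain = "pocus", config = phantom_config(),
                            seed = config$seed) {
  check_domain(domain)
  if (n_patients < 1) stop_pocusda("n_patients must be >= 1")
  if (!all(sort(names(class_mix)) == sort(CLASS_LEVELS))) {
    stop_pocusda("class_mix must name exactly the classes %s",
                 paste(CLASS_LEVELS, collapse = ", "))
  }
  if (abs(sum(class_mix) - 1) > 1e-6) stop_pocusda("class_mix must sum to 1")
  class_mix <- class_mix[CLASS_LEVELS]

  # largest-remainder apportionment of patients to classes
  raw <- class_mix * n_patients
  counts <- floor(raw)
  rem <- n_patients - sum(counts)
  if (rem > 0) {
    order_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_frac[seq_len(rem)]] <- counts[order_frac[seq_len(rem)]] + 1
  }
  if (any(counts == 0 & class_mix > 0)) {
    stop_pocusda(
      "class '%s' receives no patients at n_patients = %d; increase the cohort",
      CLASS_LEVELS[which(counts == 0 & class_mix > 0)[1]], n_patients
    )
  }

  records <- with_seed(seed, {
    classes <- sample(rep(CLASS_LEVELS, times = counts))
    out <- list()
    for (p in seq_len(n_patients)) {
      pid <- sprintf("%s-P%04d", domain, p)
      ks <- seq(images_per_patient_range[1], images_per_patient_range[2])
      k <- ks[sample.int(length(ks), 1L)]
      img_classes <- rep(classes[p], k)
      if (classes[p] != "normal" && k >= 2 &&
          runif(1) < config$contralateral_probability) {
        img_classes[k] <- "normal"
      }
      for (i in seq_len(k)) {
        rec <- generate_phantom(
          img_classes[i], domain, config,
          seed = derive_seed(seed, domain, p, i)
        )
        rec$patient_id <- pid
        out[[length(out) + 1L]] <- rec
      }
    }
    out
  })
  as_cohort(records)
}

#' Write a cohort to disk (8-bit grayscale PNG + CSV manifest)
#'
#' @param cohort a `us_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path. The manifest has columns
#'   `path,patient_id,class,domain,provenance` (plus `split` when present).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("images/img%05d.png", seq_len(n_images(cohort)))
  for (i in seq_len(n_images(cohort))) {
    png::writePNG(cohort$images[[i]] / 255, file.path(dir, paths[i]))
  }
  manifest <- cbind(data.frame(path = paths, stringsAsFactors = FALSE),
                    cohort$meta)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `manifest.csv` and `images/`.
#' @return A `us_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  images <- lapply(manifest$path, function(p) {
    px <- png::readPNG(file.path(dir, p))
    if (length(dim(px)) == 3) px <- px[, , 1]
    round(px * 255)
  })
  meta <- manifest[, setdiff(names(manifest), "path"), drop = FALSE]
  structure(list(images = images, meta = meta), class = "us_cohort")
}
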