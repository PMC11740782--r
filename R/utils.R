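#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded generators never perturb user code.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage tag, kept within the
# 32-bit signed range required by set.seed().
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (tok in c(...)) {
    for (ch in utf8ToInt(as.character(tok))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

# Content key for the leakage audit: a cheap deterministic fingerprint of a
# pixel matrix. Two fixed pseudo-random projections plus shape and total make
# accidental collisions between distinct images negligible at cohort scale.
image_key <- function(pixels) {
  v <- as.double(pixels)
  n <- length(v)
  i <- seq_len(n)
  w1 <- sin(0.7071 * i)
  w2 <- cos(0.3183 * i)
  sprintf(
    "%dx%d:%.6e:%.6e:%.6e", nrow(pixels), ncol(pixels),
    sum(v), sum(v * w1), sum(v * w2)
  )
}

stop_pocusda <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

CLASS_LEVELS <- c("normal", "benign", "malignant")
DOMAIN_LEVELS <- c("standard", "pocus", "translated")

check_class_label <- function(class_label) {
  if (length(class_label) != 1L || !class_label %in% CLASS_LEVELS) {
    stop_pocusda(
      "unknown class label '%s' (expected one of %s)",
      paste(class_label, collapse = ","), paste(CLASS_LEVELS, collapse = ", ")
    )
  }
  class_label
}

check_domain <- function(domain, allow_translated = FALSE) {
  levels <- if (allow_translated) DOMAIN_LEVELS else DOMAIN_LEVELS[1:2]
  if (length(domain) != 1L || !domain %in% levels) {
    stop_pocusda(
      "unknown domain '%s' (expected one of %s)",
      paste(domain, collapse = ","), paste(levels, collapse = ", ")
    )
  }
  domain
}

# Clamp to [0,1] then quantize to the 8-bit integer grid (stored as doubles
# 0..255 so downstream arithmetic stays numeric).
quantize8 <- function(x01) {
  round(pmin(pmax(x01, 0), 1) * 255)
}
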