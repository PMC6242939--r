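# Internal helpers shared across modules.

# Outlier flags by distance from the median in normal-consistent MAD units
# (stats::mad already applies the 1.4826 factor). `side` gives the
# direction in which a value counts as an outlier. Zero-spread metrics
# (MAD = 0) flag nothing. NA metric values are flagged as failures:
# a cell on which a quality metric cannot be computed is not trusted.
mad_outlier <- function(x, n_mads, side = c("both", "upper", "lower")) {
  side <- match.arg(side)
  med <- median(x, na.rm = TRUE)
  dev <- mad(x, na.rm = TRUE)
  hi <- med + n_mads * dev
  lo <- med - n_mads * dev
  out <- switch(side,
    both = x > hi | x < lo,
    upper = x > hi,
    lower = x < lo)
  out[is.na(x)] <- TRUE
  if (is.na(dev) || dev == 0) out[!is.na(x)] <- FALSE
  out
}

# Derive a per-stage 32-bit seed from a global seed and a stage name so
# pipeline stages are individually reproducible.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Centered moving mean with truncated windows at the boundaries.
moving_mean <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# Adjusted Rand index between two labelings (chance-corrected agreement).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (mx - expected)
}

# Spearman correlation that tolerates constant vectors (returns NA).
spearman <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

# Evaluate `code` under its own RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards (generators are pure functions of
# their config and never perturb global randomness).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_positive <- function(value, field) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0))
    stop("configuration error: `", field, "` must be positive and finite")
  invisible(value)
}

check_fraction <- function(value, field, open = TRUE) {
  if (!is.numeric(value) || !is.finite(value) ||
      (open && (value <= 0 || value >= 1)) ||
      (!open && (value < 0 || value > 1)))
    stop("configuration error: `", field, "` must lie in ",
         if (open) "(0,1)" else "[0,1]")
  invisible(value)
}

check_count <- function(value, field, min = 1) {
  if (!is.numeric(value) || !is.finite(value) || value < min ||
      value != round(value))
    stop("configuration error: `", field, "` must be an integer >= ", min)
  invisible(value)
}
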