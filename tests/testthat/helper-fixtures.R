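# Shared fixtures built in code.

# The published validation confusion counts (350 fruit): estimated class,
# actual class, n. Used as label vectors for confusion-table tests.
study_confusion_counts <- function() {
  tibble::tribble(
    ~estimated, ~actual, ~n,
    "Extra", "Extra", 103L,
    "Extra", "I", 28L,
    "I", "Extra", 13L,
    "I", "I", 85L,
    "I", "II", 13L,
    "II", "II", 82L,
    "Reject", "Reject", 26L
  )
}

expand_labels <- function(counts) {
  list(
    estimated = rep(counts$estimated, counts$n),
    actual = rep(counts$actual, counts$n)
  )
}

# Brute-force Otsu oracle: scan every threshold, compute the within-class
# variance from first principles. Deliberately written differently from the
# package implementation (explicit split + stats::var-style moments).
otsu_oracle <- function(img) {
  v <- as.numeric(img)
  n <- length(v)
  best_t <- NA_integer_
  best_w <- Inf
  for (t in 0:255) {
    lo <- v[v < t]
    hi <- v[v >= t]
    wcv <- 0
    if (length(lo) > 0) wcv <- wcv + length(lo) / n * mean((lo - mean(lo))^2)
    if (length(hi) > 0) wcv <- wcv + length(hi) / n * mean((hi - mean(hi))^2)
    if (wcv < best_w - 1e-12) {
      best_w <- wcv
      best_t <- t
    }
  }
  best_t
}

# A small measurement table with known values (weights in g, sizes in mm,
# PA in cm^2), reused by model and grading tests.
reference_means <- function() {
  tibble::tibble(
    weight_g = 97.9, length_mm = 65.9, mades_mm = 54.1, pa_cm2 = 33.7
  )
}
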