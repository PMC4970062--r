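#' Morphometric statistics of Hayward kiwifruit by grade class
#'
#' Built-in per-class means and standard deviations of weight (g), length
#' (mm), MaDES (mm), MiDES (mm), projected area (cm^2) and volume (cm^3) for
#' a 490-fruit Hayward reference population, plus the pooled "Total" row.
#' These are the default targets of the population sampler.
#'
#' @return A tibble with columns `class`, `n`, and `<var>_mean` /
#'   `<var>_sd` for the six variables.
#' @export
kiwi_class_stats <- function() {
  tibble::tribble(
    ~class, ~n,
    ~weight_g_mean, ~weight_g_sd, ~length_mm_mean, ~length_mm_sd,
    ~mades_mm_mean, ~mades_mm_sd, ~mides_mm_mean, ~mides_mm_sd,
    ~pa_cm2_mean, ~pa_cm2_sd, ~volume_cm3_mean, ~volume_cm3_sd,
    "Extra", 163L, 113.0, 15.0, 70.9, 7.5, 56.9, 6.6, 49.9, 7.0, 37.8, 4.4, 108.7, 14.9,
    "I", 157L, 90.7, 19.0, 63.6, 4.7, 52.4, 5.3, 44.1, 2.2, 31.7, 5.8, 86.5, 18.5,
    "II", 133L, 80.8, 28.2, 59.4, 4.6, 51.4, 10.6, 42.5, 3.1, 29.1, 9.1, 77.5, 27.1,
    "Reject", 37L, 64.0, 0.7, 58.8, 2.6, 47.1, 3.3, 41.4, 3.4, 24.3, 0.7, 61.8, 2.4,
    "Total", 490L, 97.9, 23.6, 65.9, 7.5, 54.1, 7.5, 46.2, 5.8, 33.7, 7.0, 93.9, 22.9
  )
}

pop_vars <- c("weight_g", "length_mm", "mades_mm", "mides_mm", "pa_cm2",
              "volume_cm3")

#' Default correlation among the morphometric variables
#'
#' The joint distribution of real fruit is not published, so the sampler
#' uses a fixed positive-definite convention: linear sizes are moderately
#' correlated, projected area tracks length x MaDES, and volume tracks
#' weight closely (fruit density ~ 1 g/cm^3).
#'
#' @return A 6 x 6 correlation matrix over
#'   `(weight_g, length_mm, mades_mm, mides_mm, pa_cm2, volume_cm3)`.
#' @export
default_correlation <- function() {
  r <- matrix(c(
    1.00, 0.70, 0.72, 0.70, 0.75, 0.97,
    0.70, 1.00, 0.95, 0.85, 0.93, 0.70,
    0.72, 0.95, 1.00, 0.95, 0.93, 0.72,
    0.70, 0.85, 0.95, 1.00, 0.85, 0.70,
    0.75, 0.93, 0.93, 0.85, 1.00, 0.75,
    0.97, 0.70, 0.72, 0.70, 0.75, 1.00
  ), 6, 6, dimnames = list(pop_vars, pop_vars))
  r
}

#' Specification of a synthetic fruit population
#'
#' @param stats A class-statistics table as returned by [kiwi_class_stats()];
#'   use the rows you want to sample from (the `"Total"` row is skipped when
#'   per-class rows are present).
#' @param n Total number of fruit; allocated to classes proportionally to
#'   `stats$n`. `NULL` uses `stats$n` as-is.
#' @param correlation Correlation matrix over the six variables.
#' @param flattened_fraction Named per-class fractions of *heavy* fruit
#'   (sampled weight >= 90 g) that are turned into flattened fruit: their
#'   MaDES is inflated until the MMR falls into the class's shape band
#'   (0.7-0.8 for class I, below 0.7 for class II). Heavy class I and II
#'   fruit are flattened by default (fraction 1): a fruit whose weight alone
#'   would put it in Extra belongs to a lower class precisely because its
#'   shape disqualifies it, so leaving such draws round would create fruit
#'   the class definitions rule out.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(stats = kiwi_class_stats(), n = NULL,
                            correlation = default_correlation(),
                            flattened_fraction = c(I = 1, II = 1)) {
  if (nrow(stats) > 1L) stats <- stats[stats$class != "Total", , drop = FALSE]
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("infeasible correlation matrix (not positive definite)", call. = FALSE)
  }
  sds <- as.matrix(stats[, paste0(pop_vars, "_sd")])
  if (any(sds < 0)) stop("standard deviations must be non-negative", call. = FALSE)
  if (!is.null(n)) {
    alloc <- round(n * stats$n / sum(stats$n))
    alloc[1] <- alloc[1] + n - sum(alloc)
    stats$n <- as.integer(alloc)
  }
  structure(
    list(stats = stats, correlation = correlation,
         flattened_fraction = flattened_fraction),
    class = "population_spec"
  )
}

# truncated (all-positive) multivariate normal draw; zero-SD dimensions are
# held at their mean
sample_class_rows <- function(n, mu, sd, corr) {
  live <- sd > 0
  out <- matrix(rep(mu, each = n), n, length(mu),
                dimnames = list(NULL, names(mu)))
  if (any(live) && n > 0) {
    sigma <- diag(sd[live], sum(live)) %*% corr[live, live, drop = FALSE] %*%
      diag(sd[live], sum(live))
    draw <- function(k) MASS::mvrnorm(k, mu[live], sigma)
    x <- matrix(draw(n), ncol = sum(live))
    for (i in 1:50) {
      bad <- which(apply(x, 1, function(r) any(r <= 0)))
      if (length(bad) == 0L) break
      x[bad, ] <- matrix(draw(length(bad)), ncol = sum(live))
    }
    out[, live] <- x
  }
  out
}

#' Sample a synthetic fruit population
#'
#' Draws per-class truncated multivariate normal fruit with the means, SDs
#' and correlations of the spec, optionally injects the flattened
#' subpopulation, and then recomputes each fruit's actual grade class from
#' its sampled weight and true MMR via [assign_grade()]. The recomputed
#' class can disagree with the generating class near the weight and MMR
#' thresholds; that disagreement is deliberate and is what makes the
#' population a realistic fixture for confusion analysis.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed (same seed, same table).
#' @return A tibble with `generating_class`, the six variables, `mmr_true`,
#'   `mlr_true` and `actual` (ordered grade factor).
#' @export
sample_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  stats <- spec$stats
  rows <- purrr::map(seq_len(nrow(stats)), function(i) {
    n <- stats$n[i]
    mu <- setNames(as.numeric(stats[i, paste0(pop_vars, "_mean")]), pop_vars)
    sd <- setNames(as.numeric(stats[i, paste0(pop_vars, "_sd")]), pop_vars)
    x <- tibble::as_tibble(sample_class_rows(n, mu, sd, spec$correlation))
    x$generating_class <- stats$class[i]
    frac <- spec$flattened_fraction[stats$class[i]]
    if (n > 0 && length(frac) == 1L && !is.na(frac) && frac > 0) {
      flat <- x$weight_g >= 90 & runif(n) < frac
      if (any(flat)) {
        k <- sum(flat)
        # inflate MaDES until the MMR lands in the class's shape band
        mmr_band <- if (stats$class[i] == "I") c(0.705, 0.795) else c(0.60, 0.69)
        x$mades_mm[flat] <- x$mides_mm[flat] / runif(k, mmr_band[1], mmr_band[2])
        # projected area and volume follow the new footprint / weight
        kappa <- mu["pa_cm2"] / (mu["length_mm"] * mu["mades_mm"])
        x$pa_cm2[flat] <- kappa * x$length_mm[flat] * x$mades_mm[flat]
        x$volume_cm3[flat] <- x$weight_g[flat] * mu["volume_cm3"] / mu["weight_g"]
      }
    }
    x
  })
  out <- dplyr::bind_rows(rows)
  out$mmr_true <- out$mides_mm / out$mades_mm
  out$mlr_true <- out$mades_mm / out$length_mm
  out$actual <- assign_grade(out$weight_g, out$mmr_true)
  dplyr::relocate(out, "generating_class")
}
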