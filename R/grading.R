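#' Grade classes, ordered
#'
#' The four grade classes as an ordered factor,
#' `Reject < II < I < Extra`. The ordering is what "classified above the
#' actual class" (overgrading) refers to.
#'
#' @param x A character vector of class names (or factor).
#' @return An ordered factor.
#' @export
grade_factor <- function(x = character()) {
  factor(as.character(x), levels = c("Reject", "II", "I", "Extra"), ordered = TRUE)
}

#' FFV-46 grading rule
#'
#' Minimum weight and minimum MMR (MiDES/MaDES ratio) per class:
#' Extra needs `>= 90` g and MMR `>= 0.8`; class I needs `>= 70` g and MMR
#' `>= 0.7`; class II needs `>= 65` g with no shape requirement. Anything
#' else is Reject. Both thresholds are inclusive.
#'
#' @param extra,class_i,class_ii Length-2 numeric `c(min_weight_g, min_mmr)`
#'   overrides; use `-Inf` for "no requirement".
#' @return A tibble with columns `class`, `min_weight_g`, `min_mmr`, ordered
#'   from the highest class down.
#' @export
grade_rule <- function(extra = c(90, 0.8), class_i = c(70, 0.7),
                       class_ii = c(65, -Inf)) {
  rule <- tibble::tibble(
    class = c("Extra", "I", "II"),
    min_weight_g = c(extra[1], class_i[1], class_ii[1]),
    min_mmr = c(extra[2], class_i[2], class_ii[2])
  )
  if (is.unsorted(rev(rule$min_weight_g), strictly = TRUE)) {
    stop("weight thresholds must strictly decrease from Extra down", call. = FALSE)
  }
  if (is.unsorted(rev(rule$min_mmr))) {
    stop("MMR thresholds must be non-increasing from Extra down", call. = FALSE)
  }
  rule
}

#' Assign grade classes from weight and MMR
#'
#' Returns, for each fruit, the first class (from Extra down) whose weight
#' and MMR requirements are both met, or Reject. A fruit below the class II
#' weight floor is Reject no matter its shape.
#'
#' @param weight_g Weights in grams.
#' @param mmr MiDES/MaDES ratios (estimated or measured).
#' @param rule A [grade_rule()].
#' @return An ordered factor (see [grade_factor()]).
#' @examples
#' assign_grade(c(95, 95, 95, 64), c(0.85, 0.75, 0.65, 0.95))
#' @export
assign_grade <- function(weight_g, mmr, rule = grade_rule()) {
  stopifnot(length(weight_g) == length(mmr))
  out <- rep("Reject", length(weight_g))
  for (i in rev(seq_len(nrow(rule)))) { # lowest class first, higher overwrite
    ok <- weight_g >= rule$min_weight_g[i] & mmr >= rule$min_mmr[i]
    out[ok] <- rule$class[i]
  }
  out[is.na(weight_g) | is.na(mmr)] <- NA
  grade_factor(out)
}

#' Grade a measurement table
#'
#' Adds a `grade` column computed by [assign_grade()] from `weight_g` and
#' `mmr`. Run [estimate_fruit()] first to obtain `mmr` from the estimated
#' MiDES, or supply a measured one.
#'
#' @param data A data frame with `weight_g` and `mmr` columns.
#' @param rule A [grade_rule()].
#' @param mmr_col Column to use as MMR (default `"mmr"`).
#' @return `data` with a `grade` column appended.
#' @export
grade_fruit <- function(data, rule = grade_rule(), mmr_col = "mmr") {
  stopifnot(all(c("weight_g", mmr_col) %in% names(data)))
  data <- tibble::as_tibble(data)
  data$grade <- assign_grade(data$weight_g, data[[mmr_col]], rule = rule)
  data
}
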