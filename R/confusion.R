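#' Confusion table of estimated versus actual grade classes
#'
#' @param estimated,actual Vectors of grade classes (coerced with
#'   [grade_factor()]); equal length.
#' @return An object of class `grade_confusion`: a 4 x 4 count matrix with
#'   estimated classes in rows and actual classes in columns, both ordered
#'   Extra, I, II, Reject.
#' @export
build_confusion <- function(estimated, actual) {
  if (length(estimated) != length(actual)) {
    stop("`estimated` and `actual` must have the same length", call. = FALSE)
  }
  lev <- c("Extra", "I", "II", "Reject") # display order, highest first
  tab <- table(
    estimated = factor(as.character(estimated), levels = lev),
    actual = factor(as.character(actual), levels = lev)
  )
  structure(unclass(tab), class = "grade_confusion")
}

#' @export
print.grade_confusion <- function(x, ...) {
  cat("Estimated (rows) x actual (columns) grade classes,",
      sum(x), "fruit\n")
  print(unclass(x))
  cat(sprintf(
    "correctly classified: %.1f%%; overgraded: %d (%.1f%%)\n",
    classification_rate(x), overgrade_count(x)$count, overgrade_count(x)$percent
  ))
  invisible(x)
}

#' @export
tidy.grade_confusion <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(as.table(unclass(x)),
                                         stringsAsFactors = FALSE))
  names(out) <- c("estimated", "actual", "n")
  out
}

#' Overall classification success rate
#'
#' @param ct A `grade_confusion` table.
#' @return Percentage of fruit whose estimated class equals the actual one,
#'   in \[0, 100\]. Report it to one decimal, as grading rates usually are.
#' @export
classification_rate <- function(ct) {
  stopifnot(inherits(ct, "grade_confusion"))
  total <- sum(ct)
  if (total == 0L) stop("empty confusion table", call. = FALSE)
  100 * sum(diag(ct)) / total
}

#' Overgraded fruit: estimated class above the actual one
#'
#' Overgrading (shipping a fruit in a class above its true one) is the
#' economically critical error; this counts every cell above the diagonal in
#' class order.
#'
#' @param ct A `grade_confusion` table.
#' @return A list with `count` and `percent` of the table total.
#' @export
overgrade_count <- function(ct) {
  stopifnot(inherits(ct, "grade_confusion"))
  lev <- grade_factor(rownames(ct))
  est <- lev[row(ct)]
  act <- lev[col(ct)]
  n <- sum(ct[est > act])
  list(count = n, percent = 100 * n / sum(ct))
}

#' Misgrade rates per actual class
#'
#' @param ct A `grade_confusion` table.
#' @return A tibble with, per actual class, the number of fruit, the number
#'   graded into a different class, and the misgrade percentage.
#' @export
misgrade_by_class <- function(ct) {
  stopifnot(inherits(ct, "grade_confusion"))
  n_class <- colSums(ct)
  wrong <- n_class - diag(ct)
  tibble::tibble(
    actual = colnames(ct),
    n = as.integer(n_class),
    misgraded = as.integer(wrong),
    percent = ifelse(n_class > 0, 100 * wrong / n_class, NA_real_)
  )
}

#' Heatmap of a confusion table
#'
#' @param object A `grade_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grade_confusion <- function(object, ...) {
  d <- tidy(object)
  d$estimated <- factor(d$estimated, levels = rev(rownames(object)))
  d$actual <- factor(d$actual, levels = colnames(object))
  ggplot2::ggplot(d, ggplot2::aes(.data$actual, .data$estimated,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "actual class", y = "estimated class", fill = "fruit")
}
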