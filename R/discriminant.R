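#' Fit a two-class linear discriminant line in shape-ratio space
#'
#' Equal-covariance linear discriminant between two grade groups in a
#' two-dimensional feature plane (by default length/MaDES versus length/PA,
#' the pair that separates flattened fruit from well-formed ones). With
#' pooled covariance `S` and group means `m1`, `m2`, the boundary is the
#' line `w . x = c` with `w = S^-1 (m1 - m2)` and `c = w . (m1 + m2) / 2`
#' (equal priors).
#'
#' @param data A data frame holding the features and a group column.
#' @param group Name of the group (class label) column.
#' @param classes Length-2 character: the positive-side class first. Rows
#'   with other labels are ignored; the second class is also the label
#'   returned for the negative side.
#' @param features Length-2 character naming the feature columns.
#' @param priors `"proportional"` (default) weighs the cutoff by the group
#'   sizes, `c = w.(m1+m2)/2 - log(n1/n2)`, the usual LDA rule with
#'   empirical priors; `"equal"` drops the prior term and puts the boundary
#'   midway between the group means.
#' @return An object of class `discriminant_line` with elements `w`
#'   (named weights), `c` (cutoff), `features`, `class_pos`, `class_neg`,
#'   and `slope`/`intercept` of the boundary in the feature plane
#'   (`intercept = NA` and a vertical `x = c/w1` boundary when `w2 = 0`).
#' @export
fit_discriminant <- function(data, group, classes,
                             features = c("length_mades", "length_pa"),
                             priors = c("proportional", "equal")) {
  stopifnot(length(classes) == 2L, length(features) == 2L)
  priors <- match.arg(priors)
  g <- as.character(data[[group]])
  x1 <- as.matrix(data[g == classes[1], features])
  x2 <- as.matrix(data[g == classes[2], features])
  if (nrow(x1) < 2L || nrow(x2) < 2L) {
    stop("need at least 2 points per group", call. = FALSE)
  }
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  s_pooled <- ((nrow(x1) - 1) * stats::cov(x1) + (nrow(x2) - 1) * stats::cov(x2)) /
    (nrow(x1) + nrow(x2) - 2)
  w <- tryCatch(
    drop(solve(s_pooled, m1 - m2)),
    error = function(e) stop("degenerate groups: pooled covariance is singular",
                             call. = FALSE)
  )
  if (all(w == 0)) stop("groups have identical means", call. = FALSE)
  cutoff <- sum(w * (m1 + m2) / 2)
  if (priors == "proportional") cutoff <- cutoff - log(nrow(x1) / nrow(x2))
  structure(
    list(
      w = setNames(w, features),
      c = cutoff,
      features = features,
      class_pos = classes[1],
      class_neg = classes[2],
      slope = if (w[2] != 0) -w[1] / w[2] else Inf,
      intercept = if (w[2] != 0) cutoff / w[2] else NA_real_
    ),
    class = "discriminant_line"
  )
}

#' @export
print.discriminant_line <- function(x, ...) {
  cat(sprintf(
    "<discriminant_line> %s vs %s in (%s, %s): %.4g*x + %.4g*y = %.4g\n",
    x$class_pos, x$class_neg, x$features[1], x$features[2],
    x$w[1], x$w[2], x$c
  ))
  invisible(x)
}

#' Classify points with a discriminant line
#'
#' @param object A `discriminant_line`.
#' @param newdata A data frame with the line's feature columns.
#' @param on_line Class given to points exactly on the boundary; by default
#'   the lower of the two grades (conservative grading).
#' @param ... Unused.
#' @return A character vector of class labels.
#' @export
predict.discriminant_line <- function(object, newdata,
                                      on_line = c("lower", "upper"), ...) {
  on_line <- match.arg(on_line)
  score <- as.matrix(newdata[, object$features]) %*% object$w - object$c
  pair <- grade_factor(c(object$class_pos, object$class_neg))
  lower <- as.character(object$class_pos)
  if (!anyNA(pair)) lower <- as.character(pair[which.min(as.integer(pair))])
  tie <- if (on_line == "lower") lower else
    setdiff(c(object$class_pos, object$class_neg), lower)[1]
  out <- ifelse(drop(score) > 0, object$class_pos,
                ifelse(drop(score) < 0, object$class_neg, tie))
  out
}

# re-derive slope/intercept after a cutoff change
refresh_line_geometry <- function(line) {
  line$slope <- if (line$w[2] != 0) -line$w[1] / line$w[2] else Inf
  line$intercept <- if (line$w[2] != 0) line$c / line$w[2] else NA_real_
  line
}

# slide the cutoff along the discriminant direction to the position with the
# fewest training misclassifications; among ties prefer moving fewer fruit
# (conservative grading)
tune_line_cutoff <- function(line, data, actual) {
  scores <- drop(as.matrix(data[, line$features]) %*% line$w)
  is_pos <- as.character(actual) == line$class_pos
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  errs <- vapply(cand, function(cc) {
    sum(is_pos & scores <= cc) + sum(!is_pos & scores > cc)
  }, numeric(1))
  best <- which(errs == min(errs))
  line$c <- cand[max(best)] # highest cutoff: fewest fruit moved to class_pos
  refresh_line_geometry(line)
}

#' Fit the reclassification line set from graded fruit with known classes
#'
#' Reclassification corrects the grades of fruit whose estimated class is
#' Extra or I, the classes polluted by MiDES estimation error. Within the
#' estimated-Extra group a single line separates actual Extra from actual
#' class I; within the estimated-I group one line splits off actual class II
#' and a second splits off actual Extra. Estimated II and Reject are never
#' touched.
#'
#' @param data A data frame with the ratio features, an estimated-grade
#'   column and an actual-grade column.
#' @param grade_col,actual_col Column names (defaults `"grade"`,
#'   `"actual"`).
#' @param features Feature pair, as in [fit_discriminant()].
#' @param tune_cutoff Slide each line's cutoff along its discriminant
#'   direction to the minimum-training-error position, and keep the line
#'   only if it strictly reduces the misclassification count within its
#'   context (default `TRUE`). This mirrors how separating lines are placed
#'   by inspection in practice and guarantees reclassification never hurts
#'   on the data the lines were fitted to. With `FALSE` the plain
#'   prior-weighted LDA cutoffs are kept.
#' @return A named list of class `grade_reclassifier`: element `Extra` holds
#'   up to one `discriminant_line` (actual I versus actual Extra), element
#'   `I` up to two (actual II, then actual Extra, against the rest). Lines
#'   whose training group is absent (fewer than 2 fruit) or that do not
#'   help are omitted; an empty context passes fruit through unchanged.
#' @export
fit_reclassifier <- function(data, grade_col = "grade", actual_col = "actual",
                             features = c("length_mades", "length_pa"),
                             tune_cutoff = TRUE) {
  est <- as.character(data[[grade_col]])
  try_line <- function(d, classes) {
    tryCatch(
      fit_discriminant(d, group = actual_col, classes = classes,
                       features = features),
      error = function(e) NULL
    )
  }
  # within a context, contrast one actual class against everything else
  contrast <- function(d, target, rest) {
    d[[actual_col]] <- ifelse(as.character(d[[actual_col]]) == target,
                              target, rest)
    d
  }
  fit_context <- function(context, targets) {
    d <- data[est == context, , drop = FALSE]
    cand <- purrr::compact(setNames(
      purrr::map(targets, function(f) try_line(contrast(d, f, context),
                                               c(f, context))),
      targets
    ))
    if (!tune_cutoff || nrow(d) == 0L) return(cand)
    actual <- d[[actual_col]]
    context_errors <- function(lns) {
      if (length(lns) == 0L) return(sum(as.character(actual) != context))
      r <- reclassify_grades(d, structure(setNames(list(lns), context),
                                          class = "grade_reclassifier"),
                             grade_col = grade_col)
      sum(as.character(r$grade_final) != as.character(actual))
    }
    kept <- list()
    for (nm in names(cand)) {
      tuned <- tune_line_cutoff(cand[[nm]], d, contrast(d, nm, context)[[actual_col]])
      trial <- c(kept, setNames(list(tuned), nm))
      if (context_errors(trial) < context_errors(kept)) kept <- trial
    }
    kept
  }
  structure(
    list(Extra = fit_context("Extra", "I"),
         I = fit_context("I", c("II", "Extra"))),
    class = "grade_reclassifier"
  )
}

#' Reclassify estimated grades with discriminant lines
#'
#' Applies a line set (see [fit_reclassifier()]) to a graded table: fruit
#' estimated Extra or I are re-examined in ratio space and moved to the class
#' their side of the line(s) indicates; estimated II and Reject pass through
#' unchanged. For contexts with several lines, the first line that votes the
#' fruit out of its context class wins. The operation is idempotent for a
#' fixed line set.
#'
#' @param data A data frame with the feature columns and a grade column.
#' @param lines A `grade_reclassifier` (or a compatible named list of
#'   `discriminant_line` objects).
#' @param grade_col Input grade column (default `"grade"`).
#' @param out_col Output column (default `"grade_final"`).
#' @param on_line Tie rule for points on a line, see
#'   [predict.discriminant_line()].
#' @return `data` with `out_col` appended (ordered grade factor).
#' @export
reclassify_grades <- function(data, lines, grade_col = "grade",
                              out_col = "grade_final", on_line = "lower") {
  stopifnot(grade_col %in% names(data))
  grade <- as.character(data[[grade_col]])
  final <- grade
  for (context in c("Extra", "I")) {
    rows <- which(grade == context)
    if (length(rows) == 0L) next
    if (!context %in% names(lines)) {
      stop("no discriminant line configured for estimated class ", context,
           call. = FALSE)
    }
    ctx_lines <- lines[[context]] # empty set = trained group was pure
    if (length(ctx_lines) == 0L) next
    if (inherits(ctx_lines, "discriminant_line")) ctx_lines <- list(ctx_lines)
    verdict <- rep(context, length(rows))
    undecided <- rep(TRUE, length(rows))
    for (ln in ctx_lines) {
      p <- predict(ln, data[rows, , drop = FALSE], on_line = on_line)
      move <- undecided & p != context
      verdict[move] <- p[move]
      undecided <- undecided & !move
    }
    final[rows] <- verdict
  }
  data <- tibble::as_tibble(data)
  data[[out_col]] <- grade_factor(final)
  data
}

#' Serialize discriminant line sets to / from JSON
#'
#' @param lines A `grade_reclassifier`.
#' @param path Output file; if `NULL` the JSON string is returned.
#' @return `lines_from_json` returns a `grade_reclassifier`.
#' @export
lines_to_json <- function(lines, path = NULL) {
  ser <- function(ln) {
    list(w = as.list(ln$w), c = ln$c, features = ln$features,
         class_pos = ln$class_pos, class_neg = ln$class_neg)
  }
  obj <- purrr::map(lines, function(x) {
    if (inherits(x, "discriminant_line")) ser(x) else purrr::map(x, ser)
  })
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname lines_to_json
#' @param json A JSON string or file path.
#' @export
lines_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  deser <- function(o) {
    w <- unlist(o$w)
    structure(
      list(
        w = w, c = o$c, features = unlist(o$features),
        class_pos = o$class_pos, class_neg = o$class_neg,
        slope = if (w[2] != 0) -w[1] / w[2] else Inf,
        intercept = if (w[2] != 0) o$c / w[2] else NA_real_
      ),
      class = "discriminant_line"
    )
  }
  out <- purrr::map(obj, function(x) {
    if (!is.null(x$w)) deser(x) else purrr::map(x, deser)
  })
  structure(out, class = "grade_reclassifier")
}

#' Scatter plot of fruit in shape-ratio space with discriminant lines
#'
#' @param data A data frame with the feature columns.
#' @param lines Optional `grade_reclassifier` or list of `discriminant_line`
#'   objects to draw.
#' @param colour Column name used for point colour (default `"grade"`).
#' @param features Feature pair to plot.
#' @return A ggplot.
#' @export
plot_ratio_space <- function(data, lines = NULL, colour = "grade",
                             features = c("length_mades", "length_pa")) {
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(.data[[features[1]]], .data[[features[2]]],
                 colour = .data[[colour]])
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = features[1], y = features[2])
  flatten <- function(x) {
    if (inherits(x, "discriminant_line")) list(x) else purrr::flatten(purrr::map(x, flatten))
  }
  if (!is.null(lines)) {
    for (ln in flatten(lines)) {
      p <- p + if (is.finite(ln$slope)) {
        ggplot2::geom_abline(slope = ln$slope, intercept = ln$intercept,
                             linetype = 2)
      } else {
        ggplot2::geom_vline(xintercept = ln$c / ln$w[1], linetype = 2)
      }
    }
  }
  p
}
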