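#' Stepwise multiple linear regression by predictor significance
#'
#' Forward-entry / backward-removal stepwise selection on the t-test p-values
#' of candidate predictors, the procedure used to build the MiDES and volume
#' estimators from calibration fruit. At each forward step the candidate with
#' the smallest p-value enters if it is below `alpha_enter`; after every
#' entry, any selected predictor whose p-value has risen above `alpha_remove`
#' is dropped (worst first). Iteration stops when no predictor moves. The
#' returned coefficients are an ordinary least-squares refit on the selected
#' set.
#'
#' @param data A data frame holding the response and the candidates.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha_enter p-value below which a predictor may enter (default 0.05).
#' @param alpha_remove p-value above which a selected predictor is removed
#'   (default 0.10); must be `>= alpha_enter`.
#' @return An object of class `smlr_fit` with elements `selected` (ordered by
#'   entry), `fit` (the final `lm`), `response` and `candidates`. Use
#'   [tidy()] / [glance()] for the coefficient table and overall F statistic,
#'   and [as_fruit_model()] to turn it into a deployable estimator.
#' @export
fit_smlr <- function(data, response, candidates,
                     alpha_enter = 0.05, alpha_remove = 0.10) {
  stopifnot(is.data.frame(data), length(candidates) >= 1L)
  if (nrow(data) < 10L) stop("need at least 10 rows", call. = FALSE)
  if (alpha_enter > alpha_remove) {
    stop("`alpha_enter` must be <= `alpha_remove`", call. = FALSE)
  }
  missing <- setdiff(c(response, candidates), names(data))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }

  fit_on <- function(terms) {
    rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
    stats::lm(stats::reformulate(rhs, response = response), data = data)
  }
  pvals <- function(fit) {
    ct <- summary(fit)$coefficients
    p <- ct[, "Pr(>|t|)"]
    p[setdiff(rownames(ct), "(Intercept)")]
  }

  selected <- character(0)
  repeat {
    changed <- FALSE
    # forward step: best candidate not yet selected
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0L) {
      entry_p <- purrr::map_dbl(pool, function(cand) {
        f <- fit_on(c(selected, cand))
        if (anyNA(coef(f))) return(NA_real_) # singular design: skip candidate
        pvals(f)[[cand]]
      })
      ok <- which(is.finite(entry_p))
      if (length(ok) > 0L) {
        best <- ok[which.min(entry_p[ok])]
        if (entry_p[best] < alpha_enter) {
          selected <- c(selected, pool[best])
          changed <- TRUE
        }
      }
    }
    # backward step: drop worst selected predictor(s)
    while (length(selected) > 0L) {
      p <- pvals(fit_on(selected))[selected]
      worst <- which.max(p)
      if (p[worst] > alpha_remove) {
        selected <- selected[-worst]
        changed <- TRUE
      } else {
        break
      }
    }
    if (!changed) break
  }

  structure(
    list(
      selected = selected,
      fit = fit_on(selected),
      response = response,
      candidates = candidates,
      alpha_enter = alpha_enter,
      alpha_remove = alpha_remove
    ),
    class = "smlr_fit"
  )
}

#' @export
print.smlr_fit <- function(x, ...) {
  cat("<smlr_fit> ", x$response, " ~ ",
      if (length(x$selected) == 0L) "1" else paste(x$selected, collapse = " + "),
      "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.smlr_fit <- function(x, ...) {
  ct <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, "Estimate"]),
    std.error = unname(ct[, "Std. Error"]),
    statistic = unname(ct[, "t value"]),
    p.value = unname(ct[, "Pr(>|t|)"])
  )
}

#' @export
glance.smlr_fit <- function(x, ...) {
  s <- summary(x$fit)
  fstat <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    p.value = if (is.null(fstat)) NA_real_ else
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    df.residual = x$fit$df.residual,
    nobs = length(x$fit$residuals),
    n.selected = length(x$selected)
  )
}

#' Convert a stepwise fit into a deployable fruit model
#'
#' @param x An `smlr_fit` whose selected predictors are measurable fruit
#'   parameters.
#' @param response Response name for the resulting model (defaults to the
#'   fitted response).
#' @return A [fruit_model()].
#' @export
as_fruit_model <- function(x, response = x$response) {
  stopifnot(inherits(x, "smlr_fit"))
  cf <- coef(x$fit)
  fruit_model(
    response = response,
    intercept = unname(cf[["(Intercept)"]]),
    coefficients = cf[setdiff(names(cf), "(Intercept)")]
  )
}

#' Plot observed versus fitted values of a stepwise fit
#'
#' @param object An `smlr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smlr_fit <- function(object, ...) {
  d <- tibble::tibble(
    fitted = stats::fitted(object$fit),
    observed = stats::fitted(object$fit) + stats::residuals(object$fit)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$fitted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = paste("fitted", object$response),
      y = paste("observed", object$response)
    )
}
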