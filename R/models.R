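#' Linear estimator over measurable fruit parameters
#'
#' A `fruit_model` is a named linear estimator
#' `response = intercept + sum(coef * predictor)` over the camera/scale
#' measurable quantities `weight_g`, `pa_cm2`, `length_mm`, `mades_mm`.
#' Note the projected-area predictor is in cm^2 at the model interface
#' (1 cm^2 = 100 mm^2); the imaging functions emit both units.
#'
#' @param response Name of the estimated quantity (e.g. `"mides_mm"`).
#' @param intercept Model constant.
#' @param coefficients Named numeric vector; names must be a subset of the
#'   measurable parameters.
#' @return An object of class `fruit_model`.
#' @export
fruit_model <- function(response, intercept, coefficients) {
  allowed <- c("weight_g", "pa_cm2", "length_mm", "mades_mm")
  coefficients <- unlist(coefficients)
  bad <- setdiff(names(coefficients), allowed)
  if (length(bad) > 0L) {
    stop("unknown predictor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(response = response, intercept = intercept,
         coefficients = coefficients),
    class = "fruit_model"
  )
}

#' Built-in MiDES estimator
#'
#' The minimum equatorial diameter cannot be seen by a top-view camera
#' because the fruit rests on its flat face; it is estimated from the
#' measurable parameters with a fixed linear model calibrated on Hayward
#' kiwifruit:
#'
#' `MiDES (mm) = -2.36 - 0.08 W + 0.66 L + 0.24 MaDES - 3.71e-4 PA(cm^2)`
#'
#' The projected-area term is retained as published even though it is not a
#' significant predictor; its contribution is negligible (~0.01 mm at
#' typical sizes).
#'
#' @return A [fruit_model()].
#' @export
mides_model <- function() {
  fruit_model(
    response = "mides_mm",
    intercept = -2.36,
    coefficients = c(
      weight_g = -0.08,
      pa_cm2 = -3.71e-4,
      length_mm = 0.66,
      mades_mm = 0.24
    )
  )
}

#' Built-in volume estimator
#'
#' Fruit volume from weight and shape:
#' `V (cm^3) = -2.69 + 0.93 W + 0.09 L + 1.65e-3 MaDES + 5.47e-5 PA(cm^2)`.
#' Weight dominates (fruit density is close to 1 g/cm^3); the MaDES and PA
#' terms are retained as published although not significant.
#'
#' @return A [fruit_model()].
#' @export
volume_model <- function() {
  fruit_model(
    response = "volume_cm3",
    intercept = -2.69,
    coefficients = c(
      weight_g = 0.93,
      pa_cm2 = 5.47e-5,
      length_mm = 0.09,
      mades_mm = 1.65e-3
    )
  )
}

#' Evaluate a fruit model on measurements
#'
#' @param object A [fruit_model()].
#' @param newdata A data frame containing every predictor the model names.
#' @param ... Unused.
#' @return A numeric vector in the model's response unit.
#' @export
predict.fruit_model <- function(object, newdata, ...) {
  missing <- setdiff(names(object$coefficients), names(newdata))
  if (length(missing) > 0L) {
    stop("missing predictor(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- rep(object$intercept, nrow(newdata))
  for (p in names(object$coefficients)) {
    out <- out + object$coefficients[[p]] * newdata[[p]]
  }
  out
}

#' @export
print.fruit_model <- function(x, ...) {
  terms <- sprintf("%+.4g*%s", x$coefficients, names(x$coefficients))
  cat("<fruit_model> ", x$response, " = ", format(x$intercept),
      " ", paste(terms, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fruit_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' Serialize a fruit model to / from JSON
#'
#' @param x A [fruit_model()].
#' @param path File path; if `NULL`, `model_to_json` returns the JSON string.
#' @return `model_from_json` returns a [fruit_model()].
#' @export
model_to_json <- function(x, path = NULL) {
  obj <- list(response = x$response, intercept = x$intercept,
              coefficients = as.list(x$coefficients))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname model_to_json
#' @param json A JSON string or file path.
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  fruit_model(obj$response, obj$intercept, unlist(obj$coefficients))
}

#' Add model estimates and shape ratios to a measurement table
#'
#' Appends the estimated MiDES and volume plus the shape ratios used for
#' grading and reclassification:
#' * `mmr` = estimated MiDES / MaDES (the FFV-46 shape criterion),
#' * `mlr` = MaDES / length,
#' * the six parameter ratios `weight_length` (g/mm), `weight_pa` (g/cm^2),
#'   `weight_mades` (g/mm), `length_mades` (dimensionless), `length_pa`
#'   (mm/cm^2) and `mades_pa` (mm/cm^2).
#'
#' @param data A data frame with `weight_g`, `length_mm`, `mades_mm`,
#'   `pa_cm2`.
#' @param mides A [fruit_model()] for MiDES (default the built-in one).
#' @param volume A [fruit_model()] for volume, or `NULL` to skip.
#' @return The input with columns `mides_est_mm`, `volume_est_cm3`, `mmr`,
#'   `mlr` and the six ratios appended.
#' @export
estimate_fruit <- function(data, mides = mides_model(), volume = volume_model()) {
  missing <- setdiff(measurement_columns, names(data))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  data$mides_est_mm <- predict(mides, data)
  if (!is.null(volume)) data$volume_est_cm3 <- predict(volume, data)
  fruit_ratios(data, mides_est = data$mides_est_mm)
}

#' Shape ratios of the measurable parameters
#'
#' @param data A data frame with the four measurable parameters.
#' @param mides_est Estimated (or measured) MiDES in mm used for `mmr`;
#'   defaults to a `mides_est_mm` column if present.
#' @return `data` with ratio columns appended (see [estimate_fruit()]).
#' @export
fruit_ratios <- function(data, mides_est = data$mides_est_mm) {
  with_cols <- function(d) {
    if (any(d$length_mm <= 0 | d$mades_mm <= 0 | d$pa_cm2 <= 0, na.rm = TRUE)) {
      stop("ratios need strictly positive sizes", call. = FALSE)
    }
    d
  }
  data <- with_cols(tibble::as_tibble(data))
  dplyr::mutate(
    data,
    mmr = if (is.null(mides_est)) NA_real_ else mides_est / .data$mades_mm,
    mlr = .data$mades_mm / .data$length_mm,
    weight_length = .data$weight_g / .data$length_mm,
    weight_pa = .data$weight_g / .data$pa_cm2,
    weight_mades = .data$weight_g / .data$mades_mm,
    length_mades = .data$length_mm / .data$mades_mm,
    length_pa = .data$length_mm / .data$pa_cm2,
    mades_pa = .data$mades_mm / .data$pa_cm2
  )
}
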