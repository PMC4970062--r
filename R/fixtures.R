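#' Build an end-to-end validation fixture
#'
#' Samples a synthetic population split into a calibration and a validation
#' set (the measure-then-grade workflow: fit estimation models on the
#' calibration fruit, grade the validation fruit), and optionally renders a
#' small number of fruit as PNG images with a weights CSV and a ground-truth
#' CSV, wiring the image pipeline into the same fixture.
#'
#' @param seed Integer seed.
#' @param n_calibration,n_validation Fruit counts for the two splits.
#' @param dir Output directory for images and CSVs; `NULL` keeps everything
#'   in memory (no images rendered unless `n_images > 0` and `dir` given).
#' @param n_images How many validation fruit to render as images.
#' @param ra Rendering resolution in pixels per mm^2.
#' @param spec A [population_spec()].
#' @return A list with `calibration` and `validation` tibbles and, when
#'   images were rendered, an `images` tibble (`image`, `image_id`,
#'   `weight_g`, plus per-image geometric truth from the renderer).
#' @export
make_validation_fixture <- function(seed = 1L, n_calibration = 140,
                                    n_validation = 350, dir = NULL,
                                    n_images = 0, ra = 25,
                                    spec = population_spec()) {
  pop <- sample_population(
    population_spec(spec$stats, n = n_calibration + n_validation,
                    correlation = spec$correlation,
                    flattened_fraction = spec$flattened_fraction),
    seed = seed
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)
  idx <- sample(nrow(pop))
  calibration <- pop[idx[seq_len(n_calibration)], ]
  validation <- pop[idx[n_calibration + seq_len(n_validation)], ]

  images <- NULL
  if (n_images > 0) {
    if (is.null(dir)) stop("`dir` is required to render images", call. = FALSE)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pick <- validation[seq_len(min(n_images, nrow(validation))), ]
    rows <- purrr::map(seq_len(nrow(pick)), function(i) {
      sp <- fruit_image_spec(
        semi_axis_long_mm = pick$length_mm[i] / 2,
        semi_axis_short_mm = pick$mades_mm[i] / 2,
        exponent = 2.5, hair_amplitude_mm = 0.3, ra = ra,
        noise_blob_count = 2
      )
      rf <- render_fruit(sp, seed = seed + i)
      path <- file.path(dir, sprintf("fruit_%03d.png", i))
      png::writePNG(rf$image / 255, path)
      dplyr::bind_cols(
        tibble::tibble(image = path, image_id = sprintf("fruit_%03d", i),
                       weight_g = pick$weight_g[i]),
        rf$truth
      )
    })
    images <- dplyr::bind_rows(rows)
    utils::write.csv(images[, c("image_id", "weight_g")],
                     file.path(dir, "weights.csv"), row.names = FALSE)
    utils::write.csv(images, file.path(dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(validation, file.path(dir, "validation.csv"),
                     row.names = FALSE)
  }
  list(calibration = calibration, validation = validation, images = images)
}
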