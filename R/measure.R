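#' Read a fruit image from disk
#'
#' Reads PNG or TIFF images into an `H x W x 3` array of integer intensities
#' in \[0, 255\]. Grayscale files are replicated across the three channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.jpg`/`.jpeg` file
#'   (JPEG requires the EBImage package).
#' @return An `H x W x 3` array.
#' @export
read_fruit_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("reading JPEG requires the EBImage package", call. = FALSE)
      }
      a <- as.array(EBImage::readImage(path))
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (is.matrix(raw)) raw <- array(raw, dim = c(dim(raw), 1L))
  if (dim(raw)[3] == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  raw <- raw[, , 1:3, drop = FALSE]
  arr <- floor(raw * 255 + 0.5)
  storage.mode(arr) <- "integer"
  arr
}

#' Measure one fruit from a top-view image
#'
#' Runs the full measurement pipeline: grayscale conversion, Otsu
#' thresholding, binarization, small-region removal, minimal bounding
#' rectangle, and calibration to physical units. The fruit is assumed
#' brighter than the background; set `invert = TRUE` when the foreground is
#' the dark side.
#'
#' @param img An `H x W x 3` RGB array, a gray matrix, or a file path.
#' @param weight_g Fruit weight in grams (carried through to the output).
#' @param ra Calibration ratio in pixels per mm^2. If `NULL`, it is estimated
#'   from the coordinate-paper grid visible in the image margins (the top and
#'   left 12% strips) via [calibrate()].
#' @param grid_pitch_mm Grid pitch used when `ra` is estimated (default 1 mm).
#' @param invert Flip foreground polarity after thresholding.
#' @param hair_offset_mm Offset subtracted from both linear sizes (default 0).
#' @param connectivity Connectivity for component labelling (4 or 8).
#' @param rotate_to_axis Measure extents along principal axes (default FALSE).
#' @param id Identifier copied to the `image_id` column.
#' @return A one-row tibble: `image_id`, `weight_g`, `length_mm`, `mades_mm`,
#'   `pa_mm2`, `pa_cm2`, `ra`, `threshold`, `n_components_removed`.
#' @export
measure_fruit_image <- function(img, weight_g = NA_real_, ra = NULL,
                                grid_pitch_mm = 1, invert = FALSE,
                                hair_offset_mm = 0, connectivity = 8,
                                rotate_to_axis = FALSE, id = NA_character_) {
  if (is.character(img)) {
    if (is.na(id)) id <- basename(img)
    img <- read_fruit_image(img)
  }
  gray <- if (length(dim(img)) == 3L) rgb_to_gray(img) else img
  if (is.null(ra)) {
    mr <- max(2L, floor(0.12 * nrow(gray)))
    mc <- max(2L, floor(0.12 * ncol(gray)))
    strips <- list(gray[seq_len(mr), , drop = FALSE],
                   gray[, seq_len(mc), drop = FALSE])
    ras <- purrr::map_dbl(strips, function(s) {
      tryCatch(calibrate(s, grid_pitch_mm = grid_pitch_mm),
               error = function(e) NA_real_)
    })
    if (all(is.na(ras))) {
      stop("calibration grid not detected; supply `ra` directly", call. = FALSE)
    }
    ra <- mean(ras, na.rm = TRUE)
  }
  thr <- otsu_threshold(gray)
  bw <- binarize(gray, thr)
  if (invert) bw <- 255L - bw
  cleaned <- remove_small_regions(bw, connectivity = connectivity)
  pm <- min_bounding_rect(cleaned$image, rotate_to_axis = rotate_to_axis)
  phys <- to_physical(pm, ra = ra, weight_g = weight_g,
                      hair_offset_mm = hair_offset_mm)
  dplyr::bind_cols(
    tibble::tibble(image_id = id),
    phys,
    tibble::tibble(
      ra = ra,
      threshold = thr,
      n_components_removed = cleaned$n_removed
    )
  )
}

#' Measure a batch of fruit images
#'
#' @param images A data frame with columns `image` (file path) and
#'   `weight_g`, and optionally `image_id`.
#' @param ... Passed on to [measure_fruit_image()] (e.g. `ra`, `invert`).
#' @return A tibble with one row per input image. Rows whose image could not
#'   be processed carry `NA` measurements and the error message in an
#'   `error` column (present only if something failed); processing continues
#'   past failures.
#' @export
measure_fruit_images <- function(images, ...) {
  stopifnot(is.data.frame(images), "image" %in% names(images))
  if (!"weight_g" %in% names(images)) images$weight_g <- NA_real_
  if (!"image_id" %in% names(images)) images$image_id <- basename(images$image)
  rows <- purrr::pmap(
    list(images$image, images$weight_g, images$image_id),
    function(path, w, id) {
      tryCatch(
        measure_fruit_image(path, weight_g = w, id = id, ...),
        error = function(e) {
          tibble::tibble(image_id = id, weight_g = w, error = conditionMessage(e))
        }
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (!"error" %in% names(out)) out else dplyr::relocate(out, "error", .after = dplyr::last_col())
}

measurement_columns <- c("weight_g", "length_mm", "mades_mm", "pa_cm2")

#' Write / read a measurement table
#'
#' Plain CSV (comma separator, `.` decimal, header row). `read_measurements`
#' validates that the grading schema columns are present.
#'
#' @param x A measurement tibble.
#' @param path File path.
#' @return `read_measurements` returns a tibble.
#' @export
write_measurements <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path))
  missing <- setdiff(measurement_columns, names(x))
  if (length(missing) > 0L) {
    stop("measurement file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x
}
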