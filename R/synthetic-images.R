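#' Specification of a synthetic fruit image
#'
#' Describes a top-view scene for the renderer: a bright superellipse
#' silhouette (the fruit, optionally with a hairy boundary) on dark
#' coordinate paper with a 1 mm calibration grid, plus pixel noise and
#' optional small bright noise blobs. All geometry is in millimetres; `ra`
#' (pixels per mm^2) fixes the rendering resolution.
#'
#' @param semi_axis_long_mm,semi_axis_short_mm Fruit semi-axes `a >= b > 0`.
#' @param exponent Superellipse exponent (`2` = exact ellipse; larger values
#'   give the blockier equatorial section of real fruit).
#' @param hair_amplitude_mm Maximum outward boundary perturbation from
#'   surface hair (0 disables it).
#' @param hair_frequency Hair oscillations per degree of boundary angle.
#' @param rotation_deg Fruit rotation in the image plane.
#' @param ra Pixels per mm^2.
#' @param noise_blob_count Number of small bright blobs away from the fruit.
#' @param blob_radius_px Radius range (px) for noise blobs.
#' @param margin_mm Paper margin around the fruit.
#' @param bg_level,grid_level,fg_level Gray levels of paper, grid lines and
#'   fruit (the fruit must sit at least 3 noise SDs above the background).
#' @param noise_sd Gaussian pixel noise SD in gray levels.
#' @return A list of class `fruit_image_spec`.
#' @export
fruit_image_spec <- function(semi_axis_long_mm = 33, semi_axis_short_mm = 27,
                             exponent = 2, hair_amplitude_mm = 0,
                             hair_frequency = 0.5, rotation_deg = 0,
                             ra = 25, noise_blob_count = 0,
                             blob_radius_px = c(2, 5), margin_mm = 10,
                             bg_level = 60, grid_level = 80, fg_level = 200,
                             noise_sd = 5) {
  stopifnot(
    semi_axis_long_mm >= semi_axis_short_mm, semi_axis_short_mm > 0,
    exponent >= 2, hair_amplitude_mm >= 0, ra > 0, margin_mm > 0,
    noise_sd >= 0
  )
  if (fg_level - bg_level < 3 * max(noise_sd, 1)) {
    stop("foreground and background must be separated by >= 3 noise SDs",
         call. = FALSE)
  }
  structure(
    list(
      a = semi_axis_long_mm, b = semi_axis_short_mm, exponent = exponent,
      hair_amplitude = hair_amplitude_mm, hair_frequency = hair_frequency,
      rotation = rotation_deg, ra = ra,
      noise_blob_count = noise_blob_count, blob_radius_px = blob_radius_px,
      margin = margin_mm, bg_level = bg_level, grid_level = grid_level,
      fg_level = fg_level, noise_sd = noise_sd
    ),
    class = "fruit_image_spec"
  )
}

# boundary radius of the (hairless) superellipse at polar angle theta
superellipse_radius <- function(theta, a, b, n) {
  (abs(cos(theta) / a)^n + abs(sin(theta) / b)^n)^(-1 / n)
}

# hair perturbation: a primary sinusoid plus a weaker incommensurate one
# with seeded random phases, clamped to [0, amplitude]; a pure function of
# the boundary angle so the rendered boundary is a closed curve
hair_profile <- function(theta, amplitude, frequency, phases) {
  if (amplitude == 0) return(rep(0, length(theta)))
  deg <- theta * 180 / pi
  raw <- 0.5 + 0.5 * sin(2 * pi * frequency * deg + phases[1]) +
    0.15 * sin(2 * pi * frequency * exp(1) / 2 * deg + phases[2])
  amplitude * pmin(pmax(raw, 0), 1)
}

#' Render a synthetic fruit image with analytic ground truth
#'
#' Draws the scene described by a [fruit_image_spec()] and returns the RGB
#' image together with ground truth computed from the boundary curve itself
#' (numerical quadrature, independent of rasterization): `length_mm = 2a`,
#' `mades_mm = 2b` (the fruit proper, excluding hair) and `pa_mm2`, the area
#' enclosed by the hairy boundary, so the mean hair contribution is part of
#' the true projected area.
#'
#' @param spec A [fruit_image_spec()].
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   image.
#' @return A list with `image` (H x W x 3 integer array), `gray_truth`
#'   (noise-free fruit mask, for segmentation checks), `truth` (one-row
#'   tibble: `length_mm`, `mades_mm`, `pa_mm2`, `pa_hairless_mm2`), `ra` and
#'   `spec`.
#' @export
render_fruit <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fruit_image_spec"))
  s <- sqrt(spec$ra) # pixels per mm
  reach <- spec$a + spec$hair_amplitude
  side_mm <- 2 * (reach + spec$margin)
  h <- as.integer(round(2 * (spec$b + spec$hair_amplitude + spec$margin) * s))
  w <- as.integer(round(side_mm * s))
  if (spec$rotation %% 180 != 0) h <- w # rotated fruit needs a square canvas
  if (2 * reach * s > w ||
      2 * (spec$b + spec$hair_amplitude) * s > h) {
    stop("fruit larger than canvas", call. = FALSE)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  phases <- runif(2, 0, 2 * pi)

  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  dx <- (matrix(rep(seq_len(w), each = h), h, w) - cx) / s
  dy <- (matrix(rep(seq_len(h), times = w), h, w) - cy) / s
  alpha <- spec$rotation * pi / 180
  u <- cos(alpha) * dx + sin(alpha) * dy
  v <- -sin(alpha) * dx + cos(alpha) * dy
  theta <- atan2(v, u)
  r <- sqrt(u^2 + v^2)
  boundary <- superellipse_radius(theta, spec$a, spec$b, spec$exponent) +
    hair_profile(theta, spec$hair_amplitude, spec$hair_frequency, phases)
  fruit <- r <= boundary

  # 1 mm calibration grid on the paper
  col_in_line <- (seq_len(w) - 1) %% s < 1
  row_in_line <- (seq_len(h) - 1) %% s < 1
  grid <- outer(row_in_line, col_in_line, `|`)

  img <- matrix(spec$bg_level, h, w)
  img[grid] <- spec$grid_level
  # noise blobs: bright discs placed clear of the fruit
  n_placed <- 0L
  tries <- 0L
  while (n_placed < spec$noise_blob_count && tries < 200L) {
    tries <- tries + 1L
    rad <- runif(1, spec$blob_radius_px[1], spec$blob_radius_px[2])
    bx <- runif(1, rad + 1, w - rad)
    by <- runif(1, rad + 1, h - rad)
    bu <- (bx - cx) / s
    bv <- (by - cy) / s
    bth <- atan2(
      -sin(alpha) * bu + cos(alpha) * bv,
      cos(alpha) * bu + sin(alpha) * bv
    )
    clear <- superellipse_radius(bth, spec$a, spec$b, spec$exponent) +
      spec$hair_amplitude + (rad + 3) / s
    if (sqrt(bu^2 + bv^2) <= clear) next
    disc <- (dx * s + cx - bx)^2 + (dy * s + cy - by)^2 <= rad^2
    img[disc] <- spec$fg_level
    n_placed <- n_placed + 1L
  }
  img[fruit] <- spec$fg_level
  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
  }
  img <- floor(pmin(pmax(img, 0), 255) + 0.5)
  rgb <- array(as.integer(img), dim = c(h, w, 3))

  # ground truth from the boundary curve: area = 1/2 integral R(theta)^2
  th <- seq(0, 2 * pi, length.out = 20001L)[-1]
  r0 <- superellipse_radius(th, spec$a, spec$b, spec$exponent)
  rh <- r0 + hair_profile(th, spec$hair_amplitude, spec$hair_frequency, phases)
  dth <- 2 * pi / length(th)
  truth <- tibble::tibble(
    length_mm = 2 * spec$a,
    mades_mm = 2 * spec$b,
    pa_mm2 = 0.5 * sum(rh^2) * dth,
    pa_hairless_mm2 = 0.5 * sum(r0^2) * dth
  )
  list(image = rgb, gray_truth = fruit, truth = truth, ra = spec$ra, spec = spec)
}

# save/restore .Random.seed so generators are deterministic without
# disturbing the caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Analytic area of a superellipse
#'
#' `4ab * gamma(1 + 1/n)^2 / gamma(1 + 2/n)`; reduces to `pi*a*b` for
#' `n = 2`. Used as the independent check of pixel-counted projected areas.
#'
#' @param a,b Semi-axes.
#' @param n Exponent (>= 2).
#' @return Area in the square of the axis unit.
#' @export
superellipse_area <- function(a, b, n) {
  4 * a * b * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}
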