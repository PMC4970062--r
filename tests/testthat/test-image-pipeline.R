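test_that("grayscale conversion follows the NTSC weights with half-up rounding", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(rgb_to_gray(px(255, 255, 255))[1, 1], 255L)
  expect_equal(rgb_to_gray(px(0, 0, 0))[1, 1], 0L)
  expect_equal(rgb_to_gray(px(100, 100, 100))[1, 1], 100L)
  # 0.299 * 255 = 76.245 -> 76
  expect_equal(rgb_to_gray(px(255, 0, 0))[1, 1], 76L)
  # half-up at .5: 0.587 * 128 + 0.299 * 44 + 0.114 * 55 = 94.561 sanity pair
  expect_equal(rgb_to_gray(px(44, 128, 55))[1, 1], 95L)
  expect_error(rgb_to_gray(array(300, dim = c(1, 1, 3))), "0, 255")
  expect_error(rgb_to_gray(matrix(1, 2, 2)), "H x W x 3")
})

test_that("grayscale conversion is monotone in each channel and bounded", {
  set.seed(101)
  base <- array(sample(0:255, 3 * 25, replace = TRUE), dim = c(5, 5, 3))
  g0 <- rgb_to_gray(base)
  expect_true(all(g0 >= 0 & g0 <= 255))
  for (ch in 1:3) {
    up <- base
    up[, , ch] <- pmin(up[, , ch] + 30, 255)
    expect_true(all(rgb_to_gray(up) >= g0))
  }
})

test_that("otsu threshold equals the exhaustive-search oracle", {
  # perfectly bimodal image: lowest separating threshold wins the tie-break
  bimodal <- matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4)
  expect_equal(otsu_threshold(bimodal), 1L)
  expect_equal(otsu_threshold(bimodal), otsu_oracle(bimodal))

  skewed <- matrix(c(rep(10L, 12), rep(200L, 4)), 4, 4)
  expect_equal(otsu_threshold(skewed), otsu_oracle(skewed))

  set.seed(7)
  for (i in 1:25) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_equal(otsu_threshold(img), otsu_oracle(img))
  }
  expect_error(otsu_threshold(matrix(42L, 3, 3)), "degenerate")
})

test_that("otsu separates a synthetic fruit from its background", {
  rf <- render_fruit(fruit_image_spec(ra = 25, noise_sd = 5), seed = 3)
  gray <- rgb_to_gray(rf$image)
  bw <- binarize(gray, otsu_threshold(gray))
  recovered <- mean(bw[rf$gray_truth] == 255)
  expect_gte(recovered, 0.99)
})

test_that("binarization maps values below the threshold to 0 and the rest to 255", {
  flat <- matrix(128L, 3, 3)
  expect_true(all(binarize(flat, 129) == 0))
  expect_true(all(binarize(flat, 100) == 255))
  expect_true(all(binarize(flat, 128) == 255)) # equality goes to white
  set.seed(11)
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  out <- binarize(img, otsu_threshold(img))
  expect_setequal(unique(as.vector(out)), c(0L, 255L))
})

test_that("small-region removal keeps the largest component and applies the 1/20 rule", {
  canvas <- function(blob_px) {
    img <- matrix(0L, 60, 80)
    img[1:40, 1:50] <- 255L # 2000-px component
    img[50:(50 + blob_px[1] - 1), 60:(60 + blob_px[2] - 1)] <- 255L
    img
  }
  # 99 px < 2000/20: removed
  res <- remove_small_regions(canvas(c(9, 11)))
  expect_equal(res$n_removed, 1L)
  expect_equal(sum(res$image == 255), 2000L)
  expect_equal(res$area_removed, 99L)
  # 100 px is not *smaller* than 100: kept
  res <- remove_small_regions(canvas(c(10, 10)))
  expect_equal(res$n_removed, 0L)
  expect_equal(sum(res$image == 255), 2100L)
  # single component untouched
  one <- matrix(0L, 10, 10); one[3:6, 3:6] <- 255L
  expect_equal(remove_small_regions(one)$image, one)
  expect_error(remove_small_regions(matrix(0L, 5, 5)), "empty foreground")
})

test_that("after region removal every survivor meets the area rule and whites never increase", {
  set.seed(23)
  for (i in 1:10) {
    img <- matrix(ifelse(stats::runif(30 * 30) < 0.3, 255L, 0L), 30, 30)
    if (!any(img > 0)) next
    res <- remove_small_regions(img)
    expect_lte(sum(res$image == 255), sum(img == 255))
    if (any(res$image > 0)) {
      lab <- label_components(res$image)
      areas <- tabulate(lab[lab > 0])
      expect_true(all(areas >= max(areas) / 20))
    }
  }
})

test_that("component labelling honours 4- versus 8-connectivity", {
  img <- matrix(0L, 4, 4)
  img[1, 1] <- 255L
  img[2, 2] <- 255L # touches only diagonally
  lab8 <- label_components(img, connectivity = 8)
  lab4 <- label_components(img, connectivity = 4)
  expect_equal(max(lab8), 1L)
  expect_equal(max(lab4), 2L)
})

test_that("minimal bounding rectangle reports long side, short side and pixel area", {
  one <- matrix(0L, 5, 5); one[3, 3] <- 255L
  expect_equal(min_bounding_rect(one), tibble::tibble(pl = 1, pw = 1, ppa = 1))
  rect <- matrix(0L, 20, 20); rect[4:9, 2:11] <- 255L # 6 rows x 10 cols
  expect_equal(min_bounding_rect(rect), tibble::tibble(pl = 10, pw = 6, ppa = 60))
  # orientation must not matter for which side is "length"
  expect_equal(min_bounding_rect(t(rect)), tibble::tibble(pl = 10, pw = 6, ppa = 60))
  expect_error(min_bounding_rect(matrix(0L, 3, 3)), "empty foreground")
})

test_that("bounding rectangle recovers ellipse axes and area from a rendered mask", {
  rf <- render_fruit(fruit_image_spec(
    semi_axis_long_mm = 30, semi_axis_short_mm = 22, ra = 25, noise_sd = 0
  ), seed = 5)
  mask <- ifelse(rf$gray_truth, 255L, 0L)
  pm <- min_bounding_rect(mask)
  s <- sqrt(25)
  expect_lte(abs(pm$pl - 2 * 30 * s), s) # within 1 px of the true diameter
  expect_lte(abs(pm$pw - 2 * 22 * s), s)
  expect_lt(abs(pm$ppa - pi * 30 * 22 * 25) / (pi * 30 * 22 * 25), 0.03)
})

test_that("grid calibration returns pixels per square millimetre", {
  mk_grid <- function(step, n = 301, lo = 120L, hi = 200L) {
    g <- matrix(hi, n, n)
    idx <- unique(round(seq(1, n, by = step)))
    g[idx, ] <- lo
    g[, idx] <- lo
    g
  }
  expect_equal(calibrate(mk_grid(5)), 25, tolerance = 1e-6)
  expect_equal(calibrate(mk_grid(7.5)), 56.25, tolerance = 0.01)
  # doubling the resolution quadruples ra
  expect_equal(calibrate(mk_grid(10)), 4 * calibrate(mk_grid(5)),
               tolerance = 0.01)
  # 2 mm pitch paper halves the pixel pitch per mm
  expect_equal(calibrate(mk_grid(10), grid_pitch_mm = 2), 25, tolerance = 0.01)
  expect_error(calibrate(matrix(128, 10, 10)), "not detected")
})

test_that("pixel measurements convert to physical units through RA", {
  pm <- tibble::tibble(pl = 330, pw = 270, ppa = 70000)
  phys <- to_physical(pm, ra = 25, weight_g = 100)
  expect_equal(phys$length_mm, 66)
  expect_equal(phys$mades_mm, 54)
  expect_equal(phys$pa_mm2, 2800)
  expect_equal(phys$pa_cm2, 28)
  expect_equal(phys$weight_g, 100)
  # identity calibration
  ident <- to_physical(pm, ra = 1)
  expect_equal(ident$length_mm, 330)
  expect_equal(ident$pa_mm2, 70000)
  # hair offset subtracts from both linear sizes only
  off <- to_physical(pm, ra = 25, hair_offset_mm = 1)
  expect_equal(off$length_mm, 65)
  expect_equal(off$mades_mm, 53)
  expect_equal(off$pa_mm2, 2800)
  expect_error(to_physical(pm, ra = 0), "> 0")
})

test_that("physical sizes are invariant under consistent image rescaling", {
  pm <- tibble::tibble(pl = 100, pw = 80, ppa = 6000)
  base <- to_physical(pm, ra = 16)
  scaled <- to_physical(dplyr::mutate(pm, pl = pl * 2, pw = pw * 2,
                                      ppa = ppa * 4), ra = 64)
  expect_equal(scaled$length_mm, base$length_mm)
  expect_equal(scaled$mades_mm, base$mades_mm)
  expect_equal(scaled$pa_mm2, base$pa_mm2)
})

test_that("the full pipeline recovers known sizes from a rendered image", {
  rf <- render_fruit(fruit_image_spec(
    semi_axis_long_mm = 33, semi_axis_short_mm = 27, ra = 25,
    noise_blob_count = 3
  ), seed = 7)
  m <- measure_fruit_image(rf$image, weight_g = 100, ra = 25)
  expect_lte(abs(m$length_mm - 66), 2 / sqrt(25))
  expect_lte(abs(m$mades_mm - 54), 2 / sqrt(25))
  expect_lt(abs(m$pa_mm2 - rf$truth$pa_mm2) / rf$truth$pa_mm2, 0.03)
  expect_equal(m$n_components_removed, 3)
  # self-calibration from the grid in the margins agrees
  m2 <- measure_fruit_image(rf$image, weight_g = 100)
  expect_equal(m2$ra, 25, tolerance = 0.02)
  expect_equal(m2$length_mm, m$length_mm, tolerance = 0.05)
})
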