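blob <- function(n, mx, my, sx, sy, label) {
  tibble::tibble(
    length_mades = stats::rnorm(n, mx, sx),
    length_pa = stats::rnorm(n, my, sy),
    actual = label
  )
}

test_that("well-separated groups are split without training errors", {
  set.seed(83)
  d <- dplyr::bind_rows(
    blob(40, 1.30, 2.0, 0.01, 0.02, "Extra"),
    blob(40, 1.05, 1.6, 0.01, 0.02, "I")
  )
  ln <- fit_discriminant(d, "actual", c("Extra", "I"))
  expect_equal(predict(ln, d), d$actual)
})

test_that("mirrored symmetric groups give a vertical boundary at the mirror line", {
  set.seed(89)
  x <- stats::rnorm(60, 0, 0.05)
  d <- dplyr::bind_rows(
    tibble::tibble(length_mades = 1.5 + abs(x) + 0.2, length_pa = stats::rnorm(60, 2, 0.1), actual = "Extra"),
    tibble::tibble(length_mades = 1.5 - abs(x) - 0.2, length_pa = stats::rnorm(60, 2, 0.1), actual = "I")
  )
  ln <- fit_discriminant(d, "actual", c("Extra", "I"))
  # boundary x-position at the data's mean y should sit at the mirror line
  x_at <- (ln$c - ln$w[2] * 2) / ln$w[1]
  expect_equal(unname(x_at), 1.5, tolerance = 0.05)
})

test_that("groups at the published ratio moments separate with >= 80% accuracy", {
  set.seed(97)
  # Monte-Carlo resubstitution accuracy at n = 200 per group
  acc <- purrr::map_dbl(1:20, function(i) {
    d <- dplyr::bind_rows(
      blob(200, 1.26, 1.89, 0.05, 0.17, "Extra"),
      blob(200, 1.18, 1.81, 0.04, 0.11, "I")
    )
    ln <- fit_discriminant(d, "actual", c("Extra", "I"))
    mean(predict(ln, d) == d$actual)
  })
  expect_gte(mean(acc), 0.80)
})

test_that("the closed-form boundary agrees with the MASS::lda reference", {
  set.seed(101)
  d <- dplyr::bind_rows(
    blob(150, 1.26, 1.89, 0.05, 0.17, "Extra"),
    blob(100, 1.15, 1.75, 0.05, 0.15, "I")
  )
  ln <- fit_discriminant(d, "actual", c("Extra", "I"))
  ref <- MASS::lda(actual ~ length_mades + length_pa, data = d)
  ref_pred <- as.character(predict(ref, d)$class)
  expect_gte(mean(predict(ln, d) == ref_pred), 0.995)
})

test_that("degenerate groups raise errors", {
  flat <- tibble::tibble(length_mades = rep(1, 6), length_pa = rep(2, 6),
                         actual = rep(c("Extra", "I"), each = 3))
  expect_error(fit_discriminant(flat, "actual", c("Extra", "I")), "degenerate|identical")
  tiny <- tibble::tibble(length_mades = c(1, 2), length_pa = c(1, 2),
                         actual = c("Extra", "I"))
  expect_error(fit_discriminant(tiny, "actual", c("Extra", "I")), "2 points")
})

test_that("points exactly on the line fall to the lower grade", {
  ln <- structure(
    list(w = c(length_mades = 1, length_pa = 0), c = 1.2,
         features = c("length_mades", "length_pa"),
         class_pos = "Extra", class_neg = "I",
         slope = Inf, intercept = NA_real_),
    class = "discriminant_line"
  )
  on_line <- tibble::tibble(length_mades = 1.2, length_pa = 2)
  expect_equal(predict(ln, on_line), "I")
  expect_equal(predict(ln, on_line, on_line = "upper"), "Extra")
  expect_equal(predict(ln, tibble::tibble(length_mades = 1.3, length_pa = 2)), "Extra")
})

test_that("reclassification only touches estimated Extra and I", {
  set.seed(103)
  d <- dplyr::bind_rows(
    dplyr::mutate(blob(30, 1.26, 1.89, 0.04, 0.1, "Extra"), grade = "Extra"),
    dplyr::mutate(blob(10, 1.10, 1.70, 0.03, 0.05, "I"), grade = "Extra"),
    dplyr::mutate(blob(30, 1.22, 2.0, 0.05, 0.1, "I"), grade = "I"),
    dplyr::mutate(blob(20, 1.02, 1.58, 0.03, 0.11, "II"), grade = "II"),
    dplyr::mutate(blob(10, 1.25, 2.4, 0.10, 0.1, "Reject"), grade = "Reject")
  )
  lines <- fit_reclassifier(d)
  out <- reclassify_grades(d, lines)
  expect_true(all(out$grade_final[d$grade == "II"] == "II"))
  expect_true(all(out$grade_final[d$grade == "Reject"] == "Reject"))
  # idempotence under a fixed line set
  again <- reclassify_grades(
    dplyr::mutate(out, grade = grade_final), lines, out_col = "grade_final2"
  )
  expect_equal(as.character(again$grade_final2), as.character(out$grade_final))
  # a context absent from the line set is an error
  expect_error(reclassify_grades(d, structure(list(), class = "grade_reclassifier")),
               "no discriminant line")
})

test_that("fitted lines cut misclassifications when overlap mimics the published table", {
  set.seed(107)
  # validation set with the published group sizes and ratio moments
  d <- dplyr::bind_rows(
    dplyr::mutate(blob(103, 1.26, 1.89, 0.05, 0.17, "Extra"), grade = "Extra"),
    dplyr::mutate(blob(28, 1.18, 1.81, 0.04, 0.11, "I"), grade = "Extra"),
    dplyr::mutate(blob(13, 1.12, 1.74, 0.03, 0.05, "Extra"), grade = "I"),
    dplyr::mutate(blob(85, 1.23, 2.10, 0.07, 0.21, "I"), grade = "I"),
    dplyr::mutate(blob(13, 1.02, 1.58, 0.03, 0.11, "II"), grade = "I"),
    dplyr::mutate(blob(82, 1.20, 2.22, 0.15, 0.34, "II"), grade = "II"),
    dplyr::mutate(blob(26, 1.25, 2.42, 0.10, 0.10, "Reject"), grade = "Reject")
  )
  errors_before <- sum(d$grade != d$actual)
  lines <- fit_reclassifier(d)
  out <- reclassify_grades(d, lines)
  errors_after <- sum(as.character(out$grade_final) != out$actual)
  expect_lt(errors_after, errors_before)
})

test_that("discriminant line sets survive a JSON round trip", {
  set.seed(109)
  d <- dplyr::bind_rows(
    dplyr::mutate(blob(30, 1.26, 1.89, 0.04, 0.1, "Extra"), grade = "Extra"),
    dplyr::mutate(blob(15, 1.10, 1.70, 0.03, 0.05, "I"), grade = "Extra"),
    dplyr::mutate(blob(30, 1.22, 2.0, 0.05, 0.1, "I"), grade = "I"),
    dplyr::mutate(blob(10, 1.02, 1.58, 0.03, 0.1, "II"), grade = "I")
  )
  lines <- fit_reclassifier(d)
  path <- withr::local_tempfile(fileext = ".json")
  lines_to_json(lines, path)
  lines2 <- lines_from_json(path)
  out1 <- reclassify_grades(d, lines)
  out2 <- reclassify_grades(d, lines2)
  expect_equal(as.character(out1$grade_final), as.character(out2$grade_final))
})

test_that("ratio-space plots build with and without lines", {
  set.seed(113)
  d <- dplyr::bind_rows(
    dplyr::mutate(blob(20, 1.26, 1.89, 0.04, 0.1, "Extra"), grade = "Extra"),
    dplyr::mutate(blob(20, 1.10, 1.70, 0.03, 0.05, "I"), grade = "Extra")
  )
  lines <- fit_reclassifier(dplyr::bind_rows(
    d, dplyr::mutate(blob(10, 1.2, 2, 0.03, 0.05, "I"), grade = "I")
  ))
  expect_s3_class(plot_ratio_space(d), "ggplot")
  expect_s3_class(plot_ratio_space(d, lines), "ggplot")
})
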