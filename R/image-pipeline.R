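#' Convert an RGB image to 8-bit grayscale
#'
#' Applies the NTSC luminance formula
#' `gray = 0.299 R + 0.587 G + 0.114 B`, rounding half-up to the nearest
#' integer and clamping to \[0, 255\].
#'
#' @param img An `H x W x 3` array of channel intensities in \[0, 255\].
#' @return An `H x W` integer matrix with values in \[0, 255\].
#' @examples
#' img <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_gray(img) # 76
#' @export
rgb_to_gray <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("`img` must be an H x W x 3 array", call. = FALSE)
  }
  if (any(dim(img)[1:2] < 1L)) stop("image has zero extent", call. = FALSE)
  if (min(img) < 0 || max(img) > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  g <- 0.299 * img[, , 1, drop = FALSE] + 0.587 * img[, , 2, drop = FALSE] +
    0.114 * img[, , 3, drop = FALSE]
  dim(g) <- dim(img)[1:2]
  # round-half-up, then clamp; round() would use banker's rounding
  g <- floor(g + 0.5)
  g[g < 0] <- 0
  g[g > 255] <- 255
  storage.mode(g) <- "integer"
  g
}

#' Otsu's threshold for a grayscale image
#'
#' Scans all 256 candidate thresholds of the 8-bit histogram and returns the
#' one minimizing the within-class (intraclass) variance of the two pixel
#' classes induced by [binarize()]: pixels `< t` are background, pixels
#' `>= t` foreground. Ties are broken towards the lowest threshold.
#'
#' @param img An integer matrix of gray values in \[0, 255\].
#' @return A single integer threshold in \[0, 255\].
#' @export
otsu_threshold <- function(img) {
  v <- as.integer(img)
  if (length(v) == 0L) stop("empty image", call. = FALSE)
  if (min(v) < 0L || max(v) > 255L) stop("gray values must lie in [0, 255]", call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L) # counts[i] = #pixels with value i-1
  if (sum(counts > 0L) < 2L) {
    stop("constant image: histogram is degenerate, no threshold exists", call. = FALSE)
  }
  n <- length(v)
  levels <- 0:255
  # cumulative moments of the background class (values 0 .. t-1)
  c0 <- cumsum(counts)                 # class sizes for t = 1..256
  s0 <- cumsum(counts * levels)
  q0 <- cumsum(counts * levels^2)
  # prepend t = 0 (empty background)
  n0 <- c(0, c0[1:255])
  sum0 <- c(0, s0[1:255])
  sq0 <- c(0, q0[1:255])
  n1 <- n - n0
  sum1 <- s0[256] - sum0
  sq1 <- q0[256] - sq0
  var0 <- ifelse(n0 > 0, sq0 / n0 - (sum0 / n0)^2, 0)
  var1 <- ifelse(n1 > 0, sq1 / n1 - (sum1 / n1)^2, 0)
  within <- (n0 * var0 + n1 * var1) / n
  # which.min takes the first (lowest) threshold on ties
  as.integer(which.min(within) - 1L)
}

#' Binarize a grayscale image at a threshold
#'
#' Pixels below the threshold map to 0 (black), pixels at or above it map to
#' 255 (white).
#'
#' @param img An integer matrix of gray values in \[0, 255\].
#' @param threshold Integer in \[0, 255\].
#' @return A matrix with values in `{0, 255}`.
#' @export
binarize <- function(img, threshold) {
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 255)
  out <- matrix(0L, nrow(img), ncol(img))
  out[img >= threshold] <- 255L
  out
}

#' Label connected components of white pixels
#'
#' @param img A binary matrix (non-zero = white).
#' @param connectivity 4 or 8 (default 8; diagonal neighbours count, which is
#'   robust to one-pixel-wide hairy boundaries).
#' @return An integer matrix of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(img, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  h <- nrow(img)
  w <- ncol(img)
  white <- which(img > 0)
  n <- length(white)
  if (n == 0L) stop("no white pixels: empty foreground", call. = FALSE)
  rank <- integer(h * w)
  rank[white] <- seq_len(n)
  rr <- ((white - 1L) %% h) + 1L
  cc <- ((white - 1L) %/% h) + 1L
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  edges <- lapply(offsets, function(o) {
    r2 <- rr + o[1]
    c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- rank[(c2[ok] - 1L) * h + r2[ok]]
    keep <- nb > 0L
    cbind(seq_len(n)[ok][keep], nb[keep])
  })
  e <- do.call(rbind, edges)
  g <- igraph::make_graph(edges = as.vector(t(e)), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  lab <- matrix(0L, h, w)
  lab[white] <- as.integer(memb)
  lab
}

#' Remove small white regions from a binary image
#'
#' Finds the largest connected component of white pixels and blanks every
#' component whose area is strictly smaller than 1/20 of it. The largest
#' component always survives.
#'
#' @inheritParams label_components
#' @param min_fraction Components smaller than `min_fraction` of the largest
#'   area are removed (default 1/20).
#' @return A list with `image` (the filtered binary matrix), `n_removed`
#'   (number of components removed) and `area_removed` (pixels removed).
#' @export
remove_small_regions <- function(img, connectivity = 8, min_fraction = 1 / 20) {
  lab <- label_components(img, connectivity = connectivity)
  areas <- tabulate(lab[lab > 0L])
  cutoff <- max(areas) * min_fraction
  drop <- which(areas < cutoff)
  out <- img
  out[lab %in% drop] <- 0L
  list(
    image = out,
    n_removed = length(drop),
    area_removed = sum(areas[drop])
  )
}

#' Minimal bounding rectangle and pixel counts of the white area
#'
#' Computes the axis-aligned bounding box of all white pixels. The long side
#' is reported as `pl` (length in pixels) and the short side as `pw`
#' (width in pixels), so the long-axis-is-length convention holds regardless
#' of fruit orientation in the frame. `ppa` is the white-pixel count.
#'
#' @param img A binary matrix (non-zero = white).
#' @param rotate_to_axis If `TRUE`, extents are measured along the principal
#'   axes of the white-pixel cloud instead of the image axes (off by default:
#'   on a sorting line the fruit's long axis is aligned with the frame).
#' @return A one-row tibble with columns `pl`, `pw`, `ppa`.
#' @export
min_bounding_rect <- function(img, rotate_to_axis = FALSE) {
  white <- which(img > 0)
  if (length(white) == 0L) stop("no white pixels: empty foreground", call. = FALSE)
  h <- nrow(img)
  rr <- ((white - 1L) %% h) + 1L
  cc <- ((white - 1L) %/% h) + 1L
  if (rotate_to_axis && length(white) > 1L) {
    xy <- cbind(rr, cc)
    ev <- eigen(stats::cov(xy), symmetric = TRUE)$vectors
    proj <- xy %*% ev
    ext <- apply(proj, 2, function(p) diff(range(p)) + 1)
  } else {
    ext <- c(diff(range(rr)) + 1L, diff(range(cc)) + 1L)
  }
  tibble::tibble(
    pl = max(ext),
    pw = min(ext),
    ppa = length(white)
  )
}
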