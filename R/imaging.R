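#' Gaussian smoothing of an RGB image
#'
#' Separable Gaussian convolution per channel with edge replication.
#' `sigma = 0` returns the image unchanged. The default sigma of 2 px is
#' stated at the native capture resolution (3264 px wide); pass
#' `scale_to_width` to rescale it proportionally for smaller rasters.
#'
#' @param image H x W x 3 numeric array, channels on 0-255.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @param scale_to_width if non-NULL, sigma is multiplied by
#'   `ncol(image)/scale_to_width` with `scale_to_width` the reference width
#'   (default NULL = use sigma as given).
#' @return Smoothed array, same shape.
#' @export
smooth_image <- function(image, sigma = 2, scale_to_width = NULL) {
  .cp_check_image(image)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (!is.null(scale_to_width)) sigma <- sigma * dim(image)[2] / scale_to_width
  if (sigma == 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  out <- image
  for (ch in 1:3) out[, , ch] <- .cp_conv_sep(image[, , ch], k)
  out
}

# separable convolution with replicated edges; k has odd length
.cp_conv_sep <- function(m, k) {
  m <- .cp_conv_1d(m, k)        # along rows (vertical)
  t(.cp_conv_1d(t(m), k))       # along columns (horizontal)
}

.cp_conv_1d <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
  out
}

.cp_check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (anyNA(image)) stop("image contains NA")
  invisible(image)
}

#' Segment roots from a blue background
#'
#' Pixels whose blue channel exceeds `max(R, G)` by at least `margin` are
#' classified as background (the blue liner of the phenotyping box); the
#' complement is the root mask, after removing connected foreground
#' components smaller than `min_area` pixels and filling enclosed background
#' holes. Fails loudly if nothing remains.
#'
#' @param image H x W x 3 array (0-255).
#' @param margin blue-dominance margin in channel units (default 30).
#' @param min_area minimum connected-component area in pixels (default 50).
#' @return Logical H x W matrix, `TRUE` = root material.
#' @export
segment_roots <- function(image, margin = 30, min_area = 50) {
  .cp_check_image(image)
  bg <- (image[, , 3] - pmax(image[, , 1], image[, , 2])) >= margin
  mask <- !bg
  if (any(mask)) {
    lab <- label_components(mask)
    keep <- which(tabulate(lab[lab > 0]) >= min_area)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) stop("no root detected: segmentation produced an empty mask")
  # fill holes: background components not connected to the image border
  hole_lab <- label_components(!mask)
  border <- unique(c(hole_lab[1, ], hole_lab[nrow(mask), ],
                     hole_lab[, 1], hole_lab[, ncol(mask)]))
  holes <- setdiff(unique(hole_lab[hole_lab > 0]), border)
  if (length(holes)) mask[hole_lab %in% holes] <- TRUE
  mask
}

#' Label connected components of a binary mask
#'
#' 4-connectivity, vectorized frontier expansion. Background is 0.
#'
#' @param mask logical matrix.
#' @return Integer matrix of component labels (1..n), 0 where `mask` is FALSE.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  todo <- which(mask)
  current <- 0L
  while (length(todo)) {
    seed <- todo[1L]
    current <- current + 1L
    frontier <- seed
    lab[seed] <- current
    while (length(frontier)) {
      up    <- frontier[(frontier - 1L) %% h != 0L] - 1L
      down  <- frontier[frontier %% h != 0L] + 1L
      left  <- frontier[frontier > h] - h
      right <- frontier[frontier <= h * (w - 1L)] + h
      nb <- c(up, down, left, right)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- current
      frontier <- nb
    }
    todo <- todo[lab[todo] == 0L]
  }
  lab
}

#' Mean RGB over a segmentation mask
#'
#' @param image H x W x 3 array (0-255).
#' @param mask logical H x W matrix with at least one `TRUE` pixel.
#' @return Named numeric triple (R, G, B), real-valued channel means.
#' @export
extract_mean_rgb <- function(image, mask) {
  .cp_check_image(image)
  if (!is.matrix(mask) || !is.logical(mask) ||
      !all(dim(mask) == dim(image)[1:2]))
    stop("mask must be a logical matrix matching the image size")
  if (!any(mask)) stop("empty mask: no foreground pixels to average")
  c(R = mean(image[, , 1][mask]),
    G = mean(image[, , 2][mask]),
    B = mean(image[, , 3][mask]))
}

#' Extract the pixel matrix under a mask
#'
#' Convenience for feeding masked pixels to [rgb_to_record()] so the
#' lightness index is computed per pixel.
#'
#' @inheritParams extract_mean_rgb
#' @return n x 3 matrix of foreground pixels.
#' @export
masked_pixels <- function(image, mask) {
  .cp_check_image(image)
  if (!any(mask)) stop("empty mask: no foreground pixels")
  cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
}

#' Average replicate colorimetric records
#'
#' Index-wise arithmetic mean over replicate records (the protocol captures
#' three images of six root pieces per genotype and averages the
#' measurements). Hue is averaged circularly via the mean resultant vector,
#' so e.g. 359 and 1 degrees average to 0, not 180. The polar identity
#' between the averaged chroma and the averaged (a*, b*) does not hold in
#' general after aggregation, so the result is built with `check = FALSE`.
#'
#' @param records list of [colorimetric_record()] objects (>= 1).
#' @return A [colorimetric_record()] with `n_replicates` set to the total.
#' @export
aggregate_replicates <- function(records) {
  if (!length(records)) stop("no records to aggregate")
  if (!all(vapply(records, inherits, logical(1), "cp_record")))
    stop("all elements must be colorimetric records")
  g <- function(f) mean(vapply(records, `[[`, numeric(1), f))
  hues <- vapply(records, `[[`, numeric(1), "hue") * pi / 180
  defined <- !vapply(records, `[[`, logical(1), "hue_undefined")
  if (any(defined)) {
    s <- mean(sin(hues[defined])); cmp <- mean(cos(hues[defined]))
    hue <- if (sqrt(s^2 + cmp^2) < 1e-12) 0 else (atan2(s, cmp) * 180 / pi) %% 360
    if (hue >= 360 - 1e-9) hue <- 0
    hue_undef <- sqrt(s^2 + cmp^2) < 1e-12
  } else {
    hue <- 0; hue_undef <- TRUE
  }
  colorimetric_record(
    L = g("L"), a = g("a"), b = g("b"), hue = hue,
    chroma = g("chroma"), lightness = g("lightness"),
    hue_undefined = hue_undef,
    n_replicates = sum(vapply(records, `[[`, integer(1), "n_replicates")),
    check = FALSE
  )
}

#' Write / read a grayscale or RGB image as PNG
#'
#' Thin wrappers around the png package (masks as 0/255 single channel).
#' Only needed when exchanging rasters on disk; the analysis itself works on
#' in-memory arrays.
#'
#' @param image H x W x 3 array (0-255) or logical mask.
#' @param path file path ending in .png.
#' @return `path`, invisibly (writer); array or logical matrix (reader).
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG I/O")
  if (is.logical(image)) {
    png::writePNG(matrix(as.numeric(image), nrow(image), ncol(image)), path)
  } else {
    .cp_check_image(image)
    png::writePNG(image / 255, path)
  }
  invisible(path)
}

#' @rdname write_image_png
#' @param as_mask logical; read as a 0/255 logical mask.
#' @export
read_image_png <- function(path, as_mask = FALSE) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG I/O")
  x <- png::readPNG(path)
  if (as_mask) {
    if (length(dim(x)) == 3L) x <- x[, , 1]
    return(x > 0.5)
  }
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3]
  x * 255
}
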