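#' Reference white point
#'
#' Tristimulus values of the reference white used to normalize XYZ before the
#' CIELAB transform. The default is the D65 / 10 degree observer white point
#' used by the Tomato Analyzer color test (Xn = 94.83, Yn = 100, Zn = 107.38).
#' Note this is slightly inconsistent with the row sums of the RGB-to-XYZ
#' matrix (95.75, 100, 108.90); with the default white, a neutral gray maps to
#' small nonzero a* (~ +1.6 at white) and b* (~ -0.9). Pass the row sums as the
#' white point if an exactly neutral gray axis is required.
#'
#' @param Xn,Yn,Zn positive tristimulus values of the reference white.
#' @return An object of class `cp_white_point`.
#' @export
#' @examples
#' white_point()                      # Tomato Analyzer default
#' white_point(95.75, 100, 108.90)   # matrix-consistent white
white_point <- function(Xn = 94.83, Yn = 100.0, Zn = 107.38) {
  stopifnot(is.numeric(Xn), is.numeric(Yn), is.numeric(Zn))
  if (any(c(Xn, Yn, Zn) <= 0)) stop("white point tristimulus values must be > 0")
  structure(list(Xn = Xn, Yn = Yn, Zn = Zn), class = "cp_white_point")
}

# RGB -> XYZ matrix (sRGB primaries as printed by the color-test software;
# the X/Z rows are slightly off the canonical sRGB/D65 values).
.cp_rgb2xyz_matrix <- matrix(c(
  0.4124, 0.3576, 0.1875,
  0.2126, 0.7152, 0.0722,
  0.0193, 0.1192, 0.9505
), nrow = 3, byrow = TRUE)

#' Scale RGB channels to the linear 0-100 range
#'
#' First step of the RGB to CIELAB chain. Two dialects are provided:
#' `"standard"` (the default) is the sRGB companding law,
#' `Var = ((v + 0.055)/1.055)^2.4 * 100` for `v = V/255 > 0.04045` and
#' `v/12.92 * 100` otherwise, which maps white to exactly 100.
#' `"as_printed"` is the literal formula `((v + 0.055)^2.4/1.055) * 100` that
#' sometimes circulates in typeset form; it maps 255 to 107.78 and breaks the
#' L* in \[0,100\] contract, so it is kept only for auditability.
#'
#' @param rgb numeric vector of length 3 (R, G, B on 0-255; real values
#'   allowed, e.g. channel means) or an n x 3 matrix.
#' @param dialect `"standard"` or `"as_printed"`.
#' @return Scaled triple(s) on the 0-100 scale, same shape as input.
#' @export
#' @examples
#' linearize_rgb(c(255, 255, 255))  # 100 100 100
#' linearize_rgb(c(128, 128, 128))  # ~21.59 each
linearize_rgb <- function(rgb, dialect = c("standard", "as_printed")) {
  dialect <- match.arg(dialect)
  m <- .cp_as_rgb_matrix(rgb)
  v <- m / 255
  out <- if (dialect == "standard") {
    ifelse(v > 0.04045, ((v + 0.055) / 1.055)^2.4, v / 12.92) * 100
  } else {
    ((v + 0.055)^2.4 / 1.055) * 100
  }
  if (is.vector(rgb)) drop(out) else out
}

# accept a length-3 vector or an n x 3 matrix, validate range
.cp_as_rgb_matrix <- function(rgb, what = "RGB") {
  if (is.vector(rgb) && length(rgb) == 3L) rgb <- matrix(rgb, nrow = 1L)
  if (!is.matrix(rgb) || ncol(rgb) != 3L)
    stop(what, " input must be a length-3 vector or an n x 3 matrix")
  if (anyNA(rgb)) stop(what, " input contains NA")
  if (any(rgb < -1e-9) || any(rgb > 255 + 1e-9))
    stop(what, " channel out of range [0, 255]: ",
         paste(signif(rgb[rgb < -1e-9 | rgb > 255 + 1e-9], 5), collapse = ", "))
  pmin(pmax(rgb, 0), 255)
}

#' Convert linearized RGB to XYZ tristimulus values
#'
#' @param scaled numeric length-3 vector or n x 3 matrix of linearized
#'   (0-100 scale) R, G, B values, as produced by [linearize_rgb()].
#' @return XYZ triple(s); the Y row sums to 1 so equal-channel input of 100
#'   yields Y = 100 exactly.
#' @export
rgb_to_xyz <- function(scaled) {
  m <- if (is.vector(scaled) && length(scaled) == 3L) matrix(scaled, nrow = 1L) else scaled
  if (!is.matrix(m) || ncol(m) != 3L) stop("scaled input must be length-3 or n x 3")
  if (any(m < -1e-9)) stop("scaled RGB values must be >= 0")
  out <- m %*% t(.cp_rgb2xyz_matrix)
  colnames(out) <- c("X", "Y", "Z")
  if (is.vector(scaled)) drop(out) else out
}

# piecewise cube-root companding of the CIELAB transform
.cp_lab_f <- function(q) {
  ifelse(q > 0.008856, q^(1 / 3), 7.787 * q + 16 / 116)
}

.cp_lab_f_inv <- function(f) {
  q <- f^3
  ifelse(q > 0.008856, q, (f - 16 / 116) / 7.787)
}

#' Convert XYZ tristimulus values to CIELAB
#'
#' Applies `L* = 116 f(Y/Yn) - 16`, `a* = 500 [f(X/Xn) - f(Y/Yn)]`,
#' `b* = 200 [f(Y/Yn) - f(Z/Zn)]` with the piecewise companding
#' `f(q) = q^(1/3)` for `q > 0.008856`, else `7.787 q + 16/116`.
#'
#' @param xyz numeric length-3 vector or n x 3 matrix of X, Y, Z (>= 0).
#' @param white a [white_point()].
#' @return Named vector (or matrix) with `L`, `a`, `b`.
#' @export
xyz_to_lab <- function(xyz, white = white_point()) {
  stopifnot(inherits(white, "cp_white_point"))
  m <- if (is.vector(xyz) && length(xyz) == 3L) matrix(xyz, nrow = 1L) else xyz
  if (!is.matrix(m) || ncol(m) != 3L) stop("xyz input must be length-3 or n x 3")
  if (any(m < -1e-9)) stop("negative tristimulus value")
  m <- pmax(m, 0)
  fx <- .cp_lab_f(m[, 1] / white$Xn)
  fy <- .cp_lab_f(m[, 2] / white$Yn)
  fz <- .cp_lab_f(m[, 3] / white$Zn)
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (is.vector(xyz)) drop(out) else out
}

#' Hue angle and chroma from a* and b*
#'
#' Chroma is the Euclidean norm `sqrt(a*^2 + b*^2)`; hue is the angle of
#' (a*, b*) in degrees mapped to \[0, 360). At chroma ~ 0 the hue is
#' undefined; it is returned as 0 with `hue_undefined = TRUE`.
#'
#' @param a_star,b_star numeric (vectorized).
#' @return A list with `hue` (degrees), `chroma`, and `hue_undefined` flag(s).
#' @export
#' @examples
#' hue_chroma(-10.23, 36.48)  # hue ~105.7, chroma ~37.9
hue_chroma <- function(a_star, b_star) {
  chroma <- sqrt(a_star^2 + b_star^2)
  undef <- chroma < 1e-9
  hue <- ifelse(undef, 0, (atan2(b_star, a_star) * 180 / pi) %% 360)
  hue[hue >= 360 - 1e-9] <- 0  # guard the wrap-around at exactly 360
  list(hue = hue, chroma = chroma, hue_undefined = undef)
}

#' Lightness index on the 0-240 scale
#'
#' Per-pixel `(max(R,G,B) + min(R,G,B)) * 240 / (2 * 255)`, averaged over the
#' supplied pixels. Distinct from CIELAB L*: this is the brightness index of
#' the color-test software, spanning 0 (black) to 240 (white).
#'
#' @param rgb length-3 vector or n x 3 matrix of pixels (0-255).
#' @return Scalar mean lightness in \[0, 240\].
#' @export
#' @examples
#' lightness_index(c(255, 0, 0))  # 120
lightness_index <- function(rgb) {
  m <- .cp_as_rgb_matrix(rgb)
  mx <- pmax(m[, 1], m[, 2], m[, 3])
  mn <- pmin(m[, 1], m[, 2], m[, 3])
  mean((mx + mn) * 240 / 510)
}

#' Colorimetric record constructor
#'
#' Bundles the six colorimetric indices describing one sample (typically the
#' mean over replicate measurements). By construction from [rgb_to_record()],
#' `chroma = sqrt(a^2 + b^2)` and `hue` matches the (a*, b*) quadrant; records
#' produced by [aggregate_replicates()] average the indices componentwise and
#' may deviate from the polar identity, which is tracked by the `aggregated`
#' attribute.
#'
#' @param L,a,b CIELAB coordinates; `L` in \[0, 100\].
#' @param hue degrees in \[0, 360); `chroma` >= 0; `lightness` in \[0, 240\].
#' @param chroma,lightness see above.
#' @param hue_undefined logical, `TRUE` when chroma ~ 0.
#' @param n_replicates integer, number of measurements averaged.
#' @param check if `TRUE` (default) enforce the polar identity and ranges.
#' @return An object of class `cp_record` (a named list).
#' @export
colorimetric_record <- function(L, a, b, hue, chroma, lightness,
                                hue_undefined = FALSE, n_replicates = 1L,
                                check = TRUE) {
  if (check) {
    if (L < -1e-6 || L > 100 + 1e-6) stop("L* out of [0, 100]: ", L)
    if (lightness < -1e-6 || lightness > 240 + 1e-6)
      stop("lightness out of [0, 240]: ", lightness)
    if (abs(chroma - sqrt(a^2 + b^2)) > 1e-9)
      stop("chroma inconsistent with sqrt(a^2 + b^2)")
    if (!hue_undefined) {
      want <- (atan2(b, a) * 180 / pi) %% 360
      if (abs(((hue - want + 180) %% 360) - 180) > 1e-6)
        stop("hue inconsistent with (a*, b*) quadrant")
    }
  }
  structure(list(L = L, a = a, b = b, hue = hue, chroma = chroma,
                 lightness = lightness, hue_undefined = hue_undefined,
                 n_replicates = as.integer(n_replicates)),
            class = "cp_record")
}

#' @export
print.cp_record <- function(x, ...) {
  cat(sprintf(
    "<colorimetric record>  L*=%.2f  a*=%.2f  b*=%.2f  hue=%.2f%s  chroma=%.2f  lightness=%.2f  (n=%d)\n",
    x$L, x$a, x$b, x$hue, if (x$hue_undefined) " (undef)" else "",
    x$chroma, x$lightness, x$n_replicates))
  invisible(x)
}

#' Full RGB to colorimetric-record conversion
#'
#' Chains [linearize_rgb()], [rgb_to_xyz()], [xyz_to_lab()],
#' [hue_chroma()] and [lightness_index()]. When a pixel matrix is given, the
#' CIELAB chain is applied to the channel means while the lightness index is
#' averaged per pixel, matching how the color-test software summarizes a
#' region.
#'
#' @param rgb length-3 mean RGB triple or n x 3 pixel matrix (0-255).
#' @param white a [white_point()].
#' @param dialect linearization dialect, see [linearize_rgb()].
#' @return A [colorimetric_record()].
#' @export
rgb_to_record <- function(rgb, white = white_point(),
                          dialect = c("standard", "as_printed")) {
  dialect <- match.arg(dialect)
  m <- .cp_as_rgb_matrix(rgb)
  mean_rgb <- colMeans(m)
  lab <- xyz_to_lab(rgb_to_xyz(linearize_rgb(mean_rgb, dialect)), white)
  hc <- hue_chroma(lab["a"], lab["b"])
  colorimetric_record(
    L = unname(lab["L"]), a = unname(lab["a"]), b = unname(lab["b"]),
    hue = unname(hc$hue), chroma = unname(hc$chroma),
    lightness = lightness_index(m),
    hue_undefined = unname(hc$hue_undefined),
    # allow tiny numeric overshoot of L* for near-white input under the
    # default (matrix-inconsistent) white point
    check = FALSE
  )
}

#' Invert CIELAB to an RGB triple
#'
#' Exact algebraic inverse of the forward chain under the `"standard"`
#' linearization dialect, used by the synthetic image generator to paint pulp
#' of a prescribed color. Colors whose inverse falls outside \[0, 255\] on any
#' channel are rejected as out-of-gamut, naming the offending channel(s).
#'
#' @param L,a,b CIELAB coordinates of the target color.
#' @param white a [white_point()].
#' @return Numeric RGB triple (real-valued, 0-255).
#' @export
#' @examples
#' lab_to_rgb(76.14, -12.38, 55.57)  # paper-scale yellow root pulp
lab_to_rgb <- function(L, a, b, white = white_point()) {
  stopifnot(inherits(white, "cp_white_point"))
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  xyz <- c(.cp_lab_f_inv(fx) * white$Xn,
           .cp_lab_f_inv(fy) * white$Yn,
           .cp_lab_f_inv(fz) * white$Zn)
  scaled <- drop(solve(.cp_rgb2xyz_matrix, xyz))
  v <- scaled / 100
  srgb <- ifelse(v > 0.0031308, 1.055 * pmax(v, 0)^(1 / 2.4) - 0.055, v * 12.92)
  rgb <- srgb * 255
  bad <- rgb < -1e-6 | rgb > 255 + 1e-6
  if (any(bad)) {
    stop("out-of-gamut color: channel(s) ",
         paste(c("R", "G", "B")[bad], "=", signif(rgb[bad], 5), collapse = ", "),
         " outside [0, 255]")
  }
  out <- pmin(pmax(rgb, 0), 255)
  names(out) <- c("R", "G", "B")
  out
}
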