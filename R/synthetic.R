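#' Cluster specification for the synthetic panel
#'
#' Describes one phenotypic group of the simulated germplasm panel: its size,
#' its mean total carotenoid content (TCC), the TCC standard deviation, and
#' the group-mean colorimetric indices around which colors are generated.
#'
#' @param cluster_id integer group label (1..K).
#' @param n_genotypes number of genotypes in the group (>= 2).
#' @param mean_tcc group mean TCC in ug/g fresh weight (> 0).
#' @param sd_tcc within-group TCC standard deviation (>= 0).
#' @param mean_L,mean_a,mean_b,mean_lightness group-mean colorimetric indices.
#' @param sd_color multiplier applied to the color model's noise sds for this
#'   group (default 1).
#' @return Object of class `cp_cluster_spec`.
#' @export
cluster_spec <- function(cluster_id, n_genotypes, mean_tcc, sd_tcc,
                         mean_L, mean_a, mean_b, mean_lightness,
                         sd_color = 1) {
  if (n_genotypes < 2) stop("n_genotypes must be >= 2")
  if (mean_tcc <= 0) stop("mean_tcc must be > 0")
  if (sd_tcc < 0 || sd_color < 0) stop("standard deviations must be >= 0")
  structure(list(cluster_id = as.integer(cluster_id),
                 n_genotypes = as.integer(n_genotypes),
                 mean_tcc = mean_tcc, sd_tcc = sd_tcc,
                 mean_L = mean_L, mean_a = mean_a, mean_b = mean_b,
                 mean_lightness = mean_lightness, sd_color = sd_color),
            class = "cp_cluster_spec")
}

#' Default five-group panel specification
#'
#' The printed structure of the 228-genotype biofortified panel: groups of
#' 76/34/26/21/71 genotypes with mean TCC 1.91/1.82/4.82/10.74/3.60 ug/g and
#' the published group-mean colorimetric indices where available. Groups 1
#' and 2 have no published color means ("low b*, highest L*, lightness and
#' hue"); their means, and all within-group standard deviations, are package
#' defaults calibrated so that the generated panel reproduces the published
#' marginal correlations (see the methods vignette for the algebra).
#'
#' @return List of five [cluster_spec()] objects.
#' @export
default_cluster_specs <- function() {
  list(
    cluster_spec(1L, 76L, 1.91, 0.70, mean_L = 79.5, mean_a = -6.5,
                 mean_b = 17.0, mean_lightness = 182.0),
    cluster_spec(2L, 34L, 1.82, 0.65, mean_L = 79.5, mean_a = -4.0,
                 mean_b = 21.0, mean_lightness = 185.0),
    cluster_spec(3L, 26L, 4.82, 1.00, mean_L = 78.60, mean_a = -10.23,
                 mean_b = 36.48, mean_lightness = 158.5),
    cluster_spec(4L, 21L, 10.74, 1.40, mean_L = 76.14, mean_a = -12.38,
                 mean_b = 55.57, mean_lightness = 136.04),
    cluster_spec(5L, 71L, 3.60, 0.90, mean_L = 73.10, mean_a = -4.60,
                 mean_b = 22.20, mean_lightness = 158.8)
  )
}

#' TCC-to-color generative model
#'
#' Within each group, b*, a* and L* are affine in TCC (deviation from the
#' group mean) with independent Gaussian noise; the 0-240 lightness index is
#' affine in TCC and L* with noise. Default slopes are the least-squares fit
#' through the published group means; default noise standard deviations are
#' derived in closed form so that, under [default_cluster_specs()], the panel
#' correlations are r(TCC,b*) = 0.90, r(TCC,a*) = -0.50,
#' r(TCC,lightness) = -0.66 and r(TCC,L*) ~ 0 (non-significant).
#'
#' @param slope_b,noise_sd_b b* units per ug/g, and residual sd (b* units).
#' @param slope_a,noise_sd_a idem for a*.
#' @param slope_L,noise_sd_L idem for L*.
#' @param slope_lightness lightness units per ug/g (within group).
#' @param coef_lightness_L lightness units per L* unit (within group).
#' @param noise_sd_lightness residual sd of lightness.
#' @return Object of class `cp_color_model`.
#' @export
color_model <- function(slope_b = 4.213, noise_sd_b = 4.7,
                        slope_a = -0.859, noise_sd_a = 3.3,
                        slope_L = 0.4, noise_sd_L = 5.0,
                        slope_lightness = -5.0, coef_lightness_L = 1.0,
                        noise_sd_lightness = 14.0) {
  if (slope_b <= 0) stop("slope_b must be > 0 (carotenoids raise yellowness)")
  sds <- c(noise_sd_b, noise_sd_a, noise_sd_L, noise_sd_lightness)
  if (any(sds < 0)) stop("noise sds must be >= 0")
  structure(list(slope_b = slope_b, noise_sd_b = noise_sd_b,
                 slope_a = slope_a, noise_sd_a = noise_sd_a,
                 slope_L = slope_L, noise_sd_L = noise_sd_L,
                 slope_lightness = slope_lightness,
                 coef_lightness_L = coef_lightness_L,
                 noise_sd_lightness = noise_sd_lightness),
            class = "cp_color_model")
}

#' Generate a synthetic phenotype table
#'
#' Draws one row per genotype: TCC from a per-group Gaussian truncated below
#' at 0.05 ug/g, colors from the TCC-to-color model around the group means,
#' chroma and hue computed (never drawn) from a* and b*, and the true group
#' label recorded in `cluster`.
#'
#' @param specs list of [cluster_spec()] (default: the five-group panel).
#' @param model a [color_model()].
#' @param seed integer seed; identical seeds give identical tables.
#' @param noise_scale multiplier on all standard deviations (TCC and color);
#'   1 = the calibrated default world, small values give an almost
#'   noise-free table useful for recovery tests.
#' @return data.frame of class `cp_phenotype` with columns
#'   `genotype, tcc, L, a, b, hue, chroma, lightness, cluster`.
#' @export
#' @examples
#' tab <- generate_phenotype_table(seed = 1)
#' nrow(tab)                 # 228
#' cor(tab$tcc, tab$b)       # ~0.90
generate_phenotype_table <- function(specs = default_cluster_specs(),
                                     model = color_model(), seed = 1L,
                                     noise_scale = 1) {
  if (!length(specs)) stop("specs must be a non-empty list of cluster specs")
  if (!all(vapply(specs, inherits, logical(1), "cp_cluster_spec")))
    stop("specs must be cluster_spec objects")
  stopifnot(inherits(model, "cp_color_model"), noise_scale >= 0)
  set.seed(as.integer(seed))
  rows <- lapply(specs, function(s) {
    n <- s$n_genotypes
    cs <- s$sd_color * noise_scale
    tcc <- pmax(0.05, stats::rnorm(n, s$mean_tcc, s$sd_tcc * noise_scale))
    d <- tcc - s$mean_tcc
    b <- s$mean_b + model$slope_b * d + stats::rnorm(n, 0, model$noise_sd_b * cs)
    a <- s$mean_a + model$slope_a * d + stats::rnorm(n, 0, model$noise_sd_a * cs)
    L <- s$mean_L + model$slope_L * d + stats::rnorm(n, 0, model$noise_sd_L * cs)
    L <- pmin(pmax(L, 0), 100)
    light <- s$mean_lightness + model$slope_lightness * d +
      model$coef_lightness_L * (L - s$mean_L) +
      stats::rnorm(n, 0, model$noise_sd_lightness * cs)
    light <- pmin(pmax(light, 0), 240)
    hc <- hue_chroma(a, b)
    data.frame(tcc = tcc, L = L, a = a, b = b, hue = hc$hue,
               chroma = hc$chroma, lightness = light,
               cluster = s$cluster_id)
  })
  out <- do.call(rbind, rows)
  out <- cbind(genotype = sprintf("GEN%03d", seq_len(nrow(out))), out)
  class(out) <- c("cp_phenotype", "data.frame")
  rownames(out) <- NULL
  out
}

#' Generate a labeled synthetic root-slice image
#'
#' Paints `n_pieces` elliptical root slices of the pulp color obtained by
#' inverting the colorimetry chain from the target record's (L*, a*, b*),
#' with per-pixel Gaussian jitter, on a saturated blue background emulating
#' the liner of the phenotyping box. The ground-truth mask and generating
#' record are stored for segmentation and color-recovery tests.
#'
#' @param record a [colorimetric_record()]; must be in-gamut.
#' @param n_pieces number of slices (>= 1, default 6 as in the protocol).
#' @param width,height raster size in pixels (default 272 x 204, a 1/12-scale
#'   version of the native 3264 x 2448 capture).
#' @param jitter_sd per-pixel Gaussian color jitter sd on the pulp, in
#'   channel units (default 6).
#' @param background RGB triple of the liner (default saturated blue).
#' @param background_jitter_sd jitter sd on the background (default 8).
#' @param seed integer seed.
#' @return Object of class `cp_image`: list with `pixels` (H x W x 3 integer
#'   array, 0-255), `truth_mask`, `truth_record`, `background_color`, `seed`.
#' @export
generate_root_image <- function(record, n_pieces = 6L, width = 272L,
                                height = 204L, jitter_sd = 6,
                                background = c(25, 60, 230),
                                background_jitter_sd = 8, seed = 1L) {
  stopifnot(inherits(record, "cp_record"), n_pieces >= 1)
  pulp <- lab_to_rgb(record$L, record$a, record$b)  # errors if out-of-gamut
  set.seed(as.integer(seed))
  h <- as.integer(height); w <- as.integer(width)
  cols <- min(n_pieces, 3L)
  rows <- ceiling(n_pieces / cols)
  rx <- floor(w / (2 * cols) * 0.7)
  ry <- floor(h / (2 * rows) * 0.7)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  mask <- matrix(FALSE, h, w)
  for (p in seq_len(n_pieces)) {
    ci <- (p - 1L) %% cols
    ri <- (p - 1L) %/% cols
    cx <- (ci + 0.5) * w / cols
    cy <- (ri + 0.5) * h / rows
    mask <- mask | (((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1)
  }
  n_px <- h * w
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    plane <- matrix(background[ch] + stats::rnorm(n_px, 0, background_jitter_sd),
                    h, w)
    nfg <- sum(mask)
    plane[mask] <- pulp[ch] + stats::rnorm(nfg, 0, jitter_sd)
    img[, , ch] <- pmin(pmax(round(plane), 0), 255)
  }
  structure(list(pixels = img, truth_mask = mask, truth_record = record,
                 background_color = background, seed = as.integer(seed)),
            class = "cp_image")
}

#' @export
print.cp_image <- function(x, ...) {
  cat(sprintf("<synthetic root image> %d x %d px, %d foreground px, seed %d\n",
              dim(x$pixels)[1], dim(x$pixels)[2], sum(x$truth_mask), x$seed))
  invisible(x)
}

#' Generate a batch of synthetic assay records
#'
#' Inverts the TCC formula: `A = TCC * E * P / (V * 1e4)`, optionally with
#' Gaussian absorbance noise (truncated at 0). With zero noise,
#' [compute_tcc()] on the result returns the inputs exactly.
#'
#' @param tcc_values TCC values in ug/g (>= 0).
#' @param weights sample weights in g (recycled).
#' @param volumes extract volumes in mL (recycled).
#' @param noise_sd absorbance noise sd (default 0).
#' @param extinction extinction coefficient (default 2592).
#' @param seed integer seed.
#' @return List of [assay_sample()] objects.
#' @export
generate_assay_batch <- function(tcc_values, weights = 10, volumes = 50,
                                 noise_sd = 0, extinction = 2592, seed = 1L) {
  if (any(tcc_values < 0)) stop("negative TCC values are not allowed")
  if (any(weights <= 0) || any(volumes <= 0))
    stop("weights and volumes must be > 0")
  n <- length(tcc_values)
  weights <- rep_len(weights, n)
  volumes <- rep_len(volumes, n)
  set.seed(as.integer(seed))
  eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  lapply(seq_len(n), function(i) {
    A <- max(0, tcc_values[i] * extinction * weights[i] / (volumes[i] * 1e4) + eps[i])
    assay_sample(A, volumes[i], weights[i], extinction,
                 genotype = sprintf("GEN%03d", i))
  })
}

#' Colorimetric record of a cluster's mean color
#'
#' Convenience: turn a [cluster_spec()]'s mean indices into a full record
#' (hue and chroma computed from the mean a*, b*), e.g. to drive
#' [generate_root_image()].
#'
#' @param spec a [cluster_spec()].
#' @return A [colorimetric_record()].
#' @export
cluster_mean_record <- function(spec) {
  stopifnot(inherits(spec, "cp_cluster_spec"))
  hc <- hue_chroma(spec$mean_a, spec$mean_b)
  colorimetric_record(spec$mean_L, spec$mean_a, spec$mean_b,
                      hue = hc$hue, chroma = hc$chroma,
                      lightness = spec$mean_lightness,
                      hue_undefined = hc$hue_undefined)
}
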