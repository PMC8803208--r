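# Shared fixtures, all generated in code.

cp_features <- c("L", "a", "b", "hue", "chroma", "lightness")

# a flat image of one color
flat_image <- function(rgb, h = 20, w = 30) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# the paper-scale group mean records (group 3 and group 4 pulp colors)
group3_record <- function() {
  hc <- hue_chroma(-10.23, 36.48)
  colorimetric_record(78.60, -10.23, 36.48, hc$hue, hc$chroma, 158.5)
}
group4_record <- function() {
  hc <- hue_chroma(-12.38, 55.57)
  colorimetric_record(76.14, -12.38, 55.57, hc$hue, hc$chroma, 136.04)
}

# gray record derived from an actual gray pixel, guaranteed in-gamut
gray_record <- function(v = 128) rgb_to_record(c(v, v, v))

# a one-cluster table (no group structure)
blob_table <- function(n = 120, seed = 2, noise_scale = 1) {
  generate_phenotype_table(
    list(cluster_spec(1L, n, 3, 1, mean_L = 75, mean_a = -5, mean_b = 20,
                      mean_lightness = 170)),
    seed = seed, noise_scale = noise_scale)
}

# small benchmark model list: RF trimmed for runtime (default is 500 trees)
bench_models <- function(ids = cp_models(), ntree = 150) {
  lapply(ids, function(id)
    if (id == "RF") model_spec("RF", list(ntree = ntree)) else model_spec(id))
}
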