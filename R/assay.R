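#' Spectrophotometric assay sample
#'
#' One absorbance reading at 450 nm together with the extract volume, sample
#' fresh weight, and the extinction coefficient of beta-carotene in petroleum
#' ether (A 1cm 1% = 2592).
#'
#' @param absorbance dimensionless absorbance at 450 nm (>= 0).
#' @param volume total extract volume in mL (> 0).
#' @param weight sample fresh weight in g (> 0).
#' @param extinction extinction coefficient (> 0, default 2592).
#' @param genotype optional genotype id.
#' @return Object of class `cp_assay`.
#' @export
assay_sample <- function(absorbance, volume, weight, extinction = 2592,
                         genotype = NA_character_) {
  if (!is.numeric(absorbance) || absorbance < 0) stop("absorbance must be >= 0")
  if (!is.numeric(volume) || volume <= 0) stop("volume must be > 0 mL")
  if (!is.numeric(weight) || weight <= 0) stop("weight must be > 0 g")
  if (!is.numeric(extinction) || extinction <= 0) stop("extinction must be > 0")
  structure(list(absorbance = absorbance, volume = volume, weight = weight,
                 extinction = extinction, genotype = genotype),
            class = "cp_assay")
}

#' Total carotenoid content from absorbance
#'
#' `TCC (ug/g) = A * V * 1e4 / (E * P)` with `A` the absorbance at 450 nm,
#' `V` the extract volume (mL), `P` the sample weight (g) and `E` the
#' extinction coefficient of beta-carotene in petroleum ether (2592). Linear
#' in `A` and `V`, inverse in `P`.
#'
#' @param sample a [assay_sample()], or a list of them (duplicates per
#'   genotype are averaged).
#' @return TCC in micrograms per gram fresh weight (scalar).
#' @export
#' @examples
#' compute_tcc(assay_sample(0.2592, 50, 10))  # 5.0
compute_tcc <- function(sample) {
  if (inherits(sample, "cp_assay")) sample <- list(sample)
  if (!length(sample) || !all(vapply(sample, inherits, logical(1), "cp_assay")))
    stop("sample must be an assay sample or a list of them")
  one <- function(s) s$absorbance * s$volume * 1e4 / (s$extinction * s$weight)
  mean(vapply(sample, one, numeric(1)))
}

#' Batch TCC from a table of assay records
#'
#' @param df data.frame with columns `genotype`, `absorbance`, `volume_ml`,
#'   `weight_g` and optionally `extinction`. Duplicate rows per genotype are
#'   averaged after conversion.
#' @return data.frame `genotype`, `tcc`.
#' @export
compute_tcc_table <- function(df) {
  need <- c("genotype", "absorbance", "volume_ml", "weight_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing assay columns: ", paste(miss, collapse = ", "))
  ext <- if ("extinction" %in% names(df)) df$extinction else rep(2592, nrow(df))
  tcc <- df$absorbance * df$volume_ml * 1e4 / (ext * df$weight_g)
  out <- aggregate(tcc, list(genotype = df$genotype), mean)
  names(out)[2] <- "tcc"
  out
}
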