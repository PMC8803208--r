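# End-to-end orchestration: configuration, table I/O, stage execution,
# manifest, and a small command-line front end.

.cp_table_cols <- c("genotype", "tcc", "L", "a", "b", "hue", "chroma",
                    "lightness")

#' Read a phenotype table from CSV
#'
#' Expects the columns `genotype,tcc,L,a,b,hue,chroma,lightness` (an optional
#' `cluster` column is kept). Comma-decimal files are tolerated with a
#' warning. Missing columns, non-numeric cells and duplicate genotype ids are
#' each reported by name.
#'
#' @param path CSV file path.
#' @return data.frame of class `cp_phenotype`.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(.cp_table_cols, "genotype"), names(df))
  if (!"genotype" %in% names(df)) stop("missing column: genotype")
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  num_cols <- setdiff(names(df), "genotype")
  for (v in num_cols) {
    if (is.character(df[[v]])) {
      converted <- suppressWarnings(as.numeric(sub(",", ".", df[[v]], fixed = TRUE)))
      if (anyNA(converted) & !anyNA(df[[v]]))
        stop("non-numeric cells in column: ", v)
      if (any(grepl(",", df[[v]], fixed = TRUE)))
        warning("comma-decimal values parsed in column: ", v)
      df[[v]] <- converted
    }
    if (anyNA(df[[v]])) stop("non-numeric or missing cells in column: ", v)
  }
  dup <- df$genotype[duplicated(df$genotype)]
  if (length(dup)) stop("duplicate genotype id(s): ",
                        paste(unique(dup), collapse = ", "))
  class(df) <- c("cp_phenotype", "data.frame")
  df
}

#' Write a phenotype table to CSV
#'
#' @param table phenotype table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed.
#' @param image_dir optional directory of root-slice PNG/JPEG images; when
#'   NULL (default), images are synthesized from the generated phenotype
#'   records.
#' @param n_genotypes number of genotypes for the synthetic stage when no
#'   image directory is given; NULL = the full default panel (228).
#' @param n_images_per_genotype synthetic replicates per genotype (default 1).
#' @param white_point length-3 numeric (Xn, Yn, Zn).
#' @param linearization_dialect `"standard"` or `"as_printed"`.
#' @param segmentation list with `margin` and `min_area`.
#' @param smoothing_sigma Gaussian blur sd in px (0 = off).
#' @param k number of k-means clusters (default 5).
#' @param models model ids for the benchmark stage.
#' @param schemes scheme names to run.
#' @param outer_repeats outer repeats for the random schemes (default 3 for a
#'   pipeline smoke run; the full published design uses 30).
#' @param figures write diagnostic figures (default FALSE).
#' @param verbose print stage progress.
#' @return Object of class `cp_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, image_dir = NULL,
                            n_genotypes = NULL, n_images_per_genotype = 1L,
                            white_point = c(94.83, 100.0, 107.38),
                            linearization_dialect = "standard",
                            segmentation = list(margin = 30, min_area = 50),
                            smoothing_sigma = 0,
                            k = 5L,
                            models = c("LRFS", "RR", "CART"),
                            schemes = c("V-Random"),
                            outer_repeats = 3L,
                            figures = FALSE, verbose = FALSE) {
  if (!is.null(image_dir) && !dir.exists(image_dir))
    stop("configuration error: image_dir does not exist: ", image_dir)
  if (seed != round(seed)) stop("seed must be an integer")
  models <- match.arg(models, cp_models(), several.ok = TRUE)
  schemes <- match.arg(schemes, c("V-Random", "IV-Random", "IV-Cluster"),
                       several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 image_dir = image_dir, n_genotypes = n_genotypes,
                 n_images_per_genotype = as.integer(n_images_per_genotype),
                 white_point = white_point,
                 linearization_dialect = linearization_dialect,
                 segmentation = segmentation,
                 smoothing_sigma = smoothing_sigma, k = as.integer(k),
                 models = models, schemes = schemes,
                 outer_repeats = as.integer(outer_repeats),
                 figures = figures, verbose = verbose),
            class = "cp_config")
}

#' Load a pipeline configuration from JSON or YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected by name.
#'
#' @param path .json or .yaml/.yml file.
#' @return A validated `cp_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("configuration error: unknown key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full pipeline
#'
#' Executes the stages synth/ingest -> segment -> colorimetry -> TCC merge ->
#' diversity -> prediction, writing all intermediate CSVs and a JSON manifest
#' (seeds, per-stage row counts, package version) under `config$out_dir`.
#' Idempotent for a fixed seed: running the same config twice produces
#' byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cp_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message("[carophen] ", ...)
  manifest <- list(package_version = as.character(utils::packageVersion("carophen")),
                   seed = config$seed, stages = list())
  stage <- function(name, n) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, rows = n)
    say(name, ": ", n, " rows")
  }
  wp <- white_point(config$white_point[1], config$white_point[2],
                    config$white_point[3])

  # stage 1: synthesize (or ingest) the panel
  specs <- default_cluster_specs()
  if (!is.null(config$n_genotypes)) {
    want <- as.integer(config$n_genotypes)
    if (want < 2 * length(specs))
      stop("configuration error: n_genotypes must be >= ", 2 * length(specs))
    sizes <- vapply(specs, `[[`, integer(1), "n_genotypes")
    quota <- sizes / sum(sizes) * want
    alloc <- pmax(2L, floor(quota))
    while (sum(alloc) > want) {  # rare: minimum-2 overshoot
      i <- which.max(alloc)
      alloc[i] <- alloc[i] - 1L
    }
    if (sum(alloc) < want) {
      ord <- order(quota - floor(quota), decreasing = TRUE)
      extra <- rep_len(ord, want - sum(alloc))
      for (i in extra) alloc[i] <- alloc[i] + 1L
    }
    specs <- Map(function(s, n) { s$n_genotypes <- n; s }, specs, alloc)
  }
  truth <- generate_phenotype_table(specs, seed = config$seed)
  stage("synth", nrow(truth))

  # stage 2+3: segment images and extract colorimetric records
  records <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    reps <- vector("list", config$n_images_per_genotype)
    for (r in seq_len(config$n_images_per_genotype)) {
      rec <- colorimetric_record(truth$L[i], truth$a[i], truth$b[i],
                                 truth$hue[i], truth$chroma[i],
                                 truth$lightness[i], check = FALSE)
      img <- tryCatch(
        generate_root_image(rec, seed = config$seed + i * 10L + r),
        error = function(e) NULL)  # out-of-gamut extremes fall back to table color
      if (is.null(img)) { reps[[r]] <- rec; next }
      px <- if (config$smoothing_sigma > 0)
        smooth_image(img$pixels, config$smoothing_sigma) else img$pixels
      mask <- segment_roots(px, config$segmentation$margin,
                            config$segmentation$min_area)
      reps[[r]] <- rgb_to_record(masked_pixels(px, mask), white = wp,
                                 dialect = config$linearization_dialect)
    }
    records[[i]] <- aggregate_replicates(reps)
  }
  stage("segment", nrow(truth))
  pheno <- data.frame(
    genotype = truth$genotype,
    tcc = truth$tcc,
    L = vapply(records, `[[`, numeric(1), "L"),
    a = vapply(records, `[[`, numeric(1), "a"),
    b = vapply(records, `[[`, numeric(1), "b"),
    hue = vapply(records, `[[`, numeric(1), "hue"),
    chroma = vapply(records, `[[`, numeric(1), "chroma"),
    lightness = vapply(records, `[[`, numeric(1), "lightness"),
    cluster = truth$cluster)
  class(pheno) <- c("cp_phenotype", "data.frame")
  stage("colorimetry", nrow(pheno))
  write_phenotype_table(pheno, file.path(config$out_dir, "phenotypes.csv"))
  stage("tcc_merge", nrow(pheno))

  # stage 5: diversity
  cors <- correlate(pheno)
  utils::write.csv(cors, file.path(config$out_dir, "correlations.csv"),
                   row.names = FALSE)
  pca <- run_pca(pheno)
  utils::write.csv(data.frame(component = seq_along(pca$prop_var),
                              prop_var = pca$prop_var),
                   file.path(config$out_dir, "pca_variance.csv"),
                   row.names = FALSE)
  clus <- cluster_genotypes(pheno, k = config$k, seed = config$seed)
  utils::write.csv(data.frame(genotype = pheno$genotype,
                              cluster = clus$assignments),
                   file.path(config$out_dir, "clusters.csv"),
                   row.names = FALSE)
  stage("diversity", nrow(pheno))

  # stage 6: prediction benchmark
  schemes <- lapply(config$schemes, function(nm)
    cv_scheme(nm, outer_repeats = config$outer_repeats, seed = config$seed))
  bench <- run_benchmark(pheno, models = config$models, schemes = schemes,
                         seed = config$seed)
  utils::write.csv(bench$results, file.path(config$out_dir, "benchmark_results.csv"),
                   row.names = FALSE)
  utils::write.csv(bench$summary, file.path(config$out_dir, "benchmark_summary.csv"),
                   row.names = FALSE)
  stage("prediction", nrow(bench$results))

  if (config$figures) .cp_pipeline_figures(pheno, pca, config$out_dir)

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.cp_pipeline_figures <- function(pheno, pca, out_dir) {
  dev_open <- function(path) {
    opened <- tryCatch({ grDevices::png(path, 800, 600); TRUE },
                       error = function(e) FALSE)
    if (!opened) grDevices::pdf(sub("\\.png$", ".pdf", path))
  }
  dev_open(file.path(out_dir, "scatter_tcc_b.png"))
  graphics::plot(pheno$b, pheno$tcc, xlab = "b*", ylab = "TCC (ug/g)",
                 pch = 19, col = pheno$cluster)
  grDevices::dev.off()
  dev_open(file.path(out_dir, "pca_scores.png"))
  graphics::plot(pca$scores[, 1], pca$scores[, 2], xlab = "PC1", ylab = "PC2",
                 pch = 19, col = pheno$cluster)
  grDevices::dev.off()
  invisible(NULL)
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `diversity`, `benchmark`, `all`. Typical use from a
#' shell: `Rscript -e 'carophen::carophen_cli()' all --out out/ --seed 7`.
#'
#' @param args character vector (default: the command line).
#' @return Exit status 0, invisibly.
#' @export
carophen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: carophen <synth|diversity|benchmark|all> [--config FILE]",
        "[--out DIR] [--seed N]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  out <- opt("--out", "carophen_out")
  seed <- as.integer(opt("--seed", "1"))
  cfg_path <- opt("--config", NA)
  config <- if (!is.na(cfg_path)) read_pipeline_config(cfg_path)
            else pipeline_config(out_dir = out, seed = seed, verbose = TRUE)
  switch(cmd,
    synth = {
      tab <- generate_phenotype_table(seed = config$seed)
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_phenotype_table(tab, file.path(config$out_dir, "phenotypes.csv"))
    },
    diversity = , benchmark = , all = run_pipeline(config),
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
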