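# Diversity analyses of a phenotype table: pairwise correlation, PCA,
# k-means with elbow diagnostics, and Tukey group contrasts.

.cp_pheno_vars <- c("tcc", "L", "a", "b", "hue", "chroma", "lightness")

.cp_numeric_table <- function(table, vars = NULL) {
  if (is.null(vars))
    vars <- intersect(.cp_pheno_vars, names(table))
  miss <- setdiff(vars, names(table))
  if (length(miss)) stop("missing variables: ", paste(miss, collapse = ", "))
  as.data.frame(table)[, vars, drop = FALSE]
}

#' Pairwise Pearson correlations of a phenotype table
#'
#' Pearson r with two-sided p-values for every pair of numeric phenotype
#' variables; rows with missing values are dropped pairwise. Constant columns
#' are flagged as undefined rather than returned as silent NaN.
#'
#' @param table a phenotype table (see [generate_phenotype_table()]).
#' @param vars variables to correlate (default: TCC plus the six indices).
#' @return data.frame of class `cp_correlation` with columns
#'   `var1, var2, r, p, n, undefined`.
#' @export
correlate <- function(table, vars = NULL) {
  df <- .cp_numeric_table(table, vars)
  v <- names(df)
  out <- list()
  for (i in seq_along(v)) for (j in seq_along(v)) {
    if (j <= i) next
    x <- df[[i]]; y <- df[[j]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (sum(ok) < 3) stop("fewer than 3 complete rows for pair ", v[i], "/", v[j])
    undef <- stats::sd(x) == 0 || stats::sd(y) == 0
    if (undef) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x, y)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      var1 = v[i], var2 = v[j], r = r, p = p, n = sum(ok), undefined = undef)
  }
  res <- do.call(rbind, out)
  class(res) <- c("cp_correlation", "data.frame")
  res
}

#' Principal component analysis of a phenotype table
#'
#' Eigen-decomposition of the correlation matrix (`standardize = TRUE`, the
#' default — mixing ug/g with a 0-240 lightness index otherwise lets one
#' scale dominate) or the covariance matrix.
#'
#' @param table phenotype table.
#' @param standardize scale variables to unit variance first (default TRUE).
#' @param vars variables to use.
#' @return Object of class `cp_pca`: list with `loadings` (variables x PCs),
#'   `scores` (genotypes x PCs), `prop_var`, and the underlying `prcomp` fit.
#' @export
run_pca <- function(table, standardize = TRUE, vars = NULL) {
  df <- .cp_numeric_table(table, vars)
  if (ncol(df) < 2 || nrow(df) < 3) stop("PCA needs >= 2 variables and >= 3 rows")
  zero <- vapply(df, function(x) stats::sd(x) == 0, logical(1))
  if (any(zero))
    stop("zero-variance column(s): ", paste(names(df)[zero], collapse = ", "))
  fit <- stats::prcomp(df, center = TRUE, scale. = standardize)
  pv <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(loadings = fit$rotation, scores = fit$x,
                 prop_var = pv, prcomp = fit),
            class = "cp_pca")
}

#' @export
print.cp_pca <- function(x, ...) {
  cat("<PCA>", length(x$prop_var), "components; variance explained:",
      paste0(round(100 * x$prop_var[1:min(3, length(x$prop_var))], 1), "%",
             collapse = ", "), "...\n")
  invisible(x)
}

#' Within-group sum of squares across k (elbow curve)
#'
#' Runs k-means with multiple restarts for k = 1..k_max on the standardized
#' variables and reports the total within-group sum of squares, together with
#' a simple knee diagnostic: the largest discrete curvature of the curve
#' relative to the total sum of squares. Curves without a pronounced knee
#' (e.g. one homogeneous blob) are flagged.
#'
#' @param table phenotype table.
#' @param k_max largest k (must be < number of rows).
#' @param seed integer seed.
#' @param restarts k-means restarts per k (default 25).
#' @param vars variables to use.
#' @return Object of class `cp_elbow`: data.frame `k, wss` plus attributes
#'   `knee` (k at maximal curvature) and `no_clear_elbow` (logical).
#' @export
elbow_curve <- function(table, k_max = 10, seed = 1L, restarts = 25,
                        vars = NULL) {
  df <- .cp_numeric_table(table, vars)
  if (k_max < 1) stop("k_max must be >= 1")
  if (k_max >= nrow(df)) stop("k_max must be < number of rows")
  X <- scale(as.matrix(df))
  set.seed(as.integer(seed))
  wss <- numeric(k_max)
  for (k in seq_len(k_max)) {
    km <- stats::kmeans(X, k, nstart = restarts, iter.max = 50)
    # guard monotonicity against unlucky restarts
    if (k > 1 && km$tot.withinss > wss[k - 1] + 1e-8)
      km <- stats::kmeans(X, k, nstart = restarts * 4, iter.max = 100)
    wss[k] <- km$tot.withinss
  }
  out <- data.frame(k = seq_len(k_max), wss = wss)
  if (k_max >= 3) {
    drops <- -diff(wss)                      # length k_max - 1
    curv <- drops[-length(drops)] - drops[-1] # curvature at k = 2..k_max-1
    knee <- which.max(curv) + 1L
    strength <- max(curv) / wss[1]
    attr(out, "knee") <- knee
    # 0.08 separates isotropic noise (~0.04) from genuinely clustered
    # tables (>= 0.12) across generator settings
    attr(out, "no_clear_elbow") <- strength < 0.08
  } else {
    attr(out, "knee") <- NA_integer_
    attr(out, "no_clear_elbow") <- NA
  }
  class(out) <- c("cp_elbow", "data.frame")
  out
}

#' K-means clustering of genotypes
#'
#' Best-of-restarts k-means on standardized variables (or on PCA scores).
#' Cluster labels are canonicalized by descending mean TCC, so cluster 1 is
#' always the highest-TCC group regardless of k-means' arbitrary numbering.
#'
#' @param table phenotype table.
#' @param k number of clusters (1 <= k <= n).
#' @param seed integer seed.
#' @param restarts number of random restarts (default 25).
#' @param on `"variables"` (default) or `"pca"` to cluster PCA scores.
#' @param vars variables to use.
#' @return Object of class `cp_cluster`: list with `k`, `assignments`,
#'   `centroids` (on the original scale), `tot_withinss`, `sizes`, `seed`.
#' @export
cluster_genotypes <- function(table, k = 5, seed = 1L, restarts = 25,
                              on = c("variables", "pca"), vars = NULL) {
  on <- match.arg(on)
  df <- .cp_numeric_table(table, vars)
  if (k < 1 || k > nrow(df)) stop("k must be between 1 and the number of rows")
  X <- scale(as.matrix(df))
  if (on == "pca") X <- stats::prcomp(X)$x
  set.seed(as.integer(seed))
  if (k == nrow(df)) {  # trivial partition: one genotype per cluster
    km <- list(cluster = seq_len(k), tot.withinss = 0)
  } else {
    km <- NULL
    for (try in 1:5) {  # restart internally if an empty cluster persists
      km <- tryCatch(stats::kmeans(X, k, nstart = restarts, iter.max = 100),
                     error = function(e) NULL)
      if (!is.null(km)) break
    }
    if (is.null(km)) stop("k-means failed repeatedly (empty cluster?)")
  }
  # canonicalize: cluster 1 = highest mean TCC
  key <- if ("tcc" %in% names(df)) df$tcc else df[[1]]
  means <- tapply(key, km$cluster, mean)
  ord <- order(means, decreasing = TRUE)
  relabel <- integer(k); relabel[as.integer(names(means))[ord]] <- seq_len(k)
  assignments <- relabel[km$cluster]
  centroids <- apply(df, 2, function(col) tapply(col, assignments, mean))
  structure(list(k = k, assignments = assignments,
                 centroids = centroids, tot_withinss = km$tot.withinss,
                 sizes = as.integer(table(assignments)), seed = as.integer(seed)),
            class = "cp_cluster")
}

#' @export
print.cp_cluster <- function(x, ...) {
  cat("<k-means clustering> k =", x$k, "; sizes (by descending TCC):",
      paste(x$sizes, collapse = "/"),
      "; within-SS =", signif(x$tot_withinss, 5), "\n")
  invisible(x)
}

#' Rand index between two partitions
#'
#' Proportion of agreeing pairs; label-permutation invariant. Used to score
#' recovery of generator truth labels.
#'
#' @param a,b integer label vectors of equal length.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  same_a <- outer(a, a, "==")[lower.tri(diag(n))]
  same_b <- outer(b, b, "==")[lower.tri(diag(n))]
  mean(same_a == same_b)
}

#' Group contrasts with compact letter display
#'
#' One-way ANOVA per variable followed by Tukey's Honest Significant
#' Difference test; groups are assigned letters such that two groups sharing
#' a letter are not significantly different at `alpha`.
#'
#' @param table phenotype table.
#' @param assignments integer group labels, one per row (e.g. from
#'   [cluster_genotypes()]).
#' @param alpha significance level (default 0.05).
#' @param vars variables to contrast.
#' @return data.frame of class `cp_groups` with one row per group x variable:
#'   `variable, group, mean, letters`.
#' @export
compare_groups <- function(table, assignments, alpha = 0.05, vars = NULL) {
  df <- .cp_numeric_table(table, vars)
  g <- factor(assignments)
  if (length(g) != nrow(df)) stop("assignments length must match table rows")
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 members")
  out <- list()
  for (v in names(df)) {
    fit <- stats::aov(df[[v]] ~ g)
    tk <- stats::TukeyHSD(fit)$g
    diffmat <- matrix(FALSE, nlevels(g), nlevels(g),
                      dimnames = list(levels(g), levels(g)))
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      sig <- !is.na(tk[i, "p adj"]) && tk[i, "p adj"] < alpha
      diffmat[pairs[[i]][1], pairs[[i]][2]] <- sig
      diffmat[pairs[[i]][2], pairs[[i]][1]] <- sig
    }
    letters_v <- .cp_letter_display(diffmat)
    means <- tapply(df[[v]], g, mean)
    out[[v]] <- data.frame(variable = v, group = levels(g),
                           mean = as.numeric(means),
                           letters = letters_v[levels(g)])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cp_groups", "data.frame")
  res
}

# insert-and-absorb compact letter display from a logical "significantly
# different" matrix
.cp_letter_display <- function(diffmat) {
  groups <- rownames(diffmat)
  cols <- list(groups)  # start with one column containing everyone
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i || !diffmat[i, j]) next
    gi <- groups[i]; gj <- groups[j]
    for (ci in seq_along(cols)) {
      if (all(c(gi, gj) %in% cols[[ci]])) {
        a <- setdiff(cols[[ci]], gi)
        b <- setdiff(cols[[ci]], gj)
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns that are subsets of others
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] %in% cols[[cj]]) &&
          (length(cols[[ci]]) < length(cols[[cj]]) || ci > cj))
        keep[ci] <- FALSE
    }
    cols <- cols[keep]
  }
  lab <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols))
    for (gg in cols[[ci]]) lab[gg] <- paste0(lab[gg], letters[ci])
  lab
}
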