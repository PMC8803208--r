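# The twelve TCC prediction learners.
#
# Selection-based linear models use stats::step; ridge uses glmnet. The
# remaining learners (regression tree, bagged forest, NIPALS partial least
# squares, Bayesian lasso via Gibbs sampling, spike-and-slab model-averaged
# Bayesian lasso, single-hidden-layer neural network, kernel support vector
# regression) are implemented here because no suitable implementation is
# available in the supported dependency set. Each learner standardizes its
# inputs internally and exposes `predict()`; learners with a native notion of
# importance also expose it (see relative_importance()).

#' The twelve model identifiers
#' @return Character vector of supported model ids.
#' @export
cp_models <- function() c("LRFS", "LRBS", "LRSS", "RR", "GLMSS", "RF",
                          "PLS", "BL", "BBL", "ANN", "SVM", "CART")

#' Model specification
#'
#' @param id one of [cp_models()]: linear regression with forward (LRFS),
#'   backward (LRBS) or stepwise (LRSS) selection, ridge regression (RR),
#'   gaussian GLM with stepwise selection (GLMSS), random forest (RF),
#'   partial least squares (PLS), Bayesian lasso (BL), model-averaged
#'   Bayesian lasso (BBL), artificial neural network (ANN), support vector
#'   machine (SVM), classification and regression tree (CART).
#' @param params named list overriding the model's default hyperparameters:
#'   RF: `ntree` (500), `mtry` (p/3), `min_bucket` (5), `max_depth` (12);
#'   CART: `min_split` (10), `min_bucket` (5), `max_depth` (8), `cp` (0.005);
#'   ANN: `size` (5 hidden units), `decay` (0.01), `maxit` (300),
#'   `restarts` (2); SVM: `cost` (10), `gamma` (median heuristic),
#'   `epsilon` (0.1); PLS: `ncomp` (chosen by internal 5-fold CV up to 6);
#'   RR: `nfolds` (5); BL/BBL: `n_iter` (1500), `burn` (500).
#' @return Object of class `cp_model_spec`.
#' @export
model_spec <- function(id, params = list()) {
  id <- match.arg(id, cp_models())
  defaults <- switch(id,
    RF   = list(ntree = 500, mtry = NULL, min_bucket = 5, max_depth = 12,
                min_split = 10),
    CART = list(min_split = 10, min_bucket = 5, max_depth = 8, cp = 0.005),
    ANN  = list(size = 5, decay = 0.01, maxit = 300, restarts = 2),
    SVM  = list(cost = 10, gamma = NULL, epsilon = 0.1, maxit = 200),
    PLS  = list(ncomp = NULL, max_ncomp = 6),
    RR   = list(nfolds = 5),
    BL   = list(n_iter = 1500, burn = 500),
    BBL  = list(n_iter = 1500, burn = 500, slab_scale = 10),
    list()
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", id, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(id = id, params = defaults), class = "cp_model_spec")
}

#' Fit a model on a training table and predict a test table
#'
#' Fits the specified learner on the training rows only — any feature
#' selection, internal cross-validation or sampling happens inside the
#' training set — and returns predictions for the test rows.
#'
#' @param spec a [model_spec()] or model id string.
#' @param train,test phenotype tables with a `tcc` column and the features.
#' @param features character vector of feature column names.
#' @return Numeric predictions for `test`, with the fitted model in
#'   attribute `"fit"`.
#' @export
fit_predict <- function(spec, train, features, test) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "cp_model_spec"))
  miss <- setdiff(c(features, "tcc"), names(train))
  if (length(miss)) stop("train is missing columns: ", paste(miss, collapse = ", "))
  if (!all(features %in% names(test)))
    stop("test is missing feature columns")
  if (nrow(train) < length(features) + 2)
    stop("need at least length(features) + 2 training rows")
  fit <- cp_fit(spec, as.matrix(as.data.frame(train)[, features, drop = FALSE]),
                train$tcc)
  pred <- predict(fit, as.matrix(as.data.frame(test)[, features, drop = FALSE]))
  attr(pred, "fit") <- fit
  pred
}

#' Fit a learner on a feature matrix
#'
#' Lower-level interface used by the benchmark harness.
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix (columns named).
#' @param y numeric response.
#' @return Object of class `cp_fit` (subclassed per learner).
#' @export
cp_fit <- function(spec, X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  f <- switch(spec$id,
    LRFS = .cp_fit_steplm, LRBS = .cp_fit_steplm, LRSS = .cp_fit_steplm,
    GLMSS = .cp_fit_steplm,
    RR = .cp_fit_ridge, RF = .cp_fit_rf, PLS = .cp_fit_pls,
    BL = .cp_fit_bl, BBL = .cp_fit_bbl, ANN = .cp_fit_ann,
    SVM = .cp_fit_svm, CART = .cp_fit_cart)
  fit <- f(spec, X, y)
  fit$spec <- spec
  fit$feature_names <- colnames(X)
  class(fit) <- c(paste0("cp_fit_", spec$id), "cp_fit", class(fit))
  fit
}

#' @export
print.cp_fit <- function(x, ...) {
  cat("<fitted", x$spec$id, "model on", length(x$feature_names), "features>\n")
  invisible(x)
}

# ---- stepwise linear family ------------------------------------------------

.cp_fit_steplm <- function(spec, X, y) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  full_terms <- paste0("`", colnames(X), "`", collapse = " + ")
  full_formula <- stats::as.formula(paste(".y ~", full_terms))
  glm_family <- spec$id == "GLMSS"
  base_fit <- function(formula) {
    if (glm_family) stats::glm(formula, data = df, family = stats::gaussian())
    else stats::lm(formula, data = df)
  }
  full <- base_fit(full_formula)
  resid_sd <- stats::sd(stats::residuals(full))
  fit <- if (!is.na(resid_sd) && resid_sd < 1e-10) {
    full  # perfect fit: AIC stepping is undefined, keep the full model
  } else {
    direction <- switch(spec$id, LRFS = "forward", LRBS = "backward", "both")
    start <- if (spec$id == "LRFS") base_fit(.y ~ 1) else full
    suppressWarnings(stats::step(
      start, scope = list(lower = .y ~ 1, upper = full_formula),
      direction = direction, trace = 0))
  }
  list(fit = fit)
}

#' @export
predict.cp_fit_LRFS <- function(object, newdata, ...) {
  unname(stats::predict(object$fit,
                        newdata = as.data.frame(newdata, check.names = FALSE)))
}
#' @export
predict.cp_fit_LRBS <- predict.cp_fit_LRFS
#' @export
predict.cp_fit_LRSS <- predict.cp_fit_LRFS
#' @export
predict.cp_fit_GLMSS <- predict.cp_fit_LRFS

# |t value| of selected terms as raw importance, 0 for dropped ones
.cp_importance_steplm <- function(fit, feature_names) {
  co <- summary(fit$fit)$coefficients
  out <- stats::setNames(rep(0, length(feature_names)), feature_names)
  rn <- gsub("`", "", rownames(co))
  for (v in feature_names) {
    if (v %in% rn) out[v] <- abs(co[match(v, rn), 3])
  }
  out
}

# ---- ridge (glmnet) --------------------------------------------------------

.cp_fit_ridge <- function(spec, X, y) {
  if (ncol(X) == 1L) {
    # glmnet needs >= 2 columns; univariate ridge in closed form with the
    # penalty fixed by generalized cross-validation over a small grid
    xc <- mean(X[, 1]); xs <- stats::sd(X[, 1]); if (xs == 0) xs <- 1
    z <- (X[, 1] - xc) / xs
    yc <- mean(y); yr <- y - yc
    n <- length(y)
    lambdas <- 10^seq(-4, 2, length.out = 25) * n
    gcv <- vapply(lambdas, function(l) {
      h <- z * z / (sum(z^2) + l)
      r <- yr - z * sum(z * yr) / (sum(z^2) + l)
      mean((r / (1 - mean(h)))^2)
    }, numeric(1))
    l <- lambdas[which.min(gcv)]
    beta <- sum(z * yr) / (sum(z^2) + l)
    return(list(uni = list(beta = beta, xc = xc, xs = xs, yc = yc),
                x_sd = stats::sd(X[, 1])))
  }
  cv <- glmnet::cv.glmnet(X, y, alpha = 0, nfolds = spec$params$nfolds,
                          standardize = TRUE)
  list(cv = cv, x_sd = apply(X, 2, stats::sd))
}

#' @export
predict.cp_fit_RR <- function(object, newdata, ...) {
  if (!is.null(object$uni)) {
    u <- object$uni
    return(drop((newdata[, 1] - u$xc) / u$xs * u$beta + u$yc))
  }
  drop(stats::predict(object$cv, newx = newdata, s = "lambda.min"))
}

.cp_importance_ridge <- function(fit, feature_names) {
  if (!is.null(fit$uni))
    return(stats::setNames(abs(fit$uni$beta), feature_names))
  beta <- as.numeric(stats::coef(fit$cv, s = "lambda.min"))[-1]
  stats::setNames(abs(beta) * fit$x_sd, feature_names)
}

# ---- regression tree and forest --------------------------------------------

# Vectorized best-split search. Returns NULL or list(var, val, reduction).
.cp_best_split <- function(X, y, candidates, min_bucket) {
  n <- length(y)
  best <- NULL
  for (j in candidates) {
    o <- order(X[, j])
    xs <- X[o, j]; ys <- y[o]
    cs <- cumsum(ys)
    k <- seq_len(n - 1)
    ok <- k >= min_bucket & (n - k) >= min_bucket & xs[k] < xs[k + 1]
    if (!any(ok)) next
    red <- cs[k]^2 / k + (cs[n] - cs[k])^2 / (n - k) - cs[n]^2 / n
    red[!ok] <- -Inf
    kbest <- which.max(red)
    if (is.null(best) || red[kbest] > best$reduction) {
      best <- list(var = j, val = (xs[kbest] + xs[kbest + 1]) / 2,
                   reduction = red[kbest])
    }
  }
  best
}

# Build a regression tree; nodes stored in a flat list. mtry = number of
# features sampled per split (NULL = all).
.cp_build_tree <- function(X, y, min_split, min_bucket, max_depth, cp_frac,
                           mtry = NULL) {
  sst <- sum((y - mean(y))^2)
  nodes <- list()
  grow <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(pred = mean(y[idx]), n = length(idx),
                         var = NA_integer_, val = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         reduction = 0)
    if (length(idx) < min_split || depth >= max_depth) return(id)
    p <- ncol(X)
    candidates <- if (is.null(mtry) || mtry >= p) seq_len(p)
                  else sample.int(p, mtry)
    sp <- .cp_best_split(X[idx, , drop = FALSE], y[idx], candidates, min_bucket)
    if (is.null(sp) || sst <= 0 || sp$reduction < cp_frac * sst) return(id)
    go_left <- X[idx, sp$var] <= sp$val
    lid <- grow(idx[go_left], depth + 1L)
    rid <- grow(idx[!go_left], depth + 1L)
    nodes[[id]]$var <<- sp$var; nodes[[id]]$val <<- sp$val
    nodes[[id]]$left <<- lid; nodes[[id]]$right <<- rid
    nodes[[id]]$reduction <<- sp$reduction
    id
  }
  grow(seq_along(y), 0L)
  nodes
}

.cp_predict_tree <- function(nodes, X) {
  out <- numeric(nrow(X))
  route <- function(id, idx) {
    nd <- nodes[[id]]
    if (is.na(nd$var)) { out[idx] <<- nd$pred; return(invisible()) }
    go_left <- X[idx, nd$var] <= nd$val
    if (any(go_left)) route(nd$left, idx[go_left])
    if (any(!go_left)) route(nd$right, idx[!go_left])
  }
  if (nrow(X)) route(1L, seq_len(nrow(X)))
  out
}

.cp_tree_importance <- function(nodes, p) {
  imp <- numeric(p)
  for (nd in nodes) if (!is.na(nd$var)) imp[nd$var] <- imp[nd$var] + nd$reduction
  imp
}

.cp_fit_cart <- function(spec, X, y) {
  pr <- spec$params
  nodes <- .cp_build_tree(X, y, pr$min_split, pr$min_bucket, pr$max_depth,
                          pr$cp)
  list(nodes = nodes)
}

#' @export
predict.cp_fit_CART <- function(object, newdata, ...) {
  .cp_predict_tree(object$nodes, newdata)
}

.cp_fit_rf <- function(spec, X, y) {
  pr <- spec$params
  n <- nrow(X); p <- ncol(X)
  mtry <- if (is.null(pr$mtry)) max(1L, floor(p / 3)) else pr$mtry
  trees <- vector("list", pr$ntree)
  imp <- numeric(p)
  for (t in seq_len(pr$ntree)) {
    bs <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- .cp_build_tree(X[bs, , drop = FALSE], y[bs],
                                 min_split = pr$min_split,
                                 min_bucket = pr$min_bucket,
                                 max_depth = pr$max_depth,
                                 cp_frac = 0, mtry = mtry)
    imp <- imp + .cp_tree_importance(trees[[t]], p)
  }
  list(trees = trees, importance = imp / pr$ntree)
}

#' @export
predict.cp_fit_RF <- function(object, newdata, ...) {
  preds <- vapply(object$trees, function(tr) .cp_predict_tree(tr, newdata),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) mean(preds) else rowMeans(preds)
}

# ---- partial least squares (NIPALS) ----------------------------------------

.cp_pls_core <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  xc <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs == 0] <- 1
  yc <- mean(y)
  Xs <- scale(X, center = xc, scale = xs)
  yr <- y - yc
  W <- P <- matrix(0, p, ncomp); Q <- TT <- numeric(ncomp)
  scores <- matrix(0, n, ncomp)
  Xd <- Xs
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yr))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pvec <- drop(crossprod(Xd, t)) / tt
    q <- sum(yr * t) / tt
    W[, a] <- w; P[, a] <- pvec; Q[a] <- q; TT[a] <- tt
    scores[, a] <- t
    Xd <- Xd - tcrossprod(t, pvec)
    yr <- yr - q * t
  }
  if (ncomp == 0L) {
    beta <- rep(0, p)
  } else {
    W <- W[, seq_len(ncomp), drop = FALSE]
    P <- P[, seq_len(ncomp), drop = FALSE]
    Q <- Q[seq_len(ncomp)]
    beta <- drop(W %*% solve(crossprod(P, W), Q))
  }
  list(beta = beta, xc = xc, xs = xs, yc = yc, ncomp = ncomp,
       W = W, Q = Q, TT = TT[seq_len(max(ncomp, 1))])
}

.cp_pls_predict <- function(core, X) {
  drop(scale(X, center = core$xc, scale = core$xs) %*% core$beta) + core$yc
}

.cp_fit_pls <- function(spec, X, y) {
  max_nc <- min(spec$params$max_ncomp, ncol(X), nrow(X) - 1L)
  ncomp <- spec$params$ncomp
  if (is.null(ncomp)) {
    # choose by internal 5-fold CV RMSE
    folds <- sample(rep_len(seq_len(5), nrow(X)))
    rmse <- numeric(max_nc)
    for (nc in seq_len(max_nc)) {
      err <- 0
      for (f in seq_len(5)) {
        tr <- folds != f
        core <- .cp_pls_core(X[tr, , drop = FALSE], y[tr], nc)
        err <- err + sum((y[!tr] - .cp_pls_predict(core, X[!tr, , drop = FALSE]))^2)
      }
      rmse[nc] <- sqrt(err / nrow(X))
    }
    ncomp <- which.min(rmse)
  }
  list(core = .cp_pls_core(X, y, min(ncomp, max_nc)))
}

#' @export
predict.cp_fit_PLS <- function(object, newdata, ...) {
  .cp_pls_predict(object$core, newdata)
}

# VIP scores from loading weights
.cp_importance_pls <- function(fit, feature_names) {
  core <- fit$core
  if (core$ncomp == 0L)
    return(stats::setNames(rep(0, length(feature_names)), feature_names))
  ssy <- core$Q^2 * core$TT[seq_len(core$ncomp)]
  p <- length(feature_names)
  vip <- sqrt(p * drop(core$W^2 %*% ssy) / sum(ssy))
  stats::setNames(vip, feature_names)
}

# ---- Bayesian lasso (Park & Casella Gibbs sampler) -------------------------

# inverse-Gaussian sampler (Michael, Schucany & Haas)
.cp_rinvgauss <- function(n, mu, lambda) {
  nu <- stats::rnorm(n)
  ysq <- nu^2
  x <- mu + mu^2 * ysq / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * ysq + mu^2 * ysq^2)
  x <- pmax(x, 1e-12)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

.cp_bl_gibbs <- function(X, y, n_iter, burn) {
  n <- nrow(X); p <- ncol(X)
  xc <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs == 0] <- 1
  Xs <- scale(X, center = xc, scale = xs)
  yc <- mean(y); yr <- y - yc
  XtX <- crossprod(Xs); Xty <- crossprod(Xs, yr)
  beta <- drop(solve(XtX + diag(p), Xty))
  sigma2 <- max(stats::var(yr - Xs %*% beta), 1e-6)
  tau2 <- rep(1, p)
  lambda2 <- 1
  keep <- matrix(0, n_iter - burn, p)
  for (it in seq_len(n_iter)) {
    A <- XtX + diag(1 / tau2, p)
    cA <- chol(A)
    mu_b <- backsolve(cA, forwardsolve(t(cA), Xty))
    beta <- drop(mu_b + backsolve(cA, stats::rnorm(p)) * sqrt(sigma2))
    resid <- yr - Xs %*% beta
    sh <- (n - 1 + p) / 2
    ra <- (sum(resid^2) + sum(beta^2 / tau2)) / 2
    sigma2 <- max(1 / stats::rgamma(1, sh, rate = ra), 1e-9)
    mu_ig <- sqrt(lambda2 * sigma2 / pmax(beta^2, 1e-12))
    tau2 <- pmax(1 / .cp_rinvgauss(p, mu_ig, lambda2), 1e-10)
    lambda2 <- stats::rgamma(1, p + 1, rate = sum(tau2) / 2 + 0.1)
    if (it > burn) keep[it - burn, ] <- beta
  }
  list(beta = colMeans(keep), xc = xc, xs = xs, yc = yc, samples = keep)
}

.cp_fit_bl <- function(spec, X, y) {
  g <- .cp_bl_gibbs(X, y, spec$params$n_iter, spec$params$burn)
  list(beta = g$beta, xc = g$xc, xs = g$xs, yc = g$yc)
}

#' @export
predict.cp_fit_BL <- function(object, newdata, ...) {
  drop(scale(newdata, center = object$xc, scale = object$xs) %*% object$beta) +
    object$yc
}

.cp_importance_linear_beta <- function(fit, feature_names) {
  stats::setNames(abs(fit$beta), feature_names)  # standardized X: |beta| is scale-free
}

# ---- model-averaged Bayesian lasso (spike-and-slab inclusion) --------------

.cp_fit_bbl <- function(spec, X, y) {
  n <- nrow(X); p <- ncol(X)
  xc <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs == 0] <- 1
  Xs <- scale(X, center = xc, scale = xs)
  yc <- mean(y); yr <- y - yc
  v <- spec$params$slab_scale     # slab variance multiplier (times sigma2)
  n_iter <- spec$params$n_iter; burn <- spec$params$burn
  xtx <- colSums(Xs^2)
  beta <- rep(0, p); gamma <- rep(1L, p)
  sigma2 <- max(stats::var(yr), 1e-6)
  pi_inc <- 0.5
  resid <- yr - Xs %*% beta
  beta_sum <- rep(0, p); inc_sum <- rep(0, p); kept <- 0L
  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      resid_j <- resid + Xs[, j] * beta[j]
      s2 <- sigma2 / (xtx[j] + 1 / v)
      m <- s2 * sum(Xs[, j] * resid_j) / sigma2
      log_odds <- log(pi_inc / (1 - pi_inc)) +
        0.5 * log(s2 / (v * sigma2)) + m^2 / (2 * s2)
      gamma[j] <- as.integer(stats::runif(1) < 1 / (1 + exp(-log_odds)))
      beta[j] <- if (gamma[j]) stats::rnorm(1, m, sqrt(s2)) else 0
      resid <- resid_j - Xs[, j] * beta[j]
    }
    sigma2 <- max(1 / stats::rgamma(1, (n + sum(gamma)) / 2,
                                    rate = (sum(resid^2) +
                                            sum(beta^2) / v) / 2), 1e-9)
    pi_inc <- stats::rbeta(1, 1 + sum(gamma), 1 + p - sum(gamma))
    if (it > burn) {
      beta_sum <- beta_sum + beta
      inc_sum <- inc_sum + gamma
      kept <- kept + 1L
    }
  }
  list(beta = beta_sum / kept, inclusion = inc_sum / kept,
       xc = xc, xs = xs, yc = yc)
}

#' @export
predict.cp_fit_BBL <- function(object, newdata, ...) {
  drop(scale(newdata, center = object$xc, scale = object$xs) %*% object$beta) +
    object$yc
}

# ---- single-hidden-layer neural network ------------------------------------

.cp_fit_ann <- function(spec, X, y) {
  pr <- spec$params
  xc <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs == 0] <- 1
  Xs <- scale(X, center = xc, scale = xs)
  yc <- mean(y); ysd <- stats::sd(y); if (ysd == 0) ysd <- 1
  ys <- (y - yc) / ysd
  p <- ncol(X); H <- pr$size
  n_par <- p * H + H + H + 1
  unpack <- function(theta) {
    W1 <- matrix(theta[seq_len(p * H)], p, H)
    b1 <- theta[p * H + seq_len(H)]
    W2 <- theta[p * H + H + seq_len(H)]
    b2 <- theta[n_par]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  obj <- function(theta) {
    w <- unpack(theta)
    A <- tanh(sweep(Xs %*% w$W1, 2, w$b1, "+"))
    yhat <- drop(A %*% w$W2) + w$b2
    mean((yhat - ys)^2) / 2 +
      pr$decay * (sum(w$W1^2) + sum(w$W2^2)) / 2
  }
  grad <- function(theta) {
    w <- unpack(theta)
    Z <- sweep(Xs %*% w$W1, 2, w$b1, "+")
    A <- tanh(Z)
    yhat <- drop(A %*% w$W2) + w$b2
    e <- (yhat - ys) / length(ys)
    gW2 <- drop(crossprod(A, e)) + pr$decay * w$W2
    gb2 <- sum(e)
    D <- (e %o% w$W2) * (1 - A^2)
    gW1 <- crossprod(Xs, D) + pr$decay * w$W1
    gb1 <- colSums(D)
    c(as.numeric(gW1), gb1, gW2, gb2)
  }
  best <- NULL
  for (r in seq_len(max(1, pr$restarts))) {
    theta0 <- stats::rnorm(n_par, 0, 0.5)
    opt <- stats::optim(theta0, obj, grad, method = "BFGS",
                        control = list(maxit = pr$maxit, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(theta = best$par, unpack = unpack, xc = xc, xs = xs, yc = yc, ysd = ysd)
}

#' @export
predict.cp_fit_ANN <- function(object, newdata, ...) {
  w <- object$unpack(object$theta)
  Xs <- scale(newdata, center = object$xc, scale = object$xs)
  A <- tanh(sweep(Xs %*% w$W1, 2, w$b1, "+"))
  (drop(A %*% w$W2) + w$b2) * object$ysd + object$yc
}

# ---- kernel support vector regression --------------------------------------

.cp_rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Huber-smoothed epsilon-insensitive loss and derivative
.cp_eps_loss <- function(r, eps, delta) {
  a <- abs(r) - eps
  ifelse(a <= 0, 0, ifelse(a <= delta, a^2 / (2 * delta), a - delta / 2))
}
.cp_eps_dloss <- function(r, eps, delta) {
  a <- abs(r) - eps
  mag <- ifelse(a <= 0, 0, ifelse(a <= delta, a / delta, 1))
  mag * sign(r)
}

.cp_fit_svm <- function(spec, X, y) {
  pr <- spec$params
  xc <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs == 0] <- 1
  Xs <- scale(X, center = xc, scale = xs)
  yc <- mean(y); ysd <- stats::sd(y); if (ysd == 0) ysd <- 1
  ys <- (y - yc) / ysd
  gamma <- pr$gamma
  if (is.null(gamma)) {  # median heuristic on pairwise squared distances
    n <- nrow(Xs)
    idx <- if (n > 120) sample.int(n, 120) else seq_len(n)
    d2 <- stats::dist(Xs[idx, , drop = FALSE])^2
    med <- stats::median(d2)
    gamma <- if (med > 0) 1 / med else 1
  }
  K <- .cp_rbf_kernel(Xs, Xs, gamma)
  n <- nrow(Xs)
  delta <- 0.05
  obj <- function(par) {
    alpha <- par[seq_len(n)]; b <- par[n + 1]
    u <- drop(K %*% alpha) + b
    0.5 * sum(alpha * (K %*% alpha)) +
      pr$cost * sum(.cp_eps_loss(ys - u, pr$epsilon, delta))
  }
  grad <- function(par) {
    alpha <- par[seq_len(n)]; b <- par[n + 1]
    Ka <- drop(K %*% alpha)
    dl <- .cp_eps_dloss(ys - Ka - b, pr$epsilon, delta)
    c(Ka - pr$cost * drop(K %*% dl), -pr$cost * sum(dl))
  }
  opt <- stats::optim(rep(0, n + 1), obj, grad, method = "BFGS",
                      control = list(maxit = pr$maxit, reltol = 1e-9))
  list(alpha = opt$par[seq_len(n)], b = opt$par[n + 1], gamma = gamma,
       Xtrain = Xs, xc = xc, xs = xs, yc = yc, ysd = ysd)
}

#' @export
predict.cp_fit_SVM <- function(object, newdata, ...) {
  Xs <- scale(newdata, center = object$xc, scale = object$xs)
  K <- .cp_rbf_kernel(Xs, object$Xtrain, object$gamma)
  (drop(K %*% object$alpha) + object$b) * object$ysd + object$yc
}
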