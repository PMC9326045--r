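#' Build the subjects x voxels feature matrix
#'
#' Extracts, for every subject, the mALFF values at the voxels of the
#' significant-cluster mask; the model is fit on the patient group only, so
#' callers pass patient maps.  Columns are ordered by voxel linear index.
#'
#' @param malff_maps List of `malff_map` objects (or 3D arrays), one per
#'   subject.
#' @param cluster_mask A `cluster_result`, or an integer/logical 3D array
#'   (nonzero = in mask).
#' @param subject_ids Optional character vector of row names.
#' @return A `feature_matrix`: list with `X` (subjects x voxels), and
#'   `voxels` (data.frame `column`, `i`, `j`, `k`, `label`).
#' @export
build_feature_matrix <- function(malff_maps, cluster_mask,
                                 subject_ids = NULL) {
  lab <- if (inherits(cluster_mask, "cluster_result"))
    cluster_mask$cluster_mask else cluster_mask
  if (!is.array(lab) || length(dim(lab)) != 3L)
    stop("`cluster_mask` must be a 3D array or cluster_result")
  storage.mode(lab) <- "integer"
  vox <- which(lab > 0L)
  if (length(vox) == 0L)
    stop("the cluster mask is empty: no features to extract")
  d <- dim(lab)
  rows <- lapply(malff_maps, function(m) {
    a <- if (is.list(m) && !is.null(m$data)) m$data else m
    if (!all(dim(a) == d))
      stop("map grid does not match the cluster mask grid")
    a[vox]
  })
  X <- do.call(rbind, rows)
  if (anyNA(X)) stop("feature matrix contains missing values")
  if (is.null(subject_ids)) subject_ids <- names(malff_maps)
  rownames(X) <- subject_ids
  ijk <- arrayInd(vox, d)
  structure(list(X = X,
                 voxels = data.frame(column = seq_along(vox),
                                     i = ijk[, 1], j = ijk[, 2],
                                     k = ijk[, 3], label = lab[vox])),
            class = "feature_matrix")
}

as_X <- function(x) if (inherits(x, "feature_matrix")) x$X else as.matrix(x)

#' Shapiro-Wilk normality check for the prediction target
#'
#' The relevance filter uses Pearson correlation, so the continuous target
#' is checked for normality first.  Non-normality produces a warning, not
#' an error: the analysis proceeds either way.
#'
#' @param y Numeric target vector, `n >= 3`, non-constant.
#' @return List with `statistic`, `p` and logical `warned`.
#' @export
shapiro_wilk_check <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 3L) stop("Shapiro-Wilk needs at least 3 observations")
  if (sd(y) == 0) stop("target vector is constant")
  sw <- shapiro.test(y)
  warned <- sw$p.value < 0.05
  if (warned)
    warning(sprintf(
      "target deviates from normality (Shapiro-Wilk W = %.3f, p = %.3g)",
      unname(sw$statistic), sw$p.value))
  list(statistic = unname(sw$statistic), p = sw$p.value, warned = warned)
}

#' Relevance feature selection by Pearson correlation
#'
#' Keeps the columns whose Pearson correlation with the training target has
#' a two-sided p value below `alpha`.  Zero-variance columns are excluded
#' with a warning.  May select no columns.
#'
#' @param X Training feature matrix (subjects x features) or
#'   `feature_matrix`.
#' @param y Training target.
#' @param alpha Two-sided p threshold (default 0.05).
#' @return Integer vector of selected column indices (possibly empty).
#' @export
select_features_relevance <- function(X, y, alpha = 0.05) {
  X <- as_X(X)
  n <- nrow(X)
  if (n < 3L) stop("relevance selection needs at least 3 training subjects")
  if (length(y) != n) stop("`y` length does not match rows of `X`")
  n1 <- n - 1L
  mu <- colMeans(X)
  sds2 <- (colSums(X^2) - n * mu^2) / n1   # column variances, one pass
  ok <- sds2 > 0
  if (!all(ok))
    warning(sum(!ok), " zero-variance feature column(s) excluded")
  if (alpha >= 1) return(unname(which(ok)))
  r <- rep(NA_real_, ncol(X))
  r[ok] <- as.vector(cor(X[, ok, drop = FALSE], y))
  r2 <- pmin(r^2, 1 - 1e-15)
  tstat <- abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(-tstat, n - 2)
  unname(which(ok & !is.na(p) & p < alpha))
}

#' Fit a linear epsilon-insensitive support-vector regression
#'
#' Thin wrapper around libsvm's epsilon-SVR with a linear kernel, returning
#' the primal weight vector and intercept so that predictions are
#' `X %*% weights + intercept`.  With no feature columns a fallback model
#' predicting the training mean is returned and flagged.
#'
#' @param X Training matrix (subjects x selected features); may have zero
#'   columns.
#' @param y Training target.
#' @param cost Regularization parameter C.  The default `NULL` uses the
#'   SVMlight convention `C = 1 / mean(||x_i||^2)`, which scales the
#'   regularization with the feature dimension; a fixed C that ignores how
#'   many voxels survive selection is badly calibrated when features far
#'   outnumber subjects.
#' @param epsilon Insensitivity tube half-width.
#' @return An `svr_model`: list with `weights`, `intercept`, `fallback`,
#'   `cost` (the C actually used).
#' @export
fit_svr <- function(X, y, cost = NULL, epsilon = 0.1) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training subjects")
  if (ncol(X) == 0L)
    return(structure(list(weights = numeric(0), intercept = mean(y),
                          fallback = TRUE, cost = NA_real_),
                     class = "svr_model"))
  if (is.null(cost)) {
    msq <- mean(rowSums(X^2))
    cost <- if (msq > 0) 1 / msq else 1
  }
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                    cost = cost, epsilon = epsilon, scale = FALSE,
                    fitted = FALSE)
  if (NROW(fit$SV) == 0L) {
    # every training point inside the epsilon tube: flat model
    b <- if (is.finite(fit$rho)) -fit$rho else mean(y)
    return(structure(list(weights = rep(0, ncol(X)), intercept = b,
                          fallback = FALSE, cost = cost),
                     class = "svr_model"))
  }
  w <- as.vector(crossprod(fit$coefs, fit$SV))
  structure(list(weights = w, intercept = -fit$rho, fallback = FALSE,
                 cost = cost),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$fallback || length(object$weights) == 0L)
    return(rep(object$intercept, nrow(newdata)))
  as.vector(newdata %*% object$weights + object$intercept)
}

# Internal: training-fold standardization (features and target both, as in
# libsvm's default preprocessing; predictions are mapped back to the
# target's original scale).
std_fit <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(pmax(0, (colSums(X^2) - n * mu^2) / (n - 1L)))
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
std_apply <- function(X, s) sweep(sweep(X, 2, s$mu), 2, s$sd, "/")
ystd_fit <- function(y) {
  s <- sd(y)
  list(mu = mean(y), sd = if (is.na(s) || s == 0) 1 else s)
}

#' Leave-one-out cross-validated SVR prediction
#'
#' For each subject in turn: the relevance filter is refit on the remaining
#' `n - 1` subjects only, features and target are standardized by the
#' training fold's mean and SD (so the epsilon tube is expressed in
#' target-SD units; predictions are returned on the original scale), a
#' linear epsilon-SVR is fit, and the held-out subject is predicted.  Feature selection inside the fold is what keeps the
#' cross-validation estimate honest; selecting on all subjects first leaks
#' the test subject into training.
#'
#' @param X Feature matrix (subjects x voxels) or `feature_matrix`.
#' @param y Target vector (one accuracy per subject).
#' @param alpha Relevance-filter threshold.
#' @param cost,epsilon SVR hyperparameters; `cost = NULL` (default) scales
#'   C to the selected feature set as in [fit_svr()].
#' @return A `cv_prediction`: list with `predicted`, `actual`, `r`, `mse`,
#'   `selected_per_fold` (list of column index vectors) and
#'   `fallback_folds`.
#' @export
loocv_predict <- function(X, y, alpha = 0.05, cost = NULL, epsilon = 0.1) {
  X <- as_X(X)
  n <- nrow(X)
  if (n < 3L) stop("LOOCV needs at least 3 subjects")
  if (length(y) != n) stop("`y` length does not match rows of `X`")
  predicted <- numeric(n)
  selected <- vector("list", n)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    sel <- suppressWarnings(select_features_relevance(Xtr, ytr, alpha))
    selected[[i]] <- sel
    if (length(sel) == 0L) {
      predicted[i] <- mean(ytr)
      fallback[i] <- TRUE
      next
    }
    s <- std_fit(Xtr[, sel, drop = FALSE])
    ys <- ystd_fit(ytr)
    fit <- fit_svr(std_apply(Xtr[, sel, drop = FALSE], s),
                   (ytr - ys$mu) / ys$sd, cost = cost, epsilon = epsilon)
    predicted[i] <- predict(fit, std_apply(X[i, sel, drop = FALSE], s)) *
      ys$sd + ys$mu
    fallback[i] <- fit$fallback
  }
  r <- if (sd(predicted) > 0) as.numeric(cor(predicted, y)) else NA_real_
  structure(list(predicted = predicted, actual = as.numeric(y), r = r,
                 mse = mean((predicted - y)^2),
                 selected_per_fold = selected, fallback_folds = fallback),
            class = "cv_prediction")
}

#' @export
print.cv_prediction <- function(x, ...) {
  cat(sprintf("<cv_prediction> n = %d, r = %.3f, MSE = %.4g\n",
              length(x$predicted), x$r, x$mse))
  invisible(x)
}

#' Permutation test of the cross-validated prediction
#'
#' Keeps the behavioral scores fixed and randomly permutes the
#' subject-to-brain assignment (row order of the feature matrix), rerunning
#' the entire leave-one-out procedure -- including per-fold feature
#' selection -- for each of the `n_permutations` datasets.  The p value of
#' r is the fraction of permuted datasets with r strictly greater than the
#' observed r; the p value of MSE is the fraction with MSE strictly lower
#' than observed.  A zero count is reported as `"<1/n_permutations"`.
#'
#' @param X Feature matrix or `feature_matrix`.
#' @param y Target vector.
#' @param n_permutations Number of permuted datasets (default 1000).
#' @param alpha,cost,epsilon Passed to [loocv_predict()].
#' @param seed Integer seed for the permutation draws.
#' @param observed Optional precomputed `cv_prediction` for the unpermuted
#'   data (recomputed if `NULL`).
#' @return A `permutation_null`: list with `null_r`, `null_mse`, `p_r`,
#'   `p_mse`, `p_r_label`, `p_mse_label`, `observed` and `seed`.
#' @export
permutation_test <- function(X, y, n_permutations = 1000L, alpha = 0.05,
                             cost = NULL, epsilon = 0.1, seed = 1L,
                             observed = NULL) {
  X <- as_X(X)
  if (n_permutations < 1L) stop("n_permutations must be at least 1")
  if (is.null(observed))
    observed <- loocv_predict(X, y, alpha = alpha, cost = cost,
                              epsilon = epsilon)
  set.seed(seed)
  n <- nrow(X)
  null_r <- null_mse <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    cv <- loocv_predict(X[perm, , drop = FALSE], y, alpha = alpha,
                        cost = cost, epsilon = epsilon)
    null_r[b] <- cv$r
    null_mse[b] <- cv$mse
  }
  n_gt <- sum(null_r > observed$r, na.rm = TRUE)
  n_lt <- sum(null_mse < observed$mse, na.rm = TRUE)
  p_r <- n_gt / n_permutations
  p_mse <- n_lt / n_permutations
  lab <- function(count, p) if (count == 0L)
    sprintf("<%g", 1 / n_permutations) else sprintf("%g", p)
  structure(list(null_r = null_r, null_mse = null_mse,
                 p_r = p_r, p_mse = p_mse,
                 p_r_label = lab(n_gt, p_r), p_mse_label = lab(n_lt, p_mse),
                 observed = observed, seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> %d permutations: observed r = %.3f (p %s), MSE = %.4g (p %s)\n",
    length(x$null_r), x$observed$r, x$p_r_label, x$observed$mse,
    x$p_mse_label))
  invisible(x)
}

#' Back-project SVR weights onto voxels and clusters
#'
#' Refits the relevance filter and the linear SVR on all subjects, assigns
#' each selected voxel its primal weight, normalizes absolute weights so
#' the maximum is 1, and summarizes each cluster by the maximum normalized
#' weight among its selected voxels (unselected voxels have weight 0).
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param y Target vector.
#' @param alpha,cost,epsilon Model settings, as in [loocv_predict()].
#' @param cluster_result Optional `cluster_result` for per-cluster
#'   summaries and a voxel-space weight volume.
#' @return A `weight_map`: list with `weight` (signed, per feature column),
#'   `normalized_weight` (`|w|`, max 1), `selected` (column indices),
#'   `cluster_weights` (data.frame `label`, `weight`) and `volume` (3D
#'   array of normalized weights, if `cluster_result` given).
#' @export
compute_weight_map <- function(fm, y, alpha = 0.05, cost = NULL,
                               epsilon = 0.1, cluster_result = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$X
  sel <- suppressWarnings(select_features_relevance(X, y, alpha))
  w_full <- numeric(ncol(X))
  if (length(sel) > 0L) {
    s <- std_fit(X[, sel, drop = FALSE])
    ys <- ystd_fit(y)
    fit <- fit_svr(std_apply(X[, sel, drop = FALSE], s),
                   (y - ys$mu) / ys$sd, cost = cost, epsilon = epsilon)
    w_full[sel] <- fit$weights
  }
  aw <- abs(w_full)
  norm_w <- if (max(aw) > 0) aw / max(aw) else aw
  cluster_weights <- NULL
  volume <- NULL
  if (!is.null(cluster_result)) {
    labs <- sort(unique(fm$voxels$label))
    cw <- vapply(labs, function(l)
      max(c(0, norm_w[fm$voxels$label == l])), 0)
    cluster_weights <- data.frame(label = labs, weight = cw)
    volume <- array(0, dim = dim(cluster_result$cluster_mask))
    idx <- (fm$voxels$k - 1L) * prod(dim(volume)[1:2]) +
      (fm$voxels$j - 1L) * dim(volume)[1] + fm$voxels$i
    volume[idx] <- norm_w
  }
  structure(list(weight = w_full, normalized_weight = norm_w,
                 selected = sel, cluster_weights = cluster_weights,
                 volume = volume),
            class = "weight_map")
}

#' Post-hoc correlation between cluster-mean mALFF and behavior
#'
#' For every significant cluster, Pearson correlation (with two-sided p)
#' between the subjects' mean mALFF over the cluster's voxels and the
#' behavioral score.
#'
#' @param malff_maps List of `malff_map` objects (or 3D arrays).
#' @param cluster_result A `cluster_result`.
#' @param y Behavioral score per subject.
#' @return data.frame with `label`, `sign`, `size_voxels`, `r`, `p`.
#' @export
posthoc_cluster_correlation <- function(malff_maps, cluster_result, y) {
  stopifnot(inherits(cluster_result, "cluster_result"))
  n <- length(malff_maps)
  if (n < 3L) stop("need at least 3 subjects")
  if (length(y) != n) stop("`y` length does not match the number of maps")
  cl <- cluster_result$clusters
  out <- cl[, c("label", "sign", "size_voxels")]
  out$r <- out$p <- NA_real_
  for (rix in seq_len(nrow(cl))) {
    vox <- which(cluster_result$cluster_mask == cl$label[rix])
    means <- vapply(malff_maps, function(m) {
      a <- if (is.list(m) && !is.null(m$data)) m$data else m
      mean(a[vox])
    }, 0)
    ct <- cor.test(means, y)
    out$r[rix] <- unname(ct$estimate)
    out$p[rix] <- ct$p.value
  }
  out[, c("label", "sign", "size_voxels", "r", "p")]
}
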