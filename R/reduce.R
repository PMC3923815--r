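#' @title Dimensionality reduction for small-sample image cohorts
#' @description Three backends — PCA via the subjects-by-subjects Gram
#'   matrix (the "eigenface" trick for voxels >> subjects), label-guided
#'   NIPALS partial least squares, and fixed-point ICA on PCA-whitened
#'   scores — plus Fisher-discriminant-ratio importance and cumulative
#'   importance component selection.
#' @name reduce
NULL

as_values <- function(X) {
  if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
}

fix_sign <- function(v) {
  if (v[which.max(abs(v))] < 0) -v else v
}

check_labels <- function(y, n_min = 2) {
  y <- factor(y)
  if (nlevels(droplevels(y)) != 2)
    stop("labels must contain exactly two classes")
  if (any(table(y) < n_min))
    stop("each class needs at least ", n_min, " samples")
  y
}

#' Fit PCA with the Gram-matrix trick
#'
#' Each image row is normalized to unit norm, the mean image is subtracted,
#' and the eigendecomposition of the voxel-space covariance is obtained by
#' diagonalizing the much smaller N x N Gram matrix of the centered rows,
#' then mapping eigenvectors back to voxel space and unit-normalizing them.
#' Components are ordered by descending eigenvalue; eigenvalue sign
#' ambiguity is resolved by forcing the largest-magnitude loading positive.
#'
#' @param X A `feature_matrix` or plain subjects x voxels matrix (>= 2
#'   rows, finite, not identically zero).
#' @return A `reduction_model` with `method = "pca"`, voxel-space
#'   `components` (columns), eigenvalue `importance` and the stored
#'   normalization state used by [project_features()].
#' @export
fit_pca <- function(X) {
  A <- as_values(X)
  n <- nrow(A)
  if (n < 2) stop("PCA needs at least 2 subjects")
  if (!all(is.finite(A))) stop("non-finite values in feature matrix")
  norms <- sqrt(rowSums(A^2))
  if (any(norms == 0)) stop("all-zero image row cannot be unit-normalized")
  U <- A / norms
  mu <- colMeans(U)
  C <- sweep(U, 2, mu)
  G <- C %*% t(C) / n                      # N x N Gram, covariance scaling
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  keep <- which(lam > max(lam) * 1e-12 & lam > 0)
  keep <- keep[seq_len(min(length(keep), n - 1))]
  comps <- matrix(0, ncol(A), length(keep))
  for (idx in seq_along(keep)) {
    v <- crossprod(C, eg$vectors[, keep[idx]])
    v <- v / sqrt(sum(v^2))
    comps[, idx] <- fix_sign(v)
  }
  structure(list(method = "pca", mean_vector = mu, components = comps,
                 importance = lam[keep], selected = NULL,
                 n_train = n),
            class = "reduction_model")
}

#' Fit partial least squares against binary labels
#'
#' NIPALS PLS1 on the column-centered image matrix X and the mean-centered
#' label vector y coded -1/+1 (stable/converter). Each round extracts the
#' weight direction maximizing covariance with the deflated label block,
#' then deflates X by the rank-one score/loading product, so that on
#' training data X = T P' + E with residual E orthogonal to the extracted
#' scores. Component importance is the Fisher discriminant ratio of each
#' training score column.
#'
#' @param X A `feature_matrix` or matrix, >= 3 subjects.
#' @param y Binary labels (factor `stable`/`converter`, or any two-level
#'   vector; the second level plays the positive class).
#' @param k Maximum number of components (default `min(n - 1, 20)`);
#'   extraction stops early when the residual is numerically exhausted.
#' @return A `reduction_model` with `method = "pls"`, `components` the
#'   voxel-space weight vectors W, loadings `P`, `Q`, training scores `T`,
#'   residual `E`, and the projection matrix `R = W (P'W)^{-1}`.
#' @export
fit_pls <- function(X, y, k = NULL) {
  A <- as_values(X)
  n <- nrow(A)
  if (n < 3) stop("PLS needs at least 3 subjects")
  yf <- check_labels(y, n_min = 1)
  if (is.null(k)) k <- min(n - 1, 20)
  if (k > n - 1) stop("more requested components than rank allows")
  ynum <- ifelse(yf == levels(yf)[2], 1, -1)
  mu <- colMeans(A)
  Xc <- sweep(A, 2, mu)
  yc <- ynum - mean(ynum)
  x_scale <- sqrt(sum(Xc^2))
  if (x_scale == 0) stop("constant feature matrix")
  W <- P <- NULL; Tm <- NULL; Q <- numeric(0)
  Xd <- Xc; yd <- yc
  for (a in seq_len(k)) {
    w <- crossprod(Xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12 * x_scale) break
    w <- as.numeric(w / wn)
    t_ <- as.numeric(Xd %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-24) break
    p <- as.numeric(crossprod(Xd, t_) / tt)
    q <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, p)
    yd <- yd - t_ * q
    W <- cbind(W, w); P <- cbind(P, p); Tm <- cbind(Tm, t_)
    Q <- c(Q, q)
  }
  if (is.null(W)) stop("no PLS component could be extracted")
  R <- W %*% solve(crossprod(P, W))
  imp <- apply(Tm, 2, fisher_ratio, y = yf)
  structure(list(method = "pls", mean_vector = mu, components = W,
                 P = P, Q = Q, scores = Tm, residual = Xd,
                 projection = R, importance = imp, selected = NULL,
                 y_levels = levels(yf), n_train = n),
            class = "reduction_model")
}

# PCA whitening used by ICA: returns N x k whitened scores with identity
# sample covariance and the p x k voxel-space whitening map.
whiten_gram <- function(A, k) {
  n <- nrow(A)
  mu <- colMeans(A)
  Cn <- sweep(A, 2, mu)
  G <- Cn %*% t(Cn) / n
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  avail <- sum(lam > max(lam) * 1e-10 & lam > 0)
  if (k > avail)
    stop("k = ", k, " exceeds the rank of the centered data (", avail, ")")
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  lam <- lam[seq_len(k)]
  Z <- sqrt(n) * U                               # Z'Z / n = I
  Mw <- crossprod(Cn, U) %*% diag(1 / sqrt(lam * n), k)
  list(Z = Z, Mw = Mw, mean_vector = mu, rank = avail)
}

#' Fit ICA by fixed-point nongaussianity maximization
#'
#' The data are centered and whitened to `k` dimensions by Gram-trick PCA,
#' then a square unmixing matrix is estimated with the symmetric
#' fixed-point iteration (tanh contrast), which maximizes nongaussianity of
#' the recovered sources. The per-subject features are the unmixed source
#' activations. The run is deterministic given `seed`; if the iteration
#' does not converge within `maxit` sweeps an error is raised (no partial
#' result is returned).
#'
#' @param X A `feature_matrix` or matrix, >= 3 subjects.
#' @param k Number of components, at most `n - 1` and at most the rank of
#'   the centered data.
#' @param seed Integer seed for the random orthonormal initialization.
#' @param y Optional binary labels; when supplied, component importance is
#'   filled with the Fisher discriminant ratio of each source activation
#'   column (required before [select_components()] with the FDR rule).
#' @param maxit,tol Iteration cap and convergence tolerance on the change
#'   of unmixing directions.
#' @param strict If `FALSE`, `k` is silently clamped to the available rank
#'   (used by the pipeline on small training folds).
#' @return A `reduction_model` with `method = "ica"` and the voxel-space
#'   map `projection` such that activations = centered data %*% projection.
#' @export
fit_ica <- function(X, k, seed = 1L, y = NULL, maxit = 2000, tol = 1e-6,
                    strict = TRUE) {
  A <- as_values(X)
  n <- nrow(A)
  if (n < 3) stop("ICA needs at least 3 subjects")
  if (k < 1) stop("k must be >= 1")
  if (k > n - 1) {
    if (strict) stop("k must be at most n - 1 = ", n - 1)
    k <- n - 1
  }
  if (!strict) {
    # probe available rank cheaply and clamp
    mu0 <- colMeans(A)
    G0 <- tcrossprod(sweep(A, 2, mu0)) / n
    lam0 <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
    avail <- sum(lam0 > max(lam0) * 1e-10 & lam0 > 0)
    k <- min(k, avail)
  }
  wh <- whiten_gram(A, k)
  Z <- wh$Z

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  W0 <- matrix(stats::rnorm(k * k), k, k)
  sv <- svd(W0); W <- sv$u %*% t(sv$v)

  sym_decorrelate <- function(W) {
    es <- eigen(tcrossprod(W), symmetric = TRUE)
    es$vectors %*% diag(1 / sqrt(es$values), k) %*% t(es$vectors) %*% W
  }
  converged <- FALSE
  for (it in seq_len(maxit)) {
    S <- Z %*% t(W)                 # n x k current source estimates
    Gs <- tanh(S)
    W_new <- crossprod(Gs, Z) / n -
      diag(colMeans(1 - Gs^2), k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("ICA fixed-point iteration did not converge within ", maxit,
         " sweeps")
  # deterministic orientation/order: fix sign, order by kurtosis magnitude
  M <- wh$Mw %*% t(W)               # p x k: activations = centered %*% M
  S <- Z %*% t(W)
  for (j in seq_len(k)) {
    s <- fix_sign(S[, j])
    if (!identical(s, S[, j])) { S[, j] <- s; M[, j] <- -M[, j] }
  }
  imp <- if (!is.null(y)) {
    yf <- check_labels(y, n_min = 1)
    apply(S, 2, fisher_ratio, y = yf)
  } else rep(NA_real_, k)
  comps <- apply(M, 2, function(v) v / sqrt(sum(v^2)))
  structure(list(method = "ica", mean_vector = wh$mean_vector,
                 components = comps, projection = M, scores = S,
                 importance = imp, selected = NULL, seed = seed,
                 n_train = n, iterations = it),
            class = "reduction_model")
}

#' Fisher discriminant ratio of one feature
#'
#' The univariate class-separability score
#' \deqn{FDR = (\mu_1 - \mu_2)^2 / (\sigma_1^2 + \sigma_2^2)}
#' with unbiased (n-1) class variances. Both variances zero with equal
#' means gives 0; with unequal means the ratio is reported as `Inf` (with a
#' warning) since the classes are perfectly separated.
#'
#' @param feature Numeric vector of per-subject values.
#' @param y Binary labels, each class with >= 2 samples.
#' @return Nonnegative real (possibly `Inf`).
#' @examples
#' fisher_ratio(c(-1, 0, 1, 1, 2, 3), rep(c("a", "b"), each = 3))  # 2
#' @export
fisher_ratio <- function(feature, y) {
  yf <- check_labels(y, n_min = 2)
  g <- split(as.numeric(feature), yf)
  m1 <- mean(g[[1]]); m2 <- mean(g[[2]])
  v1 <- stats::var(g[[1]]); v2 <- stats::var(g[[2]])
  num <- (m1 - m2)^2; den <- v1 + v2
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero within-class variance with distinct means; FDR = Inf")
    return(Inf)
  }
  num / den
}

#' Component selection rule
#'
#' @param criterion `"cumulative_variance"` (PCA) or `"cumulative_fdr"`
#'   (PLS/ICA).
#' @param threshold Fraction of total importance to cover; defaults 0.75
#'   for cumulative variance and 0.85 for cumulative FDR, the values used
#'   in the reference pipeline.
#' @return Object of class `selection_rule`.
#' @export
selection_rule <- function(criterion = c("cumulative_variance",
                                         "cumulative_fdr"),
                           threshold = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(threshold))
    threshold <- if (criterion == "cumulative_variance") 0.75 else 0.85
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  structure(list(criterion = criterion, threshold = threshold),
            class = "selection_rule")
}

#' Select components by cumulative importance
#'
#' Components are ranked by descending importance (eigenvalues for PCA, FDR
#' for PLS/ICA; ties keep original order) and the smallest prefix whose
#' cumulative importance fraction reaches the threshold is selected.
#'
#' @param model A fitted `reduction_model` with importance populated.
#' @param rule A [selection_rule()] (default chosen from the model method).
#' @return The model with `selected` filled (indices in descending
#'   importance order).
#' @export
select_components <- function(model, rule = NULL) {
  stopifnot(inherits(model, "reduction_model"))
  if (is.null(rule))
    rule <- selection_rule(if (model$method == "pca")
      "cumulative_variance" else "cumulative_fdr")
  imp <- model$importance
  if (anyNA(imp))
    stop("importance not populated (ICA fitted without labels?)")
  if (any(imp < 0)) stop("negative importance values")
  if (any(is.infinite(imp))) {
    # perfectly separating components dominate: select exactly those
    model$selected <- which(is.infinite(imp))
    return(model)
  }
  total <- sum(imp)
  if (total <= 0) stop("all-zero importance; nothing to select")
  ord <- order(-imp)                      # stable for ties (radix)
  frac <- cumsum(imp[ord]) / total
  frac[length(frac)] <- 1                 # guard float undershoot
  n_sel <- which(frac >= rule$threshold - 1e-12)[1]
  model$selected <- ord[seq_len(n_sel)]
  model
}

#' Project data through a fitted reduction model
#'
#' Applies the training normalization state (unit-norm and mean subtraction
#' for PCA, column centering for PLS/ICA) followed by the fitted linear
#' map, restricted to the selected components. No statistic is re-estimated
#' from `X`.
#'
#' @param model A fitted `reduction_model`; if `selected` is empty all
#'   components are used.
#' @param X A `feature_matrix` or matrix whose column count matches the
#'   training voxel count.
#' @return Numeric matrix, subjects x selected components.
#' @export
project_features <- function(model, X) {
  stopifnot(inherits(model, "reduction_model"))
  A <- as_values(X)
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  if (ncol(A) != length(model$mean_vector))
    stop("dimension mismatch: ", ncol(A), " columns vs ",
         length(model$mean_vector), " training voxels")
  sel <- model$selected
  if (is.null(sel)) sel <- seq_along(model$importance)
  if (model$method == "pca") {
    norms <- sqrt(rowSums(A^2))
    norms[norms == 0] <- 1
    Cn <- sweep(A / norms, 2, model$mean_vector)
    Cn %*% model$components[, sel, drop = FALSE]
  } else {
    Cn <- sweep(A, 2, model$mean_vector)
    Cn %*% model$projection[, sel, drop = FALSE]
  }
}

#' @export
print.reduction_model <- function(x, ...) {
  cat(sprintf("<reduction_model> %s: %d components (%s selected)\n",
              toupper(x$method), ncol(x$components),
              if (is.null(x$selected)) "none yet"
              else length(x$selected)))
  invisible(x)
}

#' Serialize / restore a fitted reduction model as plain text
#'
#' Components and state are written as a JSON file (numbers at full double
#' precision), so fitted bases can be archived alongside results.
#'
#' @param model A `reduction_model`.
#' @param path Output path (`.json`).
#' @return `write_reduction_model` returns the path invisibly;
#'   `read_reduction_model` returns the restored model.
#' @export
write_reduction_model <- function(model, path) {
  stopifnot(inherits(model, "reduction_model"))
  obj <- lapply(unclass(model), function(f) {
    if (is.matrix(f)) list(.matrix = TRUE, dim = dim(f),
                           data = as.numeric(f))
    else f
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_reduction_model
#' @export
read_reduction_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- lapply(obj, function(f) {
    if (is.list(f) && isTRUE(f$.matrix))
      matrix(f$data, f$dim[1], f$dim[2])
    else f
  })
  if (!is.null(obj$selected) && length(obj$selected) == 0)
    obj$selected <- NULL
  structure(obj, class = "reduction_model")
}
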