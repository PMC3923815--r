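#' @title Multimodal fusion strategies around a maximal-margin classifier
#' @description Early integration (feature concatenation), intermediate
#'   integration (weighted linear kernel combination, i.e. multikernel
#'   classification) and late integration (decision-level fusion by signed
#'   margin distance) around a support vector machine with accessible
#'   decision values. Hyperparameters (cost, kernel, kernel weights) are
#'   chosen by leave-one-out within the training data.
#' @name fuse
NULL

LABEL_LEVELS <- c("stable", "converter")

as_label_factor <- function(y) {
  if (is.factor(y) && identical(levels(y), LABEL_LEVELS)) return(y)
  chr <- as.character(y)
  if (all(chr %in% LABEL_LEVELS))
    return(factor(chr, levels = LABEL_LEVELS))
  f <- factor(y)
  if (nlevels(f) != 2) stop("labels must have exactly two classes")
  # second level plays the positive (converter) role
  factor(ifelse(f == levels(f)[2], "converter", "stable"),
         levels = LABEL_LEVELS)
}

#' Concatenate a psychometric block and an image-feature block
#'
#' Early-integration feature vector: the neuropsychological scores followed
#' by the reduced image features, in that order, with no mixing.
#'
#' @param psych Numeric vector (may be length 0 in image-only mode).
#' @param image Numeric vector (may be length 0 in scores-only mode).
#' @return Numeric vector of length `length(psych) + length(image)`.
#' @export
early_concat <- function(psych, image) {
  psych <- as.numeric(psych); image <- as.numeric(image)
  if (length(psych) == 0 && length(image) == 0)
    stop("both blocks empty: nothing to concatenate")
  c(psych, image)
}

#' Weighted linear combination of kernel matrices
#'
#' Entry-wise weighted sum of M Gram matrices with nonnegative weights
#' summing to one; the combination is symmetric and positive semidefinite
#' whenever the inputs are.
#'
#' @param kernels List of square symmetric matrices of identical size.
#' @param weights Nonnegative weights summing to 1 (within 1e-9).
#' @return The combined kernel matrix.
#' @export
combine_kernels <- function(kernels, weights) {
  if (length(kernels) != length(weights))
    stop("one weight per kernel required")
  if (any(weights < 0)) stop("negative kernel weight")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  d <- dim(kernels[[1]])
  if (d[1] != d[2]) stop("kernels must be square")
  for (K in kernels) {
    if (!identical(dim(K), d)) stop("kernel size mismatch")
    if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
      stop("kernel matrix is not symmetric")
  }
  out <- matrix(0, d[1], d[2])
  for (m in seq_along(kernels)) out <- out + weights[m] * kernels[[m]]
  out
}

# --- feature scaling ------------------------------------------------------

fit_scaler <- function(X) {
  if (is.null(X) || ncol(X) == 0)
    return(list(mean = numeric(0), sd = numeric(0)))
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mean = m, sd = s)
}

apply_scaler <- function(scaler, X) {
  if (is.null(X) || ncol(X) == 0) return(X)
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

# --- kernels --------------------------------------------------------------

# Cross-kernel between row sets A (m x d) and B (n x d).
kernel_matrix <- function(spec, A, B = A) {
  if (spec$kind == "linear") return(A %*% t(B))
  if (spec$kind == "rbf") {
    sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sq[sq < 0] <- 0
    return(exp(-sq / (2 * spec$bandwidth^2)))
  }
  stop("unknown kernel kind: ", spec$kind)
}

#' Default hyperparameter grids for fusion models
#'
#' @param cost_grid SVM cost values (default the symmetric powers-of-two
#'   grid `2^(-5..5)`).
#' @param kernels List of kernel specs, each `list(kind = "linear")` or
#'   `list(kind = "rbf", bandwidth = b)`. The default menu is linear plus
#'   RBF bandwidths `2^(-3..3)` over standardized features, with linear
#'   first so ties resolve toward it.
#' @param weight_grid Image-kernel weights for intermediate integration
#'   (`beta_image`; `beta_psych = 1 - beta_image`), default `0, 0.1, .. 1`.
#' @return List of class `fusion_hyperparams`.
#' @export
fusion_hyperparams <- function(cost_grid = 2^(-5:5),
                               kernels = NULL,
                               weight_grid = seq(0, 1, by = 0.1)) {
  if (is.null(kernels))
    kernels <- c(list(list(kind = "linear")),
                 lapply(2^(-3:3), function(b)
                   list(kind = "rbf", bandwidth = b)))
  if (any(cost_grid <= 0)) stop("costs must be positive")
  structure(list(cost_grid = sort(cost_grid), kernels = kernels,
                 weight_grid = weight_grid),
            class = "fusion_hyperparams")
}

# --- SVM wrappers ---------------------------------------------------------
# Two engines share one contract (fit + signed decision oriented so that
# positive means converter): libsvm via e1071 on explicit features (fast
# path for linear/RBF kernels), and kernlab on precomputed kernel matrices
# (needed when an RBF multikernel combination has no feature-space form).

svm_fit_feat <- function(Z, y, C, spec) {
  m <- if (spec$kind == "linear")
    e1071::svm(Z, y, kernel = "linear", cost = C, scale = FALSE)
  else
    e1071::svm(Z, y, kernel = "radial",
               gamma = 1 / (2 * spec$bandwidth^2), cost = C,
               scale = FALSE)
  d <- as.numeric(attr(predict(m, Z, decision.values = TRUE),
                       "decision.values"))
  mc <- mean(d[y == "converter"]); ms <- mean(d[y == "stable"])
  flip <- if (is.finite(mc) && is.finite(ms) && mc < ms) -1 else 1
  list(engine = "features", svm = m, flip = flip)
}

svm_decide_feat <- function(fit, Znew) {
  d <- as.numeric(attr(predict(fit$svm, Znew, decision.values = TRUE),
                       "decision.values"))
  d * fit$flip
}

svm_fit_kernel <- function(K, y, C) {
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                     C = C)
  sv <- kernlab::SVindex(m)
  d <- as.numeric(kernlab::predict(m, kernlab::as.kernelMatrix(
    K[, sv, drop = FALSE]), type = "decision"))
  # orient so positive margin means converter
  mc <- mean(d[y == "converter"]); ms <- mean(d[y == "stable"])
  flip <- if (is.finite(mc) && is.finite(ms) && mc < ms) -1 else 1
  list(svm = m, sv = sv, flip = flip)
}

svm_decision <- function(fit, Kcross) {
  d <- as.numeric(kernlab::predict(fit$svm, kernlab::as.kernelMatrix(
    Kcross[, fit$sv, drop = FALSE]), type = "decision"))
  d * fit$flip
}

# Leave-one-out accuracy of a C-SVM on a fixed precomputed kernel.
loo_kernel_accuracy <- function(K, y, C) {
  n <- nrow(K)
  correct <- 0
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2) next
    fit <- try(svm_fit_kernel(K[-i, -i, drop = FALSE], y[-i], C),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    d <- svm_decision(fit, K[i, -i, drop = FALSE])
    pred <- if (d > 0) "converter" else "stable"
    if (pred == as.character(y[i])) correct <- correct + 1
  }
  correct / n
}

# Leave-one-out accuracy on explicit features.
loo_feat_accuracy <- function(Z, y, C, spec) {
  n <- nrow(Z)
  correct <- 0
  for (i in seq_len(n)) {
    if (nlevels(droplevels(y[-i])) < 2) next
    fit <- try(svm_fit_feat(Z[-i, , drop = FALSE], y[-i], C, spec),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    d <- svm_decide_feat(fit, Z[i, , drop = FALSE])
    pred <- if (d > 0) "converter" else "stable"
    if (pred == as.character(y[i])) correct <- correct + 1
  }
  correct / n
}

# Inner model selection over a candidate list: each candidate supplies an
# `acc` closure computing its inner-LOO accuracy. Candidates are ordered so
# that the first maximum realizes the documented tie-breaks (linear before
# RBF, smaller C first). With a single candidate the loop is skipped.
select_candidate <- function(candidates) {
  if (length(candidates) == 1)
    return(list(best = candidates[[1]], accuracy = NA_real_))
  acc <- vapply(candidates, function(cand) cand$acc(), numeric(1))
  best <- which.max(acc)
  list(best = candidates[[best]], accuracy = acc[best])
}

fit_single_source <- function(Z, y, hp) {
  cands <- list()
  for (ks in hp$kernels) for (C in hp$cost_grid) {
    local({
      ks_ <- ks; C_ <- C
      cands[[length(cands) + 1]] <<-
        list(kernel = ks_, C = C_,
             acc = function() loo_feat_accuracy(Z, y, C_, ks_))
    })
  }
  sel <- select_candidate(cands)
  fit <- svm_fit_feat(Z, y, sel$best$C, sel$best$kernel)
  list(fit = fit, kernel = sel$best$kernel, C = sel$best$C,
       inner_accuracy = sel$accuracy, train = Z)
}

#' Fit a fusion model
#'
#' Trains one of the integration strategies on per-subject feature bundles.
#' Both blocks are z-scored with training statistics first (the two sources
#' live on incommensurate scales). Hyperparameters — cost, kernel, and for
#' intermediate integration the kernel weights — are selected by
#' leave-one-out within the training data, ties broken toward the linear
#' kernel and smaller cost.
#'
#' \describe{
#'   \item{early}{one SVM on the concatenated standardized features.}
#'   \item{intermediate}{one SVM on the weighted sum of one kernel per
#'     source (multikernel classification).}
#'   \item{late}{one SVM per source; prediction-time fusion keeps the class
#'     whose decision lies farther from its separating hyperplane, falling
#'     back to the source with the higher individual inner-CV accuracy on
#'     exact ties.}
#'   \item{image_only / psych_only}{single-source baselines.}
#' }
#'
#' @param strategy One of `"early"`, `"intermediate"`, `"late"`,
#'   `"image_only"`, `"psych_only"`.
#' @param psych Numeric matrix of psychometric features (subjects x 5 or
#'   7), or `NULL` in image-only mode.
#' @param image Numeric matrix of reduced image features, or `NULL` in
#'   psych-only mode.
#' @param y Binary labels (`stable`/`converter`).
#' @param hyperparams A [fusion_hyperparams()].
#' @return A `fusion_model`.
#' @export
fit_fusion <- function(strategy = c("early", "intermediate", "late",
                                    "image_only", "psych_only"),
                       psych, image, y,
                       hyperparams = fusion_hyperparams()) {
  strategy <- match.arg(strategy)
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  if (!is.null(psych)) psych <- as.matrix(psych)
  if (!is.null(image)) image <- as.matrix(image)
  needs_psych <- strategy != "image_only"
  needs_image <- strategy != "psych_only"
  if (needs_psych && (is.null(psych) || ncol(psych) == 0))
    stop("strategy '", strategy, "' requires the psychometric source")
  if (needs_image && (is.null(image) || ncol(image) == 0))
    stop("strategy '", strategy, "' requires the image source")
  hp <- hyperparams

  sc_p <- if (needs_psych) fit_scaler(psych) else NULL
  sc_i <- if (needs_image) fit_scaler(image) else NULL
  Zp <- if (needs_psych) apply_scaler(sc_p, psych) else NULL
  Zi <- if (needs_image) apply_scaler(sc_i, image) else NULL

  model <- list(strategy = strategy, scaler_psych = sc_p,
                scaler_image = sc_i, levels = LABEL_LEVELS)

  if (strategy %in% c("early", "image_only", "psych_only")) {
    Z <- if (strategy == "image_only") Zi
         else if (strategy == "psych_only") Zp
         else cbind(Zp, Zi)
    ss <- fit_single_source(Z, y, hp)
    model <- c(model, list(fit = ss$fit, kernel = ss$kernel, C = ss$C,
                           inner_accuracy = ss$inner_accuracy,
                           train = Z,
                           n_psych = if (is.null(Zp)) 0 else ncol(Zp)))
  } else if (strategy == "intermediate") {
    # a convex combination of linear kernels is itself a linear kernel on
    # weight-scaled concatenated blocks, which admits the fast explicit-
    # feature solver; RBF combinations go through the precomputed-kernel
    # solver
    cands <- list()
    for (ks in hp$kernels) {
      if (ks$kind == "linear") {
        for (beta in hp$weight_grid) for (C in hp$cost_grid) local({
          ks_ <- ks; b_ <- beta; C_ <- C
          Zc <- cbind(sqrt(b_) * Zi, sqrt(1 - b_) * Zp)
          cands[[length(cands) + 1]] <<-
            list(kernel = ks_, C = C_, beta_image = b_,
                 engine = "features", Z = Zc,
                 acc = function() loo_feat_accuracy(Zc, y, C_, ks_))
        })
      } else {
        Kp <- kernel_matrix(ks, Zp); Ki <- kernel_matrix(ks, Zi)
        for (beta in hp$weight_grid) for (C in hp$cost_grid) local({
          ks_ <- ks; b_ <- beta; C_ <- C
          K <- combine_kernels(list(Ki, Kp), c(b_, 1 - b_))
          cands[[length(cands) + 1]] <<-
            list(kernel = ks_, C = C_, beta_image = b_,
                 engine = "kernel", K = K,
                 acc = function() loo_kernel_accuracy(K, y, C_))
        })
      }
    }
    sel <- select_candidate(cands)
    best <- sel$best
    fit <- if (best$engine == "features")
      svm_fit_feat(best$Z, y, best$C, best$kernel)
    else svm_fit_kernel(best$K, y, best$C)
    model <- c(model, list(fit = fit, kernel = best$kernel, C = best$C,
                           beta_image = best$beta_image,
                           engine = best$engine,
                           inner_accuracy = sel$accuracy,
                           train_psych = Zp, train_image = Zi))
  } else {                                   # late
    fp <- fit_single_source(Zp, y, hp)
    fi <- fit_single_source(Zi, y, hp)
    accs <- c(psych = fp$inner_accuracy, image = fi$inner_accuracy)
    fallback <- if (anyNA(accs) || accs["psych"] >= accs["image"])
      "psych" else "image"
    model <- c(model, list(fit_psych = fp, fit_image = fi,
                           fallback_source = fallback,
                           inner_accuracies = accs))
  }
  class(model) <- "fusion_model"
  model
}

#' Predict labels and decision values from a fusion model
#'
#' Returns, for each subject, a predicted class and a signed decision value
#' (functional margin; positive means converter). For late integration the
#' source whose decision lies strictly farther from its hyperplane wins;
#' exact ties go to the model's fallback source.
#'
#' @param object A fitted `fusion_model`.
#' @param psych,image Feature matrices matching the training layout (rows =
#'   subjects). Supply only the source(s) the strategy uses.
#' @param ... Unused.
#' @return data.frame with columns `label` (factor) and `decision`.
#' @export
predict.fusion_model <- function(object, psych = NULL, image = NULL, ...) {
  strategy <- object$strategy
  reshape_block <- function(x, d, what) {
    if (is.null(x) || d == 0) return(x)
    if (is.matrix(x) && ncol(x) != d)
      stop(what, " block has ", ncol(x), " columns; model expects ", d)
    if (!is.matrix(x) && length(x) %% d != 0)
      stop(what, " block length is not a multiple of ", d)
    matrix(as.numeric(x), ncol = d)
  }
  if (!is.null(object$scaler_psych))
    psych <- reshape_block(psych, length(object$scaler_psych$mean),
                           "psych")
  if (!is.null(object$scaler_image))
    image <- reshape_block(image, length(object$scaler_image$mean),
                           "image")
  Zp <- if (!is.null(object$scaler_psych) && !is.null(psych))
    apply_scaler(object$scaler_psych, psych) else NULL
  Zi <- if (!is.null(object$scaler_image) && !is.null(image))
    apply_scaler(object$scaler_image, image) else NULL

  decide <- function(d) factor(ifelse(d > 0, "converter", "stable"),
                               levels = LABEL_LEVELS)
  if (strategy %in% c("early", "image_only", "psych_only")) {
    Z <- if (strategy == "image_only") Zi
         else if (strategy == "psych_only") Zp
         else cbind(Zp, Zi)
    if (is.null(Z)) stop("required source missing for strategy ", strategy)
    if (ncol(Z) != ncol(object$train)) stop("feature dimension mismatch")
    d <- svm_decide_feat(object$fit, Z)
    return(data.frame(label = decide(d), decision = d))
  }
  if (strategy == "intermediate") {
    if (is.null(Zp) || is.null(Zi)) stop("both sources required")
    b <- object$beta_image
    if (identical(object$engine, "features")) {
      d <- svm_decide_feat(object$fit,
                           cbind(sqrt(b) * Zi, sqrt(1 - b) * Zp))
    } else {
      Kp <- kernel_matrix(object$kernel, Zp, object$train_psych)
      Ki <- kernel_matrix(object$kernel, Zi, object$train_image)
      d <- svm_decision(object$fit, b * Ki + (1 - b) * Kp)
    }
    return(data.frame(label = decide(d), decision = d))
  }
  # late integration
  if (is.null(Zp) || is.null(Zi)) stop("both sources required")
  dp <- svm_decide_feat(object$fit_psych$fit, Zp)
  di <- svm_decide_feat(object$fit_image$fit, Zi)
  n <- length(dp)
  d <- numeric(n)
  for (r in seq_len(n)) {
    d[r] <- if (abs(dp[r]) > abs(di[r])) dp[r]
            else if (abs(di[r]) > abs(dp[r])) di[r]
            else if (object$fallback_source == "psych") dp[r] else di[r]
  }
  data.frame(label = decide(d), decision = d,
             decision_psych = dp, decision_image = di)
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> strategy = %s\n", x$strategy))
  invisible(x)
}
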