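#' @title Leave-one-out evaluation, metrics, ROC and permutation testing
#' @name evaluate
NULL

#' Confusion counts with converter as the positive class
#'
#' @param truth,pred Label vectors (`stable`/`converter`).
#' @return List of class `confusion_counts` with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as_label_factor(truth); pred <- as_label_factor(pred)
  stopifnot(length(truth) == length(pred))
  structure(list(
    tp = sum(truth == "converter" & pred == "converter"),
    fn = sum(truth == "converter" & pred == "stable"),
    tn = sum(truth == "stable" & pred == "stable"),
    fp = sum(truth == "stable" & pred == "converter")),
    class = "confusion_counts")
}

#' Round half away from zero (display convention for reported rates)
#' @param x Numeric. @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (detected converters), specificity, and the
#' positive/negative likelihood ratios `LR+ = sens / (1 - spec)` and
#' `LR- = (1 - sens) / spec`. Degenerate denominators yield an `Inf`
#' sentinel (logged via message), never an error. Values are returned as
#' fractions; use [format_metrics()] for the two-decimal percentage
#' display.
#'
#' @param counts A `confusion_counts`.
#' @return List of class `metrics`.
#' @examples
#' m <- compute_metrics(structure(list(tp = 24, fn = 2, tn = 17, fp = 3),
#'                                class = "confusion_counts"))
#' round_half_up(100 * m$accuracy)  # 89.13
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fn + counts$tn + counts$fp
  if (n == 0) stop("empty confusion table")
  sens <- counts$tp / (counts$tp + counts$fn)
  spec <- counts$tn / (counts$tn + counts$fp)
  lr_pos <- if (spec == 1) {
    message("specificity = 1; LR+ reported as Inf")
    Inf
  } else sens / (1 - spec)
  lr_neg <- if (spec == 0) {
    message("specificity = 0; LR- reported as Inf")
    Inf
  } else (1 - sens) / spec
  structure(list(accuracy = (counts$tp + counts$tn) / n,
                 sensitivity = sens, specificity = spec,
                 lr_pos = lr_pos, lr_neg = lr_neg, counts = counts),
            class = "metrics")
}

#' @rdname compute_metrics
#' @param m A `metrics` object.
#' @return `format_metrics`: named character vector in the display
#'   convention (percentages and ratios, two decimals, half-up).
#' @export
format_metrics <- function(m) {
  stopifnot(inherits(m, "metrics"))
  c(accuracy = sprintf("%.2f%%", round_half_up(100 * m$accuracy)),
    sensitivity = sprintf("%.2f%%", round_half_up(100 * m$sensitivity)),
    specificity = sprintf("%.2f%%", round_half_up(100 * m$specificity)),
    lr_pos = sprintf("%.2f", round_half_up(m$lr_pos)),
    lr_neg = sprintf("%.2f", round_half_up(m$lr_neg)))
}

#' @export
print.metrics <- function(x, ...) {
  f <- format_metrics(x)
  cat(sprintf("accuracy %s | sensitivity %s | specificity %s | LR+ %s | LR- %s\n",
              f[1], f[2], f[3], f[4], f[5]))
  invisible(x)
}

#' ROC curve and AUC from decision values
#'
#' Sweeps the classification threshold over the unique decision values
#' (samples with tied decisions cross the threshold simultaneously),
#' yielding the sensitivity / 1-specificity trade-off with endpoints (0,0)
#' and (1,1); the AUC is the trapezoidal integral, which equals the
#' probability that a random converter outranks a random stable subject
#' (ties counted 1/2).
#'
#' @param decision_values Numeric vector (higher means more converter-like).
#' @param y Labels (`stable`/`converter`).
#' @return List of class `roc_result`: `thresholds`, `sensitivities`,
#'   `one_minus_specificities`, `auc`.
#' @export
roc_from_decisions <- function(decision_values, y) {
  y <- as_label_factor(y)
  d <- as.numeric(decision_values)
  if (!all(is.finite(d))) stop("non-finite decision values")
  if (nlevels(droplevels(y)) < 2) stop("both classes required")
  npos <- sum(y == "converter"); nneg <- sum(y == "stable")
  if (length(unique(d)) == 1)
    message("constant decision values; degenerate two-point ROC, AUC 0.5")
  thr <- sort(unique(d), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(d >= t & y == "converter") / npos,
                 numeric(1))
  fpr <- vapply(thr, function(t) sum(d >= t & y == "stable") / nneg,
                numeric(1))
  sens <- c(0, sens, 1); fpr <- c(0, fpr, 1)
  thr <- c(Inf, thr, -Inf)
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(thresholds = thr, sensitivities = sens,
                 one_minus_specificities = fpr, auc = auc),
            class = "roc_result")
}

# ---- pipeline configuration ---------------------------------------------

#' Configuration of one end-to-end pipeline
#'
#' Bundles every choice the leave-one-out evaluation needs: the reduction
#' backend and its component-selection rule, the fusion strategy, whether
#' MMSE and age join the psychometric block, the SVM grids, and the seed.
#'
#' @param reduction `"pca"`, `"pls"` or `"ica"` (ignored for
#'   `approach = "psych_only"`).
#' @param approach Fusion strategy or single-source baseline (see
#'   [fit_fusion()]).
#' @param use_mmse_age Include MMSE and age as additional scores.
#' @param threshold Cumulative importance threshold; default 0.75
#'   (variance, PCA) or 0.85 (FDR, PLS/ICA).
#' @param n_ica Number of ICA components before selection (default
#'   `min(n - 1, 20)`, clamped to rank on each training fold).
#' @param hyperparams A [fusion_hyperparams()].
#' @param fit_on_all Compatibility flag: fit the reduction once on all
#'   subjects instead of per training fold (default `FALSE`, the
#'   leakage-safe behaviour).
#' @param seed Integer seed (drives ICA initialization and any other
#'   stochastic step).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(reduction = c("pca", "pls", "ica"),
                            approach = c("early", "intermediate", "late",
                                         "image_only", "psych_only"),
                            use_mmse_age = FALSE,
                            threshold = NULL,
                            n_ica = 20,
                            hyperparams = fusion_hyperparams(),
                            fit_on_all = FALSE,
                            seed = 1L) {
  reduction <- match.arg(reduction)
  approach <- match.arg(approach)
  rule <- if (reduction == "pca")
    selection_rule("cumulative_variance", threshold)
  else selection_rule("cumulative_fdr", threshold)
  structure(list(reduction = reduction, approach = approach,
                 use_mmse_age = isTRUE(use_mmse_age), rule = rule,
                 n_ica = n_ica, hyperparams = hyperparams,
                 fit_on_all = isTRUE(fit_on_all), seed = as.integer(seed)),
            class = "pipeline_config")
}

fit_reduction_fold <- function(Xtr, ytr, config, fold_seed) {
  model <- switch(config$reduction,
    pca = fit_pca(Xtr),
    pls = fit_pls(Xtr, ytr),
    ica = fit_ica(Xtr, k = min(config$n_ica, nrow(Xtr) - 1),
                  seed = fold_seed, y = ytr, strict = FALSE))
  select_components(model, config$rule)
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' For each subject, preprocessing statistics, the reduction basis and its
#' component selection, the feature scalers and the classifier (with inner
#' leave-one-out hyperparameter selection) are fitted on the remaining
#' subjects only; the held-out subject is then predicted. Reference
#' normalization is per-subject and involves no cross-subject statistic,
#' so it is applied once up front.
#'
#' @param cohort A `cohort` with at least 2 subjects per class.
#' @param config A [pipeline_config()].
#' @param feature_matrix Optional precomputed [vectorize_cohort()] result
#'   (it contains no cross-subject statistics, so sharing it across calls
#'   is leakage-free).
#' @return List of class `evaluation_report`: `predictions` (one row per
#'   subject in cohort order: id, truth, label, decision), `counts`,
#'   `metrics`, `roc`, `config`.
#' @export
loo_cross_validate <- function(cohort, config, feature_matrix = NULL) {
  validate_cohort(cohort)
  stopifnot(inherits(config, "pipeline_config"))
  y <- cohort$labels
  if (any(table(y) < 2)) stop("need at least 2 subjects per class")
  n <- length(y)
  use_image <- config$approach != "psych_only"
  use_psych <- config$approach != "image_only"
  X <- if (use_image) {
    if (is.null(feature_matrix)) vectorize_cohort(cohort)
    else feature_matrix
  } else NULL
  P <- if (use_psych) score_matrix(cohort, config$use_mmse_age) else NULL

  all_model <- NULL
  if (use_image && config$fit_on_all)
    all_model <- fit_reduction_fold(X$values, y, config,
                                    fold_seed = config$seed)

  labels <- character(n); decisions <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- y[tr]
    if (nlevels(droplevels(ytr)) < 2)
      stop("class absent from training fold ", i)
    img_tr <- img_te <- NULL
    if (use_image) {
      model <- if (config$fit_on_all) all_model
        else fit_reduction_fold(X$values[tr, , drop = FALSE], ytr, config,
                                fold_seed = config$seed + i)
      img_tr <- project_features(model, X$values[tr, , drop = FALSE])
      img_te <- project_features(model, X$values[i, , drop = FALSE])
    }
    psy_tr <- if (use_psych) P[tr, , drop = FALSE] else NULL
    psy_te <- if (use_psych) P[i, , drop = FALSE] else NULL
    fm <- fit_fusion(config$approach, psy_tr, img_tr, ytr,
                     config$hyperparams)
    pr <- predict(fm, psych = psy_te, image = img_te)
    labels[i] <- as.character(pr$label[1])
    decisions[i] <- pr$decision[1]
  }
  preds <- data.frame(id = cohort$ids, truth = y,
                      label = factor(labels, levels = LABEL_LEVELS),
                      decision = decisions, stringsAsFactors = FALSE)
  counts <- confusion_counts(preds$truth, preds$label)
  structure(list(predictions = preds, counts = counts,
                 metrics = compute_metrics(counts),
                 roc = roc_from_decisions(decisions, y),
                 config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / %s%s — ",
              x$config$reduction, x$config$approach,
              if (x$config$use_mmse_age) " (+MMSE+age)" else ""))
  print(x$metrics)
  invisible(x)
}

#' Permutation test of the neuropsychological contribution
#'
#' Draws `n_perm` random score panels — each subject's scores replaced by
#' independent uniforms over the observed per-score [min, max] of the true
#' cohort — reruns the complete leave-one-out pipeline on each, and counts
#' how often the permuted accuracy strictly exceeds the observed one:
#' `p = (# permuted > observed) / n_perm`.
#'
#' @param cohort A `cohort`.
#' @param config A [pipeline_config()] whose approach uses both sources.
#' @param n_perm Number of random score sets (reference value 1000;
#'   reduced-rep runs are supported since every draw is a full LOO).
#' @param seed Seed for the random draws.
#' @param observed Optional precomputed `evaluation_report` for the true
#'   cohort (skips one LOO run).
#' @return List of class `permutation_result`: `observed_accuracy`,
#'   `permuted_accuracies`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(cohort, config, n_perm = 1000, seed = 1L,
                             observed = NULL) {
  validate_cohort(cohort)
  if (!config$approach %in% c("early", "intermediate", "late"))
    stop("permutation test requires a fusion strategy using both sources")
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- vectorize_cohort(cohort)
  if (is.null(observed))
    observed <- loo_cross_validate(cohort, config, feature_matrix = X)
  obs_acc <- observed$metrics$accuracy

  cols <- score_panel_names(config$use_mmse_age, education = FALSE)
  S <- as.matrix(cohort$scores[, cols, drop = FALSE])
  lo <- apply(S, 2, min); hi <- apply(S, 2, max)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  draws <- lapply(seq_len(n_perm), function(b) {
    m <- matrix(stats::runif(nrow(S) * ncol(S)), nrow(S), ncol(S))
    sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
  })
  perm_acc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm_cohort <- cohort
    perm_cohort$scores[, cols] <- draws[[b]]
    rep_b <- loo_cross_validate(perm_cohort, config, feature_matrix = X)
    perm_acc[b] <- rep_b$metrics$accuracy
  }
  structure(list(observed_accuracy = obs_acc,
                 permuted_accuracies = perm_acc,
                 p_value = sum(perm_acc > obs_acc) / n_perm,
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.4f, p = %.4f (%d draws)\n",
              x$observed_accuracy, x$p_value, x$n_perm))
  invisible(x)
}
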