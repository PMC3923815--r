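# Shared fixtures: small cohorts and reduced hyperparameter grids keep the
# leave-one-out loops fast while exercising the full code paths.

tiny_config <- function(n_stable = 4, n_converter = 5, shape = c(8, 8, 8),
                        effect_image = 1, effect_scores = 1, seed = 1L,
                        ...) {
  synth_config(n_stable = n_stable, n_converter = n_converter,
               volume_shape = shape, effect_size_image = effect_image,
               effect_size_scores = effect_scores, seed = seed, ...)
}

tiny_cohort <- function(...) generate_cohort(tiny_config(...))

# single linear kernel, single cost: the inner selection loop is skipped
fast_hp <- function(costs = 1, weights = c(0, 0.5, 1)) {
  fusion_hyperparams(cost_grid = costs,
                     kernels = list(list(kind = "linear")),
                     weight_grid = weights)
}

fast_config <- function(reduction = "pca", approach = "early", ...,
                        hyperparams = fast_hp()) {
  pipeline_config(reduction, approach, hyperparams = hyperparams, ...)
}

# brute-force AUC: fraction of (converter, stable) pairs ranked correctly,
# ties counted one half
pairwise_auc <- function(d, y) {
  pos <- d[y == "converter"]; neg <- d[y == "stable"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

random_psd <- function(n, seed_draw = NULL) {
  A <- matrix(rnorm(n * n), n, n)
  crossprod(A) / n
}
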