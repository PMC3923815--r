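test_that("early concatenation keeps block order and values intact", {
  p <- rnorm(7); f <- rnorm(5)
  v <- early_concat(p, f)
  expect_length(v, 12)
  expect_identical(v[1:7], p)
  expect_identical(v[8:12], f)
  expect_identical(early_concat(p, numeric(0)), p)
  expect_error(early_concat(numeric(0), numeric(0)), "empty")
})

test_that("kernel combination follows the weighted-sum contract", {
  K1 <- diag(2); K2 <- matrix(2, 2, 2)
  expect_identical(combine_kernels(list(K1, K2), c(1, 0)), K1)
  expect_equal(combine_kernels(list(K1, K2), c(0.5, 0.5)),
               matrix(c(1.5, 1, 1, 1.5), 2, 2))
  K <- random_psd(4)
  expect_equal(combine_kernels(list(K, K), c(0.3, 0.7)), K)
  expect_error(combine_kernels(list(K1, K2), c(0.5, 0.6)), "sum to 1")
  expect_error(combine_kernels(list(K1, K2), c(1.5, -0.5)), "negative")
  expect_error(combine_kernels(list(K1, random_psd(3)), c(0.5, 0.5)),
               "mismatch")
})

test_that("combining PSD kernels with simplex weights stays PSD", {
  set.seed(20)
  for (r in 1:100) {
    n <- sample(3:6, 1)
    K1 <- random_psd(n); K2 <- random_psd(n)
    w <- runif(2); w <- w / sum(w)
    Kc <- combine_kernels(list(K1, K2), w)
    expect_gte(min(eigen(Kc, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

make_bundles <- function(n_per = 6, sep_psych = 3, sep_image = 3,
                         d_psych = 5, d_image = 4, seed = 30) {
  set.seed(seed)
  y <- factor(rep(c("stable", "converter"), each = n_per),
              levels = c("stable", "converter"))
  shift <- ifelse(y == "converter", 1, 0)
  psych <- matrix(rnorm(2 * n_per * d_psych), ncol = d_psych) +
    sep_psych * shift
  image <- matrix(rnorm(2 * n_per * d_image), ncol = d_image) +
    sep_image * shift
  list(psych = psych, image = image, y = y)
}

test_that("all strategies reach training accuracy 1 on separable bundles", {
  b <- make_bundles()
  for (s in c("early", "intermediate", "late", "image_only",
              "psych_only")) {
    m <- fit_fusion(s, b$psych, b$image, b$y, fast_hp())
    pr <- predict(m, psych = b$psych, image = b$image)
    expect_identical(as.character(pr$label), as.character(b$y),
                     info = s)
    expect_true(all(sign(pr$decision) ==
                      ifelse(b$y == "converter", 1, -1)), info = s)
  }
})

test_that("intermediate with beta_image = 1 matches an image-only SVM", {
  b <- make_bundles(sep_psych = 0.2)
  hp1 <- fusion_hyperparams(cost_grid = 1,
                            kernels = list(list(kind = "linear")),
                            weight_grid = 1)
  mi <- fit_fusion("intermediate", b$psych, b$image, b$y, hp1)
  mo <- fit_fusion("image_only", NULL, b$image, b$y, fast_hp())
  di <- predict(mi, psych = b$psych, image = b$image)$decision
  do <- predict(mo, image = b$image)$decision
  expect_equal(di, do, tolerance = 1e-8)
})

test_that("late fusion with duplicated sources equals the single source", {
  b <- make_bundles(sep_psych = 1.5, sep_image = 1.5, d_image = 5)
  m <- fit_fusion("late", b$psych, b$psych, b$y, fast_hp())
  pr <- predict(m, psych = b$psych, image = b$psych)
  ms <- fit_fusion("psych_only", b$psych, NULL, b$y, fast_hp())
  ps <- predict(ms, psych = b$psych)
  # identical sources give |d_P| = |d_I| everywhere: the fallback (psych)
  # decides, reproducing the single-source predictions
  expect_equal(abs(pr$decision_psych), abs(pr$decision_image),
               tolerance = 1e-8)
  expect_identical(as.character(pr$label), as.character(ps$label))
})

test_that("late fusion keeps the source with the larger margin", {
  b <- make_bundles(sep_psych = 0.1, sep_image = 4)
  m <- fit_fusion("late", b$psych, b$image, b$y, fast_hp())
  pr <- predict(m, psych = b$psych, image = b$image)
  dominant <- abs(pr$decision_image) > abs(pr$decision_psych)
  expect_identical(pr$decision[dominant], pr$decision_image[dominant])
  mi <- fit_fusion("image_only", NULL, b$image, b$y, fast_hp())
  pi_ <- predict(mi, image = b$image)
  if (all(dominant))
    expect_identical(as.character(pr$label), as.character(pi_$label))
})

test_that("flipping the label coding flips decisions, not assignments", {
  b <- make_bundles(seed = 31)
  y1 <- factor(ifelse(b$y == "converter", "pos", "neg"),
               levels = c("neg", "pos"))
  y2 <- factor(as.character(y1), levels = c("pos", "neg"))
  m1 <- fit_fusion("early", b$psych, b$image, y1, fast_hp())
  m2 <- fit_fusion("early", b$psych, b$image, y2, fast_hp())
  p1 <- predict(m1, psych = b$psych, image = b$image)
  p2 <- predict(m2, psych = b$psych, image = b$image)
  # mirror solutions agree up to the QP solver's own tolerance
  expect_equal(p1$decision, -p2$decision, tolerance = 1e-3)
  expect_true(all(p1$label != p2$label))
})

test_that("test-time scaling uses training statistics only", {
  b <- make_bundles()
  m <- fit_fusion("early", b$psych, b$image, b$y, fast_hp())
  expect_equal(m$scaler_psych$mean, colMeans(b$psych))
  expect_equal(m$scaler_image$mean, colMeans(b$image))
  # predicting an extreme subject leaves the stored statistics untouched
  extreme_p <- matrix(1e6, 1, ncol(b$psych))
  extreme_i <- matrix(1e6, 1, ncol(b$image))
  invisible(predict(m, psych = extreme_p, image = extreme_i))
  expect_equal(m$scaler_psych$mean, colMeans(b$psych))
  expect_equal(m$scaler_image$mean, colMeans(b$image))
})

test_that("degenerate inputs are rejected", {
  b <- make_bundles()
  expect_error(fit_fusion("early", b$psych, b$image,
                          rep("stable", nrow(b$psych)), fast_hp()),
               "two classes|both classes")
  expect_error(fit_fusion("intermediate", NULL, b$image, b$y, fast_hp()),
               "psychometric")
  expect_error(fit_fusion("early", b$psych, NULL, b$y, fast_hp()),
               "image")
  m <- fit_fusion("early", b$psych, b$image, b$y, fast_hp())
  expect_error(predict(m, psych = b$psych[, 1:2], image = b$image))
})

test_that("inner LOO selection prefers the better hyperparameters", {
  # widely separated data: every cost works; tie-break picks the smallest
  b <- make_bundles()
  hp <- fusion_hyperparams(cost_grid = c(0.5, 4),
                           kernels = list(list(kind = "linear")),
                           weight_grid = c(0, 1))
  m <- fit_fusion("early", b$psych, b$image, b$y, hp)
  expect_equal(m$C, 0.5)
  expect_equal(m$kernel$kind, "linear")
  expect_gte(m$inner_accuracy, 0.9)
})
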