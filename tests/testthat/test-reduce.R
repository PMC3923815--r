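# ---- PCA -----------------------------------------------------------------

test_that("rank-1 data yields a single dominant eigenvalue", {
  # rows take two directions on the unit sphere (scaled arbitrarily), so
  # after unit-norming and centering they are multiples of one vector
  set.seed(1)
  p <- rnorm(30); p <- p / sqrt(sum(p^2))
  q <- rnorm(30); q <- q / sqrt(sum(q^2))
  X <- rbind(2.0 * p, 0.7 * p, 5.1 * p, 0.5 * q, 3.3 * q)
  m <- fit_pca(X)
  lam <- m$importance
  expect_equal(sum(lam > 1e-10 * max(lam)), 1)
})

test_that("Gram-trick spectrum matches the voxel-space covariance", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(4:8, 1); p <- sample(20:50, 1)
    X <- matrix(rnorm(n * p), n, p)
    m <- fit_pca(X)
    # independent brute-force oracle on the p x p covariance of the
    # unit-normed, mean-subtracted rows
    U <- X / sqrt(rowSums(X^2))
    C <- sweep(U, 2, colMeans(U))
    cov_direct <- crossprod(C) / n
    lam_direct <- eigen(cov_direct, symmetric = TRUE,
                        only.values = TRUE)$values
    lam_direct <- lam_direct[seq_along(m$importance)]
    expect_equal(m$importance, lam_direct, tolerance = 1e-8)
  }
})

test_that("training projections are centered and isometric", {
  set.seed(3)
  X <- matrix(rnorm(7 * 40), 7, 40)
  m <- fit_pca(X)
  S <- project_features(m, X)
  expect_equal(colSums(S), rep(0, ncol(S)), tolerance = 1e-10)
  U <- X / sqrt(rowSums(X^2))
  C <- sweep(U, 2, colMeans(U))
  expect_equal(S %*% t(S), C %*% t(C), tolerance = 1e-8)
  # a held-out copy of a training row projects identically
  expect_equal(project_features(m, X[3, , drop = FALSE]),
               S[3, , drop = FALSE])
})

test_that("PCA input contracts are enforced", {
  expect_error(fit_pca(matrix(1, 1, 10)), "at least 2")
  expect_error(fit_pca(matrix(c(NA, 1, 2, 3), 2, 2)), "non-finite")
  m <- fit_pca(matrix(rnorm(50), 5, 10))
  expect_error(project_features(m, matrix(0, 1, 9)), "mismatch")
})

# ---- PLS -----------------------------------------------------------------

test_that("first PLS direction is the dominant singular direction of X'y", {
  set.seed(4)
  X <- matrix(rnorm(8 * 30), 8, 30)
  y <- rep(c("stable", "converter"), each = 4)
  m <- fit_pls(X, y)
  Xc <- sweep(X, 2, colMeans(X))
  ynum <- ifelse(y == "converter", 1, -1)
  yc <- ynum - mean(ynum)
  sv <- svd(crossprod(Xc, matrix(yc)))
  w_oracle <- sv$u[, 1]
  w1 <- m$components[, 1]
  expect_lt(min(sum((w1 - w_oracle)^2), sum((w1 + w_oracle)^2)), 1e-16)
})

test_that("first PLS score maximizes covariance with the labels", {
  set.seed(5)
  X <- matrix(rnorm(10 * 25), 10, 25)
  y <- rep(c("stable", "converter"), 5)
  m <- fit_pls(X, y)
  ynum <- ifelse(y == "converter", 1, -1)
  best <- abs(cov(m$scores[, 1], ynum))
  for (i in 1:1000) {
    w <- rnorm(25); w <- w / sqrt(sum(w^2))
    expect_lte(abs(cov(as.numeric(X %*% w), ynum)), best + 1e-12)
  }
})

test_that("PLS reconstructs X = T P' + E with orthogonal residuals", {
  set.seed(6)
  X <- matrix(rnorm(9 * 20), 9, 20)
  y <- rep(c("stable", "converter", "stable"), each = 3)
  m <- fit_pls(X, y, k = 4)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(m$scores %*% t(m$P) + m$residual, Xc, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(m$scores, m$residual))), 1e-8)
})

test_that("PLS requires two classes and bounded component counts", {
  X <- matrix(rnorm(6 * 10), 6, 10)
  expect_error(fit_pls(X, rep("stable", 6)), "two classes")
  expect_error(fit_pls(X, rep(c("a", "b"), 3), k = 6), "rank")
})

# ---- ICA -----------------------------------------------------------------

test_that("ICA recovers independent uniform sources from mixtures", {
  set.seed(2)
  S <- cbind(runif(200, -1, 1), runif(200, -1, 1))
  A <- matrix(c(1, 2, 2, 1), 2, 2)
  X <- S %*% t(A)
  m <- fit_ica(X, 2, seed = 7)
  cors <- abs(cor(m$scores, S))
  # each true source matched by one component up to permutation and sign
  expect_gt(max(cors[, 1]), 0.95)
  expect_gt(max(cors[, 2]), 0.95)
  expect_equal(sort(apply(cors, 2, which.max)), 1:2)
})

test_that("ICA is deterministic given the seed and rejects k above rank", {
  set.seed(8)
  X <- matrix(rnorm(8 * 30), 8, 30)
  m1 <- fit_ica(X, 4, seed = 3)
  m2 <- fit_ica(X, 4, seed = 3)
  expect_identical(m1$components, m2$components)
  expect_error(fit_ica(X, 8, seed = 3), "n - 1")
  # rank deficiency below n - 1: duplicate rows
  Xd <- rbind(X[1:4, ], X[1:4, ], X[1, ])
  expect_error(fit_ica(Xd, 8, seed = 3), "rank")
})

test_that("ICA importance uses labels when provided", {
  set.seed(9)
  X <- matrix(rnorm(10 * 20), 10, 20)
  y <- rep(c("stable", "converter"), each = 5)
  m <- fit_ica(X, 3, seed = 1, y = y)
  expect_true(all(is.finite(m$importance)))
  expect_true(all(m$importance >= 0))
  m0 <- fit_ica(X, 3, seed = 1)
  expect_true(all(is.na(m0$importance)))
  expect_error(select_components(m0), "importance")
})

# ---- Fisher discriminant ratio ------------------------------------------

test_that("fisher_ratio matches direct arithmetic and its invariances", {
  y <- rep(c("a", "b"), each = 3)
  x <- c(-1, 0, 1, 1, 2, 3)
  expect_equal(fisher_ratio(x, y), 2.0)
  expect_equal(fisher_ratio(c(1, 2, 3, 1, 2, 3), y), 0)
  expect_equal(fisher_ratio(x + 17, y), 2.0)
  expect_equal(fisher_ratio(x * -3.5, y), 2.0)
  expect_equal(fisher_ratio(rep(2, 6), y), 0)
  expect_warning(r <- fisher_ratio(c(1, 1, 1, 2, 2, 2), y), "Inf")
  expect_identical(r, Inf)
  expect_error(fisher_ratio(x, rep("a", 6)), "two classes")
})

# ---- component selection -------------------------------------------------

test_that("cumulative-importance selection follows the threshold rule", {
  mk <- function(imp) structure(list(method = "pls", importance = imp,
                                     components = diag(length(imp))),
                                class = "reduction_model")
  r85 <- selection_rule("cumulative_fdr", 0.85)
  expect_identical(select_components(mk(c(8, 1, 1)), r85)$selected, 1:2)
  expect_identical(
    select_components(mk(c(3, 1)),
                      selection_rule("cumulative_variance", 0.75))$selected,
    1L)
  expect_identical(select_components(mk(c(1, 1, 1, 1)), r85)$selected, 1:4)
  expect_error(select_components(mk(c(0, 0)), r85), "all-zero")
})

test_that("selection is monotone in the threshold and order-stable", {
  set.seed(10)
  imp <- runif(12)
  mk <- function(imp) structure(list(method = "pca", importance = imp,
                                     components = diag(length(imp))),
                                class = "reduction_model")
  sizes <- vapply(seq(0.05, 1, by = 0.05), function(th)
    length(select_components(mk(imp),
                             selection_rule("cumulative_variance",
                                            th))$selected),
    integer(1))
  expect_true(all(diff(sizes) >= 0))
  # permuting component order leaves the selected set unchanged
  perm <- sample(12)
  s1 <- select_components(mk(imp), selection_rule("cumulative_variance",
                                                  0.6))$selected
  s2 <- select_components(mk(imp[perm]),
                          selection_rule("cumulative_variance",
                                         0.6))$selected
  expect_setequal(perm[s2], s1)
})

test_that("default thresholds are 75% variance and 85% FDR", {
  expect_equal(selection_rule("cumulative_variance")$threshold, 0.75)
  expect_equal(selection_rule("cumulative_fdr")$threshold, 0.85)
  expect_error(selection_rule("cumulative_fdr", 1.2), "\\(0, 1\\]")
})

# ---- serialization -------------------------------------------------------

test_that("fitted models survive a JSON round trip", {
  set.seed(11)
  X <- matrix(rnorm(6 * 15), 6, 15)
  m <- select_components(fit_pca(X))
  path <- withr::local_tempfile(fileext = ".json")
  write_reduction_model(m, path)
  back <- read_reduction_model(path)
  expect_equal(back$components, m$components)
  expect_equal(project_features(back, X), project_features(m, X))
})
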