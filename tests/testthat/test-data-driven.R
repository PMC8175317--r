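# Construction helpers: feature matrices with known informative structure.
make_planted <- function(n = 200, p_noise = 30, seed = 1, jitter = 0.01) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * p_noise), n, p_noise,
              dimnames = list(NULL, sprintf("noise%02d", seq_len(p_noise))))
  X <- cbind(X, signal = y + rnorm(n, sd = jitter))
  list(X = X, y = y)
}

test_that("a region that copies the label dominates the importance ranking", {
  for (seed in 1:5) {
    d <- make_planted(seed = seed)
    imp <- cv_feature_importance(d$X, d$y, n_folds = 5, n_trees = 150,
                                 seed = seed)
    expect_equal(imp$importance$label[1], "signal", label = paste("seed", seed))
  }
})

test_that("importances are normalized, non-negative, and seed-deterministic", {
  d <- make_planted(seed = 3)
  a <- cv_feature_importance(d$X, d$y, n_folds = 5, n_trees = 100, seed = 7)
  b <- cv_feature_importance(d$X, d$y, n_folds = 5, n_trees = 100, seed = 7)
  expect_identical(a, b)
  expect_equal(sum(a$importance$mean_importance), 1, tolerance = 1e-6)
  expect_true(all(a$importance$mean_importance >= 0))
  expect_true(all(a$importance$sd_importance >= 0))
})

test_that("pure-noise features yield a flat importance profile", {
  set.seed(11)
  n <- 400
  X <- matrix(rnorm(n * 31), n, 31,
              dimnames = list(NULL, sprintf("r%02d", 1:31)))
  y <- rep(c(0, 1), each = n / 2)
  imp <- cv_feature_importance(X, y, n_folds = 5, n_trees = 150, seed = 11)
  m <- imp$importance$mean_importance
  expect_lt(max(m), 3 * median(m))
})

test_that("importance rejects degenerate inputs", {
  d <- make_planted(n = 60, p_noise = 5)
  expect_error(cv_feature_importance(d$X, rep(1, 60), n_folds = 5), "two classes")
  Xc <- matrix(1, 60, 4, dimnames = list(NULL, paste0("c", 1:4)))
  expect_error(cv_feature_importance(Xc, d$y, n_folds = 5), "constant")
})

test_that("feature clustering reflects the correlation structure", {
  set.seed(21)
  n <- 150
  base <- rnorm(n)
  X <- cbind(a = base, b = 2.5 * base + 3,        # r = 1 -> height ~ 0
             c = -base)                           # r = -1 vs a/b -> distance 2
  dend <- cluster_features(X)
  h <- dend$hclust
  expect_lt(h$height[1], 1e-9)
  expect_setequal(h$labels[-h$merge[1, ]], c("a", "b"))
  # the negated copy joins last, at the maximal distance 2
  expect_equal(tail(h$height, 1), 2, tolerance = 1e-9)
  Xz <- cbind(X, f = rep(1, n))
  expect_error(cluster_features(Xz), "f")
})

test_that("cutting at k = 2 recovers a planted two-block structure", {
  set.seed(22)
  n <- 300
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f) f * sqrt(0.9) + rnorm(n, sd = sqrt(0.1))
  X <- cbind(b1x = mk(f1), b1y = mk(f1), b1z = mk(f1),
             b2x = mk(f2), b2y = mk(f2))
  dend <- cluster_features(X)
  cl <- stats::cutree(dend$hclust, k = 2)
  expect_equal(length(unique(cl[c("b1x", "b1y", "b1z")])), 1L)
  expect_equal(length(unique(cl[c("b2x", "b2y")])), 1L)
  expect_false(cl[["b1x"]] == cl[["b2x"]])
})

test_that("representative selection keeps the informative region at every k", {
  d <- make_planted(n = 200, p_noise = 12, seed = 5)
  imp <- cv_feature_importance(d$X, d$y, n_folds = 5, n_trees = 150, seed = 5)
  dend <- cluster_features(d$X)
  sel <- select_representatives(dend, imp, d$X, d$y, K_max = 5,
                                n_folds = 5, seed = 5)
  for (k in seq_len(5)) {
    expect_true("signal" %in% sel$trace$representatives[[k]],
                label = paste("k =", k))
    expect_length(sel$trace$representatives[[k]], k)
  }
  expect_true("signal" %in% sel$selected)
  expect_true(all(sel$trace$score >= 0 & sel$trace$score <= 1))
  expect_error(select_representatives(dend, imp, d$X, d$y, K_max = 99),
               "K_max")
})

test_that("two redundant informative blocks yield one representative each at k = 2", {
  set.seed(23)
  n <- 240
  y <- rep(c(0, 1), each = n / 2)
  s1 <- y + rnorm(n, sd = 0.4); s2 <- y + rnorm(n, sd = 0.4)
  mk <- function(f) f + rnorm(n, sd = 0.15)
  X <- cbind(a1 = mk(s1), a2 = mk(s1), a3 = mk(s1),
             c1 = mk(s2), c2 = mk(s2))
  imp <- cv_feature_importance(X, y, n_folds = 5, n_trees = 150, seed = 23)
  dend <- cluster_features(X)
  sel <- select_representatives(dend, imp, X, y, K_max = 3, n_folds = 5, seed = 23)
  reps2 <- sel$trace$representatives[[2]]
  expect_length(reps2, 2)
  expect_equal(sum(reps2 %in% c("a1", "a2", "a3")), 1)
  expect_equal(sum(reps2 %in% c("c1", "c2")), 1)
})

test_that("outputs are invariant to permuting subject order", {
  d <- make_planted(n = 120, p_noise = 8, seed = 6)
  set.seed(99)
  perm <- sample(nrow(d$X))
  a <- cv_feature_importance(d$X, d$y, n_folds = 5, n_trees = 100, seed = 4)
  b <- cv_feature_importance(d$X[perm, ], d$y[perm], n_folds = 5,
                             n_trees = 100, seed = 4)
  expect_identical(a, b)
  dend <- cluster_features(d$X)
  sa <- select_representatives(dend, a, d$X, d$y, K_max = 3, n_folds = 5, seed = 4)
  sb <- select_representatives(cluster_features(d$X[perm, ]), b,
                               d$X[perm, ], d$y[perm], K_max = 3,
                               n_folds = 5, seed = 4)
  expect_equal(sa$selected, sb$selected)
  expect_equal(sa$trace$score, sb$trace$score, tolerance = 1e-12)
})

test_that("pure-noise composites score near chance in cross-validated AUC", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 400
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, sprintf("r%02d", 1:10)))
    y <- rep(c(0, 1), each = n / 2)
    dd <- derive_data_driven_roi(X, y, K_max = 3, n_folds = 5,
                                 n_trees = 100, seed = seed)
    k <- dd$selection$chosen_k
    expect_gte(dd$selection$trace$score[k], 0.4)
    expect_lte(dd$selection$trace$score[k], 0.6)
  }
})
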