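test_that("feature distance: hand values, symmetry, identity, dimension check", {
  expect_equal(feature_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(feature_distance(c(0, 0), c(2, 0)), 2)
  expect_equal(feature_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), 0.5)
  set.seed(1)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(feature_distance(a, b), feature_distance(b, a))
  expect_error(feature_distance(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("intra-class loss: hand value, degenerate sizes, pairwise-mean oracle", {
  expect_equal(intra_class_loss(rbind(c(0, 0), c(2, 0))), 2)
  expect_equal(intra_class_loss(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  expect_equal(intra_class_loss(matrix(rnorm(4), 1)), 0)  # |S| < 2
  set.seed(2)
  S <- matrix(rnorm(24), 6, 4)
  expect_equal(intra_class_loss(S), oracle_intra(S), tolerance = 1e-9)
})

test_that("inter-class loss: margin saturation, coincident singletons, oracle", {
  far <- rbind(c(10, 0)); near <- rbind(c(0, 0))
  expect_equal(inter_class_loss(far, near, margin = 0.1), 0)
  expect_equal(inter_class_loss(rbind(c(0, 0)), rbind(c(0, 0)), margin = 0.1), 0.1)
  set.seed(3)
  Sp <- matrix(rnorm(12, sd = 0.2), 3, 4)
  Sq <- matrix(rnorm(20, sd = 0.2), 5, 4)
  expect_equal(inter_class_loss(Sp, Sq, 0.3), oracle_inter(Sp, Sq, 0.3),
               tolerance = 1e-9)
})

test_that("metric loss: single class, double-counted pair hand value, oracle", {
  cfg <- loss_config(lambda = 0.1, margin = 0.1)
  one_class <- matrix(1, 3, 2)
  expect_equal(metric_loss(one_class, c(1, 1, 1), cfg), 0)
  # two coincident singleton classes: 0 intra; the inter pair enters twice
  R <- rbind(c(0, 0), c(0, 0))
  expect_equal(metric_loss(R, c(1, 2), cfg), 0.02)
  set.seed(4)
  R <- matrix(rnorm(20 * 8, sd = 0.3), 20, 8)
  labels <- rep(1:4, each = 5)
  expect_equal(metric_loss(R, labels, cfg),
               oracle_metric(R, labels, 0.1, 0.1), tolerance = 1e-9)
})

test_that("metric loss is invariant to within-class permutation and relabeling", {
  set.seed(5)
  R <- matrix(rnorm(12 * 4, sd = 0.3), 12, 4)
  labels <- sample(1:3, 12, replace = TRUE)
  cfg <- loss_config()
  base <- metric_loss(R, labels, cfg)
  perm <- sample(12)
  expect_equal(metric_loss(R[perm, ], labels[perm], cfg), base, tolerance = 1e-12)
  relabel <- c(7L, 2L, 9L)[labels]
  expect_equal(metric_loss(R, relabel, cfg), base, tolerance = 1e-12)
})

test_that("cross-entropy and focal losses: hand values and reductions", {
  expect_equal(cross_entropy_loss(c(1, 0), 1), 0)
  expect_equal(cross_entropy_loss(c(0.5, 0.5), 1), log(2))
  expect_equal(focal_loss(c(1, 0), 1, gamma = 3), 0)
  expect_equal(focal_loss(c(0.5, 0.5), 1, gamma = 0), log(2))
  expect_equal(focal_loss(c(0.5, 0.5), 1, gamma = 2), 0.25 * log(2))
})

test_that("batch focal loss is the mean of per-sample values", {
  set.seed(6)
  P <- random_prob_matrix(40, 5)
  y <- sample(1:5, 40, replace = TRUE)
  for (g in c(0, 1, 2)) {
    expect_equal(focal_loss(P, y, g), oracle_focal(P, y, g), tolerance = 1e-9)
    per_sample <- vapply(1:40, function(s) focal_loss(P[s, ], y[s], g), numeric(1))
    expect_equal(focal_loss(P, y, g), mean(per_sample), tolerance = 1e-12)
  }
})

test_that("focal loss never exceeds cross-entropy and decreases in p_t", {
  set.seed(7)
  P <- random_prob_matrix(200, 6)
  y <- sample(1:6, 200, replace = TRUE)
  for (g in c(0.5, 1, 2, 5)) {
    per_focal <- vapply(1:200, function(s) focal_loss(P[s, ], y[s], g), numeric(1))
    per_ce <- vapply(1:200, function(s) cross_entropy_loss(P[s, ], y[s]), numeric(1))
    expect_true(all(per_focal <= per_ce + 1e-12))
  }
  pt <- seq(0.01, 0.99, by = 0.01)
  vals <- -(1 - pt)^2 * log(pt)
  fl <- vapply(pt, function(q) focal_loss(c(q, 1 - q), 1, 2), numeric(1))
  expect_equal(fl, vals, tolerance = 1e-12)
  expect_true(all(diff(fl) <= 1e-12))  # non-increasing in p_t
})

test_that("combined loss decomposes into focal plus mu * metric", {
  set.seed(8)
  P <- random_prob_matrix(15, 4)
  y <- sample(1:4, 15, replace = TRUE)
  R <- matrix(rnorm(15 * 6, sd = 0.3), 15, 6)
  cfg <- loss_config(gamma = 2, lambda = 0.1, mu = 0.7, margin = 0.1)
  expect_equal(combined_loss(P, y, R, y, cfg),
               focal_loss(P, y, 2) + 0.7 * oracle_metric(R, y, 0.1, 0.1),
               tolerance = 1e-9)
  cfg0 <- loss_config(gamma = 2, mu = 0)
  expect_equal(combined_loss(P, y, R, y, cfg0), focal_loss(P, y, 2),
               tolerance = 1e-12)
  # both terms zero: perfect prediction, one tight class per batch
  Pp <- diag(4)[c(1, 1, 2, 2), ]
  Rp <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(combined_loss(Pp, c(1, 1, 2, 2), Rp, config = loss_config()), 0)
})

test_that("metric gradient matches numerical differentiation", {
  set.seed(9)
  R <- matrix(rnorm(10 * 5, sd = 0.25), 10, 5)
  labels <- sample(1:3, 10, replace = TRUE)
  cfg <- loss_config(gamma = 2, lambda = 0.1, mu = 0.8, margin = 0.15)
  g <- critens:::metric_loss_grad(R, labels, cfg)
  eps <- 1e-6
  for (i in sample(length(R), 20)) {
    Rp <- R; Rp[i] <- Rp[i] + eps
    Rm <- R; Rm[i] <- Rm[i] - eps
    num <- cfg$mu * (metric_loss(Rp, labels, cfg) - metric_loss(Rm, labels, cfg)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})
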