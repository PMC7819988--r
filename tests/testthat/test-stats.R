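make_fm <- function(y, group = NULL, age = NULL) {
  n <- ncol(y)
  if (is.null(group)) group <- rep(c("control", "patient"), each = n / 2)
  if (is.null(age)) age <- seq(20, 40, length.out = n)
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                        group = group, age = age, stringsAsFactors = FALSE)
  rownames(y) <- sprintf("f%03d", seq_len(nrow(y)))
  colnames(y) <- samples$sample_id
  msimetab:::new_msi_features(
    y, data.frame(feature_id = rownames(y), stringsAsFactors = FALSE),
    samples, logged = TRUE)
}

test_that("log transform is the natural log and validates positivity", {
  y <- matrix(c(exp(1), 1, 4, 9), 2, 2)
  fm <- make_fm(y, group = c("control", "patient"), age = c(30, 5))
  fm$logged <- FALSE
  lfm <- log_transform(fm)
  expect_equal(lfm$intensity[1, 1], 1)
  expect_equal(lfm$intensity[2, 1], 0)
  expect_true(lfm$logged)
  expect_error(log_transform(lfm), "already")
  fm$intensity[2, 2] <- 0
  expect_error(log_transform(fm), "f002.*S02")
})

test_that("BY adjustment matches hand-computed and formulaic oracles", {
  # hand computation: BH gives (0.03, 0.03, 0.04); times c(3) = 11/6
  p <- c(0.01, 0.02, 0.04)
  expect_equal(adjust_fdr(p, "BY"), 11 / 6 * c(0.03, 0.03, 0.04),
               tolerance = 1e-12)
  expect_equal(adjust_fdr(0.05, "BY"), 0.05) # c(1) = 1
  expect_equal(adjust_fdr(rep(1, 5), "BY"), rep(1, 5))
  # independently coded step-up formula on random vectors
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_fdr(p, "BY"), step_up_adjust(p, "BY"),
                 tolerance = 1e-12)
    expect_equal(adjust_fdr(p, "BH"), step_up_adjust(p, "BH"),
                 tolerance = 1e-12)
    # BY dominates BH pointwise and both dominate the raw p
    expect_true(all(adjust_fdr(p, "BY") >= adjust_fdr(p, "BH") - 1e-12))
    expect_true(all(adjust_fdr(p, "BY") >= p - 1e-12))
  }
  expect_error(adjust_fdr(c(0.1, 1.2)), "domain error")
})

test_that("missing p-values propagate and are excluded from the family", {
  p <- c(0.01, NA, 0.02, 0.04)
  adj <- adjust_fdr(p, "BY")
  expect_true(is.na(adj[2]))
  expect_equal(adj[-2], adjust_fdr(p[-2], "BY"))
})

test_that("a feature with equal group means has estimate 0 and p near 1", {
  y <- rbind(c(1, 2, 3, 1, 2, 3))
  fm <- make_fm(y, group = rep(c("control", "patient"), each = 3),
                age = rep(c(30, 35, 40), 2))
  res <- differential_test(fm, age = NULL)
  expect_equal(res$estimate, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-9)
})

test_that("without the covariate the test equals a pooled two-sample t-test", {
  set.seed(14)
  y <- matrix(rnorm(50 * 18), 50, 18)
  g <- rep(c("control", "patient"), each = 9)
  fm <- make_fm(y, group = g)
  res <- differential_test(fm, age = NULL)
  for (i in c(1, 17, 50)) {
    tt <- t.test(y[i, g == "patient"], y[i, g == "control"], var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-9)
    expect_equal(res$estimate[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-9)
  }
})

test_that("the age-adjusted test has nominal type-I error", {
  set.seed(15)
  n_feat <- 2000
  y <- matrix(rnorm(n_feat * 18), n_feat, 18)
  age <- c(rnorm(9, 5.5, 1.9), rnorm(9, 5.5, 1.9))
  fm <- make_fm(y, age = age)
  res <- differential_test(fm)
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  ci <- 2 * sqrt(0.05 * 0.95 / n_feat)
  expect_gt(rate, 0.05 - ci)
  expect_lt(rate, 0.05 + ci)
})

test_that("a 2-SD effect at n = 9/9 is detected with power above 0.8", {
  set.seed(16)
  n_feat <- 400
  y <- matrix(rnorm(n_feat * 18), n_feat, 18)
  g <- rep(c("control", "patient"), each = 9)
  y[, g == "patient"] <- y[, g == "patient"] + 2  # 2-SD shift, unit SD
  fm <- make_fm(y, age = rnorm(18, 5.5, 1.9))
  res <- differential_test(fm)
  expect_gte(mean(res$significant), 0.8)
  expect_true(all(res$direction[res$significant] == "up"))
})

test_that("BY keeps the realized false-discovery proportion controlled", {
  set.seed(17)
  fdps <- vapply(1:50, function(r) {
    y <- matrix(rnorm(60 * 18), 60, 18)
    true <- seq_len(34)
    y[true, 10:18] <- y[true, 10:18] + 2
    fm <- make_fm(y, age = rnorm(18, 30, 5))
    res <- differential_test(fm)
    sig <- which(res$significant)
    if (!length(sig)) return(0)
    sum(!(sig %in% true)) / length(sig)
  }, numeric(1))
  expect_lte(mean(fdps), 0.05 + 0.03)
})

test_that("group effect estimates of planted features are unbiased", {
  set.seed(18)
  ests <- vapply(1:40, function(r) {
    y <- matrix(rnorm(5 * 18, sd = 0.4), 5, 18)
    y[1, 10:18] <- y[1, 10:18] + 0.8
    fm <- make_fm(y, age = rnorm(18, 30, 5))
    differential_test(fm)$estimate[1]
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.8), 2 * se + 0.02)
})

test_that("degenerate designs and zero-variance features are flagged", {
  y <- matrix(1, 2, 18) # zero residual variance
  y[2, ] <- rnorm(18)
  fm <- make_fm(y)
  res <- differential_test(fm)
  expect_true(res$singular[1])
  expect_true(is.na(res$p[1]))
  expect_false(res$singular[2])
  expect_error(differential_test(fm, group = rep("patient", 18)), "two groups")
})

test_that("Spearman correlation matches the direct rank formula", {
  set.seed(19)
  # 5-sample instances against the explicit rank-based computation
  for (i in 1:25) {
    y <- matrix(sample(1:10, 15, replace = TRUE), 3, 5) # ties included
    rho <- spearman_matrix(y)
    for (a in 1:3) for (b in 1:3) {
      if (a == b) next
      expect_equal(rho[a, b], brute_force_spearman(y[a, ], y[b, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("Spearman handles self, monotone and degenerate features", {
  y <- rbind(a = c(1, 2, 3, 4), b = c(8, 6, 4, 2), c = c(5, 5, 5, 5))
  rho <- spearman_matrix(y)
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))
  expect_equal(rho["a", "b"], -1)
  expect_true(is.na(rho["a", "c"]))
  expect_equal(rho, t(rho))
  expect_error(spearman_matrix(y[, 1:2]), "3 samples")
  # independent features: correlations concentrate near zero
  set.seed(20)
  yy <- matrix(rnorm(30 * 18), 30, 18)
  rr <- spearman_matrix(yy)
  expect_lt(mean(abs(rr[upper.tri(rr)])), 0.3)
})

test_that("well-separated groups cluster perfectly at k = 2", {
  set.seed(21)
  y <- matrix(rnorm(20 * 18, sd = 0.3), 20, 18)
  y[, 10:18] <- y[, 10:18] + 3
  fm <- make_fm(y)
  cl <- cluster_samples(fm)
  expect_equal(adjusted_rand_index(cl$labels, fm$samples$group), 1)
  # deterministic under peak/sample permutations: same partition
  fm2 <- fm
  ord <- c(5, 1, 18, 3:4, 2, 6:17)
  fm2$intensity <- fm2$intensity[, ord]
  fm2$samples <- fm2$samples[ord, ]
  cl2 <- cluster_samples(fm2)
  expect_equal(cl2$labels[names(cl$labels)], cl$labels)
})

test_that("duplicate samples and constant features merge at height zero", {
  y <- cbind(A = c(1, 2), B = c(1, 2), C = c(5, 6))
  samples <- data.frame(sample_id = c("A", "B", "C"),
                        group = c("control", "control", "patient"),
                        age = c(1, 2, 3), stringsAsFactors = FALSE)
  fm <- msimetab:::new_msi_features(
    y, data.frame(feature_id = c("f1", "f2")), samples, logged = TRUE)
  cl <- cluster_samples(fm)
  expect_equal(min(cl$hclust$height), 0)
  y2 <- matrix(1, 1, 3, dimnames = list("f1", c("A", "B", "C")))
  fm2 <- msimetab:::new_msi_features(
    y2, data.frame(feature_id = "f1"), samples, logged = TRUE)
  expect_true(all(cluster_samples(fm2)$hclust$height == 0))
  fm3 <- fm; fm3$intensity <- y[, 1, drop = FALSE]; fm3$samples <- samples[1, ]
  expect_error(cluster_samples(fm3), "2 samples")
})

test_that("the clustering tree exports as readable Newick", {
  set.seed(22)
  y <- matrix(rnorm(5 * 6), 5, 6)
  fm <- make_fm(y, group = rep(c("control", "patient"), each = 3),
                age = 1:6)
  cl <- cluster_samples(fm)
  path <- tempfile(fileext = ".nwk")
  write_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, fm$samples$sample_id)
})

test_that("the adjusted Rand index agrees with an established implementation", {
  set.seed(23)
  for (i in 1:20) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:4, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})
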