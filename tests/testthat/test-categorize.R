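# Standardization, PCA with sign alignment, k-means scan, cluster-count
# diagnostics, and AIC adjudication.

fake_features <- function(X, prefix = "f") {
  d <- tibble::as_tibble(as.data.frame(X), .name_repair = ~paste0(prefix, seq_along(.x)))
  d$subject <- sprintf("S%04d", seq_len(nrow(d)))
  d
}

test_that("standardization yields exact z-scores and keeps the scaler", {
  X <- withr::with_seed(1, matrix(rnorm(60, 5, 3), 20, 3))
  d <- fake_features(X)
  zm <- standardize_features(d, c("f1", "f2", "f3"))
  expect_lt(max(abs(colMeans(zm$z))), 1e-9)
  expect_lt(max(abs(apply(zm$z, 2, sd) - 1)), 1e-9)
  expect_equal(unname(zm$z[, 1]), unname((X[, 1] - mean(X[, 1])) / sd(X[, 1])))
  expect_equal(unname(zm$scaler$mean), unname(colMeans(X)))

  dup <- fake_features(matrix(rep(c(1, 2, 3), each = 4), 4, 3))
  expect_error(standardize_features(dup, c("f1", "f2", "f3")), "zero-variance")
})

test_that("PCA explained variances match an independent eigen-decomposition", {
  X <- withr::with_seed(2, {
    z1 <- rnorm(50); z2 <- rnorm(50)
    cbind(z1, z1 + 0.3 * z2, z2, rnorm(50), z1 - z2)
  })
  d <- fake_features(X)
  zm <- standardize_features(d, paste0("f", 1:5))
  pca <- run_pca(zm, anchor = "f1")
  ev_oracle <- eigen(stats::cor(X), symmetric = TRUE)$values
  expect_equal(pca$explained_variance_pct,
               100 * ev_oracle / sum(ev_oracle), tolerance = 1e-8)
  expect_equal(sum(pca$explained_variance_pct), 100)
  # full-rank reconstruction: scores %*% t(loadings) recovers z
  expect_lt(norm(pca$scores %*% t(pca$loadings) - zm$z, "F") / norm(zm$z, "F"),
            1e-8)
})

test_that("two perfectly correlated variables put 100% on PC1", {
  x <- withr::with_seed(3, rnorm(30))
  d <- fake_features(cbind(x, 2 * x + 5))
  zm <- standardize_features(d, c("f1", "f2"))
  pca <- run_pca(zm, anchor = "f1")
  expect_equal(pca$explained_variance_pct[1], 100, tolerance = 1e-9)
})

test_that("isotropic noise spreads variance evenly across components", {
  d <- fake_features(withr::with_seed(4, matrix(rnorm(10000 * 5), 10000, 5)))
  pca <- run_pca(standardize_features(d, paste0("f", 1:5)), anchor = "f1")
  expect_true(all(abs(pca$explained_variance_pct - 20) < 2))
})

test_that("sign alignment anchors components positively and is idempotent", {
  d <- fake_features(withr::with_seed(5, matrix(rnorm(200), 40, 5)),
                     prefix = "v")
  names(d)[1] <- "preferred_time"
  zm <- standardize_features(d, c("preferred_time", paste0("v", 2:5)))
  pca <- run_pca(zm)
  expect_true(all(pca$loadings["preferred_time", ] >= 0))
  again <- align_signs(pca)
  expect_equal(again$loadings, pca$loadings)
  expect_equal(again$scores, pca$scores)
  # flipping a column by hand is undone by alignment, scores included
  flipped <- pca
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  flipped$scores[, 1] <- -flipped$scores[, 1]
  expect_equal(align_signs(flipped)$loadings, pca$loadings)
  expect_equal(align_signs(flipped)$scores, pca$scores)
  # alignment never changes explained variance
  expect_equal(align_signs(flipped)$explained_variance_pct,
               pca$explained_variance_pct)
  expect_warning(align_signs(pca, anchor = "absent"), "not present")
})

# well-separated mixture fixture: every coordinate separates the clusters,
# so the structure survives column-wise z-scoring
blob_features <- function(n_per = 30, sep = 10, k = 3, p = 4, seed = 6L) {
  coh <- simulate_cluster_cohort(n = n_per * k, k = k, p = p,
                                 separation = sep, seed = seed)
  list(features = coh, label = coh$label)
}

test_that("k-means scan has the definitional endpoints and monotone WSS", {
  d <- fake_features(withr::with_seed(7, matrix(rnorm(15 * 3), 15, 3)))
  zm <- standardize_features(d, paste0("f", 1:3))
  scan <- kmeans_scan(zm, k_range = c(1:5, 15), seed = 1L, n_init = 10)
  expect_equal(scan$variance_explained_pct[scan$k == 1], 0)
  expect_equal(scan$wss[scan$k == 1], sum(zm$z^2))  # WSS(1) = TSS
  expect_equal(scan$variance_explained_pct[scan$k == 15], 100)
  expect_true(is.na(scan$aic[scan$k == 15]))
  ec <- elbow_curve(scan)
  expect_true(all(diff(ec$wss) <= 1e-8))
  expect_equal(ec$wss[ec$k == 15], 0)
})

test_that("well-separated blobs are recovered with high silhouette and a sharp elbow", {
  b <- blob_features(sep = 10, k = 3)
  zm <- standardize_features(b$features, paste0("f", 1:4))
  scan <- kmeans_scan(zm, k_range = 1:6, seed = 2L, n_init = 10)
  k3 <- which(scan$k == 3)
  expect_equal(label_recovery_accuracy(b$label, scan$assignments[[k3]]), 1)
  expect_gt(scan$silhouette[k3], 0.8)
  # elbow: the WSS drop into k=3 dwarfs the drop beyond it
  drops <- -diff(scan$wss)
  expect_gt(drops[2] / drops[3], 5)
  # and the scan is deterministic given the seed
  scan2 <- kmeans_scan(zm, k_range = 1:6, seed = 2L, n_init = 10)
  expect_identical(tidy(scan), tidy(scan2))
})

test_that("silhouette separates structure from arbitrary splits", {
  # two blobs 20 within-cluster SDs apart, measured in the blobs' own space
  X <- withr::with_seed(8, cbind(c(rnorm(40), rnorm(40, mean = 20))))
  expect_gt(silhouette_statistic(X, rep(1:2, each = 40)), 0.9)

  cloud <- fake_features(withr::with_seed(9, matrix(runif(200 * 2), 200, 2)))
  zc <- standardize_features(cloud, c("f1", "f2"))
  split <- kmeans_scan(zc, k_range = 2, seed = 3L, n_init = 10)
  expect_lt(split$silhouette[1], 0.5)
  expect_true(abs(split$silhouette[1]) <= 1)
})

test_that("gap statistic finds the true k on blobs and k = 1 on a single cloud", {
  b <- blob_features(sep = 10, k = 3, n_per = 25)
  zm <- standardize_features(b$features, paste0("f", 1:4))
  gap <- gap_statistic(zm, k_max = 6, B = 50, seed = 4L, n_init = 5)
  expect_equal(gap$suggested_k, 3)
  gap2 <- gap_statistic(zm, k_max = 6, B = 50, seed = 4L, n_init = 5)
  expect_identical(gap$table, gap2$table)

  cloud <- fake_features(withr::with_seed(10, matrix(rnorm(80 * 3), 80, 3)))
  zc <- standardize_features(cloud, paste0("f", 1:3))
  gap_null <- gap_statistic(zc, k_max = 5, B = 50, seed = 5L, n_init = 5)
  expect_equal(gap_null$suggested_k, 1)
})

test_that("cluster variance explained matches a hand decomposition", {
  # six points, two obvious clusters on one axis
  z <- cbind(c(-2, -2.5, -1.5, 2, 2.5, 1.5), c(0.2, -0.2, 0, 0.1, -0.1, 0))
  assign <- c(1, 1, 1, 2, 2, 2)
  ssw <- sum((z[1:3, 1] - mean(z[1:3, 1]))^2) + sum((z[4:6, 1] - mean(z[4:6, 1]))^2) +
    sum((z[1:3, 2] - mean(z[1:3, 2]))^2) + sum((z[4:6, 2] - mean(z[4:6, 2]))^2)
  sst <- sum(sweep(z, 2, colMeans(z))^2)
  expect_equal(cluster_variance_explained(z, assign), 100 * (1 - ssw / sst))
  expect_equal(cluster_variance_explained(z, rep(1, 6)), 0)
  expect_equal(cluster_variance_explained(z, 1:6), 100)
})

test_that("cluster AIC pays exactly 2p for a redundant split and tracks WSS", {
  z <- withr::with_seed(11, matrix(rnorm(40), 10, 4))
  z <- rbind(z, matrix(5, 4, 4))  # four identical points in their own cluster
  a1 <- c(rep(1, 10), rep(2, 4))
  a2 <- c(rep(1, 10), c(2, 3, 2, 3))  # split the identical cluster: WSS unchanged
  expect_equal(cluster_aic(z, a2) - cluster_aic(z, a1), 2 * ncol(z))

  b <- blob_features(sep = 6, k = 3, seed = 12L)
  zb <- standardize_features(b$features, paste0("f", 1:4))$z
  better <- kmeans(zb, 3, nstart = 20)
  worse <- list(cluster = withr::with_seed(13L, sample(rep(1:3, length.out = nrow(zb)))))
  expect_lt(cluster_aic(zb, better$cluster), cluster_aic(zb, worse$cluster))

  # five true clusters at the top of the candidate grid: AIC bottoms at k* = 5
  b5 <- blob_features(n_per = 40, sep = 3, k = 5, p = 5, seed = 14L)
  scan <- kmeans_scan(standardize_features(b5$features, paste0("f", 1:5)),
                      k_range = 2:5, seed = 6L, n_init = 10)
  expect_equal(scan$k[which.min(scan$aic)], 5)
})

test_that("adjudication populates the full grid and picks the AIC minimum", {
  feats <- small_cohort_features()
  adj <- adjudicate_clusters(feats, seed = 9L, n_init = 10)
  expect_equal(nrow(adj$grid), 16)  # 4 sets x 4 k
  expect_true(all(!is.na(adj$grid$aic)))
  best <- adj$grid[which.min(adj$grid$aic), ]
  expect_equal(adj$chosen$set, best$set)
  expect_equal(adj$chosen$k, best$k)
  # variance explained non-decreasing in k within each set
  for (s in unique(adj$grid$set)) {
    g <- adj$grid[adj$grid$set == s, ]
    expect_true(all(diff(g$variance_explained_pct[order(g$k)]) >= -1e-8))
  }
  asg <- cluster_assignments(adj)
  n_complete <- sum(stats::complete.cases(feats[, variable_sets()[[adj$chosen$set]]]))
  expect_equal(nrow(asg), n_complete)
  expect_true(all(asg$cluster %in% seq_len(adj$chosen$k)))
})
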