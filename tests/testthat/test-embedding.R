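test_that("centered MCP matrices have rank at most n - 1", {
  E <- random_expression(10, 5, seed = 31)
  T <- mcp_matrix(E)
  p <- pca_mcp(T, 4)
  rel <- p$sdev / p$sdev[1]
  expect_true(all(rel[5:length(rel)] < 1e-8))
  expect_error(pca_mcp(T, 5), "rank")
  expect_error(pca_mcp(T, 0), "rank|k must")
})

test_that("full-rank scores preserve pairwise distances of centered MCPs", {
  E <- random_expression(9, 4, seed = 32)
  T <- mcp_matrix(E)
  p <- pca_mcp(T, 3)
  centered <- scale(unclass(T), center = TRUE, scale = FALSE)
  expect_equal(as.numeric(dist(p$scores)), as.numeric(dist(centered)),
    tolerance = 1e-6
  )
  expect_true(all(diff(p$explained_variance) <= 1e-12))
})

test_that("pca scores match an independent eigendecomposition up to sign", {
  E <- random_expression(3, 4, seed = 33)
  T <- unclass(mcp_matrix(E))
  p <- pca_mcp(mcp_matrix(E), 2)
  C <- scale(T, center = TRUE, scale = FALSE)
  eig <- eigen(C %*% t(C), symmetric = TRUE) # m x m Gram trick, m = 3
  for (j in 1:2) {
    score_oracle <- eig$vectors[, j] * sqrt(eig$values[j])
    expect_equal(abs(unname(p$scores[, j])), abs(score_oracle), tolerance = 1e-8)
  }
})

test_that("pca scores are invariant (up to sign) to gene order", {
  E <- random_expression(12, 5, seed = 34)
  T1 <- mcp_matrix(E)
  perm <- c(5, 1, 12, 3, 8, 2, 11, 4, 10, 6, 9, 7)
  T2 <- mcp_matrix(E[perm, ])
  s1 <- pca_mcp(T1, 3)$scores
  s2 <- pca_mcp(T2, 3)$scores[order(perm), ]
  expect_equal(abs(unname(s1)), abs(unname(s2)), tolerance = 1e-8)
})

test_that("t-SNE keeps duplicate rows together and input order", {
  b <- simulate_blobs(m = 30, k = 2, separation = 5, seed = 41)
  P <- rbind(b$values, dup = b$values[1, ])
  e <- tsne_embed(P, perplexity = 5, max_iter = 500)
  expect_identical(dim(e$coords), c(31L, 2L))
  expect_identical(rownames(e$coords), rownames(P))
  d_to_twin <- sqrt(sum((e$coords[31, ] - e$coords[1, ])^2))
  others <- sqrt(rowSums((e$coords[2:30, , drop = FALSE] -
    matrix(e$coords[31, ], 29, 2, byrow = TRUE))^2))
  expect_lt(d_to_twin, min(others)) # twin is the nearest embedded point
})

test_that("t-SNE separates far-apart blobs and enforces the perplexity bound", {
  b <- simulate_blobs(m = 100, k = 2, separation = 6, seed = 42)
  e <- tsne_embed(b$values, perplexity = 10, max_iter = 500)
  expect_gt(average_silhouette(e, b$group), 0.5)
  expect_error(tsne_embed(b$values, perplexity = 50), "perplexity")
})

test_that("deterministic init makes embeddings reproducible and order-equivariant", {
  set.seed(43)
  X <- matrix(rnorm(40 * 6), 40)
  e1 <- tsne_embed(X, perplexity = 5, max_iter = 300, theta = 0)
  e2 <- tsne_embed(X, perplexity = 5, max_iter = 300, theta = 0)
  expect_identical(e1$coords, e2$coords)
  perm <- sample(40)
  e3 <- tsne_embed(X[perm, ], perplexity = 5, max_iter = 300, theta = 0)
  back <- e3$coords[order(perm), ]
  expect_equal(as.numeric(dist(back)), as.numeric(dist(e1$coords)),
    tolerance = 1e-4
  )
})

test_that("average silhouette matches brute force and the cluster package", {
  # 5-point fixture, checked against the literal per-point loops
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(10, 10), c(11, 10))
  labels <- c(1, 1, 1, 2, 2)
  expect_equal(average_silhouette(coords, labels), oracle_silhouette(coords, labels))
  set.seed(44)
  co2 <- matrix(rnorm(60), 30, 2)
  lab2 <- sample(3, 30, replace = TRUE)
  expect_equal(average_silhouette(co2, lab2), oracle_silhouette(co2, lab2))
  sil <- cluster::silhouette(lab2, dist(co2))
  expect_equal(average_silhouette(co2, lab2), mean(sil[, "sil_width"]),
    tolerance = 1e-12
  )
})

test_that("silhouette hits the extremes where it should", {
  set.seed(45)
  tight <- rbind(
    matrix(rnorm(40, 0, 0.01), 20, 2),
    matrix(rnorm(40, 100, 0.01), 20, 2)
  )
  expect_gt(average_silhouette(tight, rep(1:2, each = 20)), 0.99)
  blob <- matrix(rnorm(60), 30, 2)
  expect_lt(average_silhouette(blob, sample(2, 30, replace = TRUE)), 0.1)
  expect_error(average_silhouette(blob, rep(1, 30)), "two clusters")
})

test_that("singleton clusters contribute zero silhouette width", {
  coords <- rbind(c(0, 0), c(0.5, 0), c(9, 9))
  labels <- c(1, 1, 2)
  s12 <- vapply(1:2, function(i) {
    a <- sqrt(sum((coords[1, ] - coords[2, ])^2))
    b <- sqrt(sum((coords[i, ] - coords[3, ])^2))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(average_silhouette(coords, labels), mean(c(s12, 0)))
})

test_that("measure-space silhouette accepts a dissimilarity matrix directly", {
  E <- random_expression(20, 5, seed = 46)
  D <- pairwise_dissimilarity(E, "pcc-mcp")
  fit <- icc_cluster(D, 3)
  s <- average_silhouette(D, fit$labels, diss = TRUE)
  sil <- cluster::silhouette(fit$labels, as.dist(D))
  expect_equal(s, mean(sil[, "sil_width"]), tolerance = 1e-12)
})

test_that("map selection maximizes the silhouette over candidate k", {
  b <- simulate_blobs(m = 90, k = 3, separation = 5, seed = 47, n = 6)
  T <- mcp_matrix(b$values)
  D <- pairwise_dissimilarity(b$values, "pcc-mcp")
  fit <- icc_cluster(D, 3)
  sel <- select_tsne_mcp_o(T, fit$labels, ks = c(1, 2, 4), perplexity = 10,
    max_iter = 400)
  expect_identical(sel$candidates$k, c(1L, 2L, 4L))
  expect_identical(sel$chosen_k, sel$candidates$k[which.max(sel$candidates$S)])
  # reported S values are exactly the silhouette of each candidate map
  for (i in seq_len(3)) {
    expect_equal(sel$candidates$S[i],
      average_silhouette(sel$embeddings[[i]], fit$labels))
  }
  one <- select_tsne_mcp_o(T, fit$labels, ks = 2, perplexity = 10, max_iter = 400)
  expect_identical(one$chosen_k, 2L)
  expect_error(select_tsne_mcp_o(T, fit$labels, ks = 6, perplexity = 10), "1..n-1")
})

test_that("comparison maps embed normalized or centered profiles", {
  b <- simulate_blobs(m = 60, k = 2, separation = 5, seed = 48)
  e <- comparison_map(b$values, "tsne-n", perplexity = 10, max_iter = 400)
  expect_gt(average_silhouette(e, b$group), 0.2)
  centered <- b$values - rowMeans(b$values)
  e1 <- comparison_map(centered, "tsne-c", perplexity = 10, max_iter = 400)
  e2 <- tsne_embed(centered, perplexity = 10, max_iter = 400)
  expect_equal(e1$coords, e2$coords)
  flat <- b$values
  flat[3, ] <- 0
  expect_error(comparison_map(flat, "tsne-n"), "degenerate")
})

test_that("neighbor maps list the two closest genes, ties to the lower index", {
  D <- dist1d(c(0, 1, 3))
  nb <- neighbor_map(D)
  expect_identical(nb$nearest, c(2L, 1L, 2L))
  expect_identical(nb$second, c(3L, 3L, 1L))
  # asymmetry witness: 3's nearest is 2, but 2's nearest is 1
  expect_identical(nb$nearest[3], 2L)
  expect_identical(nb$nearest[2], 1L)
  Dt <- dist1d(c(0, 1, 2)) # 1 and 3 equidistant from 2
  expect_identical(neighbor_map(Dt)$nearest[2], 1L)
  # brute force on a random instance
  E <- random_expression(9, 4, seed = 49)
  Dr <- pairwise_dissimilarity(E, "ed-mcp")
  nbr <- neighbor_map(Dr)
  for (i in 1:9) {
    d <- Dr[i, ]
    d[i] <- Inf
    expect_identical(nbr$nearest[i], unname(order(d)[1]))
    expect_identical(nbr$second[i], unname(order(d)[2]))
  }
  expect_error(neighbor_map(dist1d(c(0, 1))), "at least 3")
})
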