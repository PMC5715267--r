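test_that("farthest-first seeding picks the most distant pair, then maximin", {
  D <- dist1d(c(0, 1, 10))
  expect_identical(icc_seed_centers(D, 2), c(1L, 3L))
  expect_identical(icc_seed_centers(D, 3), c(1L, 3L, 2L))
  D2 <- dist1d(c(0, 2, 3, 10))
  # after {0, 10}: min-dists are 2 (point 2) and 3 (point 3)
  expect_identical(icc_seed_centers(D2, 3), c(1L, 4L, 3L))
  expect_error(icc_seed_centers(D, 5), "k must be in")
})

test_that("seeding ties break toward the lowest gene index", {
  D <- dist1d(c(0, 5, 10, 15)) # pairs (1,4) unique max; then 2 and 3 tie at 5
  expect_identical(icc_seed_centers(D, 3), c(1L, 4L, 2L))
})

test_that("assignment labels each gene by its nearest center", {
  set.seed(7)
  for (rep in 1:3) {
    M <- matrix(runif(100), 10)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    centers <- sample(10, 3)
    labels <- icc_assign(D, centers)
    for (i in setdiff(1:10, centers)) {
      expect_identical(labels[i], unname(which.min(D[i, centers])))
    }
    expect_identical(labels[centers], 1:3) # centers self-assign
  }
})

test_that("assignment ties go to the center with the lower gene index", {
  D <- dist1d(c(0, 5, 10)) # point 2 equidistant to centers 1 and 3
  labels <- icc_assign(D, centers = c(3L, 1L)) # seeding order reversed on purpose
  expect_identical(labels[2], 2L) # cluster 2 = center at gene 1
})

test_that("medoid update minimizes the within-cluster dissimilarity sum", {
  D <- dist1d(c(0, 1, 5))
  expect_identical(icc_update_medoid(D, 1:3), 2L) # sums 6, 5, 9
  expect_identical(icc_update_medoid(D, 2L), 2L) # singleton
  Dt <- matrix(1, 4, 4) - diag(4) # all sums tie
  expect_identical(icc_update_medoid(Dt, c(4L, 2L, 3L)), 2L)
  expect_error(icc_update_medoid(D, integer(0)), "empty")
})

test_that("icc_cluster reaches a fixed point with a non-increasing objective", {
  set.seed(12)
  for (rep in 1:4) {
    E <- random_expression(12, 5, seed = 100 + rep)
    D <- pairwise_dissimilarity(E, "pcc-mcp")
    fit <- icc_cluster(D, 3)
    expect_true(fit$converged)
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
    # fixed point: every gene nearest its medoid, every medoid the brute-force
    # medoid of its cluster
    expect_identical(fit$labels, icc_assign(D, fit$medoids))
    for (l in 1:3) {
      members <- which(fit$labels == l)
      sums <- sapply(members, function(g) sum(D[g, members]))
      expect_identical(fit$medoids[l], members[which.min(sums)])
    }
    expect_equal(fit$objective, sum(D[cbind(1:12, fit$medoids[fit$labels])]))
  }
})

test_that("k = m gives singleton clusters with objective zero", {
  D <- dist1d(c(0, 2, 5, 9))
  fit <- icc_cluster(D, 4)
  expect_identical(sort(tabulate(fit$labels, 4)), rep(1L, 4))
  expect_identical(fit$objective, 0)
})

test_that("well-separated groups are recovered exactly and deterministically", {
  b <- simulate_blobs(m = 40, k = 2, separation = 6, seed = 5)
  D <- pairwise_dissimilarity(b$values, "pcc-mcp")
  fit1 <- icc_cluster(D, 2)
  expect_true(all(table(fit1$labels, b$group) %in% c(0L, 20L)))
  fit2 <- icc_cluster(D, 2)
  expect_identical(fit1, fit2) # no randomness anywhere
})

test_that("the 8-point exhaustive instance converges to brute-force medoids", {
  p <- c(0, 0.5, 1, 1.2, 7, 7.4, 8, 8.3)
  D <- dist1d(p)
  fit <- icc_cluster(D, 2)
  expect_identical(sort(unique(fit$labels[1:4])), unique(fit$labels[1:4]))
  expect_true(all(fit$labels[1:4] == fit$labels[1]))
  expect_true(all(fit$labels[5:8] == fit$labels[5]))
  for (l in 1:2) {
    members <- which(fit$labels == l)
    sums <- sapply(members, function(g) sum(D[g, members]))
    expect_identical(fit$medoids[l], members[which.min(sums)])
  }
})

test_that("the k-means baseline recovers blobs and is seed-deterministic", {
  b <- simulate_blobs(m = 40, k = 2, separation = 6, seed = 6)
  for (measure in c("pcc-mcp", "ed-n")) {
    km <- kmeans_baseline(b$values, 2, measure, seed = 1)
    expect_true(all(table(km$labels, b$group) %in% c(0L, 20L)))
  }
  km1 <- kmeans_baseline(b$values, 3, "pcc-mcp", seed = 42)
  km2 <- kmeans_baseline(b$values, 3, "pcc-mcp", seed = 42)
  expect_identical(km1$labels, km2$labels)
  km3 <- kmeans_baseline(b$values, 1, "ed-mcp", seed = 0)
  expect_true(all(km3$labels == 1L))
})
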