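#' Farthest-first (maximin) seeding of cluster centers
#'
#' The first two centers are a pair of genes attaining the maximum pairwise
#' dissimilarity. Each subsequent center is the non-center gene whose minimum
#' dissimilarity to all already-chosen centers is largest (maximin). All ties
#' break toward the lowest gene index, so seeding is fully deterministic.
#'
#' @param D Symmetric dissimilarity matrix (see [pairwise_dissimilarity()]).
#' @param k Number of centers, `2 <= k <= nrow(D)`.
#' @return Integer vector of `k` gene (row) indices, in seeding order.
#' @export
icc_seed_centers <- function(D, k) {
  D <- as_dissimilarity(D)
  m <- nrow(D)
  if (k < 2 || k > m) stop("k must be in 2..", m)
  # farthest pair; scan column-major so ties resolve to the lowest (i, j)
  up <- upper.tri(D)
  mx <- max(D[up])
  hit <- which(D == mx & up, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  centers <- as.integer(hit[1, c(1, 2)])
  mind <- pmin(D[, centers[1]], D[, centers[2]])
  while (length(centers) < k) {
    mind[centers] <- -Inf
    nxt <- which.max(mind) # first maximum = lowest index on ties
    centers <- c(centers, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  unname(centers)
}

#' Assign genes to their nearest cluster center
#'
#' Each gene is labeled by the center with the smallest dissimilarity to it;
#' a gene that is itself a center always gets its own cluster, and ties go to
#' the tied center with the lowest gene index.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param centers Distinct gene indices of the current centers; cluster `l`
#'   is the cluster of `centers[l]`.
#' @return Integer label vector of length `nrow(D)` with values in
#'   `1..length(centers)`.
#' @export
icc_assign <- function(D, centers) {
  D <- as_dissimilarity(D)
  if (anyDuplicated(centers)) stop("centers must be distinct")
  ord <- order(centers) # tie-break by gene index, not seeding order
  A <- D[, centers[ord], drop = FALSE]
  pos <- max.col(-A, ties.method = "first")
  labels <- match(centers[ord][pos], centers)
  labels[centers] <- seq_along(centers)
  labels
}

#' Medoid of a cluster
#'
#' The cluster member minimizing the sum of dissimilarities to all members of
#' the cluster (ties: lowest gene index).
#'
#' @param D Symmetric dissimilarity matrix.
#' @param members Non-empty vector of gene indices in one cluster.
#' @return A single gene index, an element of `members`.
#' @export
icc_update_medoid <- function(D, members) {
  if (length(members) == 0) stop("cannot take the medoid of an empty cluster")
  members <- sort(as.integer(members))
  sums <- rowSums(D[members, members, drop = FALSE])
  members[which.min(sums)]
}

#' icc-cluster: k-medoid clustering by iterated cluster centers
#'
#' Deterministic k-medoid clustering of a dissimilarity matrix. Centers are
#' seeded farthest-first ([icc_seed_centers()]); the algorithm then
#' alternates nearest-center assignment ([icc_assign()]) and within-cluster
#' medoid updates ([icc_update_medoid()]) until the label vector stops
#' changing. The objective (total dissimilarity of genes to their medoid)
#' never increases across iterations.
#'
#' There is no randomness anywhere: identical inputs give identical outputs.
#'
#' @param D Symmetric dissimilarity matrix with gene ids as dimnames.
#' @param k Number of clusters, `2 <= k <= nrow(D)`.
#' @param max_iter Iteration cap; if reached without convergence the current
#'   (best-so-far) solution is returned with `converged = FALSE` and a
#'   warning.
#' @return An object of class `"icc_cluster"`: a list with `labels` (integer
#'   vector, `1..k`), `medoids` (gene indices; medoid `l` has label `l`),
#'   `medoid_ids` (their rownames), `objective`, `objective_trace` (one value
#'   per iteration), `iterations`, `converged`, `k`, `measure`.
#' @examples
#' E <- simulate_blobs(m = 40, k = 2, separation = 6, seed = 1)
#' D <- pairwise_dissimilarity(E$values, "pcc-mcp")
#' fit <- icc_cluster(D, k = 2)
#' table(fit$labels, E$group)
#' @export
icc_cluster <- function(D, k, max_iter = 100) {
  D <- as_dissimilarity(D)
  m <- nrow(D)
  if (k < 2 || k > m) stop("k must be in 2..", m)
  centers <- icc_seed_centers(D, k)
  labels <- NULL
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    new_labels <- icc_assign(D, centers)
    trace <- c(trace, sum(D[cbind(seq_len(m), centers[new_labels])]))
    if (identical(new_labels, labels)) {
      converged <- TRUE
      labels <- new_labels
      break
    }
    labels <- new_labels
    centers <- vapply(
      seq_len(k),
      function(l) icc_update_medoid(D, which(labels == l)),
      integer(1)
    )
  }
  if (!converged) {
    warning("icc_cluster did not converge in ", max_iter, " iterations")
  }
  structure(
    list(
      labels = labels,
      medoids = centers,
      medoid_ids = rownames(D)[centers],
      objective = trace[length(trace)],
      objective_trace = trace,
      iterations = iter,
      converged = converged,
      k = k,
      measure = attr(D, "measure")
    ),
    class = "icc_cluster"
  )
}

#' @export
print.icc_cluster <- function(x, ...) {
  cat(
    "icc-cluster solution: k =", x$k,
    if (!is.null(x$measure)) paste0("(", x$measure, ")"), "\n"
  )
  cat("  objective:", format(x$objective), "after", x$iterations, "iteration(s)",
    if (!x$converged) "(NOT converged)", "\n"
  )
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

# Validate a square symmetric non-negative dissimilarity matrix.
as_dissimilarity <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("dissimilarity matrix must be square")
  if (any(abs(D - t(D)) > 1e-8)) stop("dissimilarity matrix must be symmetric")
  if (any(D < 0)) stop("dissimilarities must be non-negative")
  D
}
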