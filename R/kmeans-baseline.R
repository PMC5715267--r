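#' k-means baseline on the feature space a measure implies
#'
#' Lloyd-style k-means used as the comparison baseline for [icc_cluster()].
#' The feature vectors follow the measure: MCP vectors for `"pcc-mcp"` and
#' `"ed-mcp"`, normalized profiles for `"pcc"` and `"ed-n"`. Point-to-centroid
#' distance is squared Euclidean for the `ed-*` measures and `1 -` Pearson
#' correlation for the `pcc-*` measures; centroids are the arithmetic mean of
#' cluster members. Seeding is k-means++-style (probability proportional to
#' the distance to the nearest chosen seed) driven entirely by `seed`, and an
#' emptied cluster is reseeded to the point farthest from its centroid.
#'
#' These details are deliberately pinned down and recorded in the returned
#' object so baseline comparisons are reproducible.
#'
#' @param E Numeric gene-by-sample matrix.
#' @param k Number of clusters, `>= 1`.
#' @param measure One of `"pcc-mcp"`, `"pcc"`, `"ed-mcp"`, `"ed-n"`.
#' @param seed Integer seed controlling the k-means++ initialization.
#' @param max_iter Iteration cap, as in [icc_cluster()].
#' @return An object of class `"icc_cluster"` (same shape as [icc_cluster()]
#'   output) with `algorithm = "kmeans"`, `seed`, and `centroids` (the final
#'   k x p centroid matrix) added; `medoids`/`medoid_ids` are `NULL` because
#'   centroids are means, not members.
#' @export
kmeans_baseline <- function(E, k, measure = c("pcc-mcp", "pcc", "ed-mcp", "ed-n"),
                            seed = 0, max_iter = 100) {
  measure <- match.arg(measure)
  E <- as_expression_values(E)
  if (k < 1 || k > nrow(E)) stop("k must be in 1..", nrow(E))
  F <- if (measure %in% c("pcc-mcp", "ed-mcp")) {
    unclass(mcp_matrix(E))
  } else {
    normalize_matrix(E)
  }
  corr <- startsWith(measure, "pcc")
  m <- nrow(F)

  dist_to <- function(centroids) {
    # m x k matrix of point-to-centroid distances under the active metric
    if (corr) {
      1 - stats::cor(t(F), t(centroids))
    } else {
      # squared Euclidean via the expansion |f|^2 - 2 f.c + |c|^2
      d2 <- outer(rowSums(F^2), rowSums(centroids^2), "+") - 2 * F %*% t(centroids)
      pmax(d2, 0)
    }
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  # k-means++ initialization on the active metric
  seeds <- sample.int(m, 1)
  while (length(seeds) < k) {
    d <- dist_to(F[seeds, , drop = FALSE])
    nd <- apply(d, 1, min)
    nd[seeds] <- 0
    p <- if (sum(nd) > 0) nd / sum(nd) else rep(1 / m, m)
    seeds <- c(seeds, sample.int(m, 1, prob = p))
  }
  centroids <- F[seeds, , drop = FALSE]

  labels <- NULL
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    d <- dist_to(centroids)
    new_labels <- max.col(-d, ties.method = "first")
    trace <- c(trace, sum(d[cbind(seq_len(m), new_labels)]))
    if (identical(new_labels, labels)) {
      converged <- TRUE
      break
    }
    labels <- new_labels
    for (l in seq_len(k)) {
      members <- which(labels == l)
      if (length(members) == 0) {
        # reseed an emptied cluster to the globally farthest point
        far <- which.max(apply(d, 1, min))
        labels[far] <- l
        members <- far
      }
      centroids[l, ] <- colMeans(F[members, , drop = FALSE])
    }
  }
  if (!converged) warning("kmeans_baseline did not converge in ", max_iter, " iterations")
  structure(
    list(
      labels = labels,
      medoids = NULL,
      medoid_ids = NULL,
      centroids = centroids,
      objective = trace[length(trace)],
      objective_trace = trace,
      iterations = iter,
      converged = converged,
      k = k,
      measure = measure,
      algorithm = "kmeans",
      seed = seed
    ),
    class = "icc_cluster"
  )
}
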