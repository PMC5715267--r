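#' Principal-component truncation of MCP vectors (KC-data)
#'
#' Column-centered PCA of the `m x n^2` MCP matrix, truncated to the first
#' `k` component scores. Each MCP block sums to a row-constant (`n/2` minus
#' half the profile mass), so after centering the MCP matrix has rank at most
#' `n - 1`: components beyond `n - 1` are numerically zero, and `k` is
#' therefore capped at `n - 1`.
#'
#' @param T MCP matrix from [mcp_matrix()] (attribute `n` = block size).
#' @param k Number of components to keep, `1 <= k <= n - 1`.
#' @return An object of class `"kc_data"`: list with `scores` (`m x k`),
#'   `k`, `explained_variance` (proportion per kept component), `sdev` (all
#'   singular values / sqrt(m-1)), and `n`.
#' @export
pca_mcp <- function(T, k) {
  n <- attr(T, "n")
  if (is.null(n)) n <- as.integer(sqrt(ncol(T)))
  if (k < 1 || k > n - 1) {
    stop(
      "k must be in 1..", n - 1,
      ": centered MCP matrices have rank at most n - 1"
    )
  }
  p <- stats::prcomp(unclass(T), center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(
      scores = p$x[, seq_len(k), drop = FALSE],
      k = k,
      explained_variance = ev[seq_len(k)],
      sdev = p$sdev,
      n = n
    ),
    class = "kc_data"
  )
}

#' 2D t-SNE embedding of a feature matrix
#'
#' Thin wrapper around [Rtsne::Rtsne()] producing one 2D point per input row,
#' in input order. By default the embedding is initialized from the first two
#' principal-component scores (scaled to sd `1e-4`), which makes the result a
#' deterministic function of the data and parameters; with
#' `init = "random"` the initialization is drawn under `seed`.
#'
#' @param P Numeric matrix, one row per gene (MCP vectors, KC-data scores,
#'   normalized or centered profiles, ...).
#' @param seed Integer seed (used by the random initialization only).
#' @param perplexity t-SNE perplexity; requires `nrow(P) - 1 >= 3 *
#'   perplexity`.
#' @param max_iter Gradient-descent iterations.
#' @param theta Barnes-Hut accuracy parameter (0 = exact).
#' @param init `"pca"` (deterministic, default) or `"random"`.
#' @return An object of class `"embedding2d"`: list with `coords` (`m x 2`,
#'   rownames preserved), `source`, `seed`, `perplexity`.
#' @export
tsne_embed <- function(P, seed = 0, perplexity = 30, max_iter = 1000,
                       theta = 0.5, init = c("pca", "random")) {
  init <- match.arg(init)
  P <- as.matrix(P)
  m <- nrow(P)
  if (m - 1 < 3 * perplexity) {
    stop(
      "perplexity ", perplexity, " too large for ", m,
      " points; need m - 1 >= 3 * perplexity (try perplexity <= ",
      floor((m - 1) / 3), ")"
    )
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  y_init <- NULL
  if (init == "pca") {
    sc <- stats::prcomp(P, center = TRUE, scale. = FALSE)$x
    if (ncol(sc) < 2) sc <- cbind(sc, 0)
    y_init <- sc[, 1:2, drop = FALSE]
    sds <- apply(y_init, 2, stats::sd)
    sds[sds == 0] <- 1
    y_init <- sweep(y_init, 2, sds / 1e-4, "/")
  }
  fit <- Rtsne::Rtsne(
    P,
    dims = 2, perplexity = perplexity, theta = theta, max_iter = max_iter,
    Y_init = y_init, pca = FALSE, check_duplicates = FALSE, verbose = FALSE
  )
  coords <- fit$Y
  rownames(coords) <- rownames(P)
  colnames(coords) <- c("x", "y")
  structure(
    list(coords = coords, source = "matrix", seed = seed, perplexity = perplexity),
    class = "embedding2d"
  )
}

#' Average silhouette width of a labeled point set
#'
#' The mean over points of `(b_i - a_i) / max(a_i, b_i)`, where `a_i` is the
#' average distance from point `i` to the other members of its cluster and
#' `b_i` the smallest average distance from `i` to the members of another
#' cluster. Members of singleton clusters contribute `s_i = 0` (the usual
#' convention). Distances are Euclidean on the supplied coordinates unless
#' `diss = TRUE`, in which case `x` is itself a dissimilarity matrix — useful
#' for scoring a clustering in its own measure space rather than on a 2D map.
#'
#' @param x `m x d` coordinate matrix, an `"embedding2d"` object, or (with
#'   `diss = TRUE`) an `m x m` dissimilarity matrix.
#' @param labels Cluster labels, length `m`, at least two distinct values.
#' @param diss Set `TRUE` when `x` is already a dissimilarity matrix.
#' @return Average silhouette width in `[-1, 1]`.
#' @export
average_silhouette <- function(x, labels, diss = FALSE) {
  if (inherits(x, "embedding2d")) x <- x$coords
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  m <- length(labels)
  if (diss) {
    if (nrow(x) != m || ncol(x) != m) stop("dissimilarity matrix does not match labels")
    D <- x
  } else {
    if (nrow(x) != m) stop("coordinate rows do not match labels")
    D <- as.matrix(stats::dist(x))
  }
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("average silhouette needs at least two clusters")
  sizes <- tabulate(labels)
  # mean distance from every point to every cluster, m x k
  member <- outer(labels, ks, "==") * 1
  sums <- D %*% member
  s <- numeric(m)
  for (i in seq_len(m)) {
    li <- labels[i]
    if (sizes[li] == 1) next # singleton: s_i = 0
    a <- sums[i, li] / (sizes[li] - 1)
    b <- min(sums[i, -li] / sizes[-li])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Silhouette-selected t-SNE map of MCP vectors
#'
#' Generates one candidate 2D t-SNE map per requested `k`: for `k >= 2` the
#' map embeds the first `k` PCA scores of the MCP matrix (KC-data); `k = 1`
#' denotes the map of the raw MCP vectors (a 1-dimensional score matrix is
#' never embedded). Each candidate is scored by the average silhouette of the
#' supplied cluster labels on its 2D coordinates, and the candidate with the
#' largest score is selected (ties: smallest `k`).
#'
#' @param T MCP matrix from [mcp_matrix()].
#' @param labels Cluster labels from a prior clustering of the same genes.
#' @param ks Candidate `k` values, a subset of `1..n-1` (1 = raw MCPs).
#'   Default: all of `1..n-1`, evenly thinned to at most `max_candidates`.
#' @param seed,perplexity,max_iter,theta,init Passed to [tsne_embed()].
#' @param max_candidates Cap on the number of candidate maps.
#' @return An object of class `"map_selection"`: list with `candidates`
#'   (data.frame of `k` and silhouette `S`), `embeddings` (list of
#'   `"embedding2d"`, one per candidate), `chosen_k`, `chosen_map`, `labels`.
#' @export
select_tsne_mcp_o <- function(T, labels, ks = NULL, seed = 0, perplexity = 30,
                              max_iter = 1000, theta = 0.5, init = "pca",
                              max_candidates = 30) {
  n <- attr(T, "n")
  if (is.null(n)) n <- as.integer(sqrt(ncol(T)))
  if (length(labels) != nrow(T)) stop("labels do not match the MCP matrix rows")
  if (is.null(ks)) {
    ks <- seq_len(n - 1)
    if (length(ks) > max_candidates) {
      ks <- unique(round(seq(1, n - 1, length.out = max_candidates)))
    }
  }
  ks <- sort(unique(as.integer(ks)))
  if (any(ks < 1 | ks > n - 1)) stop("ks must lie in 1..n-1")
  embeddings <- vector("list", length(ks))
  S <- numeric(length(ks))
  full_pca <- if (any(ks >= 2)) pca_mcp(T, max(max(ks), 2)) else NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    P <- if (k == 1) unclass(T) else full_pca$scores[, seq_len(k), drop = FALSE]
    e <- tsne_embed(P, seed = seed, perplexity = perplexity, max_iter = max_iter,
      theta = theta, init = init)
    e$source <- if (k == 1) "raw-mcp" else paste0("kc-", k)
    embeddings[[i]] <- e
    S[i] <- average_silhouette(e, labels)
  }
  best <- which.max(S) # first max = smallest k on ties
  structure(
    list(
      candidates = data.frame(k = ks, S = S),
      embeddings = embeddings,
      chosen_k = ks[best],
      chosen_map = embeddings[[best]],
      labels = labels
    ),
    class = "map_selection"
  )
}

#' @export
print.map_selection <- function(x, ...) {
  cat("t-SNE map selection over", nrow(x$candidates), "candidate(s):\n")
  print(x$candidates, row.names = FALSE)
  cat("chosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' Baseline t-SNE maps of normalized or centered profiles
#'
#' Comparison embeddings that bypass the MCP transform: `"tsne-n"` embeds the
#' row-normalized profiles, `"tsne-c"` the row-mean-centered raw profiles.
#'
#' @param E Numeric gene-by-sample matrix.
#' @param variant `"tsne-n"` or `"tsne-c"`.
#' @inheritParams tsne_embed
#' @return An `"embedding2d"` object.
#' @export
comparison_map <- function(E, variant = c("tsne-n", "tsne-c"), seed = 0,
                           perplexity = 30, max_iter = 1000, theta = 0.5,
                           init = "pca") {
  variant <- match.arg(variant)
  E <- as_expression_values(E)
  P <- switch(variant,
    "tsne-n" = normalize_matrix(E),
    "tsne-c" = E - rowMeans(E)
  )
  e <- tsne_embed(P, seed = seed, perplexity = perplexity, max_iter = max_iter,
    theta = theta, init = init)
  e$source <- switch(variant, "tsne-n" = "normalized", "tsne-c" = "centered")
  e
}

#' Nearest and second-nearest gene neighbors
#'
#' For every gene, the indices of the genes with the smallest and
#' second-smallest off-diagonal dissimilarity (ties: lower index first).
#' Intended as an overlay on a 2D map: drawn edges reveal which nearby map
#' points are truly close in the measure and which are artifacts of the
#' projection. The relation is directed and need not be symmetric.
#'
#' @param D Symmetric dissimilarity matrix, `m >= 3`.
#' @return A data.frame with one row per gene: `gene`, `nearest`, `second`
#'   (indices) and `gene_id`, `nearest_id`, `second_id`.
#' @export
neighbor_map <- function(D) {
  D <- as_dissimilarity(D)
  m <- nrow(D)
  if (m < 3) stop("neighbor map needs at least 3 genes")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("g", seq_len(m))
  nn <- t(vapply(seq_len(m), function(i) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(m)) # ties toward the lower index
    ord[1:2]
  }, integer(2)))
  data.frame(
    gene = seq_len(m),
    nearest = nn[, 1],
    second = nn[, 2],
    gene_id = ids,
    nearest_id = ids[nn[, 1]],
    second_id = ids[nn[, 2]],
    stringsAsFactors = FALSE
  )
}

#' Plot a 2D embedding colored by cluster, with optional neighbor edges
#'
#' @param x An `"embedding2d"` object.
#' @param labels Optional cluster labels used for point colors.
#' @param neighbors Optional [neighbor_map()] output; nearest-neighbor edges
#'   are drawn in blue, second-nearest in red.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.embedding2d <- function(x, labels = NULL, neighbors = NULL, ...) {
  co <- x$coords
  col <- if (is.null(labels)) "grey30" else as.integer(factor(labels)) + 1
  graphics::plot(co[, 1], co[, 2], col = col, pch = 16, cex = 0.6,
    xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  if (!is.null(neighbors)) {
    graphics::segments(co[neighbors$gene, 1], co[neighbors$gene, 2],
      co[neighbors$second, 1], co[neighbors$second, 2], col = "red", lwd = 0.4)
    graphics::segments(co[neighbors$gene, 1], co[neighbors$gene, 2],
      co[neighbors$nearest, 1], co[neighbors$nearest, 2], col = "blue", lwd = 0.5)
  }
  invisible(x)
}
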