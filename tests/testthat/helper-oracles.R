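# Brute-force oracles, written as literal loops so they share no code path
# with the vectorized implementations they check.

# MCP by explicit loops over rotations and cumulative sums
oracle_mcp <- function(x) {
  shift <- min(min(x), 0)
  y <- (x - shift) / sum(x - shift)
  n <- length(y)
  out <- numeric(0)
  for (s in seq_len(n)) {
    z <- y[((seq_len(n) + s - 2) %% n) + 1]
    block <- numeric(n)
    for (j in seq_len(n)) {
      acc <- 0
      if (j > 1) for (l in seq_len(j - 1)) acc <- acc + z[l]
      block[j] <- acc + z[j] / 2
    }
    out <- c(out, block)
  }
  out
}

# per-pair dissimilarity by direct recomputation
oracle_dissimilarity <- function(E, measure) {
  m <- nrow(E)
  d <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      xi <- E[i, ]
      xj <- E[j, ]
      d[i, j] <- switch(measure,
        "pcc-mcp" = 1 - stats::cor(oracle_mcp(xi), oracle_mcp(xj)),
        "pcc" = 1 - stats::cor(xi, xj),
        "ed-mcp" = sqrt(sum((oracle_mcp(xi) - oracle_mcp(xj))^2)),
        "ed-n" = {
          ni <- (xi - min(min(xi), 0)) / sum(xi - min(min(xi), 0))
          nj <- (xj - min(min(xj), 0)) / sum(xj - min(min(xj), 0))
          sqrt(sum((ni - nj)^2))
        }
      )
    }
  }
  d
}

# silhouette by explicit per-point loops on a coordinate matrix
oracle_silhouette <- function(coords, labels) {
  m <- nrow(coords)
  dmat <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) dmat[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  }
  s <- numeric(m)
  for (i in seq_len(m)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(dmat[i, same])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dmat[i, which(labels == l)]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# dissimilarity matrix of 1D points under absolute difference, handy for
# hand-checkable clustering fixtures
dist1d <- function(p) {
  d <- abs(outer(p, p, "-"))
  rownames(d) <- colnames(d) <- paste0("p", seq_along(p))
  d
}

# strictly positive random expression matrix
random_expression <- function(m, n, seed) {
  set.seed(seed)
  E <- matrix(stats::runif(m * n, 0.5, 10), m, n)
  rownames(E) <- paste0("g", seq_len(m))
  colnames(E) <- paste0("s", seq_len(n))
  E
}
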