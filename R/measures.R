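#' Pearson correlation with a fixed policy for constant input
#'
#' Standard Pearson correlation coefficient. A constant vector has no defined
#' correlation; since constant profiles only arise in the raw-PCC comparison
#' baseline (MCP vectors of valid profiles are never constant), the policy is
#' to return 0 with a warning rather than abort.
#'
#' @param u,v Numeric vectors of equal length `>= 2`.
#' @return Correlation in `[-1, 1]`; 0 (with a warning) if either input is
#'   constant.
#' @export
pcc <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (length(u) < 2) stop("vectors must have length >= 2")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    warning("constant input to pcc(); returning correlation 0")
    return(0)
  }
  stats::cor(u, v)
}

#' Pearson correlation of MCP vectors (PCC-MCP)
#'
#' The similarity measure at the core of the package: the Pearson correlation
#' between the length-`n^2` MCP vectors of two profiles. Unlike raw PCC, it
#' compares the distribution of expression mass over time points rather than
#' the literal curve shape, so noisy but flat profiles score as similar and
#' positive rescaling has no effect.
#'
#' @param x1,x2 Numeric expression profiles of equal length `n >= 2`.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' pcc_mcp(c(1, 2, 3), 3 * c(1, 2, 3)) # 1: scale invariant
#' @export
pcc_mcp <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("profiles must have equal length")
  pcc(mcp(x1), mcp(x2))
}

#' Euclidean distance of MCP vectors (ED-MCP)
#'
#' @inheritParams pcc_mcp
#' @return Non-negative distance; 0 iff the normalized profiles coincide.
#' @export
ed_mcp <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("profiles must have equal length")
  sqrt(sum((mcp(x1) - mcp(x2))^2))
}

MEASURES <- c("pcc-mcp", "pcc", "ed-mcp", "ed-n")

#' Pairwise gene dissimilarity matrix
#'
#' Computes the symmetric `m x m` dissimilarity matrix of all genes under one
#' of four measures:
#' \describe{
#'   \item{`pcc-mcp`}{`1 -` Pearson correlation of MCP vectors (the default
#'     and the recommended measure).}
#'   \item{`pcc`}{`1 -` Pearson correlation of the raw profiles (comparison
#'     baseline).}
#'   \item{`ed-mcp`}{Euclidean distance of MCP vectors.}
#'   \item{`ed-n`}{Euclidean distance of the normalized profiles.}
#' }
#'
#' Correlation-based entries lie in `[0, 2]`; all entries are non-negative
#' with a zero diagonal. Gene order follows the input row order.
#'
#' @param E Numeric gene-by-sample matrix (rownames = gene ids).
#' @param measure One of `"pcc-mcp"`, `"pcc"`, `"ed-mcp"`, `"ed-n"`.
#' @return Symmetric numeric matrix with gene ids on both dimnames and
#'   attribute `measure`.
#' @examples
#' E <- rbind(g1 = c(1, 2, 3, 2), g2 = c(2, 4, 6, 4), g3 = c(5, 1, 1, 5))
#' pairwise_dissimilarity(E, "pcc-mcp")
#' @export
pairwise_dissimilarity <- function(E, measure = c("pcc-mcp", "pcc", "ed-mcp", "ed-n")) {
  measure <- match.arg(measure)
  E <- as_expression_values(E)
  d <- switch(measure,
    "pcc-mcp" = 1 - stats::cor(t(mcp_matrix(E))),
    "pcc" = {
      sds <- apply(E, 1, stats::sd)
      if (any(sds == 0)) {
        stop(
          "constant profile(s) have no defined correlation under measure 'pcc': ",
          paste(rownames(E)[sds == 0], collapse = ", ")
        )
      }
      1 - stats::cor(t(E))
    },
    "ed-mcp" = as.matrix(stats::dist(mcp_matrix(E))),
    "ed-n" = as.matrix(stats::dist(normalize_matrix(E)))
  )
  # enforce exact symmetry and a clean zero diagonal against rounding noise
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(E), rownames(E))
  structure(d, measure = measure)
}
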