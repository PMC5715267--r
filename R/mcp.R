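#' Normalize an expression profile to a discrete probability vector
#'
#' Shifts the profile so that all values are non-negative (only when the
#' minimum is negative; non-negative profiles are left untouched) and divides
#' by the total, so the result is a probability vector over the `n` time
#' points.
#'
#' Profiles whose shifted total is (numerically) zero -- an all-zero
#' non-negative profile, or a constant profile equal to its own non-positive
#' minimum -- carry no distributional information and are rejected.
#'
#' @param x Numeric vector of expression values at `n >= 2` points. Negative
#'   values are allowed.
#' @param gene Optional gene identifier used in error messages.
#' @return Numeric vector of length `n`, non-negative, summing to 1.
#' @examples
#' normalize_profile(c(2, 2, 2, 2))
#' normalize_profile(c(-1, 0, 1))
#' @export
normalize_profile <- function(x, gene = NULL) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("profile must be a numeric vector of length >= 2")
  }
  if (anyNA(x)) stop("profile contains NA", if (!is.null(gene)) paste0(" (gene ", gene, ")"))
  shift <- min(min(x), 0)
  y <- x - shift
  total <- sum(y)
  if (!is.finite(total) || total < 1e-12) {
    stop(
      "degenerate profile",
      if (!is.null(gene)) paste0(" for gene ", gene),
      ": normalization denominator is zero (constant or all-zero profile)"
    )
  }
  y / total
}

#' Cyclic permutation of a profile
#'
#' Rotates `y` so that position `s` comes first:
#' `(y_s, y_{s+1}, ..., y_n, y_1, ..., y_{s-1})`.
#'
#' @param y Numeric vector.
#' @param s Start position, an integer in `1..length(y)`.
#' @return Numeric vector of the same length.
#' @examples
#' cyclic_shift(c(1, 2, 3), 2) # 2 3 1
#' @export
cyclic_shift <- function(y, s) {
  n <- length(y)
  if (length(s) != 1 || s != as.integer(s) || s < 1 || s > n) {
    stop("shift index s must be a single integer in 1..", n)
  }
  if (s == 1) return(y)
  y[c(s:n, seq_len(s - 1))]
}

#' Modified cumulative sum of a probability vector
#'
#' Element `j` of the result is `sum(z[seq_len(j - 1)]) + z[j] / 2`: the usual
#' cumulative sum in which each position contributes only half of its own
#' mass. Unlike the plain cumulative sum (whose last element is always 1),
#' every element stays strictly inside (0, 1) for strictly positive input,
#' and each position of `z` enters the result with the same total weight.
#'
#' @param z Numeric probability vector (non-negative, summing to 1 within
#'   `1e-9`).
#' @return Numeric vector of the same length.
#' @examples
#' modified_cumsum(c(0.2, 0.3, 0.5)) # 0.10 0.35 0.75
#' @export
modified_cumsum <- function(z) {
  if (any(z < 0)) stop("input must be non-negative")
  if (abs(sum(z) - 1) > 1e-9) stop("input must sum to 1 (got ", format(sum(z)), ")")
  cumsum(z) - z / 2
}

#' Multiple-cumulative probability (MCP) vector of a profile
#'
#' The MCP of an `n`-point profile is the length-`n^2` concatenation, over the
#' `n` cyclic rotations of the normalized profile, of their modified
#' cumulative sums. Block `s` (positions `(s-1)*n + 1 .. s*n`) is
#' `modified_cumsum(cyclic_shift(normalize_profile(x), s))`.
#'
#' Because every rotation is summed, each time point takes every position in
#' the cumulative sum exactly once: the MCP depends only on the normalized
#' profile, not on an arbitrary choice of origin, and is invariant to positive
#' rescaling of `x`.
#'
#' @param x Numeric expression profile of length `n >= 2`.
#' @param gene Optional gene identifier for error messages.
#' @return Numeric vector of length `n^2` with attribute `n` (the block size).
#' @examples
#' mcp(c(1, 1)) # 0.25 0.75 0.25 0.75
#' @export
mcp <- function(x, gene = NULL) {
  y <- normalize_profile(x, gene = gene)
  n <- length(y)
  t <- unlist(lapply(seq_len(n), function(s) modified_cumsum(cyclic_shift(y, s))),
    use.names = FALSE
  )
  structure(t, n = n)
}

# Upper-triangular weight matrix W with W[l, j] = 1 for l < j and 1/2 on the
# diagonal, so that Z %*% W is the modified cumulative sum of each row of Z.
.mcp_weights <- function(n) {
  w <- upper.tri(diag(n)) * 1
  diag(w) <- 0.5
  w
}

#' MCP vectors of every gene in an expression matrix
#'
#' Row-wise [mcp()] of a gene-by-sample matrix, computed with one matrix
#' product per rotation.
#'
#' @param E Numeric matrix, genes in rows (rownames are gene identifiers),
#'   samples in columns.
#' @return Numeric matrix `m x n^2` with the same rownames, column names
#'   `T<s>.<j>` for block `s` position `j`, and attribute `n`.
#' @seealso [mcp()], [pairwise_dissimilarity()]
#' @export
mcp_matrix <- function(E) {
  E <- as_expression_values(E)
  m <- nrow(E)
  n <- ncol(E)
  shift <- pmin(apply(E, 1, min), 0)
  Y <- E - shift
  total <- rowSums(Y)
  bad <- !is.finite(total) | total < 1e-12
  if (any(bad)) {
    stop(
      "degenerate profile(s), normalization denominator is zero: ",
      paste(rownames(E)[bad], collapse = ", ")
    )
  }
  Y <- Y / total
  w <- .mcp_weights(n)
  blocks <- lapply(seq_len(n), function(s) {
    Y[, c(s:n, seq_len(s - 1)), drop = FALSE] %*% w
  })
  T <- do.call(cbind, blocks)
  colnames(T) <- paste0("T", rep(seq_len(n), each = n), ".", rep(seq_len(n), n))
  structure(T, n = n)
}

#' Normalized profiles of every gene in an expression matrix
#'
#' Row-wise [normalize_profile()].
#'
#' @inheritParams mcp_matrix
#' @return Numeric matrix of the same dimensions; rows are non-negative and
#'   sum to 1.
#' @export
normalize_matrix <- function(E) {
  E <- as_expression_values(E)
  shift <- pmin(apply(E, 1, min), 0)
  Y <- E - shift
  total <- rowSums(Y)
  bad <- !is.finite(total) | total < 1e-12
  if (any(bad)) {
    stop(
      "degenerate profile(s), normalization denominator is zero: ",
      paste(rownames(E)[bad], collapse = ", ")
    )
  }
  Y / total
}

# Coerce to a validated genes-by-samples numeric matrix with unique rownames.
as_expression_values <- function(E) {
  E <- as.matrix(E)
  if (!is.numeric(E)) stop("expression matrix must be numeric")
  if (nrow(E) < 1 || ncol(E) < 2) stop("expression matrix needs >= 1 gene and >= 2 samples")
  if (is.null(rownames(E))) rownames(E) <- paste0("g", seq_len(nrow(E)))
  if (anyDuplicated(rownames(E))) {
    stop(
      "duplicate gene identifiers: ",
      paste(unique(rownames(E)[duplicated(rownames(E))]), collapse = ", ")
    )
  }
  if (anyNA(E)) {
    idx <- which(is.na(E), arr.ind = TRUE)[1, ]
    stop("NA expression value at gene ", rownames(E)[idx[1]], ", column ", idx[2])
  }
  E
}
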