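#' Flatten the upper triangle of a symmetric connectivity matrix
#'
#' Extracts the strictly upper-triangular entries of a square symmetric
#' matrix in row-major order (pairs (1,2), (1,3), ..., (1,n), (2,3), ...),
#' excluding the diagonal. This is the canonical vectorization of a
#' functional-connectivity matrix into a subject feature vector of length
#' n(n-1)/2.
#'
#' @param M Square symmetric numeric matrix (symmetry tolerance 1e-6).
#' @return Numeric vector of length `nrow(M) * (nrow(M) - 1) / 2`.
#' @examples
#' flatten_upper_triangle(matrix(c(1, 0.5, 0.5, 1), 2))  # 0.5
#' @export
flatten_upper_triangle <- function(M) {
  assert_that(is.matrix(M) && nrow(M) == ncol(M), "M must be a square matrix")
  assert_that(max(abs(M - t(M))) <= 1e-6, "M is not symmetric within tolerance 1e-6")
  # t(M)[lower.tri] walks the upper triangle of M in row-major order
  t(M)[lower.tri(M)]
}

# Inverse of flatten_upper_triangle: rebuild a symmetric matrix with unit
# diagonal from a flattened upper triangle.
unflatten_upper_triangle <- function(x, n) {
  assert_that(length(x) == n * (n - 1) / 2,
              "vector length %d does not match n = %d", length(x), n)
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- x      # fills t(M)'s upper triangle row-major
  M <- t(M)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 1
  M
}

#' Squeeze: global average of connectivity features across subjects
#'
#' First stage of the squeeze-and-excitation block: aggregates all subjects
#' into one global feature vector z, where z_j is the mean of feature j over
#' subjects (each subject contributes equally).
#'
#' @param X N x d numeric matrix, rows = subjects.
#' @return Numeric vector z of length d.
#' @export
squeeze_features <- function(X) {
  assert_that(is.matrix(X) && nrow(X) >= 1, "X must be a matrix with >= 1 row")
  colMeans(X)
}

#' Excitation: feature-importance weights from the global vector
#'
#' Second stage of the squeeze-and-excitation block: the global vector z is
#' compressed by a bottleneck layer (width floor(d / r)) with ReLU, expanded
#' back to width d, and squashed by a sigmoid, yielding a weight
#' s_j in (0, 1) per connectivity feature:
#' `s = sigmoid(W2 %*% relu(W1 %*% z))`.
#'
#' @param z Global feature vector of length d (from [squeeze_features()]).
#' @param params An `se_params` object (or any list with matrices `W1`
#'   (d/r x d) and `W2` (d x d/r)).
#' @return Weight vector s of length d, every entry strictly in (0, 1).
#' @export
excitation <- function(z, params) {
  W1 <- params$W1; W2 <- params$W2
  assert_that(ncol(W1) == length(z),
              "W1 has %d columns but z has length %d", ncol(W1), length(z))
  assert_that(nrow(W2) == ncol(W1) && ncol(W2) == nrow(W1),
              "W2 dimensions do not chain with W1")
  as.vector(sigmoid(W2 %*% relu(W1 %*% z)))
}

#' Rescale subject features by the excitation weights
#'
#' Third stage of the squeeze-and-excitation block: every subject's feature
#' vector is multiplied elementwise by the shared weight vector s, shrinking
#' unimportant connections (|rescaled| <= |raw| since s in (0,1)).
#'
#' @param X N x d matrix of raw features.
#' @param s Weight vector of length d.
#' @return N x d matrix of rescaled features.
#' @export
rescale_features <- function(X, s) {
  assert_that(ncol(X) == length(s),
              "X has %d columns but s has length %d", ncol(X), length(s))
  sweep(X, 2L, s, "*")
}
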