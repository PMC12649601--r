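# Principal gradients of the covariance network, approximated from a random
# landmark set so the full vertex-by-vertex matrix never has to be formed,
# with an exact full-matrix decomposition as the in-package oracle.
#
# The embedding is a plain singular-value decomposition of column-centered
# connectivity profiles ("principal components" in the standard convention:
# vertices are observations, per-landmark profiles are variables): no
# affinity kernel and no diffusion-map alpha-normalization.
# variance_explained(i) is the i-th squared singular value over the total
# variance (squared Frobenius norm) of the centered profile matrix.
# Row-centering (centering each vertex's profile) was evaluated and
# rejected: it adds a rank-one mean-profile term that measurably
# contaminates the weaker components (see the methods vignette).

#' Select random landmarks
#'
#' Uniform sample of vertex indices without replacement, reproducible from
#' the seed. The conventional landmark count for full-resolution cortical
#' analyses is `min(3000, n_vertices)`.
#'
#' @param n_vertices number of vertices.
#' @param n_landmarks number of landmarks, `1 <= n_landmarks <= n_vertices`.
#'   Default `min(3000, n_vertices)`.
#' @param seed integer seed.
#' @return An object of class `mcn_landmarks`: sorted unique 1-based
#'   `indices`, `n_landmarks`, `n_vertices`, `seed`.
#' @export
select_landmarks <- function(n_vertices, n_landmarks = min(3000L, n_vertices),
                             seed = 1L) {
  n_vertices <- check_count(n_vertices, "n_vertices")
  n_landmarks <- check_count(n_landmarks, "n_landmarks")
  if (n_landmarks > n_vertices) {
    stopf("n_landmarks (%d) exceeds n_vertices (%d)", n_landmarks, n_vertices)
  }
  idx <- with_seed(seed, sort(sample.int(n_vertices, n_landmarks)))
  out <- list(indices = idx, n_landmarks = n_landmarks,
              n_vertices = n_vertices, seed = as.integer(seed))
  class(out) <- "mcn_landmarks"
  out
}

#' @export
print.mcn_landmarks <- function(x, ...) {
  cat("Landmark set:", x$n_landmarks, "of", x$n_vertices,
      "vertices (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Vertex-to-landmark connectivity
#'
#' Pearson correlation of every vertex's residual column with each landmark
#' column. Memory scales with `n_vertices x n_landmarks` only; the full
#' square matrix is never formed.
#'
#' @param residuals an `mcn_residuals` or subjects x vertices matrix.
#' @param landmarks an `mcn_landmarks` object (or integer index vector).
#' @return `n_vertices x n_landmarks` correlation matrix.
#' @export
landmark_connectivity <- function(residuals, landmarks) {
  R <- as_residual_matrix(residuals)
  idx <- if (inherits(landmarks, "mcn_landmarks")) landmarks$indices
         else as.integer(landmarks)
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > ncol(R))) {
    stopf("landmark indices must be unique and within 1..%d", ncol(R))
  }
  check_column_variance(R)
  stats::cor(R, R[, idx, drop = FALSE])
}

# centered-SVD embedding shared by the approximate and exact routes
#' @noRd
gradient_svd <- function(conn, k, landmarks) {
  conn <- check_matrix(conn, "conn")
  k <- check_count(k, "k")
  if (k > ncol(conn)) {
    stopf("k (%d) exceeds the number of landmark profiles (%d)", k, ncol(conn))
  }
  Xc <- sweep(conn, 2L, colMeans(conn))  # center each landmark profile
  sv <- svd(Xc)
  total <- sum(sv$d^2)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (k > rank) stopf("k (%d) exceeds the rank of the centered profiles (%d)",
                      k, rank)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: loading positive at its highest-|loading| landmark
  for (j in seq_len(k)) {
    l <- which.max(abs(loadings[, j]))
    if (loadings[l, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- sprintf("G%d", seq_len(k))
  out <- list(scores = scores,
              variance_explained = sv$d[seq_len(k)]^2 / total,
              loadings = loadings, k = k, landmarks = landmarks)
  class(out) <- "mcn_gradients"
  out
}

#' Approximate gradients from landmark connectivity
#'
#' Treats the rows of the vertex-by-landmark correlation matrix as vertex
#' connectivity profiles, centers each landmark column over vertices (the
#' standard principal-component convention) and extracts the top-`k`
#' singular components as gradients.
#'
#' @param conn vertex x landmark correlation matrix from
#'   [landmark_connectivity()].
#' @param k number of gradients (the usual reporting choice is 3).
#' @param landmarks optional `mcn_landmarks` recorded in the result.
#' @return An object of class `mcn_gradients`: `scores` (vertices x k),
#'   `variance_explained` (non-increasing, sums to <= 1), `loadings`, `k`,
#'   `landmarks`.
#' @export
approximate_gradients <- function(conn, k = 3L, landmarks = NULL) {
  gradient_svd(conn, k, landmarks)
}

#' Exact gradients of the full covariance network
#'
#' Same embedding as [approximate_gradients()] applied to the full square
#' correlation matrix (every vertex is a landmark); serves as the oracle
#' for the landmark approximation at test scale.
#'
#' @param network an `mcn_covnet` or square correlation matrix.
#' @param k number of gradients.
#' @return An `mcn_gradients` object with `landmarks = "full"`.
#' @export
exact_gradients <- function(network, k = 3L) {
  rho <- as_rho(network)
  gradient_svd(rho, k, landmarks = "full")
}

#' @export
print.mcn_gradients <- function(x, ...) {
  cat("Gradient set: k =", x$k, "over", nrow(x$scores), "vertices\n")
  cat("  variance explained:",
      paste(sprintf("%.2f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Align two gradient sets up to per-component sign
#'
#' Singular vectors are defined up to sign; this reports, per component, the
#' sign flip that maximizes the correlation between the two score columns
#' and the achieved absolute correlation.
#'
#' @param a,b `mcn_gradients` objects (or score matrices) with the same
#'   vertex count and the same `k`.
#' @return data.frame with `component`, `flip` (+1/-1), `r` (achieved
#'   absolute correlation).
#' @export
align_components <- function(a, b) {
  sa <- if (inherits(a, "mcn_gradients")) a$scores else check_matrix(a, "a")
  sb <- if (inherits(b, "mcn_gradients")) b$scores else check_matrix(b, "b")
  if (!identical(dim(sa), dim(sb))) {
    stopf("gradient sets differ in shape (%s vs %s)",
          paste(dim(sa), collapse = "x"), paste(dim(sb), collapse = "x"))
  }
  r <- vapply(seq_len(ncol(sa)), function(j) stats::cor(sa[, j], sb[, j]),
              numeric(1))
  data.frame(component = seq_len(ncol(sa)),
             flip = ifelse(r >= 0, 1, -1), r = abs(r))
}
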