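#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Computes the proper rigid transform `T` minimizing the sum of squared
#' residuals over the mapped pairs,
#' `sum_i || T(q_j(i)) - p_i ||^2`, and the minimized RMSD
#' `sqrt(min_T sum_i || T(q_j(i)) - p_i ||^2 / l)` with `l` the number of
#' mapped pairs.  The transform maps Q-space points onto P.  Closed form via
#' the SVD of the 3 x 3 cross-correlation matrix of the centered coordinates;
#' runtime is linear in the number of pairs.
#'
#' Reflections are excluded by the usual determinant sign correction: when
#' `det(U V')` of the SVD factors is negative, the singular direction with
#' the smallest singular value is flipped.  For degenerate (collinear or
#' planar) configurations any minimizing proper rotation may be returned;
#' the RMSD value is still optimal.
#'
#' @param P,Q [point_sequence()]s or coordinate matrices.
#' @param mapping a [pair_mapping()] with at least one pair; defaults to the
#'   identity mapping over `min(n, m)` points.
#' @return a list with components `transform` (a [rigid_transform()]) and
#'   `rmsd` (nonnegative numeric).
#' @examples
#' P <- point_sequence(rbind(c(0, 0, 0), c(4, 0, 0)))
#' Q <- point_sequence(rbind(c(0, 0, 0), c(2, 0, 0)))
#' superpose(P, Q, identity_mapping(2))$rmsd  # 1: two-point closed form
#' @export
superpose <- function(P, Q, mapping = NULL) {
  if (is.null(mapping))
    mapping <- identity_mapping(min(n_points(P), n_points(Q)))
  mc <- mapped_coords(P, Q, mapping)
  if (!all(is.finite(mc$P)) || !all(is.finite(mc$Q)))
    stop("non-finite coordinates")
  l <- nrow(mc$P)
  cen_p <- colMeans(mc$P)
  cen_q <- colMeans(mc$Q)
  Pc <- sweep(mc$P, 2L, cen_p)
  Qc <- sweep(mc$Q, 2L, cen_q)
  ## correlation matrix M[u, v] = sum_k Pc[k, u] * Qc[k, v]
  M <- crossprod(Pc, Qc)
  R <- kabsch_rotation(M)
  t <- cen_p - as.vector(R %*% cen_q)
  res2 <- sum((Qc %*% t(R) - Pc)^2)
  list(transform = rigid_transform(R, t, tol = 1e-6),
       rmsd = sqrt(max(res2, 0) / l))
}

#' Proper rotation maximizing trace(R M') from a correlation matrix
#'
#' Given the 3 x 3 matrix `M` of dot products between centered P-side and
#' Q-side coordinate vectors (`M[u, v] = U_P . V_Q`), returns the proper
#' rotation `R` maximizing `trace(R M')` -- the rotation step of the Kabsch
#' superposition, also used on enumerated lattice matrices that need not be
#' realizable correlation matrices.  SVD with determinant sign correction;
#' rank-deficient `M` is allowed (any maximizer is returned).
#'
#' @param M 3 x 3 numeric matrix.
#' @return a 3 x 3 proper rotation matrix.
#' @examples
#' rotation_from_m(diag(3))           # identity
#' rotation_from_m(diag(c(1, 1, -1))) # sign-corrected to identity
#' @export
rotation_from_m <- function(M) {
  M <- as.matrix(M)
  stopifnot(all(dim(M) == c(3L, 3L)), all(is.finite(M)))
  kabsch_rotation(M)
}

kabsch_rotation <- function(M) {
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' RMSD at a fixed transform
#'
#' The un-minimized RMSD `sqrt(sum_i || T(q_j(i)) - p_i ||^2 / l)` of the
#' mapped pairs under a given rigid transform.  Always at least the
#' [superpose()] RMSD of the same mapping.
#'
#' @inheritParams superpose
#' @param T a [rigid_transform()] applied to the Q-side points.
#' @return nonnegative numeric RMSD.
#' @export
rmsd_fixed <- function(P, Q, mapping, T = identity_transform()) {
  mc <- mapped_coords(P, Q, mapping)
  if (!all(is.finite(mc$P)) || !all(is.finite(mc$Q)))
    stop("non-finite coordinates")
  tq <- transform_points(mc$Q, T)
  sqrt(sum((tq - mc$P)^2) / nrow(mc$P))
}

## squared-distance matrix d[i, j] = || T(q_j) - p_i ||^2.
## On integral inputs with an integral transform these are exact integers.
pair_cost_matrix <- function(P, Q, T = identity_transform()) {
  cp <- as_coord_matrix(P)
  cq <- transform_points(as_coord_matrix(Q), T)
  outer(rowSums(cp^2), rep(1, nrow(cq))) +
    outer(rep(1, nrow(cp)), rowSums(cq^2)) - 2 * cp %*% t(cq)
}
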