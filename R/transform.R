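#' Rigid transformation (proper rotation + translation)
#'
#' Transforms act on Q-space points and map them onto P:
#' `x -> R x + t`.  Only proper rotations are admitted (det(R) = +1, no
#' reflection), matching the convention of RMSD in structural biology.
#'
#' @param rotation 3 x 3 orthogonal matrix with determinant +1.
#' @param translation length-3 numeric vector.
#' @param tol orthogonality / determinant tolerance (max-abs elementwise).
#' @return an object of class `rigid_transform`.
#' @examples
#' rigid_transform(diag(3), c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("non-finite transform")
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stop("rotation is not orthogonal within tolerance")
  if (abs(det(rotation) - 1) > tol)
    stop("rotation is not proper (det != +1): reflections are not allowed")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: t =", sprintf("%.4g", x$translation), "\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Apply a rigid transform to a point sequence
#'
#' @param Q a [point_sequence()] or coordinate matrix.
#' @param T a [rigid_transform()].
#' @return an object of the same kind as `Q` with transformed coordinates
#'   (the `integral` flag is dropped, since a rigid motion rarely preserves
#'   the integer lattice).
#' @export
apply_transform <- function(Q, T) {
  stopifnot(inherits(T, "rigid_transform"))
  cq <- as_coord_matrix(Q)
  out <- transform_points(cq, T)
  if (inherits(Q, "point_sequence")) {
    Q$coords <- out
    Q$integral <- FALSE
    Q
  } else out
}

transform_points <- function(coords, T) {
  out <- coords %*% t(T$rotation)
  out <- sweep(out, 2L, T$translation, "+")
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Compose two rigid transforms
#' @param T2,T1 [rigid_transform()]s; the result applies `T1` first.
#' @return the composed [rigid_transform()] `T2 o T1`.
#' @export
compose_transform <- function(T2, T1) {
  rigid_transform(T2$rotation %*% T1$rotation,
                  as.vector(T2$rotation %*% T1$translation) + T2$translation)
}

#' Invert a rigid transform
#' @param T a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(T) {
  rigid_transform(t(T$rotation), -as.vector(t(T$rotation) %*% T$translation))
}

#' Identity transform
#' @return the identity [rigid_transform()].
#' @export
identity_transform <- function() rigid_transform()

#' Uniform random proper rotation
#'
#' Draws a rotation uniformly from SO(3) via a random unit quaternion
#' (Marsaglia / Shoemake).  Used by the synthetic-data generator and the
#' property tests; respects the R RNG stream, so `set.seed()` makes it
#' reproducible.
#'
#' @return a 3 x 3 proper rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3L, byrow = TRUE)
}

#' Rotation from ZYZ Euler angles
#' @param alpha,beta,gamma angles in radians.
#' @return a 3 x 3 proper rotation matrix `Rz(alpha) Ry(beta) Rz(gamma)`.
#' @export
euler_rotation <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3L, byrow = TRUE)
  ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                           3L, byrow = TRUE)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}
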