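#' Generate a protein-like random-walk chain
#'
#' Emulates a C-alpha trace as a 3D random walk: steps of fixed length
#' `bond` (default 3.8 length units, the natural cap on consecutive C-alpha
#' distances) in uniformly random directions, starting at the origin.
#' Coordinates are optionally multiplied by `scale` and rounded to integers,
#' which is the regime of the exact algorithms; rounding moves each point by
#' at most `sqrt(3)/2`, so consecutive rounded points are at most
#' `bond * scale + sqrt(3)` apart.  The default `scale = 1` keeps `c_max`
#' (and hence oracle and lattice sizes) small for algorithm tests;
#' `scale = 1000` mirrors PDB three-decimal precision.
#'
#' @param n number of points, `>= 1`.
#' @param bond step length (= the consecutive-distance cap), default 3.8.
#' @param scale integer scale factor applied before rounding, `>= 1`.
#' @param seed optional integer seed (local RNG state; restored on exit).
#' @param integral round to integers (default TRUE); `FALSE` returns the raw
#'   walk, whose steps have length exactly `bond`.
#' @param globular confine the walk to a ball of radius
#'   `ceiling(bond * n^(1/3)) * scale` by rejection, emulating the tighter
#'   `c_max = O(n^(1/3))` regime of globular structures.
#' @return a [point_sequence()] in protein mode.
#' @examples
#' P <- generate_chain(10, seed = 1)
#' max(abs(P$coords)) <= 10 * 3.8 + 1   # connectivity bound on c_max
#' @export
generate_chain <- function(n, bond = 3.8, scale = 1L, seed = NULL,
                           integral = TRUE, globular = FALSE) {
  stopifnot(n >= 1L, bond > 0, scale >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  radius <- if (globular) ceiling(bond * n^(1 / 3)) else Inf
  coords <- matrix(0, nrow = n, ncol = 3L)
  for (i in seq_len(n)[-1L]) {
    repeat {
      u <- stats::rnorm(3)
      step <- bond * u / sqrt(sum(u^2))
      nxt <- coords[i - 1L, ] + step
      if (sqrt(sum(nxt^2)) <= radius) break
    }
    coords[i, ] <- nxt
  }
  coords <- coords * scale
  if (integral) coords <- round(coords)
  point_sequence(coords, name = sprintf("chain%d", n), integral = integral,
                 protein_mode = TRUE, bond_cap = bond, scale = scale)
}

## uniformly random proper signed permutation matrix (the 24 rotations of
## the cubic lattice): maps integer points to integer points
random_lattice_rotation <- function() {
  perm <- sample(3L)
  signs <- sample(c(-1, 1), 3L, replace = TRUE)
  R <- matrix(0, 3L, 3L)
  R[cbind(seq_len(3L), perm)] <- signs
  if (det(R) < 0) R[1L, perm[1L]] <- -R[1L, perm[1L]]
  R
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Plant a rigidly transformed common fragment
#'
#' Builds a second chain `Q` containing a copy of a fragment of `P` under a
#' random rigid motion, with optional isotropic Gaussian noise, spliced
#' between random-walk decoy flanks, and re-rounded to integers.  The
#' returned ground-truth mapping records the fragment correspondence, so
#' recovery can be scored: with `sigma = 0` and no rounding loss the LCP at
#' `theta = 0` is at least the fragment length.
#'
#' @param P a [point_sequence()] from [generate_chain()].
#' @param start first fragment index in `P`.
#' @param k fragment length; `start + k - 1` must be within `P`.
#' @param sigma isotropic noise scale added per coordinate (length units,
#'   before rounding).
#' @param decoys number of decoy residues on each side of the fragment in
#'   `Q`.
#' @param seed optional integer seed.
#' @param lattice_transform use a random *lattice* rigid motion (proper
#'   signed permutation rotation + integer translation), which maps integers
#'   to integers so the planted copy is exactly congruent -- no rounding
#'   loss.  Defaults to `TRUE` for integral `P`; set `FALSE` for a generic
#'   rotation (the planted RMSD then reflects rounding, about
#'   `0.5 / scale` per coordinate).
#' @return a list with `Q` (a [point_sequence()]), `truth` (a
#'   [pair_mapping()] from P indices to Q indices), and `transform` (the
#'   planted [rigid_transform()] in the package convention: it maps the
#'   Q-side fragment back onto P, so
#'   `rmsd_fixed(P, Q, truth, transform) == 0` when `sigma = 0` and the
#'   motion is lattice-exact).
#' @export
plant_common_fragment <- function(P, start, k, sigma = 0, decoys = 2L,
                                  seed = NULL,
                                  lattice_transform = P$integral) {
  stopifnot(inherits(P, "point_sequence"), sigma >= 0, decoys >= 0L)
  n <- n_points(P)
  if (start < 1L || start + k - 1L > n) stop("fragment outside P")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  frag <- P$coords[start:(start + k - 1L), , drop = FALSE]
  R0 <- if (lattice_transform) random_lattice_rotation() else random_rotation()
  ## keep the planted copy near the origin: rotate about the fragment
  ## centroid, then add a small random integer offset so c_max stays small
  cen <- colMeans(frag)
  t0 <- -as.vector(R0 %*% cen) + sample(-3:3, 3L, replace = TRUE)
  if (lattice_transform) t0 <- round(t0)
  T0 <- rigid_transform(R0, t0, tol = 1e-6)
  moved <- transform_points(frag, T0)
  if (sigma > 0)
    moved <- moved + matrix(stats::rnorm(length(moved), sd = sigma), ncol = 3L)
  bond <- P$bond_cap * P$scale
  walk_from <- function(from, len) {
    if (len == 0L) return(matrix(0, 0L, 3L))
    out <- matrix(0, len, 3L)
    cur <- from
    for (i in seq_len(len)) {
      u <- stats::rnorm(3)
      cur <- cur + bond * u / sqrt(sum(u^2))
      out[i, ] <- cur
    }
    out
  }
  pre <- walk_from(moved[1L, ], decoys)[rev(seq_len(decoys)), , drop = FALSE]
  post <- walk_from(moved[k, ], decoys)
  coords <- rbind(pre, moved, post)
  if (P$integral) coords <- round(coords)
  ## isotropic noise can stretch consecutive distances past the cap, so a
  ## noisy plant is not flagged as a protein-mode chain
  Q <- point_sequence(coords, name = "planted", integral = P$integral,
                      protein_mode = sigma == 0, bond_cap = P$bond_cap,
                      scale = P$scale)
  truth <- pair_mapping(cbind(start:(start + k - 1L),
                              (decoys + 1L):(decoys + k)))
  list(Q = Q, truth = truth, transform = invert_transform(T0))
}
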