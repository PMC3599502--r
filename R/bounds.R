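#' Pairwise-distance lower bound on the RMSD
#'
#' A rigid motion preserves intra-structure distances, so discrepancies
#' between the internal distance matrices of the mapped subsets bound the
#' RMSD from below without computing any superposition.  For a permutation
#' `Pi` of the `l` mapped pairs, splitting them into `floor(l/2)` disjoint
#' index pairs `(Pi(i), Pi(i + floor(l/2)))` gives
#'
#' `sqrt( (1 / (2 l)) * sum_i | dP_i - dQ_i |^2 )  <=  RMSD`
#'
#' where `dP_i`, `dQ_i` are the corresponding intra-P and intra-Q distances.
#' For `l = 2` this is tight: the two-point RMSD equals `|dP - dQ| / 2`.
#'
#' @param P,Q [point_sequence()]s or coordinate matrices.
#' @param mapping a [pair_mapping()] with `l >= 2` pairs.
#' @param Pi permutation of `1..l` (default identity) selecting the disjoint
#'   index pairs.
#' @return nonnegative numeric, `<=` the [superpose()] RMSD of the same
#'   mapping.
#' @export
pairdist_lower_bound <- function(P, Q, mapping, Pi = NULL) {
  mc <- mapped_coords(P, Q, mapping)
  l <- nrow(mc$P)
  if (l < 2L) stop("need at least two mapped pairs")
  if (is.null(Pi)) Pi <- seq_len(l)
  if (length(Pi) != l || !setequal(Pi, seq_len(l)))
    stop("Pi is not a permutation of 1..l")
  h <- l %/% 2L
  a <- Pi[seq_len(h)]
  b <- Pi[seq_len(h) + h]
  dp <- sqrt(rowSums((mc$P[a, , drop = FALSE] - mc$P[b, , drop = FALSE])^2))
  dq <- sqrt(rowSums((mc$Q[a, , drop = FALSE] - mc$Q[b, , drop = FALSE])^2))
  sqrt(sum((dp - dq)^2) / (2 * l))
}

#' Minimum nonzero RMSD for integer coordinates (resolution gap)
#'
#' With integer coordinates bounded by `c_max`, squared intra-structure
#' distances are integers at most `12 c_max^2` (the cube diagonal of
#' `[-c_max, c_max]^3` with both endpoints in range), so two unequal
#' distances differ by at least `sqrt(12 c_max^2) - sqrt(12 c_max^2 - 1)`.
#' Via the pairwise-distance lower bound this yields the smallest possible
#' nonzero RMSD
#'
#' `gap(c_max, ell) = ( sqrt(12 c_max^2) - sqrt(12 c_max^2 - 1) ) / sqrt(2 ell)`
#'
#' which also spaces any two distinct achievable RMSD values, and therefore
#' serves as the termination criterion of the MAD-via-LCP binary search.
#'
#' @param c_max maximum absolute coordinate, `>= 1` (at `c_max = 0` only
#'   RMSD 0 is achievable and no gap exists).
#' @param ell subset size, `>= 1`.
#' @return positive numeric gap in length units.
#' @examples
#' resolution_gap(1, 2)   # (sqrt(12) - sqrt(11)) / 2
#' @export
resolution_gap <- function(c_max, ell) {
  stopifnot(ell >= 1L)
  if (c_max < 1) stop("c_max must be >= 1 in the integral regime")
  (sqrt(12 * c_max^2) - sqrt(12 * c_max^2 - 1)) / sqrt(2 * ell)
}

#' Coordinate-bound upper bound on the RMSD
#'
#' Any two points of structures with all coordinates in
#' `[-c_max, c_max]^3` are at most the doubled cube diagonal apart, giving
#' `RMSD <= sqrt(48) * c_max = 4 sqrt(3) c_max` for every mapping and every
#' superposition (equivalently `ell * RMSD^2 <= 48 ell c_max^2`).
#'
#' @param c_max maximum absolute coordinate, `>= 0`.
#' @return nonnegative numeric bound in length units.
#' @export
rmsd_upper_bound <- function(c_max) {
  stopifnot(c_max >= 0)
  sqrt(48) * c_max
}
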