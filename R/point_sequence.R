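#' Ordered 3D point sequence (C-alpha trace)
#'
#' A `point_sequence` models a protein structure for alignment purposes as an
#' ordered sequence of 3D points, one per residue (the C-alpha trace).
#' Coordinates are stored as an n x 3 numeric matrix.  Two optional regimes
#' are tracked as flags:
#'
#' * `integral` -- all coordinates are integers.  This is the regime in which
#'   the exact lattice-enumeration algorithm and the LCP/MAD binary-search
#'   reduction are valid (any fixed-precision input can be scaled up to
#'   integers, e.g. by [scale_to_integral()]).
#' * `protein_mode` -- consecutive points are at most `bond_cap * scale`
#'   apart (default 3.8 length units, the natural upper bound on the distance
#'   between consecutive C-alpha atoms).  For integral sequences a rounding
#'   slack of `sqrt(3)` is allowed on top of the cap, since rounding each
#'   coordinate moves a point by at most `sqrt(3)/2`.
#'
#' @param coords numeric n x 3 matrix (or coercible), one point per row.
#' @param name optional text label.
#' @param integral logical; assert (and check) integer coordinates.
#' @param protein_mode logical; assert (and check) the consecutive-distance
#'   cap.
#' @param bond_cap consecutive-point distance cap in length units at
#'   `scale = 1`; default 3.8.
#' @param scale positive multiplier applied to `bond_cap` for scaled-up
#'   (e.g. PDB-precision) coordinates.
#' @return an object of class `point_sequence`.
#' @examples
#' P <- point_sequence(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 3, 0)))
#' n_points(P)
#' @export
point_sequence <- function(coords, name = "", integral = FALSE,
                           protein_mode = FALSE, bond_cap = 3.8, scale = 1) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) < 1L)
    stop("a point_sequence needs at least one point")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates")
  if (integral && !all(coords == round(coords)))
    stop("integral = TRUE but coordinates are not integers")
  if (protein_mode && nrow(coords) >= 2L) {
    step <- consecutive_distances(coords)
    cap <- bond_cap * scale + if (integral) sqrt(3) else 0
    if (any(step > cap + 1e-9))
      stop(sprintf("protein_mode: consecutive-point distance %.4f exceeds cap %.4f",
                   max(step), cap))
  }
  structure(
    list(coords = coords, name = as.character(name)[1L],
         integral = isTRUE(integral), protein_mode = isTRUE(protein_mode),
         bond_cap = bond_cap, scale = scale),
    class = "point_sequence")
}

## coerce to an n x 3 double matrix with canonical column names
as_coord_matrix <- function(x) {
  if (inherits(x, "point_sequence")) return(x$coords)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L) stop("coordinate vector length not a multiple of 3")
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  storage.mode(x) <- "double"
  dimnames(x) <- list(NULL, c("x", "y", "z"))
  x
}

consecutive_distances <- function(coords) {
  if (nrow(coords) < 2L) return(numeric(0))
  d <- diff(coords)
  sqrt(rowSums(d^2))
}

#' @export
print.point_sequence <- function(x, ...) {
  cat(sprintf("point_sequence '%s': %d points, c_max = %g%s%s\n",
              x$name, n_points(x), c_max(x),
              if (x$integral) ", integral" else "",
              if (x$protein_mode) sprintf(", protein_mode (cap %g x %g)",
                                          x$bond_cap, x$scale) else ""))
  invisible(x)
}

#' Number of points in a sequence
#' @param P a [point_sequence()] or coordinate matrix.
#' @return integer count.
#' @export
n_points <- function(P) nrow(as_coord_matrix(P))

#' Maximum absolute coordinate
#'
#' `c_max` is the largest absolute coordinate value over one or more
#' structures.  It bounds the achievable RMSD (see [rmsd_upper_bound()]) and
#' sets the lattice ranges of the exact enumeration algorithm.  For connected
#' chains anchored at the origin it is O(n); for globular structures
#' O(n^(1/3)).
#'
#' @param ... point sequences or coordinate matrices.
#' @return nonnegative numeric scalar.
#' @export
c_max <- function(...) {
  xs <- lapply(list(...), as_coord_matrix)
  max(vapply(xs, function(m) max(abs(m)), numeric(1)))
}

#' Scale coordinates to the integer lattice
#'
#' Multiplies coordinates by `10^k` and rounds, turning fixed-precision
#' decimal coordinates (PDB files carry three decimals) into exact integers.
#' The resulting sequence has `integral = TRUE` and, when the input was in
#' protein mode, keeps the consecutive-distance cap with `scale = 10^k`.
#'
#' @param P a [point_sequence()].
#' @param k decimal places to absorb; default 3 (PDB precision).
#' @return an integral [point_sequence()].
#' @export
scale_to_integral <- function(P, k = 3L) {
  stopifnot(inherits(P, "point_sequence"), k >= 0L)
  point_sequence(round(P$coords * 10^k), name = P$name, integral = TRUE,
                 protein_mode = P$protein_mode, bond_cap = P$bond_cap,
                 scale = P$scale * 10^k)
}

#' Index-pair mapping between two point sequences
#'
#' A (partial) bijection between points of `P` and points of `Q`, stored as a
#' two-column integer matrix of (i, j) pairs, 1-based.  A mapping is
#' *sequential* when both index columns are strictly increasing along the
#' list, i.e. it preserves residue order in both structures.
#'
#' @param pairs two-column matrix (or data.frame) of (i, j) index pairs.
#' @param sequential logical; check and record order preservation.
#' @param n,m optional lengths of the target sequences for bounds checking.
#' @return an object of class `pair_mapping`.
#' @examples
#' pair_mapping(cbind(1:3, 2:4), sequential = TRUE)
#' @export
pair_mapping <- function(pairs, sequential = NA, n = NULL, m = NULL) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) pairs <- matrix(integer(0), ncol = 2L)
  if (ncol(pairs) != 2L) stop("pairs must have two columns (i, j)")
  storage.mode(pairs) <- "integer"
  dimnames(pairs) <- list(NULL, c("i", "j"))
  if (anyDuplicated(pairs[, 1L]) || anyDuplicated(pairs[, 2L]))
    stop("mapping is not a bijection: duplicated indices")
  if (any(pairs < 1L)) stop("indices must be >= 1")
  if (!is.null(n) && any(pairs[, 1L] > n)) stop("i index out of range")
  if (!is.null(m) && any(pairs[, 2L] > m)) stop("j index out of range")
  is_seq <- nrow(pairs) <= 1L ||
    (all(diff(pairs[, 1L]) > 0L) && all(diff(pairs[, 2L]) > 0L))
  if (isTRUE(sequential) && !is_seq)
    stop("mapping is not sequential (indices must strictly increase)")
  structure(list(pairs = pairs, sequential = is_seq), class = "pair_mapping")
}

#' @export
print.pair_mapping <- function(x, ...) {
  cat(sprintf("pair_mapping: %d pairs%s\n", nrow(x$pairs),
              if (x$sequential) " (sequential)" else ""))
  invisible(x)
}

#' Identity mapping of the first k positions
#' @param k number of pairs.
#' @return a sequential [pair_mapping()] (1,1),...,(k,k).
#' @export
identity_mapping <- function(k) pair_mapping(cbind(seq_len(k), seq_len(k)))

#' Alignment result container
#'
#' Bundles the output of an LCP or MAD solver: the mapping, the rigid
#' transform that realizes the reported RMSD (mapping Q onto P), the RMSD
#' itself, and the alignment size.
#'
#' @param mapping a [pair_mapping()].
#' @param transform a [rigid_transform()] or NULL.
#' @param rmsd nonnegative RMSD in length units.
#' @param method text label of the producing algorithm.
#' @param exact logical; FALSE flags heuristic (e.g. rotation-sampled)
#'   results.
#' @param extra optional named list of solver diagnostics.
#' @return an object of class `alignment_result`.
#' @export
alignment_result <- function(mapping, transform = NULL, rmsd,
                             method = "", exact = TRUE, extra = list()) {
  stopifnot(inherits(mapping, "pair_mapping"), rmsd >= -1e-12)
  structure(
    list(mapping = mapping, transform = transform, rmsd = max(rmsd, 0),
         size = nrow(mapping$pairs), method = method, exact = exact,
         extra = extra),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result [%s%s]: size = %d, rmsd = %.6g\n",
              x$method, if (x$exact) "" else ", heuristic (not exact)",
              x$size, x$rmsd))
  invisible(x)
}

## coordinates of the mapped pairs: list(P = l x 3, Q = l x 3)
mapped_coords <- function(P, Q, mapping) {
  cp <- as_coord_matrix(P)
  cq <- as_coord_matrix(Q)
  pr <- mapping$pairs
  if (nrow(pr) == 0L) stop("empty mapping")
  if (max(pr[, 1L]) > nrow(cp) || max(pr[, 2L]) > nrow(cq))
    stop("mapping index out of range")
  list(P = cp[pr[, 1L], , drop = FALSE], Q = cq[pr[, 2L], , drop = FALSE])
}
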