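#' Lattice specification for the exact enumeration algorithm
#'
#' For integral coordinates, the optimal MAD superposition is determined by
#' lattice quantities: the centering translations `t_P`, `t_Q` are centroids
#' of `ell` integer points, so each coordinate is `I / ell` with integer
#' `|I| <= ell * c_max`; and each entry of the 3 x 3 correlation matrix of
#' the centered subsets is `I / ell^2` with integer
#' `|I| <= 4 ell^3 c_max^2` (entry magnitude `<= 4 ell c_max^2`).
#' Enumerating all lattice points and solving the fixed-transform problem at
#' each yields the exact optimum -- pseudo-polynomially many cases, but far
#' too many to run in full at any scale (the matrix lattice alone has
#' `(8 ell^3 c_max^2 + 1)^9` points).  A `lattice_spec` therefore carries
#' explicit numerator sub-ranges; full ranges assert exactness, restricted
#' ranges give a labelled lower-coverage run whose scanned fraction is
#' always reported.
#'
#' @param ell alignment size.
#' @param c_max maximum absolute coordinate of the instance (integer).
#' @param tp,tq per-axis translation numerators: list of 3 integer vectors
#'   (values `I`, meaning `t = I / ell`), or `NULL` for the full range
#'   `-ell*c_max .. ell*c_max`.
#' @param m_entries per-entry matrix numerators: list of 9 integer vectors
#'   (values `I`, meaning entry `I / ell^2`), or `NULL` for the full range.
#' @param single_translation use the collapsed single-translation form
#'   `q -> R q - t` (enumerates only `tq`-style numerators over the combined
#'   translation) instead of the two-translation form
#'   `q -> R (q - t_Q) + t_P`.
#' @return an object of class `lattice_spec`.
#' @export
lattice_spec <- function(ell, c_max, tp = NULL, tq = NULL, m_entries = NULL,
                         single_translation = FALSE) {
  stopifnot(ell >= 1L, c_max >= 0)
  t_range <- seq.int(-ell * c_max, ell * c_max)
  m_range_card <- 8 * ell^3 * c_max^2 + 1
  fill3 <- function(x) if (is.null(x)) rep(list(t_range), 3L) else x
  spec <- structure(list(
    ell = ell, c_max = c_max,
    tp = fill3(tp), tq = fill3(tq),
    m_entries = m_entries,   # NULL means full range, materialized lazily
    m_full_range = c(-4 * ell^3 * c_max^2, 4 * ell^3 * c_max^2),
    single_translation = single_translation), class = "lattice_spec")
  spec
}

#' @export
print.lattice_spec <- function(x, ...) {
  card <- lattice_cardinality(x)
  cat(sprintf(
    "lattice_spec: ell = %d, c_max = %g (%s-translation form)\n", x$ell,
    x$c_max, if (x$single_translation) "single" else "two"))
  cat(sprintf("  full lattice: %.4g transforms; selected: %.4g (coverage %.3g)\n",
              card$full, card$selected, card$selected / card$full))
  invisible(x)
}

#' Cardinalities of a lattice specification
#'
#' Closed-form counts (never materialized): the full translation lattice has
#' `(2 ell c_max + 1)^3` points per translation and the matrix lattice
#' `(8 ell^3 c_max^2 + 1)^9` points.
#'
#' @param spec a [lattice_spec()].
#' @return list with `full` and `selected` transform counts.
#' @export
lattice_cardinality <- function(spec) {
  t_axis <- 2 * spec$ell * spec$c_max + 1
  m_axis <- 8 * spec$ell^3 * spec$c_max^2 + 1
  n_tr <- if (spec$single_translation) t_axis^3 else t_axis^6
  full <- n_tr * m_axis^9
  sel_t <- prod(vapply(spec$tp, length, numeric(1)))
  if (!spec$single_translation)
    sel_t <- sel_t * prod(vapply(spec$tq, length, numeric(1)))
  sel_m <- if (is.null(spec$m_entries)) m_axis^9
           else prod(vapply(spec$m_entries, length, numeric(1)))
  list(full = full, selected = sel_t * sel_m)
}

#' Exact MAD by lattice enumeration
#'
#' The pseudo-polynomial algorithm: for every enumerated combination of
#' centering translations and correlation-matrix lattice point, derive the
#' rotation by SVD ([rotation_from_m()]), map the Q side by
#' `q -> R (q - t_Q) + t_P` (or `q -> R q - t` in single-translation mode),
#' solve the resulting fixed-transform MAD with the DP, and keep the
#' minimum.  With full lattice ranges the result is the exact MAD optimum;
#' with restricted ranges it is an upper bound, and the scanned fraction of
#' the lattice is reported in `$extra$coverage`.
#'
#' @param P,Q integral [point_sequence()]s.
#' @param ell alignment size.
#' @param spec a [lattice_spec()]; its selected cardinality must not exceed
#'   `budget`.
#' @param sequential restrict to order-preserving mappings (DP) or not
#'   (min-cost flow).
#' @param budget refuse enumerations larger than this many transforms.
#' @return an [alignment_result()]; `$extra$coverage` is the scanned
#'   fraction, `$extra$lattice_point` the best transform's numerators.
#' @export
solve_mad_enumerated <- function(P, Q, ell, spec, sequential = TRUE,
                                 budget = 2e5) {
  if (!is_integral(P) || !is_integral(Q))
    stop("integral coordinates required")
  n <- n_points(P); m <- n_points(Q)
  if (ell < 1L || ell > min(n, m))
    stop(sprintf("ell must be in [1, %d]", min(n, m)))
  stopifnot(inherits(spec, "lattice_spec"), spec$ell == ell)
  card <- lattice_cardinality(spec)
  if (card$selected > budget)
    stop(sprintf(
      "enumeration of %.4g transforms exceeds the budget (%g); restrict the lattice_spec ranges",
      card$selected, budget))
  m_lists <- spec$m_entries
  if (is.null(m_lists))
    m_lists <- rep(list(seq.int(spec$m_full_range[1L], spec$m_full_range[2L])),
                   9L)
  t_lists <- if (spec$single_translation) spec$tp else c(spec$tp, spec$tq)
  t_grid <- as.matrix(expand.grid(t_lists)) / ell
  m_grid <- as.matrix(expand.grid(m_lists)) / ell^2
  cq <- as_coord_matrix(Q)
  best <- NULL
  for (ti in seq_len(nrow(t_grid))) {
    tv <- t_grid[ti, ]
    for (mi in seq_len(nrow(m_grid))) {
      M <- matrix(m_grid[mi, ], 3L, 3L)   # column-major: M[u,v] = U_P . V_Q
      R <- rotation_from_m(M)
      T <- if (spec$single_translation)
        rigid_transform(R, -tv[1:3], tol = 1e-6)
      else   # q -> R (q - t_Q) + t_P
        rigid_transform(R, tv[1:3] - as.vector(R %*% tv[4:6]), tol = 1e-6)
      sol <- if (sequential) mad_fixed_transform(P, Q, T, ell)
             else nonsequential_fixed_transform(P, Q, T, "mad", ell = ell)
      if (is.null(best) || sol$rmsd < best$rmsd) {
        best <- sol
        best$extra <- list(lattice_point = list(t = tv * ell,
                                                m = m_grid[mi, ] * ell^2))
      }
    }
  }
  best$method <- "mad_enumerated"
  best$exact <- card$selected >= card$full
  best$extra$coverage <- card$selected / card$full
  best
}

#' Exact LCP by lattice enumeration
#'
#' Runs [solve_mad_enumerated()] for `ell = min(n, m)` downwards and returns
#' the largest `ell` whose enumerated MAD RMSD is `<= theta` (early exit at
#' the first feasible size).  The caller supplies a `lattice_spec` per size
#' via `spec_for`, since lattice ranges depend on `ell`.
#'
#' @inheritParams solve_mad_enumerated
#' @param theta RMSD threshold, `>= 0`.
#' @param spec_for callable `ell -> lattice_spec`.
#' @return an [alignment_result()] (size 0 when no size fits).
#' @export
solve_lcp_enumerated <- function(P, Q, theta, spec_for, sequential = TRUE,
                                 budget = 2e5) {
  stopifnot(theta >= 0)
  kmax <- min(n_points(P), n_points(Q))
  for (ell in rev(seq_len(kmax))) {
    sol <- solve_mad_enumerated(P, Q, ell, spec_for(ell),
                                sequential = sequential, budget = budget)
    if (sol$rmsd <= theta + 1e-7) {
      sol$method <- "lcp_enumerated"
      sol$extra$theta <- theta
      return(sol)
    }
  }
  alignment_result(pair_mapping(matrix(integer(0), ncol = 2L)),
                   identity_transform(), 0, method = "lcp_enumerated",
                   exact = FALSE, extra = list(theta = theta))
}

#' Lattice spec restricted to the neighborhood of a known transform
#'
#' Convenience builder for conditional-exactness runs: snaps a known optimal
#' subset's centroid translations and correlation matrix to their lattice
#' numerators and returns a [lattice_spec()] covering just those points
#' (plus `halo` lattice steps on each side).
#'
#' @param P,Q integral [point_sequence()]s.
#' @param mapping the subset's [pair_mapping()].
#' @param c_max instance `c_max` (defaults to computing it from P and Q).
#' @param halo nonnegative integer number of neighboring lattice steps to
#'   include per axis/entry.
#' @return a [lattice_spec()].
#' @export
lattice_spec_around <- function(P, Q, mapping, c_max = NULL, halo = 0L) {
  lp <- lattice_point_of(P, Q, mapping)
  ell <- nrow(mapping$pairs)
  if (is.null(c_max))   # the argument shadows the c_max() accessor
    c_max <- ceiling(max(abs(as_coord_matrix(P)), abs(as_coord_matrix(Q))))
  rng <- function(i) seq.int(i - halo, i + halo)
  lattice_spec(
    ell, c_max,
    tp = lapply(lp$tp_num, rng),
    tq = lapply(lp$tq_num, rng),
    m_entries = lapply(lp$m_num, rng))
}

## exact lattice numerators of a subset's centering translations and
## correlation matrix.  All-integer arithmetic:
##   t_P = S_P / ell            (S_P = column sums of the P subset)
##   M[u,v] = (ell * sum p_u q_v - S_P[u] S_Q[v]) / ell^2
lattice_point_of <- function(P, Q, mapping) {
  mc <- mapped_coords(P, Q, mapping)
  ell <- nrow(mc$P)
  SP <- colSums(mc$P)
  SQ <- colSums(mc$Q)
  PQ <- crossprod(mc$P, mc$Q)          # sum over k of p_u q_v
  m_num <- ell * PQ - outer(SP, SQ)    # numerator of I / ell^2
  list(ell = ell, tp_num = as.list(SP), tq_num = as.list(SQ),
       m_num = as.list(as.vector(m_num)))
}

#' Verify the lattice membership of an oracle-optimal transform
#'
#' Computes the brute-force-optimal `ell`-subset, then checks in exact
#' integer arithmetic that (a) the centroid translations `t_P`, `t_Q` have
#' coordinates of the form `I / ell` with `|I| <= ell * c_max` (i.e. within
#' `[-c_max, c_max]`), and (b) every correlation-matrix entry is of the form
#' `I / ell^2` with `|I| <= 4 ell^3 c_max^2` (entry magnitude
#' `<= 4 ell c_max^2`).  These are the facts that make the enumeration
#' lattice finite.
#'
#' @param P,Q integral [point_sequence()]s (brute force must be feasible).
#' @param ell subset size.
#' @param sequential restrict the oracle to order-preserving mappings.
#' @return a list with `pass` (logical), the numerator `witnesses`, and the
#'   checked `bounds`.
#' @export
lattice_membership_check <- function(P, Q, ell, sequential = TRUE) {
  if (!is_integral(P) || !is_integral(Q))
    stop("integral coordinates required")
  oracle <- brute_force_mad(P, Q, ell, sequential = sequential)
  lp <- lattice_point_of(P, Q, oracle$mapping)
  cm <- c_max(P, Q)
  tp_num <- unlist(lp$tp_num)
  tq_num <- unlist(lp$tq_num)
  m_num <- unlist(lp$m_num)
  ## integrality is structural (sums of integers); assert anyway
  pass <- all(tp_num == round(tp_num)) && all(tq_num == round(tq_num)) &&
    all(m_num == round(m_num)) &&
    all(abs(tp_num) <= ell * cm) && all(abs(tq_num) <= ell * cm) &&
    all(abs(m_num) <= 4 * ell^3 * cm^2)
  list(pass = pass,
       witnesses = list(tp_num = tp_num, tq_num = tq_num, m_num = m_num,
                        oracle_rmsd = oracle$rmsd),
       bounds = list(t_num = ell * cm, m_num = 4 * ell^3 * cm^2))
}
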