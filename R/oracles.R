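#' Brute-force MAD solver (reference oracle)
#'
#' Exhausts all `ell`-subsets of both structures (all order-preserving
#' subset pairs in the sequential case, additionally all bijections in the
#' non-sequential case), superposes each candidate optimally (Kabsch), and
#' returns the global minimum RMSD.  Exact by construction; used as ground
#' truth in every equivalence test.  When `transform` is supplied, candidates
#' are scored at that fixed transform instead of being re-superposed, giving
#' the fixed-transform oracle for the DP and flow solvers (exact integer
#' squared sums on integral inputs).
#'
#' @param P,Q [point_sequence()]s or coordinate matrices.
#' @param ell alignment size, `1 <= ell <= min(n, m)`.
#' @param sequential logical; restrict to order-preserving mappings.
#' @param transform optional [rigid_transform()]; score at this fixed
#'   transform (no re-superposition).
#' @param budget refuse instances with more candidate mappings than this
#'   (default 1e6).
#' @return an [alignment_result()].
#' @export
brute_force_mad <- function(P, Q, ell, sequential = TRUE, transform = NULL,
                            budget = 1e6) {
  n <- n_points(P); m <- n_points(Q)
  if (ell < 1L || ell > min(n, m))
    stop(sprintf("ell must be in [1, %d]", min(n, m)))
  count <- choose(n, ell) * choose(m, ell) *
    if (sequential) 1 else factorial(ell)
  if (count > budget)
    stop(sprintf("brute force budget exceeded: %.3g candidate mappings", count))
  fixed <- !is.null(transform)
  d <- if (fixed) pair_cost_matrix(P, Q, transform) else NULL
  perms <- if (sequential) list(seq_len(ell)) else perm_list(ell)
  best <- NULL
  for (si in utils::combn(n, ell, simplify = FALSE)) {
    for (sj in utils::combn(m, ell, simplify = FALSE)) {
      for (pm in perms) {
        pairs <- cbind(si, sj[pm])
        if (fixed) {
          cost <- sum(d[pairs])
          score <- sqrt(max(cost, 0) / ell)
          tr <- transform
        } else {
          mp <- pair_mapping(pairs)
          sp <- superpose(P, Q, mp)
          score <- sp$rmsd
          tr <- sp$transform
        }
        if (is.null(best) || score < best$score - 1e-15) {
          best <- list(score = score, pairs = pairs, transform = tr)
        }
      }
    }
  }
  alignment_result(pair_mapping(best$pairs), best$transform, best$score,
                   method = if (fixed) "brute_force_mad_fixed"
                            else "brute_force_mad")
}

perm_list <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- perm_list(k - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, ifelse(p >= i, p + 1L, p))
  }
  out
}

#' MAD profile over all sizes (memoized brute force)
#'
#' Computes [brute_force_mad()] for every `ell = 1..min(n, m)` in one pass,
#' so that repeated LCP queries at different thresholds (e.g. inside the
#' binary-search reduction) reuse the same exhaustive scan.
#'
#' @inheritParams brute_force_mad
#' @return a list with `rmsd` (numeric vector indexed by ell) and
#'   `solutions` (list of [alignment_result()]s).
#' @export
brute_force_mad_profile <- function(P, Q, sequential = TRUE, budget = 1e6) {
  kmax <- min(n_points(P), n_points(Q))
  sols <- lapply(seq_len(kmax), function(ell)
    brute_force_mad(P, Q, ell, sequential = sequential, budget = budget))
  list(rmsd = vapply(sols, function(s) s$rmsd, numeric(1)), solutions = sols)
}

#' Brute-force LCP solver (reference oracle)
#'
#' The largest `ell` with brute-force MAD RMSD `<= theta`; among
#' maximum-size mappings the minimum-RMSD one is returned.  A tolerance of
#' `1e-7` absorbs SVD round-off so exactly congruent integer subsets pass a
#' `theta = 0` query.
#'
#' @inheritParams brute_force_mad
#' @param theta RMSD threshold, `>= 0`.
#' @param profile optional precomputed [brute_force_mad_profile()].
#' @return an [alignment_result()] (size 0 when even a single pair misses,
#'   which cannot happen since one pair always superposes exactly).
#' @export
brute_force_lcp <- function(P, Q, theta, sequential = TRUE, budget = 1e6,
                            profile = NULL) {
  stopifnot(theta >= 0)
  if (is.null(profile))
    profile <- brute_force_mad_profile(P, Q, sequential = sequential,
                                       budget = budget)
  ok <- which(profile$rmsd <= theta + 1e-7)
  if (length(ok) == 0L)
    return(alignment_result(pair_mapping(matrix(integer(0), ncol = 2L)),
                            identity_transform(), 0,
                            method = "brute_force_lcp"))
  sol <- profile$solutions[[max(ok)]]
  sol$method <- "brute_force_lcp"
  sol$extra <- list(theta = theta)
  sol
}
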