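#' Solve MAD by binary search over an LCP solver
#'
#' On integral coordinates, distinct achievable RMSD values are spaced at
#' least [resolution_gap()] apart, so the optimal MAD value can be pinned by
#' bisection on the LCP threshold: start with the interval
#' `[0, ell * c_max]`, call the LCP solver at the midpoint, shrink the upper
#' end when the LCP solution has size `>= ell` (threshold feasible) and
#' raise the lower end otherwise, and stop once the interval is narrower
#' than the gap.  The most recent feasible LCP solution is returned; when
#' its size exceeds `ell` it is re-reported at exactly `ell` pairs by
#' dropping the largest-residual pairs and re-superposing.
#'
#' @param lcp_solver a callable `(P, Q, theta) -> alignment_result` solving
#'   the LCP exactly (e.g. a closure over [brute_force_lcp()]).
#' @param P,Q integral [point_sequence()]s.
#' @param ell target alignment size, `1 <= ell <= min(n, m)`.
#' @param upper_start `"table"` for the printed `ell * c_max` start of the
#'   search interval, `"lemma6"` for the tighter coordinate bound
#'   `4 sqrt(3) c_max` (useful for `ell >= 7`).
#' @param verbose log each bisection (theta, feasible, size).
#' @return an [alignment_result()]; `$extra$iterations` counts bisections,
#'   which never exceed [iteration_budget()].
#' @export
mad_via_lcp <- function(lcp_solver, P, Q, ell,
                        upper_start = c("table", "lemma6"), verbose = FALSE) {
  upper_start <- match.arg(upper_start)
  if (!is_integral(P) || !is_integral(Q))
    stop("integral coordinates required: the binary search is not guaranteed to terminate otherwise")
  n <- n_points(P); m <- n_points(Q)
  if (ell < 1L || ell > min(n, m))
    stop(sprintf("ell must be in [1, %d]", min(n, m)))
  cm <- c_max(P, Q)
  if (cm < 1) cm <- 1
  gap <- resolution_gap(cm, ell)
  lo <- 0
  hi <- if (upper_start == "table") ell * cm else rmsd_upper_bound(cm)
  ## seed feasibility at the upper end so a feasible solution always exists
  feasible <- lcp_solver(P, Q, hi)
  if (feasible$size < ell)
    stop("no alignment of the requested size is feasible at the upper threshold; ",
         "try upper_start = \"lemma6\"")
  hist_theta <- hi
  hist_size <- feasible$size
  iter <- 0L
  while (hi - lo > gap) {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    sol <- lcp_solver(P, Q, mid)
    if (any(hist_theta < mid & hist_size > sol$size) ||
        any(hist_theta > mid & hist_size < sol$size))
      stop("solver not monotone")
    hist_theta <- c(hist_theta, mid)
    hist_size <- c(hist_size, sol$size)
    if (verbose)
      message(sprintf("  bisect %2d: theta = %.6f  size = %d  %s",
                      iter, mid, sol$size,
                      if (sol$size >= ell) "feasible" else "infeasible"))
    if (sol$size >= ell) {
      hi <- mid
      feasible <- sol
    } else lo <- mid
  }
  out <- report_at_size(P, Q, feasible, ell)
  out$method <- "mad_via_lcp"
  out$extra <- list(iterations = iter, gap = gap,
                    budget = iteration_budget(cm, ell),
                    interval = c(lo, hi))
  out
}

## re-report a feasible solution at exactly ell pairs: drop the
## largest-residual pairs under the solution's own superposition, then
## re-superpose the survivors
report_at_size <- function(P, Q, sol, ell) {
  if (sol$size == ell) return(sol)
  mc <- mapped_coords(P, Q, sol$mapping)
  sp <- superpose(P, Q, sol$mapping)
  res <- rowSums((transform_points(mc$Q, sp$transform) - mc$P)^2)
  keep <- sort(order(res)[seq_len(ell)])
  mapping <- pair_mapping(sol$mapping$pairs[keep, , drop = FALSE])
  sp2 <- superpose(P, Q, mapping)
  alignment_result(mapping, sp2$transform, sp2$rmsd, method = sol$method)
}

is_integral <- function(P) {
  cp <- as_coord_matrix(P)
  all(cp == round(cp))
}

#' Bisection budget of the MAD-via-LCP reduction
#'
#' The binary search halves an interval of initial width `ell * c_max` until
#' it is narrower than [resolution_gap()], so it needs at most
#' `ceil(log2( ell * c_max / gap ))` LCP calls -- logarithmic in `c_max`,
#' which is what makes the reduction polynomial.
#'
#' @inheritParams resolution_gap
#' @return positive integer iteration bound.
#' @export
iteration_budget <- function(c_max, ell) {
  as.integer(ceiling(log2((ell * c_max) / resolution_gap(c_max, ell))))
}
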