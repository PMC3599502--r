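#' Three-index alignment cost table for a fixed superposition
#'
#' When the optimal superposition `T` is known, the sequential LCP and MAD
#' problems reduce to a dynamic program over the table `M[i, j; k]`: the
#' minimum squared-sum cost of `k` matched pairs within the prefixes
#' `(p_1..p_i)` and `(q_1..q_j)`, with pair cost
#' `d[i, j] = || T(q_j) - p_i ||^2`.  The recurrence is
#'
#' `M[i, j; k] = min( M[i-1, j-1; k-1] + d[i, j], M[i, j-1; k], M[i-1, j; k] )`
#'
#' with `M[i, j; 0] = 0` and `M[i, j; k] = Inf` whenever `k > min(i, j)`.
#' Runtime O(n m k_max).
#'
#' @param P,Q [point_sequence()]s or coordinate matrices (n and m points).
#' @param T a [rigid_transform()] applied to the Q side.
#' @param k_max largest number of matched pairs to tabulate,
#'   `1 <= k_max <= min(n, m)`.
#' @return an object of class `dp_table`: a list with the `(n+1) x (m+1) x
#'   (k_max+1)` cost array (`Inf` marks infeasible entries), the cost matrix
#'   `d`, and the dimensions.
#' @export
build_dp <- function(P, Q, T = identity_transform(), k_max) {
  d <- pair_cost_matrix(P, Q, T)
  n <- nrow(d); m <- ncol(d)
  if (k_max < 1L || k_max > min(n, m))
    stop(sprintf("k_max must be in [1, %d]", min(n, m)))
  M <- array(Inf, dim = c(n + 1L, m + 1L, k_max + 1L))
  M[, , 1L] <- 0   # k = 0 costs nothing
  for (k in seq_len(k_max)) {
    for (i in seq_len(n)) {
      ## A[j] = M[i-1, j-1; k-1] + d[i, j];  B[j] = M[i-1, j; k]
      A <- M[i, seq_len(m), k] + d[i, ]
      B <- M[i, seq_len(m) + 1L, k + 1L]
      M[i + 1L, seq_len(m) + 1L, k + 1L] <- cummin(pmin(A, B))
    }
  }
  structure(list(cost = M, d = d, n = n, m = m, k_max = k_max),
            class = "dp_table")
}

#' @export
print.dp_table <- function(x, ...) {
  cat(sprintf("dp_table: n = %d, m = %d, k_max = %d, M[n,m;k_max] = %g\n",
              x$n, x$m, x$k_max, dp_cost(x, x$k_max)))
  invisible(x)
}

#' Optimal k-pair squared-sum cost from a DP table
#' @param dp a [build_dp()] table.
#' @param k number of matched pairs, `0 <= k <= k_max`.
#' @return the minimum squared-sum cost `M[n, m; k]` (Inf if infeasible).
#' @export
dp_cost <- function(dp, k) dp$cost[dp$n + 1L, dp$m + 1L, k + 1L]

## traceback of an optimal k-pair sequential mapping.
## Tie-break: prefer the diagonal (match) move, then the j-skip, then the
## i-skip -- deterministic outputs.
dp_traceback <- function(dp, k) {
  if (k == 0L) return(pair_mapping(matrix(integer(0), ncol = 2L)))
  M <- dp$cost; d <- dp$d
  i <- dp$n; j <- dp$m
  pairs <- matrix(0L, nrow = k, ncol = 2L)
  kk <- k
  tol <- function(v) 1e-9 * max(1, abs(v))
  while (kk > 0L) {
    v <- M[i + 1L, j + 1L, kk + 1L]
    diag_v <- if (i >= 1L && j >= 1L) M[i, j, kk] + d[i, j] else Inf
    if (is.finite(diag_v) && abs(diag_v - v) <= tol(v)) {
      pairs[kk, ] <- c(i, j); i <- i - 1L; j <- j - 1L; kk <- kk - 1L
    } else if (j >= 1L && abs(M[i + 1L, j, kk + 1L] - v) <= tol(v)) {
      j <- j - 1L
    } else if (i >= 1L && abs(M[i, j + 1L, kk + 1L] - v) <= tol(v)) {
      i <- i - 1L
    } else stop("dp_traceback: inconsistent table")   # numerical safety net
  }
  pair_mapping(pairs, sequential = TRUE)
}

## threshold comparison: exact <= on integer costs, tiny relative epsilon
## otherwise (so float noise cannot flip an integral decision)
cost_within <- function(cost, bound) {
  cost <= bound + 1e-12 * max(1, abs(bound))
}

#' Sequential LCP at a fixed superposition
#'
#' Returns the largest `k` such that the optimal `k`-pair squared-sum cost
#' satisfies `M[n, m; k] <= k * theta^2`, together with a realizing
#' sequential mapping (traceback of the DP).  The reported RMSD is the
#' fixed-transform value `sqrt(M[n, m; k] / k)` (0 for the empty result).
#'
#' @inheritParams build_dp
#' @param theta RMSD threshold, `theta >= 0`.
#' @return an [alignment_result()].
#' @export
lcp_fixed_transform <- function(P, Q, T = identity_transform(), theta) {
  stopifnot(theta >= 0)
  n <- n_points(P); m <- n_points(Q)
  dp <- build_dp(P, Q, T, k_max = min(n, m))
  best <- 0L
  for (k in seq_len(dp$k_max))
    if (cost_within(dp_cost(dp, k), k * theta^2)) best <- k
  mapping <- dp_traceback(dp, best)
  rmsd <- if (best > 0L) sqrt(max(dp_cost(dp, best), 0) / best) else 0
  alignment_result(mapping, T, rmsd, method = "lcp_fixed_transform",
                   extra = list(theta = theta))
}

#' Sequential MAD at a fixed superposition
#'
#' Returns a sequential mapping of exactly `ell` pairs minimizing the
#' fixed-transform squared sum, i.e. realizing `M[n, m; ell]`.
#'
#' @inheritParams build_dp
#' @param ell required alignment size, `1 <= ell <= min(n, m)`.
#' @return an [alignment_result()].
#' @export
mad_fixed_transform <- function(P, Q, T = identity_transform(), ell) {
  n <- n_points(P); m <- n_points(Q)
  if (ell < 1L || ell > min(n, m))
    stop(sprintf("ell must be in [1, %d]", min(n, m)))
  dp <- build_dp(P, Q, T, k_max = ell)
  mapping <- dp_traceback(dp, ell)
  alignment_result(mapping, T, sqrt(max(dp_cost(dp, ell), 0) / ell),
                   method = "mad_fixed_transform")
}

#' Non-sequential LCP / MAD at a fixed superposition
#'
#' Order-free matching: selects `k` pairs forming a (partial) bijection
#' minimizing the total fixed-transform cost, via min-cost max-flow on the
#' complete bipartite graph with unit capacities and edge cost
#' `d[i, j] = || T(q_j) - p_i ||^2`.  Successive shortest-path augmentation
#' makes every intermediate flow value `k` optimal for its own size, so the
#' LCP mode reads off the largest `k` with cost `<= k * theta^2` and the MAD
#' mode the `ell`-pair minimum.
#'
#' @inheritParams build_dp
#' @param mode `"lcp"` or `"mad"`.
#' @param theta RMSD threshold (LCP mode).
#' @param ell alignment size (MAD mode).
#' @return an [alignment_result()]; the mapping is generally non-sequential.
#' @export
nonsequential_fixed_transform <- function(P, Q, T = identity_transform(),
                                          mode = c("lcp", "mad"),
                                          theta = NULL, ell = NULL) {
  mode <- match.arg(mode)
  d <- pair_cost_matrix(P, Q, T)
  kmax <- min(nrow(d), ncol(d))
  if (mode == "mad") {
    if (is.null(ell) || ell < 1L || ell > kmax)
      stop(sprintf("ell must be in [1, %d]", kmax))
    kmax <- ell
  } else if (is.null(theta) || theta < 0) stop("theta must be >= 0")
  fl <- min_cost_flow_assignment(d, kmax)
  if (mode == "mad") {
    mapping <- flow_mapping(fl$match[[ell]])
    alignment_result(mapping, T, sqrt(max(fl$cost[ell], 0) / ell),
                     method = "mad_nonsequential")
  } else {
    best <- 0L
    for (k in seq_len(kmax))
      if (cost_within(fl$cost[k], k * theta^2)) best <- k
    mapping <- if (best > 0L) flow_mapping(fl$match[[best]])
               else pair_mapping(matrix(integer(0), ncol = 2L))
    rmsd <- if (best > 0L) sqrt(max(fl$cost[best], 0) / best) else 0
    alignment_result(mapping, T, rmsd, method = "lcp_nonsequential",
                     extra = list(theta = theta))
  }
}

flow_mapping <- function(match_row) {
  idx <- which(match_row > 0L)
  pair_mapping(cbind(idx, match_row[idx]))
}

## Min-cost bipartite matching of every size 1..kmax by successive shortest
## paths (Bellman-Ford on the residual graph; costs >= 0, so no negative
## cycles arise).  Returns cumulative optimal costs and the matching after
## each augmentation.  Intended for desk-scale n, m.
min_cost_flow_assignment <- function(d, kmax) {
  n <- nrow(d); m <- ncol(d)
  match_row <- integer(n)          # 0 = unmatched, else matched column
  match_col <- integer(m)
  costs <- numeric(kmax)
  matches <- vector("list", kmax)
  total <- 0
  for (k in seq_len(kmax)) {
    ## Bellman-Ford over nodes: rows 1..n, cols n+1..n+m, virtual source
    nn <- n + m
    dist <- rep(Inf, nn)
    pred <- integer(nn)            # predecessor node (0 = source side)
    dist[which(match_row == 0L)] <- 0
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        if (!is.finite(dist[i])) next
        ## forward edges i -> j (unmatched pairs)
        for (j in seq_len(m)) {
          if (match_row[i] == j) next
          nd <- dist[i] + d[i, j]
          if (nd < dist[n + j] - 1e-15) {
            dist[n + j] <- nd; pred[n + j] <- i; changed <- TRUE
          }
        }
      }
      for (j in seq_len(m)) {
        if (!is.finite(dist[n + j])) next
        i <- match_col[j]
        if (i > 0L) {              # backward edge j -> i (matched pair)
          nd <- dist[n + j] - d[i, j]
          if (nd < dist[i] - 1e-15) {
            dist[i] <- nd; pred[i] <- n + j; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    free_cols <- which(match_col == 0L)
    if (length(free_cols) == 0L || !any(is.finite(dist[n + free_cols])))
      stop("min_cost_flow_assignment: no augmenting path")
    jend <- free_cols[which.min(dist[n + free_cols])]
    total <- total + dist[n + jend]
    ## augment: walk predecessors back to an unmatched row
    node <- n + jend
    repeat {
      i <- pred[node]              # row preceding this column
      j <- node - n
      match_row[i] <- j; match_col[j] <- i
      node <- pred[i]              # column preceding this row (0 at source)
      if (node == 0L) break
      match_col[node - n] <- 0L    # will be re-set on the next hop
    }
    costs[k] <- total
    matches[[k]] <- match_row
  }
  list(cost = costs, match = matches)
}
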