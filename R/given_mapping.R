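#' Displacement set of a known correspondence
#'
#' For a given bijection `F` between subsequences of P and Q, the residual of
#' pair `i` under a pure translation `t` of the Q side is
#' `|| q'_i + t - p'_i || = || w_i + t ||` with displacement
#' `w_i = q'_i - p'_i`.  Working in the translation space reduces the
#' model-superposition LCP/MAD under translations to geometry on the `w_i`.
#' (Internally the algorithms use `s = -t`, the point in displacement space
#' nearest the selected `w_i`; results are identical.)
#'
#' @param P,Q [point_sequence()]s or coordinate matrices.
#' @param F a [pair_mapping()] with `l >= 1` pairs.
#' @return an object of class `displacement_set`: list with matrix `w`
#'   (l x 3) and the mapping.
#' @export
displacement_set <- function(P, Q, F) {
  mc <- mapped_coords(P, Q, F)
  structure(list(w = mc$Q - mc$P, mapping = F), class = "displacement_set")
}

#' Separating planes of the translation-space arrangement
#'
#' Pairs `i` and `j` swap their residual order exactly on the plane where
#' `|| w_i - s ||^2 = || w_j - s ||^2`, i.e. the perpendicular bisector of
#' `w_i` and `w_j` in displacement space:
#' `2 (w_i - w_j) . s = || w_i ||^2 - || w_j ||^2`.  One plane is emitted per
#' unordered pair with `w_i != w_j`; pairs with equal displacements can never
#' change order and are recorded as always tied.
#'
#' @param D a [displacement_set()] with `l >= 2`.
#' @return a list with `planes` (data.frame: i, j, normal nx/ny/nz, offset)
#'   and `tied` (two-column matrix of always-tied index pairs).
#' @export
build_planes <- function(D) {
  w <- D$w
  l <- nrow(w)
  if (l < 2L) stop("need at least two pairs")
  cmb <- utils::combn(l, 2L)
  ni <- cmb[1L, ]; nj <- cmb[2L, ]
  normal <- 2 * (w[ni, , drop = FALSE] - w[nj, , drop = FALSE])
  offset <- rowSums(w[ni, , drop = FALSE]^2) - rowSums(w[nj, , drop = FALSE]^2)
  deg <- rowSums(normal^2) < 1e-20
  planes <- data.frame(i = ni[!deg], j = nj[!deg],
                       nx = normal[!deg, 1L], ny = normal[!deg, 2L],
                       nz = normal[!deg, 3L], offset = offset[!deg])
  list(planes = planes, tied = cbind(i = ni[deg], j = nj[deg]))
}

plane_normals <- function(planes) as.matrix(planes[, c("nx", "ny", "nz")])

#' Enumerate the cells of a plane arrangement by sign vector
#'
#' Produces at least one interior witness point per full-dimensional cell of
#' the arrangement of the given planes in R^3 (for `k` planes in general
#' position there are `1 + k + C(k,2) + C(k,3)` cells).  Witnesses are built
#' from all vertices (triples of planes), edge points (pairs) and face points
#' (single planes), each perturbed into the adjacent cells by solving for a
#' displacement with prescribed signed distances to the incident planes,
#' plus far-field points on a sphere enclosing the arrangement for unbounded
#' cells that touch no vertex.  Witnesses are deduplicated by sign vector.
#' Exact arrangement construction is deliberately avoided; the brute-force
#' equivalence tests enforce coverage.
#'
#' @param planes the `planes` data.frame from [build_planes()] (may have 0
#'   rows).
#' @return a list of cells; each cell is a list with `witness` (length-3
#'   numeric) and `signs` (integer vector, +1/-1 per plane).
#' @export
enumerate_cells <- function(planes) {
  k <- nrow(planes)
  if (k == 0L)
    return(list(list(witness = c(0, 0, 0), signs = integer(0))))
  N <- plane_normals(planes)
  b <- planes$offset
  nrm <- sqrt(rowSums(N^2))
  Nu <- N / nrm
  bu <- b / nrm
  scale <- max(1, abs(bu))         # typical distance of planes from origin
  cand <- list(matrix(0, 1L, 3L))

  rowcross <- function(A, B)       # rowwise 3D cross product
    cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
          A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
          A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])

  ## perturbation step sizes for a batch of base points lying on the planes
  ## in idx (matrix, one row of plane indices per base): half the distance
  ## to the nearest non-incident plane
  eps_for <- function(V, idx) {
    D <- abs(V %*% t(Nu) - rep(1, nrow(V)) %o% bu)
    for (cc in seq_len(ncol(idx))) D[cbind(seq_len(nrow(V)), idx[, cc])] <- Inf
    dmin <- D[, 1L]
    for (cc in seq_len(ncol(D))[-1L]) dmin <- pmin(dmin, D[, cc])
    e <- pmin(dmin / 2, scale * 1e-3)
    ifelse(is.finite(e) & e > 0, e, scale * 1e-6)
  }

  ## vertices: triples of planes, solved in closed form via Cramer's rule;
  ## all 8 sign-pattern perturbations per vertex
  if (k >= 3L) {
    tri <- t(utils::combn(k, 3L))
    n1 <- Nu[tri[, 1L], , drop = FALSE]
    n2 <- Nu[tri[, 2L], , drop = FALSE]
    n3 <- Nu[tri[, 3L], , drop = FALSE]
    c23 <- rowcross(n2, n3); c31 <- rowcross(n3, n1); c12 <- rowcross(n1, n2)
    dt <- rowSums(n1 * c23)
    ok <- abs(dt) > 1e-10
    if (any(ok)) {
      tri <- tri[ok, , drop = FALSE]
      c1 <- c23[ok, , drop = FALSE] / dt[ok]   # columns of A^{-1}
      c2 <- c31[ok, , drop = FALSE] / dt[ok]
      c3 <- c12[ok, , drop = FALSE] / dt[ok]
      V <- bu[tri[, 1L]] * c1 + bu[tri[, 2L]] * c2 + bu[tri[, 3L]] * c3
      eps <- eps_for(V, tri)
      for (sa in c(-1, 1)) for (sb in c(-1, 1)) for (sc in c(-1, 1))
        cand[[length(cand) + 1L]] <-
          V + eps * (sa * c1 + sb * c2 + sc * c3)
    }
  }
  ## edges: pairs of planes; min-norm point on the intersection line plus
  ## two offsets along it, perturbed into the 4 adjacent sign quadrants
  if (k >= 2L) {
    pr <- t(utils::combn(k, 2L))
    ni <- Nu[pr[, 1L], , drop = FALSE]
    nj <- Nu[pr[, 2L], , drop = FALSE]
    ln <- rowcross(ni, nj)
    lsq <- rowSums(ln^2)
    ok <- lsq > 1e-16                          # drop parallel pairs
    if (any(ok)) {
      pr <- pr[ok, , drop = FALSE]
      ni <- ni[ok, , drop = FALSE]; nj <- nj[ok, , drop = FALSE]
      lhat <- ln[ok, , drop = FALSE] / sqrt(lsq[ok])
      g <- rowSums(ni * nj)
      den <- 1 - g^2
      bi <- bu[pr[, 1L]]; bj <- bu[pr[, 2L]]
      ## u(s) = A' G^{-1} s with G = [[1, g], [g, 1]]
      a1 <- (ni - g * nj) / den                # A' G^{-1} e1
      a2 <- (nj - g * ni) / den                # A' G^{-1} e2
      base0 <- bi * a1 + bj * a2               # min-norm point on the line
      for (tpar in c(0, 3 * scale, -3 * scale)) {
        B <- base0 + tpar * lhat
        eps <- eps_for(B, pr)
        for (si in c(-1, 1)) for (sj in c(-1, 1))
          cand[[length(cand) + 1L]] <- B + eps * (si * a1 + sj * a2)
      }
    }
  }
  ## faces: single planes, both sides
  Bp <- bu * Nu
  eps <- eps_for(Bp, matrix(seq_len(k), ncol = 1L))
  cand[[length(cand) + 1L]] <- Bp + eps * Nu
  cand[[length(cand) + 1L]] <- Bp - eps * Nu
  ## far field: unbounded cells of near-parallel families
  dirs <- rbind(diag(3), -diag(3),
                unname(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))))
  cand[[length(cand) + 1L]] <- 50 * scale * dirs / sqrt(rowSums(dirs^2))

  ## deduplicate by sign vector, discarding on-plane witnesses
  W <- do.call(rbind, cand)
  SG <- W %*% t(Nu) - rep(1, nrow(W)) %o% bu    # signed distances, n x k
  ok <- rowSums(abs(SG) < 1e-12 * scale) == 0L
  W <- W[ok, , drop = FALSE]
  SV <- sign(SG[ok, , drop = FALSE])
  idx <- which(!duplicated(row_keys(SV > 0, 2)))
  lapply(idx, function(i)
    list(witness = as.numeric(W[i, ]), signs = as.integer(SV[i, ])))
}

## optimal translation for a subset of displacements = minus their mean;
## rmsd is the root mean squared deviation of w about its mean
subset_translation_rmsd <- function(w, idx) {
  ws <- w[idx, , drop = FALSE]
  mu <- colMeans(ws)
  list(t = -mu, rmsd = sqrt(sum(sweep(ws, 2L, mu)^2) / length(idx)))
}

## all distinct residual orderings of the pairs over the arrangement cells,
## as a matrix with one order per row.  Ranks are computed by vectorized
## pairwise comparisons (O(l^2) vector ops over all cells at once); ties are
## broken by pair index.
given_mapping_cells <- function(P, Q, F) {
  D <- displacement_set(P, Q, F)
  l <- nrow(D$w)
  if (l == 1L)
    return(list(D = D, orders = matrix(1L, 1L, 1L)))
  pl <- build_planes(D)
  cells <- enumerate_cells(pl$planes)
  ## within-cell ordering ignores the ||witness||^2 term (constant per cell)
  W <- do.call(rbind, lapply(cells, `[[`, "witness"))
  nc <- nrow(W)
  res <- rep(1, nc) %o% rowSums(D$w^2) - 2 * W %*% t(D$w)
  rk <- matrix(1L, nc, l)
  for (i in seq_len(l)) for (j in seq_len(l)) {
    if (i == j) next
    rk[, i] <- rk[, i] + (res[, j] < res[, i] |
                            (res[, j] == res[, i] & j < i))
  }
  ord <- matrix(0L, nc, l)
  rows <- seq_len(nc)
  for (i in seq_len(l)) ord[cbind(rows, rk[, i])] <- i
  list(D = D, orders = ord[!duplicated(row_keys(ord, l + 1L)), , drop = FALSE])
}

## fast row fingerprints: pack small nonnegative integer rows into doubles
## (base^ncol must stay below 2^53), falling back to string keys
row_keys <- function(M, base) {
  k <- ncol(M)
  if (base^k < 2^53) as.vector(M %*% base^(seq_len(k) - 1L))
  else do.call(paste, c(as.data.frame(M), sep = ""))
}

## batch optimal-translation RMSD of index subsets (one subset per row of
## idx): rmsd^2 = ( sum ||w||^2 - ||sum w||^2 / k ) / k
subset_rmsd_batch <- function(w, idx) {
  k <- ncol(idx)
  sq <- rowSums(matrix(rowSums(w^2)[idx], nrow(idx), k))
  s2 <- 0
  for (cc in 1:3) s2 <- s2 + rowSums(matrix(w[, cc][idx], nrow(idx), k))^2
  sqrt(pmax(sq - s2 / k, 0) / k)
}

#' Exact MAD under translations for a known correspondence
#'
#' Model superposition: given the bijection `F` (l pairs) and restricting
#' transforms to translations, finds the `ell`-pair subset of `F` minimizing
#' the optimal-translation RMSD.  Every cell of the translation-space
#' arrangement induces a fixed residual ordering of the pairs; the candidate
#' subsets are the first `ell` pairs of each cell's ordering, and each
#' subset's optimal translation is (minus) the mean of its displacements.
#' Exact: equals brute force over all `ell`-subsets.
#'
#' @param P,Q [point_sequence()]s or coordinate matrices.
#' @param F a [pair_mapping()] (the known correspondence).
#' @param ell subset size, `1 <= ell <= l`.
#' @return an [alignment_result()]; the transform is the pure translation.
#' @export
mad_given_mapping_translation <- function(P, Q, F, ell) {
  l <- nrow(F$pairs)
  if (ell < 1L || ell > l) stop(sprintf("ell must be in [1, %d]", l))
  gc <- given_mapping_cells(P, Q, F)
  prefix <- gc$orders[, seq_len(ell), drop = FALSE]
  rmsds <- subset_rmsd_batch(gc$D$w, prefix)
  b <- which.min(rmsds)
  idx <- sort(prefix[b, ])
  tr <- subset_translation_rmsd(gc$D$w, idx)
  mapping <- pair_mapping(F$pairs[idx, , drop = FALSE])
  alignment_result(mapping, rigid_transform(diag(3), tr$t), tr$rmsd,
                   method = "mad_given_mapping_translation")
}

#' Exact LCP under translations for a known correspondence
#'
#' For each arrangement cell's residual ordering, evaluates the
#' optimal-translation RMSD of every prefix and keeps the longest prefix
#' with RMSD `<= theta`; returns the maximum over cells.
#'
#' @inheritParams mad_given_mapping_translation
#' @param theta RMSD threshold, `theta >= 0`.
#' @return an [alignment_result()] (size 0 with empty mapping when no single
#'   pair fits, which cannot happen under translations since one pair always
#'   fits exactly).
#' @export
lcp_given_mapping_translation <- function(P, Q, F, theta) {
  stopifnot(theta >= 0)
  gc <- given_mapping_cells(P, Q, F)
  eps <- 1e-9 * max(1, theta)
  l <- ncol(gc$orders)
  ## prefix RMSDs for every order at once: cumulative sums column by column
  best_k <- 0L; best <- NULL
  w <- gc$D$w
  sq <- rowSums(w^2)
  csq <- 0; s2 <- list(0, 0, 0)
  feas_k <- rep(0L, nrow(gc$orders))
  for (k in seq_len(l)) {
    col <- gc$orders[, k]
    csq <- csq + sq[col]
    for (cc in 1:3) s2[[cc]] <- s2[[cc]] + w[, cc][col]
    pr2 <- pmax(csq - (s2[[1L]]^2 + s2[[2L]]^2 + s2[[3L]]^2) / k, 0) / k
    feas_k[sqrt(pr2) <= theta + eps] <- k
  }
  if (any(feas_k > 0L)) {
    best_k <- max(feas_k)
    b <- which.max(feas_k)
    idx <- sort(gc$orders[b, seq_len(best_k)])
    tr <- subset_translation_rmsd(w, idx)
    best <- list(idx = idx, t = tr$t, rmsd = tr$rmsd)
  }
  if (best_k == 0L)
    return(alignment_result(pair_mapping(matrix(integer(0), ncol = 2L)),
                            identity_transform(), 0,
                            method = "lcp_given_mapping_translation"))
  mapping <- pair_mapping(F$pairs[best$idx, , drop = FALSE])
  alignment_result(mapping, rigid_transform(diag(3), best$t), best$rmsd,
                   method = "lcp_given_mapping_translation",
                   extra = list(theta = theta))
}

#' Rotation-sampled MAD under full rigid motions (heuristic)
#'
#' Stand-in for the exact sign-condition algorithm over rigid transforms,
#' which is out of scope: samples a uniform grid of ZYZ Euler-angle
#' rotations, rotates the Q side, and runs the exact translation-space
#' solver for each.  The result is explicitly labelled heuristic: its RMSD
#' is an upper bound on (never below) the exact rigid optimum, converging as
#' the grid is refined.
#'
#' @inheritParams mad_given_mapping_translation
#' @param grid_deg grid resolution in degrees (e.g. 15); a value `>= 360`
#'   degenerates to the identity rotation only.
#' @return an [alignment_result()] with `exact = FALSE`; the transform
#'   combines the best grid rotation with its optimal translation.
#' @export
mad_given_mapping_rigid_sampled <- function(P, Q, F, ell, grid_deg = 15) {
  stopifnot(grid_deg >= 1)
  step <- grid_deg * pi / 180
  alphas <- seq(-pi, pi - 1e-9, by = step)
  betas <- seq(0, pi, by = step)
  gammas <- alphas
  if (step >= 2 * pi) { alphas <- 0; betas <- 0; gammas <- 0 }
  cq <- as_coord_matrix(Q)
  best <- NULL
  for (a in alphas) for (b in betas) for (g in gammas) {
    R <- euler_rotation(a, b, g)
    Qrot <- cq %*% t(R)
    res <- mad_given_mapping_translation(P, Qrot, F, ell)
    if (is.null(best) || res$rmsd < best$rmsd) {
      res$transform <- rigid_transform(R, res$transform$translation, tol = 1e-6)
      best <- res
    }
  }
  best$exact <- FALSE
  best$method <- "mad_given_mapping_rigid_sampled"
  best$extra <- list(grid_deg = grid_deg)
  best
}
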