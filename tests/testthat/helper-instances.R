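## Shared fixtures: random integral instances and independent mini-oracles.
## Oracles here are deliberately written from first principles (combn +
## closed forms), independent of the package code paths they check.

rand_int_points <- function(n, cmax = 5L) {
  matrix(sample(seq.int(-cmax, cmax), n * 3L, replace = TRUE), n, 3L)
}

rand_instance <- function(nrange = 4:7, cmax = 5L) {
  n <- sample(nrange, 1L)
  m <- sample(nrange, 1L)
  list(P = rand_int_points(n, cmax), Q = rand_int_points(m, cmax),
       n = n, m = m)
}

## exhaustive sequential fixed-transform optimum: min total cost of k
## order-preserving matches, straight from the cost matrix
bf_seq_fixed <- function(d, k) {
  n <- nrow(d); m <- ncol(d)
  best <- Inf
  for (si in utils::combn(n, k, simplify = FALSE))
    for (sj in utils::combn(m, k, simplify = FALSE)) {
      cost <- sum(d[cbind(si, sj)])
      if (cost < best) best <- cost
    }
  best
}

## exhaustive non-sequential fixed-transform optimum (all bijections)
bf_nonseq_fixed <- function(d, k) {
  n <- nrow(d); m <- ncol(d)
  best <- Inf
  perms <- all_perms(k)
  for (si in utils::combn(n, k, simplify = FALSE))
    for (sj in utils::combn(m, k, simplify = FALSE))
      for (pm in perms) {
        cost <- sum(d[cbind(si, sj[pm])])
        if (cost < best) best <- cost
      }
  best
}

all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k))
    for (p in all_perms(k - 1L))
      out[[length(out) + 1L]] <- c(i, ifelse(p >= i, p + 1L, p))
  out
}

## exhaustive translation-only MAD over ell-subsets of a displacement set
bf_disp_mad <- function(w, ell) {
  best <- Inf
  for (s in utils::combn(nrow(w), ell, simplify = FALSE)) {
    ws <- w[s, , drop = FALSE]
    mu <- colMeans(ws)
    r <- sqrt(sum(sweep(ws, 2L, mu)^2) / ell)
    if (r < best) best <- r
  }
  best
}

## exhaustive rigid MAD over ell-subsets of a known correspondence
## (subset brute force + Kabsch through the public superpose API)
bf_rigid_mad_given_mapping <- function(Pm, Qm, ell) {
  l <- nrow(Pm)
  best <- Inf
  for (s in utils::combn(l, ell, simplify = FALSE)) {
    r <- superpose(Pm[s, , drop = FALSE], Qm[s, , drop = FALSE],
                   identity_mapping(ell))$rmsd
    if (r < best) best <- r
  }
  best
}
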