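test_that("separating planes are perpendicular bisectors in displacement
           space", {
  ## l = 2 worked example: w = (0,0,0) and (2,0,0) -> plane x = 1
  D <- displacement_set(rbind(c(0, 0, 0), c(0, 0, 0)),
                        rbind(c(0, 0, 0), c(2, 0, 0)),
                        identity_mapping(2L))
  pl <- build_planes(D)
  expect_equal(nrow(pl$planes), 1L)
  expect_equal(unlist(pl$planes[1L, c("nx", "ny", "nz", "offset")]),
               c(nx = -4, ny = 0, nz = 0, offset = -4))
  ## equal displacements produce no plane, flagged tied
  D2 <- displacement_set(rbind(c(0, 0, 0), c(1, 1, 1)),
                         rbind(c(2, 0, 0), c(3, 1, 1)),
                         identity_mapping(2L))
  pl2 <- build_planes(D2)
  expect_equal(nrow(pl2$planes), 0L)
  expect_equal(nrow(pl2$tied), 1L)
})

test_that("on-plane points equalize the residuals of their defining pair", {
  set.seed(31)
  for (rep in 1:10) {
    w <- matrix(rnorm(15), 5L, 3L)
    D <- structure(list(w = w, mapping = identity_mapping(5L)),
                   class = "displacement_set")
    pl <- build_planes(D)$planes
    for (r in seq_len(nrow(pl))) {
      nrm <- unlist(pl[r, c("nx", "ny", "nz")])
      ## sample a point on the plane: offset point + in-plane component
      t0 <- pl$offset[r] * nrm / sum(nrm^2)
      u <- rnorm(3)
      t_on <- t0 + (u - sum(u * nrm) / sum(nrm^2) * nrm)
      ri <- sum((w[pl$i[r], ] - t_on)^2)
      rj <- sum((w[pl$j[r], ] - t_on)^2)
      expect_equal(ri, rj, tolerance = 1e-8)
    }
  }
})

test_that("cell enumeration realizes the general-position counting formula", {
  set.seed(32)
  for (k in c(1L, 2L, 3L, 4L, 6L)) {
    N <- matrix(rnorm(k * 3), k, 3L)
    planes <- data.frame(i = seq_len(k), j = seq_len(k), nx = N[, 1L],
                         ny = N[, 2L], nz = N[, 3L], offset = rnorm(k))
    cells <- enumerate_cells(planes)
    expect_equal(length(cells),
                 1L + k + choose(k, 2L) + choose(k, 3L))
    ## witnesses reproduce their recorded sign vectors
    nrm <- sqrt(rowSums(N^2))
    for (cl in cells[seq_len(min(5L, length(cells)))]) {
      sg <- sign((as.vector(N %*% cl$witness) - planes$offset) / nrm)
      expect_equal(as.integer(sg), cl$signs)
    }
  }
})

test_that("witnesses sharing a sign vector share their pair ordering", {
  set.seed(33)
  for (rep in 1:10) {
    Pm <- rand_int_points(6L)
    Qm <- rand_int_points(6L)
    D <- displacement_set(Pm, Qm, identity_mapping(6L))
    pl <- build_planes(D)
    cells <- enumerate_cells(pl$planes)
    N <- rmsdalign:::plane_normals(pl$planes)
    b <- pl$planes$offset
    ordering <- function(t) order(rowSums(sweep(D$w, 2L, t)^2),
                                  seq_len(nrow(D$w)))
    for (cl in cells[sample(length(cells), min(8L, length(cells)))]) {
      ## jitter the witness without crossing any plane
      sg0 <- cl$signs
      for (j in 1:3) {
        t2 <- cl$witness + rnorm(3) * 1e-9
        if (!all(as.integer(sign(as.vector(N %*% t2) - b)) == sg0)) next
        expect_identical(ordering(t2), ordering(cl$witness))
      }
    }
  }
})

test_that("translation-space MAD equals the subset brute force", {
  set.seed(34)
  ## worked example: two identical displacements beat the outlier
  res <- mad_given_mapping_translation(
    rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0)),
    rbind(c(0, 0, 0), c(5, 0, 0), c(6, 5, 0)), identity_mapping(3L), 2L)
  expect_equal(res$rmsd, 0, tolerance = 1e-12)
  expect_equal(res$mapping$pairs[, 1L], c(1L, 2L))
  for (rep in 1:15) {
    l <- sample(3:8, 1L)
    Pm <- rand_int_points(l)
    Qm <- rand_int_points(l)
    ell <- sample(seq_len(l), 1L)
    res <- mad_given_mapping_translation(Pm, Qm, identity_mapping(l), ell)
    expect_equal(res$rmsd, bf_disp_mad(Qm - Pm, ell), tolerance = 1e-9)
    ## the reported transform realizes the reported rmsd
    expect_equal(rmsd_fixed(Pm, Qm, res$mapping, res$transform), res$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("translation-space LCP equals the subset brute force", {
  set.seed(35)
  for (rep in 1:15) {
    l <- sample(3:8, 1L)
    Pm <- rand_int_points(l)
    Qm <- rand_int_points(l)
    w <- Qm - Pm
    theta <- runif(1, 0, 4)
    res <- lcp_given_mapping_translation(Pm, Qm, identity_mapping(l), theta)
    per_size <- sapply(seq_len(l), function(k) bf_disp_mad(w, k))
    expect_equal(res$size, max(c(0L, which(per_size <= theta + 1e-9))))
  }
  ## theta huge keeps all pairs; theta = 0 with distinct displacements keeps 1
  Pm <- rand_int_points(5L)
  Qm <- Pm + matrix(seq_len(15L), 5L, 3L)   # all displacements distinct
  expect_equal(lcp_given_mapping_translation(Pm, Qm, identity_mapping(5L),
                                             1e6)$size, 5L)
  expect_equal(lcp_given_mapping_translation(Pm, Qm, identity_mapping(5L),
                                             0)$size, 1L)
})

test_that("chosen subset has the smallest residuals at its own optimal
           translation (prefix optimality)", {
  set.seed(36)
  for (rep in 1:10) {
    l <- 7L
    Pm <- rand_int_points(l)
    Qm <- rand_int_points(l)
    ell <- sample(2:5, 1L)
    res <- mad_given_mapping_translation(Pm, Qm, identity_mapping(l), ell)
    w <- Qm - Pm
    chosen <- res$mapping$pairs[, 1L]
    t_opt <- -colMeans(w[chosen, , drop = FALSE])
    resid <- rowSums(sweep(w, 2L, -t_opt)^2)
    expect_lte(max(resid[chosen]), min(resid[-chosen]) + 1e-9)
  }
})

test_that("rotation-sampled rigid MAD is a labelled upper bound that tightens
           with the grid", {
  set.seed(37)
  Pm <- rand_int_points(6L, cmax = 4L)
  Qm <- rand_int_points(6L, cmax = 4L)
  F <- identity_mapping(6L)
  ## identity-only grid reduces to the translation solver
  a <- mad_given_mapping_rigid_sampled(Pm, Qm, F, 3L, grid_deg = 360)
  b <- mad_given_mapping_translation(Pm, Qm, F, 3L)
  expect_equal(a$rmsd, b$rmsd, tolerance = 1e-12)
  expect_false(a$exact)
  ## congruent instance under a grid rotation is recovered exactly
  R90 <- euler_rotation(pi / 2, 0, 0)
  Qc <- Pm %*% t(R90)    # Q = R90' applied inverse... rotate P into Q frame
  res0 <- mad_given_mapping_rigid_sampled(Pm, Qc, F, 4L, grid_deg = 90)
  expect_lt(res0$rmsd, 1e-9)
  ## 15-degree grid lands within 10% of the exact rigid optimum
  exact <- bf_rigid_mad_given_mapping(Pm, Qm, 3L)
  res15 <- mad_given_mapping_rigid_sampled(Pm, Qm, F, 3L, grid_deg = 15)
  expect_gte(res15$rmsd, exact - 1e-9)
  expect_lte(res15$rmsd, exact * 1.10)
})
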