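test_that("point_sequence validates its invariants", {
  expect_error(point_sequence(matrix(numeric(0), 0L, 3L)), "at least one")
  expect_error(point_sequence(rbind(c(0, 0, NA))), "non-finite")
  expect_error(point_sequence(rbind(c(0.5, 0, 0)), integral = TRUE),
               "not integers")
  expect_error(point_sequence(rbind(c(0, 0, 0), c(10, 0, 0)),
                              protein_mode = TRUE), "exceeds cap")
  ## rounding slack admitted for integral chains
  P <- point_sequence(rbind(c(0, 0, 0), c(4, 1, 1)), integral = TRUE,
                      protein_mode = TRUE)
  expect_equal(n_points(P), 2L)
  expect_equal(c_max(P), 4)
})

test_that("pair_mapping enforces bijection and sequential order", {
  expect_error(pair_mapping(rbind(c(1, 1), c(1, 2))), "bijection")
  expect_error(pair_mapping(rbind(c(2, 1), c(1, 2)), sequential = TRUE),
               "not sequential")
  m <- pair_mapping(rbind(c(2, 1), c(1, 2)))
  expect_false(m$sequential)
  expect_true(pair_mapping(cbind(1:3, 4:6))$sequential)
  expect_error(pair_mapping(cbind(1:3, 4:6), n = 2L), "out of range")
})

test_that("rigid_transform rejects reflections and non-orthogonal matrices", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "reflections")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthogonal")
  T1 <- rigid_transform(diag(3), c(1, 0, 0))
  expect_equal(apply_transform(rbind(c(0, 0, 0)), T1), rbind(c(1, 0, 0)),
               ignore_attr = TRUE)
})

test_that("apply_transform composes and inverts consistently", {
  set.seed(11)
  for (i in 1:20) {
    T1 <- rigid_transform(random_rotation(), rnorm(3), tol = 1e-6)
    T2 <- rigid_transform(random_rotation(), rnorm(3), tol = 1e-6)
    X <- matrix(rnorm(15), 5L, 3L)
    via_two <- apply_transform(apply_transform(X, T1), T2)
    via_comp <- apply_transform(X, compose_transform(T2, T1))
    expect_equal(via_two, via_comp, tolerance = 1e-9)
    back <- apply_transform(apply_transform(X, T1), invert_transform(T1))
    expect_equal(back, X, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("two-point superposition matches the closed form and a numerical
           minimization over rigid transforms", {
  P <- rbind(c(0, 0, 0), c(4, 0, 0))
  Q <- rbind(c(0, 0, 0), c(2, 0, 0))
  sp <- superpose(P, Q, identity_mapping(2L))
  ## closed form |(||u|| - ||v||)| / 2 for two points
  expect_equal(sp$rmsd, 1.0, tolerance = 1e-12)
  ## independent oracle: numerical minimization over Euler angles + shift
  obj <- function(par) {
    T <- rigid_transform(euler_rotation(par[1], par[2], par[3]), par[4:6],
                         tol = 1e-6)
    rmsd_fixed(P, Q, identity_mapping(2L), T)
  }
  fits <- sapply(1:10, function(i) {
    set.seed(i)
    optim(c(runif(3, -pi, pi), rnorm(3)), obj,
          control = list(maxit = 2000, reltol = 1e-14))$value
  })
  expect_gte(min(fits), sp$rmsd - 1e-5)
})

test_that("superposition of congruent sets recovers the planted transform", {
  set.seed(12)
  for (i in 1:20) {
    Qm <- matrix(rnorm(18), 6L, 3L)
    R0 <- random_rotation()
    t0 <- rnorm(3)
    Pm <- Qm %*% t(R0) + rep(1, 6) %o% t0
    sp <- superpose(Pm, Qm, identity_mapping(6L))
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(sp$transform$rotation, R0, tolerance = 1e-7)
    expect_equal(sp$transform$translation, t0, tolerance = 1e-7)
  }
})

test_that("superpose rmsd is invariant under rigid pre-transformations", {
  set.seed(13)
  for (i in 1:25) {
    inst <- rand_instance()
    mp <- identity_mapping(min(inst$n, inst$m))
    base <- superpose(inst$P, inst$Q, mp)$rmsd
    Tp <- rigid_transform(random_rotation(), rnorm(3), tol = 1e-6)
    Tq <- rigid_transform(random_rotation(), rnorm(3), tol = 1e-6)
    expect_equal(superpose(apply_transform(inst$P, Tp), inst$Q, mp)$rmsd,
                 base, tolerance = 1e-9)
    expect_equal(superpose(inst$P, apply_transform(inst$Q, Tq), mp)$rmsd,
                 base, tolerance = 1e-9)
  }
})

test_that("fixed-transform rmsd dominates the optimal superposition", {
  set.seed(14)
  for (i in 1:1000) {
    n <- sample(2:6, 1L)
    Pm <- matrix(rnorm(n * 3), n, 3L)
    Qm <- matrix(rnorm(n * 3), n, 3L)
    mp <- identity_mapping(n)
    T <- rigid_transform(random_rotation(), rnorm(3), tol = 1e-6)
    expect_gte(rmsd_fixed(Pm, Qm, mp, T) + 1e-12,
               superpose(Pm, Qm, mp)$rmsd)
  }
  expect_equal(rmsd_fixed(c(0, 0, 0), c(1, 2, 2), identity_mapping(1L)), 3.0)
})

test_that("returned rotations are proper even for degenerate configurations", {
  ## collinear and planar configurations exercise the rank-deficient SVD
  P1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  Q1 <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 2, 0))
  sp1 <- superpose(P1, Q1, identity_mapping(3L))
  expect_equal(det(sp1$transform$rotation), 1, tolerance = 1e-9)
  expect_lt(sp1$rmsd, 1e-9)   # congruent collinear sets
  P2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  Q2 <- sweep(P2[, c(2, 1, 3)], 2L, c(1, -1, 1), "*")  # reflected copy
  sp2 <- superpose(P2, Q2, identity_mapping(4L))
  expect_equal(det(sp2$transform$rotation), 1, tolerance = 1e-9)
})

test_that("superpose rmsd is zero iff the mapped subsets are congruent", {
  set.seed(15)
  for (i in 1:20) {
    Qm <- rand_int_points(5L)
    Pm <- apply_transform(Qm, rigid_transform(random_rotation(), rnorm(3),
                                              tol = 1e-6))
    expect_lt(superpose(Pm, Qm, identity_mapping(5L))$rmsd, 1e-9)
    ## perturb one point: distances change, rmsd must be positive
    Pm2 <- Pm
    Pm2[1L, 1L] <- Pm2[1L, 1L] + 1
    expect_gt(superpose(Pm2, Qm, identity_mapping(5L))$rmsd, 1e-6)
  }
})

test_that("scale_to_integral mirrors PDB precision", {
  P <- point_sequence(rbind(c(1.234, -0.001, 2.5), c(3.3, 1.1, -2.25)))
  Pi <- scale_to_integral(P, k = 3L)
  expect_true(Pi$integral)
  expect_equal(Pi$coords[1L, ], c(x = 1234, y = -1, z = 2500))
})
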