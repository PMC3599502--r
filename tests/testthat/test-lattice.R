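test_that("rotation_from_m maximizes the trace objective", {
  expect_equal(rotation_from_m(diag(3)), diag(3), tolerance = 1e-12)
  ## reflective M is sign-corrected to a proper rotation
  M <- diag(c(1, 1, -1))
  R <- rotation_from_m(M)
  expect_equal(det(R), 1, tolerance = 1e-9)
  obj <- sum(R * M)                    # trace(R M')
  set.seed(61)
  sampled <- replicate(10000, sum(random_rotation() * M))
  expect_gte(obj, max(sampled) - 1e-9)
  expect_equal(R, diag(3), tolerance = 1e-9)
  ## M from a congruent pair superposes it exactly
  Qm <- matrix(rnorm(15), 5L, 3L)
  R0 <- random_rotation()
  Pm <- Qm %*% t(R0)
  Pc <- sweep(Pm, 2L, colMeans(Pm))
  Qc <- sweep(Qm, 2L, colMeans(Qm))
  Rhat <- rotation_from_m(crossprod(Pc, Qc))
  expect_equal(max(abs(Qc %*% t(Rhat) - Pc)), 0, tolerance = 1e-9)
})

test_that("lattice cardinalities follow the closed forms", {
  for (ell in c(1L, 2L, 3L)) for (cm in c(1, 2)) {
    spec <- lattice_spec(ell, cm)
    card <- lattice_cardinality(spec)
    t_axis <- 2 * ell * cm + 1
    m_axis <- 8 * ell^3 * cm^2 + 1
    expect_equal(card$full, t_axis^6 * m_axis^9)
    single <- lattice_spec(ell, cm, single_translation = TRUE)
    expect_equal(lattice_cardinality(single)$full, t_axis^3 * m_axis^9)
    ## translation numerators span -ell*c_max .. ell*c_max
    expect_equal(range(spec$tp[[1L]]), c(-ell * cm, ell * cm))
  }
})

test_that("oracle-optimal transforms live on the lattice (membership, exact
           integer arithmetic)", {
  set.seed(62)
  for (rep in 1:40) {
    n <- sample(3:5, 1L)
    m <- sample(3:5, 1L)
    P <- point_sequence(rand_int_points(n, 2L), integral = TRUE)
    Q <- point_sequence(rand_int_points(m, 2L), integral = TRUE)
    ell <- sample(seq_len(min(n, m)), 1L)
    chk <- lattice_membership_check(P, Q, ell)
    expect_true(chk$pass)
    ## witnesses are integers within the stated numerator bounds
    expect_true(all(chk$witnesses$tp_num == round(chk$witnesses$tp_num)))
    expect_true(all(abs(chk$witnesses$m_num) <= chk$bounds$m_num))
  }
  ## ell = 1: centroid translations are plain integers
  P1 <- point_sequence(rbind(c(2, -1, 0), c(0, 0, 3)), integral = TRUE)
  chk1 <- lattice_membership_check(P1, P1, 1L)
  expect_true(chk1$pass)
  expect_error(lattice_membership_check(
    point_sequence(rbind(c(0.5, 0, 0))), P1, 1L), "integral")
})

test_that("enumeration restricted to the oracle-optimal lattice point
           reproduces the oracle optimum", {
  set.seed(63)
  for (rep in 1:10) {
    P <- point_sequence(rand_int_points(3L, 2L), integral = TRUE)
    Q <- point_sequence(rand_int_points(3L, 2L), integral = TRUE)
    ell <- 2L
    oracle <- brute_force_mad(P, Q, ell)
    spec <- lattice_spec_around(P, Q, oracle$mapping)
    res <- solve_mad_enumerated(P, Q, ell, spec)
    expect_equal(res$rmsd, oracle$rmsd, tolerance = 1e-7)
    expect_lt(res$extra$coverage, 1)
    expect_false(res$exact)            # restricted run is labelled as such
    ## enumerated result never beats the oracle
    expect_gte(res$rmsd, oracle$rmsd - 1e-9)
  }
})

test_that("planted congruent fragment is found from its lattice
           neighborhood", {
  set.seed(64)
  P <- generate_chain(6L, seed = 101L)
  pl <- plant_common_fragment(P, 2L, 3L, sigma = 0, decoys = 1L, seed = 102L)
  oracle <- brute_force_mad(P, pl$Q, 3L)
  expect_lt(oracle$rmsd, 1e-9)
  spec <- lattice_spec_around(P, pl$Q, oracle$mapping)
  res <- solve_mad_enumerated(P, pl$Q, 3L, spec)
  expect_lt(res$rmsd, 1e-9)
})

test_that("lcp enumeration iterates sizes and honors theta", {
  set.seed(65)
  P <- point_sequence(rand_int_points(4L, 2L), integral = TRUE)
  Q <- point_sequence(rand_int_points(4L, 2L), integral = TRUE)
  profile <- brute_force_mad_profile(P, Q)
  spec_for <- function(ell)
    lattice_spec_around(P, Q, profile$solutions[[ell]]$mapping)
  ## huge theta matches everything
  big <- rmsd_upper_bound(c_max(P, Q)) + 1
  expect_equal(solve_lcp_enumerated(P, Q, big, spec_for)$size, 4L)
  ## generic theta agrees with the brute-force LCP size
  th <- profile$rmsd[2L] + 1e-6
  bf <- brute_force_lcp(P, Q, th, profile = profile)
  expect_equal(solve_lcp_enumerated(P, Q, th, spec_for)$size, bf$size)
})

test_that("enumeration guardrails: budget and integrality", {
  P <- point_sequence(rand_int_points(3L, 2L), integral = TRUE)
  expect_error(solve_mad_enumerated(P, P, 2L, lattice_spec(2L, 2)),
               "budget")
  Pf <- point_sequence(rbind(c(0.5, 0, 0), c(1, 1, 1)))
  expect_error(
    solve_mad_enumerated(Pf, P, 1L,
                         lattice_spec(1L, 2, tp = rep(list(0L), 3L),
                                      tq = rep(list(0L), 3L),
                                      m_entries = rep(list(0L), 9L))),
    "integral")
})
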