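params <- tb_params()


test_that("build_hamiltonian follows the on-site/hopping contract", {
  one <- atomic_system("C", matrix(0, 1, 3))
  expect_equal(build_hamiltonian(one, params), matrix(-6, 1, 1))

  # two identical sites at exactly r0: off-diagonal is t0 * exp(0) = t0
  two <- atomic_system(c("C", "C"), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  H <- build_hamiltonian(two, params)
  expect_equal(H[1, 2], -1.0)
  expect_equal(H, t(H))

  # different fragment labels: zero coupling at any distance
  split2 <- atomic_system(c("C", "C"), rbind(c(0, 0, 0), c(1.4, 0, 0)),
                          fragment = c(0L, 1L))
  expect_equal(build_hamiltonian(split2, params)[1, 2], 0)

  # beyond the 2 r0 cutoff: zero coupling
  far <- atomic_system(c("C", "C"), rbind(c(0, 0, 0), c(2.81, 0, 0)))
  expect_equal(build_hamiltonian(far, params)[1, 2], 0)

  expect_error(
    build_hamiltonian(atomic_system("Zz", matrix(0, 1, 3)), params),
    "onsite_table")
})

test_that("solve_orbitals matches the two-site closed form", {
  two <- atomic_system(c("C", "C"), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  H <- build_hamiltonian(two, params)
  sol <- solve_orbitals(H, params, mode = "max")
  expect_equal(sol$values, c(-7, -5))             # alpha +/- |t|
  expect_equal(sol$reference$target_energy, -7)   # 1 occupied orbital
  expect_equal(sol$reference$l_frac, c(0.5, 0.5))
  expect_equal(sol$reference$L, 0)
  expect_error(solve_orbitals(matrix(c(0, 1, 0, 0), 2, 2), params),
               "symmetric")
})

test_that("eigensolver agrees with the characteristic-polynomial oracle", {
  set.seed(101)
  for (case in 1:20) {
    n <- sample(3:8, 1)
    A <- matrix(rnorm(n * n), n, n)
    H <- (A + t(A)) / 2 - 6 * diag(n)
    sol <- solve_orbitals(H, params, mode = "max")
    expect_lt(max(abs(sol$values - charpoly_eigenvalues(H))), 1e-8)
    # orthonormal eigenvectors
    V <- sol$vectors
    expect_lt(max(abs(crossprod(V) - diag(n))), 1e-8)
  }
})

test_that("degenerate HOMOs get basis-invariant subspace-averaged fractions", {
  # two uncoupled identical dimers: HOMO doubly degenerate
  sys <- atomic_system(rep("C", 4),
                       rbind(c(0, 0, 0), c(1.4, 0, 0),
                             c(50, 0, 0), c(51.4, 0, 0)),
                       fragment = c(0L, 0L, 1L, 1L))
  sol <- solve_orbitals(build_hamiltonian(sys, params), params)
  expect_true(sol$degenerate)
  expect_equal(sol$reference$l_frac, rep(0.25, 4), tolerance = 1e-10)
})

test_that("generated datasets are deterministic and span both L regimes", {
  cfg <- generator_config(n_molecules = 500, seed = 1)
  d1 <- suppressWarnings(generate_dataset(cfg, params))
  d2 <- suppressWarnings(generate_dataset(cfg, params))
  expect_identical(d1$coords, d2$coords)
  expect_identical(d1$target_energy, d2$target_energy)
  expect_identical(d1$l_frac, d2$l_frac)

  # localization fractions are exactly normalized
  expect_true(all(abs(map_dbl_(d1$l_frac, sum) - 1) < 1e-10))

  # stated L-distribution contract at default settings
  expect_gte(mean(d1$L >= 0.8), 0.05)
  expect_gte(mean(d1$L < 0.4), 0.20)
})

test_that("weakly coupled in-gap substituents localize the HOMO", {
  # conjugated 5-site chain with a substituent level inside the occupied
  # manifold, attached at a weak-coupling distance
  r0 <- 1.4
  bb <- atomic_system(
    c(rep("C", 5), "S1"),
    rbind(t(sapply(0:4, function(j) c(j * r0 * sin(pi / 3),
                                      (j %% 2) * r0 * cos(pi / 3), 0))),
          c(2 * r0 * sin(pi / 3), 0, 2.45)))
  p <- tb_params(onsite_table = c(C = -6, S1 = -6.6))
  sol <- solve_orbitals(build_hamiltonian(bb, p), p)
  expect_equal(sol$reference$target_energy,
               charpoly_eigenvalues(build_hamiltonian(bb, p))[3],
               tolerance = 1e-8)
  expect_gte(sol$reference$L, 0.8)
  expect_equal(which.max(sol$reference$l_frac), 6L)

  # bare conjugated chain: near-uniform HOMO, delocalized
  chain <- atomic_system(rep("C", 6),
                         t(sapply(0:5, function(j)
                           c(j * r0 * sin(pi / 3),
                             (j %% 2) * r0 * cos(pi / 3), 0))))
  solc <- solve_orbitals(build_hamiltonian(chain, params), params)
  expect_lt(solc$reference$L, 0.4)
})

test_that("non-interacting composition selects the winning fragment", {
  fixtures <- toy_monomer_fixtures()

  ww <- compose_noninteracting(fixtures[c(1, 1), ], 15)
  expect_equal(ww$target_energy[[1]], 12.6)

  wc <- compose_noninteracting(fixtures, 15)
  expect_equal(wc$target_energy[[1]], 12.6)
  l <- wc$l_frac[[1]]
  expect_equal(sum(l[1:3]), 1)            # all mass on the water atoms
  expect_identical(l[4:6], rep(0, 3))
  expect_identical(wc$fragment[[1]], rep(0:1, each = 3L))

  # k identical copies: tie-averaging scales each copy's fractions by 1/k
  k3 <- compose_noninteracting(fixtures[c(1, 1, 1), ], 15)
  expect_equal(k3$target_energy[[1]], 12.6)
  expect_equal(k3$l_frac[[1]], rep(c(0.8, 0.1, 0.1) / 3, 3))

  expect_error(compose_noninteracting(fixtures, 9, descriptor_cutoff = 5),
               "twice the descriptor cutoff")
})

test_that("composition keeps fragment spectra exactly separate", {
  set.seed(9)
  ds <- tiny_dataset()[1:3, ]
  super <- compose_noninteracting(ds, 20)
  H_super <- build_hamiltonian(record_system(super, 1), params)
  vals_super <- sort(eigen(H_super, symmetric = TRUE,
                           only.values = TRUE)$values)
  vals_parts <- sort(unlist(lapply(1:3, function(i)
    eigen(build_hamiltonian(record_system(ds, i), params),
          symmetric = TRUE, only.values = TRUE)$values)))
  expect_lt(max(abs(vals_super - vals_parts)), 1e-10)
})

test_that("toy monomer fixtures carry the textbook values", {
  fx <- toy_monomer_fixtures()
  expect_equal(fx$target_energy, c(12.6, 13.8))
  expect_identical(fx$mode, c("min", "min"))
  # water geometry: two 0.96 A OH bonds at 104.5 degrees
  d <- as.matrix(dist(fx$coords[[1]]))
  expect_equal(d[1, 2], 0.96, tolerance = 1e-10)
  expect_equal(d[1, 3], 0.96, tolerance = 1e-10)
  # CO2: linear, r_CO = 1.16
  d2 <- as.matrix(dist(fx$coords[[2]]))
  expect_equal(d2[1, 2], 1.16, tolerance = 1e-10)
  expect_equal(d2[2, 3], 2.32, tolerance = 1e-10)
  expect_silent(validate_orb_dataset(fx))
})

test_that("split assignment partitions records deterministically", {
  ds <- tiny_dataset()
  s1 <- assign_splits(ds, c(train = 0.5, val = 0.25, test = 0.25), seed = 3)
  s2 <- assign_splits(ds, c(train = 0.5, val = 0.25, test = 0.25), seed = 3)
  expect_identical(s1$split, s2$split)
  expect_setequal(unique(s1$split), c("train", "val", "test"))
  expect_error(assign_splits(ds, c(train = 0.5, val = 0.2, test = 0.2)),
               "sum to 1")
})
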