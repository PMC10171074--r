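test_that("sum and average pooling follow their closed forms", {
  expect_equal(pool_sum(c(1, 3)), 4)
  expect_equal(pool_sum(-7), -7)
  expect_equal(pool_avg(c(1, 3)), 2)
  # extensive vs intensive under k-fold replication
  eps <- c(-7.2, -6.1, -5.5)
  for (k in c(2, 3, 5)) {
    expect_equal(pool_sum(rep(eps, k)), k * pool_sum(eps))
    expect_equal(pool_avg(rep(eps, k)), pool_avg(eps))
  }
  # concatenating two monomer vectors averages the two monomer means:
  # the documented failure mode on non-interacting water + CO2
  water <- c(12.5, 12.7, 12.6)
  co2 <- c(13.8, 13.9, 13.7)
  expect_equal(pool_avg(c(water, co2)),
               mean(c(pool_avg(water), pool_avg(co2))))
  expect_error(pool_sum(numeric(0)), "at least one")
})

test_that("max pooling tracks the mode", {
  expect_equal(pool_max(c(-7, -5), "max"), -5)
  expect_equal(pool_max(c(-7, -5), "min"), -7)
  expect_equal(pool_max(3.2, "max"), 3.2)
  # IE toy: min mode picks the water-side (lower) values
  expect_equal(pool_max(c(12.5, 12.7, 12.6, 13.8, 13.9, 13.7), "min"), 12.5)
})

test_that("softmax pooling matches the direct Boltzmann sum", {
  expect_equal(pool_softmax(rep(2.5, 6), "max"), 2.5)   # symmetric case

  # two-term oracle, evaluated directly
  boltz <- function(eps, s) sum(exp(s * eps) / sum(exp(s * eps)) * eps)
  expect_equal(pool_softmax(c(0, 20), "max"), boltz(c(0, 20), 1),
               tolerance = 1e-12)
  expect_lt(abs(pool_softmax(c(0, 20), "max") - 20), 1e-7)
  expect_equal(pool_softmax(c(1, 2), "max"), boltz(c(1, 2), 1),
               tolerance = 1e-12)
  expect_equal(pool_softmax(c(1, 2), "min"), boltz(c(1, 2), -1),
               tolerance = 1e-12)
  # overflow safety
  expect_equal(pool_softmax(c(1000, 2000), "max"), 2000)
  expect_error(pool_softmax(c(1, NaN), "max"), "finite")
})

test_that("weighted-average pooling serves WA, OWA and coefficient heads", {
  expect_equal(pool_weighted_average(c(-7, -6, -5), c(0, 1, 0)), -6)
  eps <- c(2.5, -1.5, 0.5, 4)
  expect_equal(pool_weighted_average(eps, rep(0.25, 4)), pool_avg(eps))
  # 3-term hand computation
  expect_equal(pool_weighted_average(c(-7.5, -6.1, -8.0), c(0.2, 0.7, 0.1)),
               0.2 * -7.5 + 0.7 * -6.1 + 0.1 * -8.0)
  expect_error(pool_weighted_average(eps, c(0.5, 0.5, 0.2, -0.2)), "simplex")
  expect_error(pool_weighted_average(eps, c(1, 0)), "length")
})

test_that("all heads are permutation-invariant and bounded; sum is extensive", {
  set.seed(21)
  for (case in 1:8) {
    n <- sample(2:9, 1)
    eps <- rnorm(n, -6, 1.5)
    w <- runif(n); w <- w / sum(w)
    perm <- sample(n)
    mode <- sample(c("max", "min"), 1)
    head_vals <- c(
      avg = pool_avg(eps),
      max = pool_max(eps, mode),
      softmax = pool_softmax(eps, mode),
      wa = pool_weighted_average(eps, w)
    )
    # boundedness within [min, max]
    expect_true(all(head_vals >= min(eps) - 1e-12 &
                      head_vals <= max(eps) + 1e-12))
    # permutation invariance
    expect_equal(pool_avg(eps[perm]), head_vals[["avg"]])
    expect_equal(pool_max(eps[perm], mode), head_vals[["max"]])
    expect_equal(pool_softmax(eps[perm], mode), head_vals[["softmax"]])
    expect_equal(pool_weighted_average(eps[perm], w[perm]),
                 head_vals[["wa"]])
    # intensivity under replication (weights renormalized by 1/k)
    for (k in c(2, 3)) {
      expect_equal(pool_avg(rep(eps, k)), head_vals[["avg"]])
      expect_equal(pool_max(rep(eps, k), mode), head_vals[["max"]])
      expect_lt(abs(pool_softmax(rep(eps, k), mode) -
                      head_vals[["softmax"]]), 1e-12)
      expect_lt(abs(pool_weighted_average(rep(eps, k), rep(w / k, k)) -
                      head_vals[["wa"]]), 1e-12)
    }
    expect_equal(pool_sum(rep(eps, 3)), 3 * pool_sum(eps))
  }
})

test_that("softmax approaches max pooling as outputs are rescaled", {
  eps <- c(-7.1, -6.3, -5.9)
  for (mode in c("max", "min")) {
    target <- pool_max(eps * 50, mode)
    expect_lt(abs(pool_softmax(eps * 50, mode) - target), 1e-6)
  }
  # and equals average pooling for identical entries
  expect_equal(pool_softmax(rep(-6.4, 5), "min"), -6.4)
})

test_that("apply_pooling dispatches by head name and validates weights", {
  eps <- c(-7, -6, -5)
  expect_equal(apply_pooling(pooling_head("sum"), eps), -18)
  expect_equal(apply_pooling(pooling_head("avg"), eps), -6)
  expect_equal(apply_pooling(pooling_head("max", "min"), eps), -7)
  expect_equal(apply_pooling(pooling_head("coeff"), eps, c(1, 0, 0)), -7)
  expect_error(apply_pooling(pooling_head("wa"), eps), "weight vector")
})
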