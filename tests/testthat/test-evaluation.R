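test_that("stratified RMSE has the closed-form behavior", {
  ds <- tiny_dataset()[1:10, ]
  ds$L <- c(0.9, 0.85, 0.5, 0.45, 0.3, 0.2, 0.1, 0.05, 0.6, 0.95)

  perfect <- make_stub_model(ds, ds$target_energy)
  rep_p <- stratified_rmse(perfect, ds)
  expect_equal(rep_p$rmse_overall, 0)
  expect_equal(rep_p$rmse_localized, 0)
  expect_equal(rep_p$rmse_delocalized, 0)
  expect_equal(rep_p$n_localized, 3L)
  expect_equal(rep_p$n_delocalized, 4L)
  expect_equal(rep_p$n_middle, 3L)

  # constant predictor: RMSE = population spread around the constant
  const <- make_stub_model(ds, rep(mean(ds$target_energy), 10))
  rep_c <- stratified_rmse(const, ds)
  strata <- stratify_by_L(ds)
  for (nm in c("localized", "delocalized", "middle")) {
    y <- ds$target_energy[strata[[nm]]]
    expect_equal(rep_c[[paste0("rmse_", nm)]],
                 sqrt(mean((y - mean(ds$target_energy))^2)))
  }
  # determinism and record-order invariance
  expect_identical(stratified_rmse(const, ds), rep_c)
  shuffled <- ds[sample(10), ]
  expect_equal(stratified_rmse(const, shuffled)$rmse_overall,
               rep_c$rmse_overall)

  # an empty stratum is absent (NA), not zero
  ds2 <- ds
  ds2$L <- rep(0.1, 10)
  expect_true(is.na(stratified_rmse(const, ds2)$rmse_localized))
})

test_that("weight correlations match the population Pearson formula", {
  full <- tiny_dataset()
  ds <- full[which(vapply(full$elements, length, integer(1)) >= 5)[1], ]
  l <- ds$l_frac[[1]]
  w <- rev(seq_along(l)); w <- w / sum(w)

  # omega identical to l: R = 1
  ident <- make_stub_model(ds, ds$target_energy, weights = list(l),
                           head = "owa")
  expect_equal(weight_correlations(ident, ds, quiet = TRUE)$pearson_r, 1)

  # fixed 5+-atom example against an independent covariance evaluation
  fixed <- make_stub_model(ds, ds$target_energy, weights = list(w),
                           head = "owa")
  r <- weight_correlations(fixed, ds, quiet = TRUE)$pearson_r
  r_oracle <- sum((w - mean(w)) * (l - mean(l))) /
    sqrt(sum((w - mean(w))^2) * sum((l - mean(l))^2))
  expect_equal(r, r_oracle, tolerance = 1e-12)

  # uniform weights: zero variance, excluded with a logged count
  unif <- make_stub_model(ds, ds$target_energy,
                          weights = list(rep(1 / length(l), length(l))),
                          head = "owa")
  expect_message(out <- weight_correlations(unif, ds), "excluded")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_excluded"), 1L)

  # weightless heads are rejected
  expect_error(weight_correlations(make_stub_model(ds, 1, head = "avg"), ds),
               "no weights")
})

test_that("molecules with fewer than three atoms are excluded", {
  sys <- atomic_system(c("C", "C"), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  ds <- orb_dataset(list(sys), list(
    electronic_reference(-6, "max", l_frac = c(0.8, 0.2), L = 0.36)))
  stub <- make_stub_model(ds, -6, weights = list(c(0.7, 0.3)), head = "owa")
  out <- weight_correlations(stub, ds, quiet = TRUE)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_excluded"), 1L)
})

test_that("intensivity audit reports deviations and sum ratios", {
  ds <- tiny_dataset()
  audit_set <- ds[ds$split == "test", ][1:4, ]
  m_avg <- train_pooling_model(ds, tiny_model_config("avg", ds),
                               max_epochs = 30L, patience = 30L)
  aud <- intensivity_audit(m_avg, audit_set, k = c(2L, 3L))
  expect_equal(nrow(aud), 8L)
  expect_lt(max(aud$deviation), 1e-6)

  m_sum <- train_pooling_model(ds, tiny_model_config("sum", ds),
                               max_epochs = 30L, patience = 30L)
  aud_s <- intensivity_audit(m_sum, audit_set[1:2, ], k = 3L)
  expect_equal(aud_s$ratio, rep(3, 2), tolerance = 1e-6)

  expect_error(intensivity_audit(m_avg, audit_set, separation = 8),
               "cutoff")
})

test_that("learning curves have the stated cardinality and determinism", {
  ds <- tiny_dataset()
  cfgs <- list(avg = tiny_model_config("avg", ds),
               max = tiny_model_config("max", ds))
  c1 <- learning_curve(ds, cfgs, sizes = c(10L, 25L), seeds = 1:3,
                       max_epochs = 10L, patience = 10L)
  expect_equal(nrow(c1), 2 * 2 * 3)
  c2 <- learning_curve(ds, cfgs, sizes = c(10L, 25L), seeds = 1:3,
                       max_epochs = 10L, patience = 10L)
  expect_identical(c1, c2)
  sm <- summarise_learning_curve(c1)
  expect_equal(nrow(sm), 2 * 2 * 4)
  expect_true(all(sm$n_seeds == 3))
  expect_error(learning_curve(ds, cfgs, sizes = c(10L, 1e5L)),
               "exceeds")
  expect_s3_class(autoplot(c1), "ggplot")
})

test_that("pseudoorbital export round-trips weights next to fractions", {
  ds <- tiny_dataset()
  m <- train_pooling_model(ds, tiny_model_config("owa", ds),
                           loss_config(1, 1), max_epochs = 40L,
                           patience = 40L)
  path <- withr::local_tempfile(fileext = ".extxyz")
  export_pseudoorbitals(m, ds[1:5, ], path)
  back <- read_extxyz(path)
  expect_true(all(c("l_frac", "owa_weight") %in% names(back)))
  sums <- vapply(back$owa_weight, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-6))

  m_avg <- train_pooling_model(ds, tiny_model_config("avg", ds),
                               max_epochs = 5L, patience = 5L)
  expect_error(export_pseudoorbitals(m_avg, ds, path), "weight-bearing")
})
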