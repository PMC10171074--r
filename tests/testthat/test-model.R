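test_that("the joint loss reduces to its closed forms", {
  expect_equal(owa_loss(12.6, 12.6, c(0.5, 0.5), c(0.5, 0.5),
                        loss_config(1, 1)), 0)
  expect_equal(owa_loss(c(12.7, 13.0), c(12.6, 13.8),
                        cfg = loss_config(alpha = 2)),
               mean(2 * c(0.1, -0.8)^2))
  # alpha = 1, beta = 1, energy error 0.1, weight errors (0.1, -0.1)
  expect_equal(owa_loss(12.7, 12.6, c(0.6, 0.4), c(0.5, 0.5),
                        loss_config(1, 1)), 0.01 + 0.02, tolerance = 1e-12)
  expect_error(owa_loss(1, 1, c(0.9, 0.4), c(0.9, 0.4), loss_config(1, 1)),
               "simplex")
  expect_error(loss_config(0, 0), "positive")
})

test_that("an overparameterized model memorizes two records", {
  fixtures <- toy_monomer_fixtures()
  mc <- tiny_model_config("avg", fixtures, batch_size = 2L)
  m <- train_pooling_model(fixtures, mc, max_epochs = 3000L,
                           patience = 3000L)
  preds <- predict_dataset(m, fixtures)
  expect_lt(mean((preds$prediction - preds$target_energy)^2), 1e-4)
})

test_that("training is bit-reproducible for a fixed seed", {
  ds <- tiny_dataset()
  mc <- tiny_model_config("avg", ds)
  m1 <- train_pooling_model(ds, mc, max_epochs = 25L, patience = 25L)
  m2 <- train_pooling_model(ds, mc, max_epochs = 25L, patience = 25L)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$nets, m2$nets)
  mc2 <- mc
  mc2$seed <- 12L
  m3 <- train_pooling_model(ds, mc2, max_epochs = 25L, patience = 25L)
  expect_false(identical(m1$history, m3$history))
})

test_that("an average-pooling model beats the constant predictor", {
  ds <- tiny_dataset()
  mc <- tiny_model_config("avg", ds)
  m <- train_pooling_model(ds, mc, max_epochs = 250L, patience = 60L)
  test_ds <- ds[ds$split == "test", ]
  preds <- predict_dataset(m, test_ds)
  rmse <- sqrt(mean((preds$prediction - preds$target_energy)^2))
  const <- mean(ds$target_energy[ds$split == "train"])
  rmse_const <- sqrt(mean((const - test_ds$target_energy)^2))
  expect_lt(rmse, rmse_const)
})

test_that("predictions are permutation-invariant with simplex weights", {
  ds <- tiny_dataset()
  mc <- tiny_model_config("wa", ds)
  m <- train_pooling_model(ds, mc, max_epochs = 40L, patience = 40L)
  sys <- record_system(ds, 3)
  p <- predict(m, sys)
  expect_true(all(p$weights >= 0))
  expect_lt(abs(sum(p$weights) - 1), 1e-8)
  set.seed(2)
  perm <- sample(seq_along(sys$elements))
  p2 <- predict(m, atomic_system(sys$elements[perm],
                                 sys$coords[perm, , drop = FALSE]))
  expect_lt(abs(p2$energy - p$energy), 1e-9)
  expect_equal(p2$weights, p$weights[perm], tolerance = 1e-9)
})

test_that("zeroed output layers predict the target-normalizer shift", {
  ds <- tiny_dataset()
  mc <- tiny_model_config("avg", ds)
  m <- train_pooling_model(ds, mc, max_epochs = 5L, patience = 5L)
  last <- length(m$nets$energy)
  m$nets$energy[[last]]$W[] <- 0
  m$nets$energy[[last]]$b[] <- 0
  p <- predict(m, record_system(ds, 1))
  expect_equal(p$energy, m$normalizers$y_shift)
})

test_that("head/label contracts are enforced", {
  ds <- tiny_dataset()
  expect_error(
    train_pooling_model(ds, tiny_model_config("avg", ds), loss_config(1, 1)),
    "owa")
  stripped <- ds
  stripped$l_frac <- rep(list(NULL), nrow(ds))
  stripped$L <- rep(0.5, nrow(ds))
  expect_error(
    train_pooling_model(stripped, tiny_model_config("owa", stripped),
                        loss_config(1, 1)),
    "localization fractions")
  expect_error(
    train_pooling_model(ds, tiny_model_config("avg", ds, mode = "min")),
    "mode")
})

test_that("alpha/beta selection minimizes val RMSE with ties toward beta", {
  ds <- tiny_dataset()
  mc <- tiny_model_config("owa", ds)
  sel1 <- suppressMessages(
    select_alpha_beta(ds, mc, data.frame(alpha = 1, beta = 0.5),
                      max_epochs = 15L, patience = 15L))
  expect_equal(sel1$alpha, 1)
  expect_equal(sel1$beta, 0.5)
  expect_equal(nrow(sel1$table), 1L)
  # tie rule on a fabricated result table
  tab <- tibble::tibble(alpha = c(1, 1), beta = c(0, 1),
                        val_rmse = c(0.3, 0.3))
  expect_equal(owapool:::pick_alpha_beta(tab), 2L)
  tab2 <- tibble::tibble(alpha = c(1, 1), beta = c(0, 1),
                         val_rmse = c(0.2, 0.3))
  expect_equal(owapool:::pick_alpha_beta(tab2), 1L)
})

test_that("tidy and glance expose the training history", {
  ds <- tiny_dataset()
  m <- train_pooling_model(ds, tiny_model_config("avg", ds),
                           max_epochs = 8L, patience = 8L)
  h <- tidy(m)
  expect_named(h, c("epoch", "train_loss", "val_rmse"))
  expect_equal(nrow(h), 8L)
  g <- glance(m)
  expect_equal(g$head, "avg")
  expect_gt(g$n_parameters, 0)
})
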