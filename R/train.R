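#' Model configuration
#'
#' The atomistic regression model: a per-atom energy network on top of the
#' descriptor, plus — for `wa`/`owa` heads — a second weight network whose
#' softmax-normalized outputs weight the per-atom energies. Weight logits are
#' `z_i = s_i + gamma * sign * tanh(eps_i)`: the learned score `s_i`,
#' optionally biased by the atom's own (standardized, bounded) energy output
#' so that atoms carrying the extremal property dominate the weights
#' consistently across non-interacting fragments. The default `gamma = 0` is
#' the pure second-network softmax; set `gamma > 0` (the toy experiment uses
#' 5) when a model trained on monomers must pick the correct fragment of a
#' non-interacting supersystem, which a per-molecule softmax alone cannot
#' determine.
#'
#' @param descriptor A [descriptor_config()] or the name of a registered
#'   adapter.
#' @param pooling A [pooling_head()].
#' @param energy_net_layers Hidden-layer widths of the energy net
#'   (default `c(64, 64)`).
#' @param weight_net_layers Hidden-layer widths of the weight net
#'   (default `c(64, 64)`); only instantiated for `wa`/`owa` heads.
#' @param activation Smooth nonlinearity, `"tanh"` (default) or
#'   `"softplus"`.
#' @param share_trunk If `TRUE`, energy and weight outputs are two linear
#'   heads on one shared trunk (default `FALSE`: two separate networks).
#' @param gamma Energy-guidance coefficient of the weight logits
#'   (default 0: pure weight-net softmax).
#' @param owa_energy_path Gradient path of the OWA energy term:
#'   `"teacher"` (default) pools the energy loss with the reference
#'   fractions during training — the clean coefficient-pooling gradient,
#'   equivalent at the optimum where the learned weights reach `l` —
#'   while `"pooled"` differentiates through the learned weights, which
#'   lets the two networks co-adapt (used by the toy experiment, where the
#'   energy-guided weights must track the energy net).
#' @param score_decay L2 anchor on the weight-net scores (default 5e-3).
#'   Softmax weights are invariant under a per-molecule score shift, so
#'   without an anchor the shift drifts arbitrarily and can override the
#'   energy-guidance ordering across non-interacting fragments; the anchor
#'   keeps scores mean-zero without changing the expressible weight shapes.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Molecules per minibatch (default 32).
#' @param seed Seed controlling initialization and shuffling.
#' @return A `model_config` object.
#' @export
model_config <- function(descriptor, pooling,
                         energy_net_layers = c(64L, 64L),
                         weight_net_layers = c(64L, 64L),
                         activation = c("tanh", "softplus"),
                         share_trunk = FALSE, gamma = 0,
                         owa_energy_path = c("teacher", "pooled"),
                         score_decay = 5e-3,
                         learning_rate = 1e-3, batch_size = 32L,
                         seed = 1L) {
  activation <- match.arg(activation)
  owa_energy_path <- match.arg(owa_energy_path)
  if (!inherits(pooling, "pooling_head")) {
    abort("pooling must be a pooling_head")
  }
  structure(list(descriptor = descriptor, pooling = pooling,
                 energy_net_layers = as.integer(energy_net_layers),
                 weight_net_layers = as.integer(weight_net_layers),
                 activation = activation, share_trunk = share_trunk,
                 gamma = as.numeric(gamma),
                 owa_energy_path = owa_energy_path,
                 score_decay = as.numeric(score_decay),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Loss configuration
#'
#' Joint energy + localization loss: per system
#' `alpha * (P - P_ref)^2 + beta * sum_i (w_i - l_i)^2`, averaged over the
#' systems of a batch. `beta > 0` is the OWA objective (weights supervised by
#' Mulliken fractions); every other head trains with `beta = 0`.
#'
#' @param alpha Energy-term coefficient (>= 0, default 1).
#' @param beta Localization-term coefficient (>= 0, default 0).
#' @return A `loss_config` object.
#' @export
loss_config <- function(alpha = 1, beta = 0) {
  if (alpha < 0 || beta < 0) abort("alpha and beta must be >= 0")
  if (alpha + beta <= 0) abort("alpha + beta must be positive")
  structure(list(alpha = alpha, beta = beta), class = "loss_config")
}

#' Joint OWA loss
#'
#' `alpha * (pred - ref)^2 + beta * sum_i (w_i - l_i)^2` per system, averaged
#' over systems. With `beta = 0` this reduces to the plain squared energy
#' error used by all non-OWA heads.
#'
#' @param pred_energy,ref_energy Numeric vectors of predictions and
#'   references (eV), one entry per system.
#' @param pred_weights,ref_fractions Lists of per-atom weight/fraction
#'   vectors (or single vectors for one system); `ref_fractions` must be
#'   valid simplex vectors. Ignored when `beta = 0`.
#' @param cfg A [loss_config()].
#' @return Scalar batch loss.
#' @export
owa_loss <- function(pred_energy, ref_energy, pred_weights = NULL,
                     ref_fractions = NULL, cfg = loss_config()) {
  b <- length(pred_energy)
  if (length(ref_energy) != b) {
    abort("pred_energy and ref_energy must have the same length")
  }
  e2 <- (pred_energy - ref_energy)^2
  w2 <- numeric(b)
  if (cfg$beta > 0) {
    if (is.numeric(pred_weights)) pred_weights <- list(pred_weights)
    if (is.numeric(ref_fractions)) ref_fractions <- list(ref_fractions)
    if (length(pred_weights) != b || length(ref_fractions) != b) {
      abort("need one weight and one fraction vector per system")
    }
    for (a in seq_len(b)) {
      l <- ref_fractions[[a]]
      if (any(l < -1e-8) || abs(sum(l) - 1) > 1e-6) {
        abort("ref_fractions must be valid simplex vectors")
      }
      w2[a] <- sum((pred_weights[[a]] - l)^2)
    }
  }
  mean(cfg$alpha * e2 + cfg$beta * w2)
}

# ---- internal: dataset preparation ----------------------------------------

# net input: one-hot central-element block + descriptor row. The one-hot
# block plays the role of element-specific subnets in a shared network: the
# neighbor-density descriptor alone cannot tell which element sits at the
# center. Purely local, so intensivity is untouched. Adapters are assumed to
# encode the central element themselves.
model_features <- function(system, descriptor) {
  feat <- featurize(system, descriptor)$values
  if (inherits(descriptor, "descriptor_config")) {
    onehot <- outer(system$elements, descriptor$element_channels, "==") * 1
    feat <- cbind(onehot, feat)
  }
  feat
}

prepare_training_data <- function(dataset, cfg) {
  n <- nrow(dataset)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    feats[[i]] <- model_features(record_system(dataset, i), cfg$descriptor)
  }
  natoms <- map_int(feats, nrow)
  X <- do.call(rbind, feats)
  idx <- split(seq_len(nrow(X)), rep(seq_len(n), natoms))
  list(X = X, idx = idx, natoms = natoms,
       y = dataset$target_energy, l = dataset$l_frac,
       split = dataset$split)
}

make_normalizers <- function(prep, head, train_rows, train_mols) {
  Xt <- prep$X[train_rows, , drop = FALSE]
  fm <- colMeans(Xt)
  fs <- apply(Xt, 2L, stats::sd)
  fs[!is.finite(fs) | fs < 1e-12] <- 1
  y <- prep$y[train_mols]
  if (head$name == "sum") {
    atom_shift <- mean(y / prep$natoms[train_mols])
    resid <- y - prep$natoms[train_mols] * atom_shift
    y_scale <- max(stats::sd(resid), 1e-8)
    if (!is.finite(y_scale)) y_scale <- 1
    list(feat_mean = fm, feat_sd = fs, y_shift = atom_shift,
         y_scale = y_scale, per_atom_shift = TRUE)
  } else {
    y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale < 1e-8) y_scale <- 1
    list(feat_mean = fm, feat_sd = fs, y_shift = mean(y),
         y_scale = y_scale, per_atom_shift = FALSE)
  }
}

std_targets <- function(y, natoms, nz) {
  if (nz$per_atom_shift) {
    (y - natoms * nz$y_shift) / nz$y_scale
  } else {
    (y - nz$y_shift) / nz$y_scale
  }
}

# pooled value and gradients in standardized units for one molecule
pool_with_grads <- function(head, eps, s = NULL, gamma = 0, l = NULL) {
  n <- length(eps)
  sign <- head$softmax_sign
  switch(head$name,
    sum = list(P = sum(eps), deps = rep(1, n), ds = NULL, w = NULL),
    avg = list(P = mean(eps), deps = rep(1 / n, n), ds = NULL, w = NULL),
    max = {
      j <- if (head$mode == "max") which.max(eps) else which.min(eps)
      g <- numeric(n); g[j] <- 1
      list(P = eps[j], deps = g, ds = NULL, w = NULL)
    },
    softmax = {
      w <- softmax_weights(eps, head$mode, head$temperature)
      P <- sum(w * eps)
      list(P = P,
           deps = w * (1 + sign * head$temperature * (eps - P)),
           ds = NULL, w = w)
    },
    coeff = {
      if (is.null(l)) abort("coeff pooling requires reference fractions")
      list(P = sum(l * eps), deps = l, ds = NULL, w = l)
    },
    wa = ,
    owa = {
      # bounded energy guidance: tanh caps the logit bias so a single
      # off-support per-atom output cannot capture the whole weight
      g <- tanh(eps)
      z <- s + gamma * sign * g
      z <- z - max(z)
      w <- exp(z); w <- w / sum(w)
      P <- sum(w * eps)
      dP_dz <- w * (eps - P)
      list(P = P, deps = w + gamma * sign * (1 - g^2) * dP_dz, ds = dP_dz,
           w = w, dP_dz = dP_dz)
    }
  )
}

# d(sum((w - l)^2))/dz for softmax weights w(z)
weight_term_grad <- function(w, l) {
  r <- w - l
  2 * w * (r - sum(r * w))
}

#' Train a pooling model
#'
#' Minibatch Adam on the joint loss, early stopping on validation energy
#' RMSE, best-on-validation parameters returned. Deterministic for a fixed
#' `model_cfg$seed`: same initialization, same shuffles.
#'
#' @param dataset An `orb_dataset` with non-empty `train` and `val` splits
#'   (if no `val` rows exist, the train split doubles as validation).
#' @param model_cfg A [model_config()]; its pooling mode must match the
#'   dataset mode.
#' @param loss_cfg A [loss_config()]; `beta > 0` requires an `owa` head and
#'   localization fractions on every training record.
#' @param max_epochs Epoch budget (default 500).
#' @param patience Early-stopping patience in epochs (default 50).
#' @param verbose Print progress every 50 epochs.
#' @return An object of class `owa_model` with elements `nets`, `config`,
#'   `loss_cfg`, `normalizers` and a per-epoch `history` tibble.
#' @export
train_pooling_model <- function(dataset, model_cfg,
                                loss_cfg = loss_config(),
                                max_epochs = 500L, patience = 50L,
                                verbose = FALSE) {
  validate_orb_dataset(dataset)
  head <- model_cfg$pooling
  if (nrow(dataset) == 0) abort("empty dataset")
  if (dataset$mode[[1]] != head$mode) {
    abort(sprintf("dataset mode '%s' does not match pooling mode '%s'",
                  dataset$mode[[1]], head$mode))
  }
  if (loss_cfg$beta > 0 && head$name != "owa") {
    abort("beta > 0 is only defined for the owa head")
  }
  needs_l <- head$name %in% c("owa", "coeff")
  train_mols <- which(dataset$split == "train")
  val_mols <- which(dataset$split == "val")
  if (length(train_mols) == 0) abort("no training records")
  if (length(val_mols) == 0) val_mols <- train_mols
  if (needs_l &&
      any(map_lgl(dataset$l_frac[train_mols], is.null))) {
    abort(sprintf(
      "the %s head needs localization fractions (l_frac) on every training record",
      head$name))
  }

  prep <- prepare_training_data(dataset, model_cfg)
  train_rows <- unlist(prep$idx[train_mols])
  nz <- make_normalizers(prep, head, train_rows, train_mols)
  X <- sweep(sweep(prep$X, 2L, nz$feat_mean, "-"), 2L, nz$feat_sd, "/")
  y_std <- std_targets(prep$y, prep$natoms, nz)
  l_lab <- lapply(prep$l, function(l) {
    if (is.null(l)) NULL else clip_fractions_for_training(l, quiet = TRUE)
  })

  has_weight_net <- head$name %in% c("wa", "owa")
  D <- ncol(X)
  set.seed(model_cfg$seed)
  if (model_cfg$share_trunk && has_weight_net) {
    nets <- list(shared = mlp_init(D, model_cfg$energy_net_layers, 2L))
  } else {
    nets <- list(energy = mlp_init(D, model_cfg$energy_net_layers, 1L))
    if (has_weight_net) {
      nets$weight <- mlp_init(D, model_cfg$weight_net_layers, 1L)
    }
  }
  states <- lapply(nets, adam_init)

  eval_split <- function(nets, mols) {
    rows <- unlist(prep$idx[mols])
    outs <- net_outputs(nets, X[rows, , drop = FALSE],
                        model_cfg$activation, has_weight_net)
    pos <- 0L
    pred <- numeric(length(mols))
    for (j in seq_along(mols)) {
      m <- mols[j]
      nm <- prep$natoms[m]
      sel <- (pos + 1L):(pos + nm)
      pg <- pool_with_grads(head, outs$eps[sel],
                            s = if (has_weight_net) outs$s[sel],
                            gamma = model_cfg$gamma,
                            l = l_lab[[m]])
      pred[j] <- pg$P
      pos <- pos + nm
    }
    pred
  }

  n_train <- length(train_mols)
  bs <- max(1L, min(model_cfg$batch_size, n_train))
  best <- list(rmse = Inf, nets = nets, epoch = 0L)
  hist_epoch <- integer(0)
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  t_adam <- 0L
  wait <- 0L

  for (epoch in seq_len(max_epochs)) {
    order_m <- train_mols[sample.int(n_train)]
    epoch_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n_train, by = bs)) {
      mols <- order_m[start:min(n_train, start + bs - 1L)]
      rows <- unlist(prep$idx[mols])
      Xb <- X[rows, , drop = FALSE]
      fw <- net_forward(nets, Xb, model_cfg$activation, has_weight_net)
      eps <- fw$eps
      s <- fw$s
      B <- length(mols)
      deps <- numeric(length(rows))
      ds <- if (has_weight_net) numeric(length(rows)) else NULL
      pos <- 0L
      loss <- 0
      for (j in seq_len(B)) {
        m <- mols[j]
        nm <- prep$natoms[m]
        sel <- (pos + 1L):(pos + nm)
        pg <- pool_with_grads(head, eps[sel],
                              s = if (has_weight_net) s[sel],
                              gamma = model_cfg$gamma, l = l_lab[[m]])
        if (loss_cfg$beta > 0 && model_cfg$owa_energy_path == "teacher") {
          # owa, teacher path: the energy term is pooled with the reference
          # fractions (the gradient coefficient pooling would have), while
          # the localization term alone trains the weight net; the two
          # objectives coincide at the optimum omega = l, and validation/
          # inference always go through the learned weights.
          lw <- l_lab[[m]]
          err <- sum(lw * eps[sel]) - y_std[m]
          loss <- loss + loss_cfg$alpha * err^2
          g_e <- (2 * loss_cfg$alpha * err / B) * lw
          g_s <- numeric(length(sel))
        } else if (loss_cfg$beta > 0) {
          # owa, pooled path: energy loss through the learned weights, taken
          # as constants (no gradient into the softmax), so the nets do not
          # chase each other; the weight net still sees only the beta term
          err <- pg$P - y_std[m]
          loss <- loss + loss_cfg$alpha * err^2
          g_e <- (2 * loss_cfg$alpha * err / B) * pg$w
          g_s <- numeric(length(sel))
        } else {
          err <- pg$P - y_std[m]
          loss <- loss + loss_cfg$alpha * err^2
          g_e <- (2 * loss_cfg$alpha * err / B) * pg$deps
          g_s <- if (has_weight_net) (2 * loss_cfg$alpha * err / B) * pg$ds
        }
        if (loss_cfg$beta > 0) {
          # localization supervision updates the weight net only: the
          # energy-guidance term in the logits is a fixed bias here, so the
          # weight objective cannot distort the per-atom energies
          lw <- l_lab[[m]]
          loss <- loss + loss_cfg$beta * sum((pg$w - lw)^2)
          g_s <- g_s + (loss_cfg$beta / B) * weight_term_grad(pg$w, lw)
        }
        if (has_weight_net && model_cfg$score_decay > 0) {
          # anchor scores at zero (see model_config); per-atom average so
          # molecule size does not rescale the penalty
          g_s <- g_s + (2 * model_cfg$score_decay / (B * nm)) * s[sel]
        }
        deps[sel] <- g_e
        if (has_weight_net) ds[sel] <- g_s
        pos <- pos + nm
      }
      grads_out <- if (!is.null(fw$shared_cache)) {
        cbind(deps, ds)
      } else {
        deps
      }
      t_adam <- t_adam + 1L
      nets_states <- net_backward_update(
        nets, states, fw, grads_out, ds, model_cfg, t_adam)
      nets <- nets_states$nets
      states <- nets_states$states
      epoch_loss <- epoch_loss + loss / B
      n_batches <- n_batches + 1L
    }
    val_pred <- eval_split(nets, val_mols)
    val_rmse <- sqrt(mean((val_pred - y_std[val_mols])^2)) * nz$y_scale
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, epoch_loss / n_batches)
    hist_val <- c(hist_val, val_rmse)
    if (val_rmse < best$rmse - 1e-12) {
      best <- list(rmse = val_rmse, nets = nets, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
    if (verbose && epoch %% 50 == 0) {
      inform(sprintf("epoch %d: train loss %.3e, val RMSE %.4f eV",
                     epoch, epoch_loss / n_batches, val_rmse))
    }
  }

  structure(list(
    nets = best$nets, config = model_cfg, loss_cfg = loss_cfg,
    normalizers = nz, has_weight_net = has_weight_net,
    history = tibble(epoch = hist_epoch, train_loss = hist_train,
                     val_rmse = hist_val),
    best_epoch = best$epoch, best_val_rmse = best$rmse,
    mode = head$mode
  ), class = "owa_model")
}

# forward through whichever net layout is active; returns eps, s and caches
net_forward <- function(nets, Xb, activation, has_weight_net) {
  if (!is.null(nets$shared)) {
    fw <- mlp_forward(nets$shared, Xb, activation)
    list(eps = fw$out[, 1L], s = fw$out[, 2L], shared_cache = fw)
  } else {
    fe <- mlp_forward(nets$energy, Xb, activation)
    out <- list(eps = fe$out[, 1L], s = NULL, energy_cache = fe)
    if (has_weight_net) {
      fs <- mlp_forward(nets$weight, Xb, activation)
      out$s <- fs$out[, 1L]
      out$weight_cache <- fs
    }
    out
  }
}

net_outputs <- function(nets, Xb, activation, has_weight_net) {
  fw <- net_forward(nets, Xb, activation, has_weight_net)
  list(eps = fw$eps, s = fw$s)
}

net_backward_update <- function(nets, states, fw, grads_out, ds,
                                model_cfg, t_adam) {
  act <- model_cfg$activation
  lr <- model_cfg$learning_rate
  if (!is.null(nets$shared)) {
    g <- mlp_backward(nets$shared, fw$shared_cache,
                      as.matrix(grads_out), act)
    up <- adam_step(nets$shared, g, states$shared, lr, t_adam)
    nets$shared <- up$layers
    states$shared <- up$state
  } else {
    g <- mlp_backward(nets$energy, fw$energy_cache,
                      matrix(grads_out, ncol = 1L), act)
    up <- adam_step(nets$energy, g, states$energy, lr, t_adam)
    nets$energy <- up$layers
    states$energy <- up$state
    if (!is.null(nets$weight)) {
      gw <- mlp_backward(nets$weight, fw$weight_cache,
                         matrix(ds, ncol = 1L), act)
      upw <- adam_step(nets$weight, gw, states$weight, lr, t_adam)
      nets$weight <- upw$layers
      states$weight <- upw$state
    }
  }
  list(nets = nets, states = states)
}

#' Predict with a trained pooling model
#'
#' Featurizes the system, evaluates the per-atom energy network, pools with
#' the model's head and un-normalizes to eV. For `wa`/`owa` heads the
#' returned weights are the softmax-normalized logits (non-negative, summing
#' to 1 within 1e-8); for `softmax` they are the softmax-pooling weights.
#'
#' @param object A trained `owa_model`.
#' @param system An [atomic_system()].
#' @param l_frac Reference localization fractions, required by the `coeff`
#'   head only.
#' @param ... Unused.
#' @return List with `energy` (scalar, eV) and `weights` (length-N vector or
#'   `NULL` for weightless heads).
#' @export
predict.owa_model <- function(object, system, l_frac = NULL, ...) {
  cfg <- object$config
  nz <- object$normalizers
  feat <- model_features(system, cfg$descriptor)
  X <- sweep(sweep(feat, 2L, nz$feat_mean, "-"), 2L, nz$feat_sd, "/")
  outs <- net_outputs(object$nets, X, cfg$activation, object$has_weight_net)
  head <- cfg$pooling
  if (head$name == "coeff" && is.null(l_frac)) {
    abort("coeff pooling requires l_frac at prediction time")
  }
  pg <- pool_with_grads(head, outs$eps,
                        s = outs$s, gamma = cfg$gamma,
                        l = if (!is.null(l_frac)) {
                          clip_fractions_for_training(l_frac, quiet = TRUE)
                        })
  energy <- if (nz$per_atom_shift) {
    nz$y_scale * pg$P + length(outs$eps) * nz$y_shift
  } else {
    nz$y_scale * pg$P + nz$y_shift
  }
  if (!is.finite(energy)) abort("non-finite prediction")
  list(energy = energy, weights = pg$w)
}

#' Predict over a whole dataset
#'
#' @param model A trained `owa_model`.
#' @param dataset An `orb_dataset`.
#' @return A tibble with `system_id`, `split`, `target_energy`, `L`,
#'   `prediction` (eV) and a `weights` list-column.
#' @export
predict_dataset <- function(model, dataset) {
  preds <- map(seq_len(nrow(dataset)), function(i) {
    predict(model, record_system(dataset, i),
            l_frac = dataset$l_frac[[i]])
  })
  tibble(system_id = dataset$system_id,
         split = dataset$split,
         target_energy = dataset$target_energy,
         L = dataset$L,
         prediction = map_dbl(preds, "energy"),
         weights = map(preds, "weights"))
}

#' @export
print.owa_model <- function(x, ...) {
  cat(sprintf(
    "<owa_model> %s pooling (mode = %s), best val RMSE %.4f eV (epoch %d)\n",
    x$config$pooling$name, x$mode, x$best_val_rmse, x$best_epoch))
  invisible(x)
}

#' Tidy a trained model's history
#'
#' @param x An `owa_model`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`, `val_rmse`).
#' @export
tidy.owa_model <- function(x, ...) x$history

#' One-line model summary
#'
#' @param x An `owa_model`.
#' @param ... Unused.
#' @return One-row tibble with head, mode, parameters count, epochs run and
#'   best validation RMSE.
#' @export
glance.owa_model <- function(x, ...) {
  n_par <- sum(map_dbl(x$nets, function(net)
    sum(map_dbl(net, function(l) length(l$W) + length(l$b)))))
  tibble(head = x$config$pooling$name, mode = x$mode,
         n_parameters = n_par, epochs = nrow(x$history),
         best_epoch = x$best_epoch, val_rmse = x$best_val_rmse)
}

#' Grid search for the loss coefficients
#'
#' Trains one model per `(alpha, beta)` pair and returns the pair minimizing
#' validation energy RMSE; ties (within 1e-12) break toward larger `beta`,
#' i.e. more localization supervision.
#'
#' @param dataset An `orb_dataset`.
#' @param model_cfg A [model_config()] (an `owa` head for `beta > 0` rows).
#' @param grid Data frame or tibble with columns `alpha`, `beta`.
#' @param ... Passed to [train_pooling_model()].
#' @return List with `alpha`, `beta` and the search `table`
#'   (alpha, beta, val_rmse).
#' @export
select_alpha_beta <- function(dataset, model_cfg, grid, ...) {
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort("grid must be non-empty")
  rmse <- map_dbl(seq_len(nrow(grid)), function(i) {
    m <- train_pooling_model(dataset, model_cfg,
                             loss_config(grid$alpha[i], grid$beta[i]), ...)
    m$best_val_rmse
  })
  tab <- mutate(grid, val_rmse = rmse)
  pick <- pick_alpha_beta(tab)
  inform(paste0("alpha/beta selection: ",
                paste(sprintf("(%g, %g) -> %.4f eV", tab$alpha, tab$beta,
                              tab$val_rmse), collapse = "; ")))
  list(alpha = tab$alpha[pick], beta = tab$beta[pick], table = tab)
}

# tie rule: minimal RMSE, ties toward larger beta
pick_alpha_beta <- function(tab) {
  best <- min(tab$val_rmse)
  cand <- which(tab$val_rmse <= best + 1e-12)
  cand[which.max(tab$beta[cand])]
}
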