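#' Stratified RMSE report
#'
#' RMSE of a model over a dataset, overall and split by localization index
#' strata (localized `L >= 0.8`, delocalized `L < 0.4`, middle band). Empty
#' strata are reported as `NA`, not 0.
#'
#' @param model A trained `owa_model` (or any object with a
#'   `predict(model, system, l_frac)` method).
#' @param dataset An `orb_dataset` whose records carry `L`.
#' @param localized_cut,delocalized_cut Stratum thresholds (defaults
#'   0.8 / 0.4).
#' @return An `eval_report`: one-row tibble with `rmse_overall`,
#'   `rmse_localized`, `rmse_delocalized`, `rmse_middle` (eV) and the stratum
#'   counts.
#' @export
stratified_rmse <- function(model, dataset, localized_cut = 0.8,
                            delocalized_cut = 0.4) {
  strata <- stratify_by_L(dataset, localized_cut, delocalized_cut)
  preds <- predict_dataset(model, dataset)
  err <- preds$prediction - preds$target_energy
  rmse_of <- function(ix) if (length(ix) == 0) NA_real_ else
    sqrt(mean(err[ix]^2))
  out <- tibble(
    rmse_overall = rmse_of(seq_along(err)),
    rmse_localized = rmse_of(strata$localized),
    rmse_delocalized = rmse_of(strata$delocalized),
    rmse_middle = rmse_of(strata$middle),
    n_overall = length(err),
    n_localized = length(strata$localized),
    n_delocalized = length(strata$delocalized),
    n_middle = length(strata$middle)
  )
  class(out) <- c("eval_report", class(out))
  out
}

# population Pearson correlation; NA when either side is degenerate
pearson_pop <- function(a, b) {
  va <- mean((a - mean(a))^2)
  vb <- mean((b - mean(b))^2)
  if (va <= 0 || vb <= 0) return(NA_real_)
  mean((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
}

#' Per-molecule correlation between learned weights and l_i
#'
#' Pearson correlation (population covariance form) between the model's
#' pooling weights and the reference Mulliken fractions, one coefficient per
#' molecule. Only weight-bearing heads are supported (`softmax`, `wa`,
#' `owa`, `coeff`; softmax weights are reconstructed from the per-atom
#' energies). Molecules with fewer than 3 atoms or with zero variance in
#' either vector are excluded; the exclusion count is reported as an
#' attribute and a message.
#'
#' @param model A trained `owa_model`.
#' @param dataset An `orb_dataset` whose records carry `l_frac`.
#' @param quiet Suppress the exclusion message.
#' @return Tibble with `system_id`, `L` and `pearson_r`; excluded molecules
#'   are dropped (count in `attr(, "n_excluded")`).
#' @export
weight_correlations <- function(model, dataset, quiet = FALSE) {
  head_name <- model$config$pooling$name
  if (!head_name %in% c("softmax", "wa", "owa", "coeff")) {
    abort(sprintf("head '%s' carries no weights to correlate", head_name))
  }
  if (any(map_lgl(dataset$l_frac, is.null))) {
    abort("every record needs localization fractions l_frac")
  }
  preds <- predict_dataset(model, dataset)
  r <- map_dbl(seq_len(nrow(dataset)), function(i) {
    w <- preds$weights[[i]]
    l <- dataset$l_frac[[i]]
    if (length(l) < 3L) return(NA_real_)
    pearson_pop(w, l)
  })
  keep <- !is.na(r)
  n_excl <- sum(!keep)
  if (n_excl > 0 && !quiet) {
    inform(sprintf(
      "%d molecule(s) excluded from correlations (N < 3 or zero variance)",
      n_excl))
  }
  out <- tibble(system_id = dataset$system_id[keep],
                L = dataset$L[keep], pearson_r = r[keep])
  attr(out, "n_excluded") <- n_excl
  out
}

#' Size-intensivity audit
#'
#' Replicates each record k times as a non-interacting supersystem (gap
#' `separation`, which must exceed twice the descriptor cutoff) and compares
#' the prediction with the monomer prediction. Intensive heads must deviate
#' by at most 1e-6 eV; for the extensive `sum` head the ratio to the monomer
#' prediction is reported instead (ideal ratio k).
#'
#' @param model A trained `owa_model`.
#' @param dataset Records to audit.
#' @param k Replication counts (default `c(2, 3, 5)`).
#' @param separation Fragment gap in Angstrom (default
#'   `2.5 * cutoff`).
#' @return Tibble with `system_id`, `k`, `monomer`, `supersystem` (eV) and
#'   either `deviation` (eV, intensive heads) or `ratio` (sum head).
#' @export
intensivity_audit <- function(model, dataset, k = c(2L, 3L, 5L),
                              separation = NULL) {
  cutoff <- descriptor_cutoff_of(model)
  separation <- separation %||% (2.5 * cutoff)
  if (separation <= 2 * cutoff) {
    abort(sprintf("separation %.3g must exceed 2 x cutoff = %.3g",
                  separation, 2 * cutoff))
  }
  is_sum <- model$config$pooling$name == "sum"
  rows <- list()
  for (i in seq_len(nrow(dataset))) {
    mono_ds <- dataset[i, ]
    mono <- predict(model, record_system(dataset, i),
                    l_frac = dataset$l_frac[[i]])$energy
    for (kk in k) {
      rep_ds <- mono_ds[rep(1L, kk), ]
      super <- compose_noninteracting(rep_ds, separation,
                                      descriptor_cutoff = cutoff)
      ps <- predict(model, record_system(super, 1L),
                    l_frac = super$l_frac[[1]])$energy
      rows[[length(rows) + 1L]] <- tibble(
        system_id = dataset$system_id[[i]], k = kk,
        monomer = mono, supersystem = ps,
        deviation = if (!is_sum) abs(ps - mono) else NA_real_,
        ratio = if (is_sum) ps / mono else NA_real_)
    }
  }
  bind_rows(rows)
}

descriptor_cutoff_of <- function(model) {
  d <- model$config$descriptor
  if (inherits(d, "descriptor_config")) return(d$cutoff_radius)
  abort("cannot determine the cutoff of an adapter descriptor; pass separation explicitly")
}

#' Learning curves over training-set size
#'
#' For each pooling-head configuration, training size and seed: draw a fresh
#' training subsample from the train pool, train, and evaluate stratified
#' RMSE on the fixed test split. Mirrors the five-random-draws protocol used
#' for learning-curve error bars.
#'
#' @param dataset An `orb_dataset` with `train`/`val`/`test` splits; the
#'   train split is the subsampling pool.
#' @param model_cfgs Named list of [model_config()]s (names label the
#'   heads).
#' @param sizes Ascending training-set sizes.
#' @param seeds Seeds for the random draws (default `1:5`).
#' @param loss_cfgs Optional named list of [loss_config()]s matching
#'   `model_cfgs` (default: plain energy loss, with `beta = 1` for `owa`
#'   configs).
#' @param ... Passed to [train_pooling_model()].
#' @return Long tibble: `head`, `size`, `seed`, `rmse_overall`,
#'   `rmse_localized`, `rmse_delocalized`, `rmse_middle`; summarize with
#'   [summarise_learning_curve()].
#' @export
learning_curve <- function(dataset, model_cfgs, sizes, seeds = 1:5,
                           loss_cfgs = NULL, ...) {
  if (is.unsorted(sizes)) abort("sizes must be ascending")
  pool <- which(dataset$split == "train")
  val <- which(dataset$split == "val")
  test_ds <- dataset[dataset$split == "test", ]
  if (max(sizes) > length(pool)) {
    abort(sprintf("largest size %d exceeds the train pool (%d records)",
                  max(sizes), length(pool)))
  }
  if (nrow(test_ds) == 0) abort("dataset has no test split")
  if (is.null(names(model_cfgs))) {
    names(model_cfgs) <- map_chr(model_cfgs, ~ .x$pooling$name)
  }
  rows <- list()
  for (head_nm in names(model_cfgs)) {
    cfg <- model_cfgs[[head_nm]]
    lcfg <- loss_cfgs[[head_nm]] %||%
      loss_config(1, if (cfg$pooling$name == "owa") 1 else 0)
    for (size in sizes) {
      for (seed in seeds) {
        old_seed <- get0(".Random.seed", envir = globalenv())
        set.seed(seed)
        draw <- sample(pool, size)
        if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                       envir = globalenv())
        sub <- dataset[c(draw, val), ]
        cfg_seed <- cfg
        cfg_seed$seed <- as.integer(cfg$seed + seed)
        m <- train_pooling_model(sub, cfg_seed, lcfg, ...)
        rep_i <- stratified_rmse(m, test_ds)
        rows[[length(rows) + 1L]] <- mutate(
          as_tibble(rep_i)[, c("rmse_overall", "rmse_localized",
                               "rmse_delocalized", "rmse_middle")],
          head = head_nm, size = size, seed = seed, .before = 1L)
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("learning_curve", class(out))
  out
}

#' Summarise a learning-curve table
#'
#' Mean and standard deviation of each stratum RMSE across seeds.
#'
#' @param curve Output of [learning_curve()].
#' @return Tibble with one row per (head, size, stratum): `mean_rmse`,
#'   `sd_rmse`, `n_seeds`.
#' @export
summarise_learning_curve <- function(curve) {
  long <- tidyr::pivot_longer(as_tibble(curve),
                              dplyr::starts_with("rmse_"),
                              names_to = "stratum", names_prefix = "rmse_",
                              values_to = "rmse")
  summarise(group_by(long, .data$head, .data$size, .data$stratum),
            mean_rmse = mean(.data$rmse), sd_rmse = stats::sd(.data$rmse),
            n_seeds = dplyr::n(), .groups = "drop")
}

#' Export learned pseudoorbitals
#'
#' Writes the dataset as extended XYZ with the model's pooling weights as a
#' per-atom `owa_weight` column next to the reference `l_frac`, for
#' side-by-side visualization as semitransparent spheres in standard
#' structure viewers.
#'
#' @param model A trained weight-bearing model (`softmax`, `wa`, `owa`,
#'   `coeff`).
#' @param dataset An `orb_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_pseudoorbitals <- function(model, dataset, path) {
  if (!model$config$pooling$name %in% c("softmax", "wa", "owa", "coeff")) {
    abort("pseudoorbital export needs a weight-bearing pooling head")
  }
  preds <- predict_dataset(model, dataset)
  out <- dataset
  out$owa_weight <- preds$weights
  write_extxyz(out, path)
}
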