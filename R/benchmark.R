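# The frozen desk-scale benchmark protocol used by the stratified
# learning-curve and parameter-recovery experiments, so that tests, scripts
# and documentation all run the same stated world.

#' Default synthetic benchmark dataset
#'
#' Generates the benchmark pool with the default tight-binding world
#' (backbones 2-8, 41 substituents, mixed saturated/conjugated, geometry
#' noise 0.05 Angstrom unless `noiseless`) and assigns fixed splits:
#' 60% training pool, 5% validation, 35% test. The large test share keeps
#' the localized stratum (a few percent of records) big enough for stable
#' stratified RMSEs at desk scale.
#'
#' @param seed Generator/split seed (default 21).
#' @param n_molecules Pool size (default 1500).
#' @param noiseless Set the geometry noise to zero (used by the
#'   parameter-recovery experiment).
#' @return An `orb_dataset` with split tags.
#' @export
benchmark_dataset <- function(seed = 21L, n_molecules = 1500L,
                              noiseless = FALSE) {
  gen <- generator_config(n_molecules = n_molecules, seed = seed,
                          geometry_noise_sigma = if (noiseless) 0 else 0.05)
  ds <- withCallingHandlers(
    generate_dataset(gen, tb_params()),
    warning = function(w) invokeRestart("muffleWarning"))
  assign_splits(ds, c(train = 0.60, val = 0.05, test = 0.35), seed = seed)
}

#' Default benchmark model configuration
#'
#' The desk-scale model used in the benchmark experiments: radial descriptor
#' with 8 centers and 5 Angstrom cutoff over the dataset's elements,
#' two 32-unit tanh layers per network, Adam at 3e-3, pure weight-net
#' softmax (`gamma = 0`). Small enough that a full learning-curve run over
#' several heads and seeds stays within minutes on one CPU.
#'
#' @param head Pooling-head name.
#' @param dataset The benchmark dataset (element channels are read from it).
#' @param seed Model seed (default 100).
#' @param mode Pooling mode (default the dataset's).
#' @return A [model_config()].
#' @export
benchmark_model_config <- function(head, dataset, seed = 100L,
                                   mode = NULL) {
  desc <- descriptor_config(sort(unique(unlist(dataset$elements))),
                            cutoff_radius = 5.0, n_centers = 8L)
  model_config(desc, pooling_head(head, mode %||% dataset$mode[[1]]),
               energy_net_layers = c(32L, 32L),
               weight_net_layers = c(32L, 32L),
               learning_rate = 3e-3, seed = as.integer(seed))
}
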