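# Synthetic reference data from an orthogonal tight-binding (Hueckel-like)
# model: one basis function per atom, on-site energies per site symbol,
# distance-decaying hoppings, exact diagonalization. Stands in for a DFT
# reference; only the statistics of orbital localization matter here.

#' Tight-binding model parameters
#'
#' @param onsite_table Named numeric vector mapping site symbols to on-site
#'   energies alpha in eV. Defaults to a backbone carbon at -6 eV plus a fixed
#'   41-entry substituent table `X01..X41` spanning \[-9, -3\] eV.
#' @param hopping_scale t0 in eV, negative (default -1).
#' @param hopping_decay lambda in 1/Angstrom (default 2); hoppings decay as
#'   `t0 * exp(-lambda * (r - r0))`.
#' @param reference_bond r0 in Angstrom (default 1.4). Hoppings are cut off at
#'   `2 * r0`.
#' @param electron_filling Filling rule; only `"half"` is defined: the number
#'   of occupied orbitals is `floor(N / 2)` with a minimum of 1.
#' @param degeneracy_tol Eigenvalues within this window of the HOMO are
#'   treated as one degenerate subspace (default 1e-6 eV).
#' @return A `tb_params` object.
#' @export
tb_params <- function(onsite_table = default_onsite_table(),
                      hopping_scale = -1.0, hopping_decay = 2.0,
                      reference_bond = 1.4, electron_filling = "half",
                      degeneracy_tol = 1e-6) {
  if (hopping_scale >= 0) abort("hopping_scale t0 must be negative")
  if (hopping_decay <= 0) abort("hopping_decay lambda must be positive")
  if (reference_bond <= 0) abort("reference_bond r0 must be positive")
  if (!identical(electron_filling, "half")) {
    abort("only half filling is implemented")
  }
  if (is.null(names(onsite_table)) || any(!nzchar(names(onsite_table)))) {
    abort("onsite_table must be a named numeric vector")
  }
  structure(list(onsite_table = onsite_table,
                 hopping_scale = hopping_scale,
                 hopping_decay = hopping_decay,
                 reference_bond = reference_bond,
                 electron_filling = electron_filling,
                 degeneracy_tol = degeneracy_tol),
            class = "tb_params")
}

#' Default on-site energy table
#'
#' Backbone carbon at -6 eV plus 41 substituent site symbols `X01..X41` with
#' on-site energies evenly spaced over \[-9, -3\] eV, mirroring the diversity
#' of electron-donating and electron-withdrawing side groups: levels inside
#' the occupied backbone manifold produce localized HOMOs, levels outside it
#' leave the HOMO on the delocalized backbone.
#'
#' @return Named numeric vector of on-site energies (eV).
#' @export
default_onsite_table <- function() {
  subs <- seq(-9, -3, length.out = 41)
  names(subs) <- sprintf("X%02d", 1:41)
  c(C = -6.0, subs)
}

#' Synthetic-molecule generator configuration
#'
#' Describes the library of backbones and substituents the generator samples:
#' zig-zag carbon backbones of 2-8 sites, saturated (narrow band) or
#' conjugated (full hopping), decorated with one or two single-site
#' substituent fragments whose attachment sites are at least
#' `min_site_separation` backbone atoms apart.
#'
#' @param backbone_lengths Integer vector of allowed backbone lengths
#'   (default 2:8).
#' @param backbone_kind `"mixed"` (default; each molecule drawn 50/50),
#'   `"saturated"` or `"conjugated"`.
#' @param substituent_library Tibble with columns `symbol` (site symbol) and
#'   `attach_dist` (Angstrom, distance from the backbone attachment site);
#'   defaults to the 41 symbols of [default_onsite_table()] with attachment
#'   distances cycling over 1.0-1.8 bond lengths so coupling strengths vary.
#' @param min_site_separation Minimum backbone-site separation between two
#'   substitution sites (default 3).
#' @param backbone_bond Named vector of backbone bond lengths in Angstrom
#'   (default saturated 1.54, conjugated 1.35, the C-C vs C=C distinction),
#'   so the backbone kind is visible to geometric descriptors.
#' @param saturated_hopping_factor Multiplier on `hopping_scale` for
#'   saturated backbones (default 0.35), emulating the narrower sigma band.
#' @param geometry_noise_sigma Gaussian positional noise in Angstrom
#'   (default 0.05).
#' @param seed RNG seed (default 1).
#' @param n_molecules Number of molecules to generate (default 500).
#' @return A `generator_config` object.
#' @export
generator_config <- function(backbone_lengths = 2:8,
                             backbone_kind = c("mixed", "saturated",
                                               "conjugated"),
                             substituent_library = default_substituent_library(),
                             min_site_separation = 3L,
                             backbone_bond = c(saturated = 1.54,
                                               conjugated = 1.35),
                             saturated_hopping_factor = 0.35,
                             geometry_noise_sigma = 0.05,
                             seed = 1L, n_molecules = 500L) {
  backbone_kind <- match.arg(backbone_kind)
  if (min_site_separation < 1L) abort("min_site_separation must be >= 1")
  if (n_molecules < 1L) abort("n_molecules must be >= 1")
  if (any(backbone_lengths < 2L)) abort("backbone lengths must be >= 2")
  if (!all(c("symbol", "attach_dist") %in% names(substituent_library))) {
    abort("substituent_library needs columns 'symbol' and 'attach_dist'")
  }
  if (!all(c("saturated", "conjugated") %in% names(backbone_bond))) {
    abort("backbone_bond must name saturated and conjugated lengths")
  }
  structure(list(backbone_lengths = as.integer(backbone_lengths),
                 backbone_kind = backbone_kind,
                 substituent_library = substituent_library,
                 min_site_separation = as.integer(min_site_separation),
                 backbone_bond = backbone_bond,
                 saturated_hopping_factor = saturated_hopping_factor,
                 geometry_noise_sigma = geometry_noise_sigma,
                 seed = as.integer(seed),
                 n_molecules = as.integer(n_molecules)),
            class = "generator_config")
}

#' Default substituent fragment library
#'
#' One single-site fragment per substituent symbol; attachment distances
#' cycle over `r0 * c(1.0, 1.2, 1.4, 1.6, 1.8)` so substituent-backbone
#' couplings span strong to weak (the hopping decays exponentially with
#' distance); substituent levels inside the occupied backbone window with
#' weak attachment produce the strongly localized frontier orbitals.
#'
#' @param r0 Reference bond length in Angstrom (default 1.4).
#' @return Tibble with columns `symbol` and `attach_dist`.
#' @export
default_substituent_library <- function(r0 = 1.4) {
  tibble(symbol = sprintf("X%02d", 1:41),
         attach_dist = r0 * rep(c(1.0, 1.2, 1.4, 1.6, 1.8),
                                length.out = 41))
}

#' Build the tight-binding Hamiltonian of a system
#'
#' `H[i, i] = alpha(element_i)`; `H[i, j] = t0 * exp(-lambda * (r_ij - r0))`
#' for `r_ij <= 2 * r0` and atoms sharing a fragment label, else 0. Atoms in
#' different fragments are exactly non-interacting, so the spectrum of a
#' composed supersystem is the union of its fragment spectra.
#'
#' @param system An [atomic_system()]; every element symbol must appear in
#'   the on-site table.
#' @param params A [tb_params()].
#' @param hopping_factor Optional multiplier on the hopping scale (used for
#'   saturated backbones).
#' @return Symmetric N x N matrix in eV.
#' @export
build_hamiltonian <- function(system, params, hopping_factor = 1.0) {
  unknown <- setdiff(unique(system$elements), names(params$onsite_table))
  if (length(unknown) > 0) {
    abort(sprintf("elements not in onsite_table: %s",
                  paste(unknown, collapse = ", ")))
  }
  n <- n_atoms(system)
  alpha <- unname(params$onsite_table[system$elements])
  H <- diag(alpha, nrow = n)
  if (n > 1L) {
    d <- as.matrix(stats::dist(system$coords))
    t0 <- params$hopping_scale * hopping_factor
    hop <- t0 * exp(-params$hopping_decay * (d - params$reference_bond))
    cutoff <- 2 * params$reference_bond
    same_frag <- outer(system$fragment, system$fragment, "==")
    mask <- (d <= cutoff) & same_frag
    diag(mask) <- FALSE
    H[mask] <- hop[mask]
    H <- (H + t(H)) / 2
  }
  H
}

#' Diagonalize a tight-binding Hamiltonian
#'
#' Exact eigendecomposition at half filling: `floor(N / 2)` occupied orbitals
#' (minimum 1); the HOMO is the highest occupied eigenvalue and becomes the
#' target energy. Localization fractions come from the HOMO eigenvector (the
#' basis is orthogonal, so `l_i = c_i^2`); if the HOMO is degenerate within
#' `degeneracy_tol`, fractions are averaged over the degenerate subspace
#' (a basis-invariant projector average) and `degenerate` is flagged.
#'
#' @param H Symmetric finite matrix (eV).
#' @param params A [tb_params()].
#' @param mode `"max"` (HOMO energy) or `"min"` (stored IE-style target); the
#'   target is the HOMO eigenvalue either way, the mode only tags the record.
#' @return List with `reference` (an [electronic_reference()]), `values`
#'   (eigenvalues ascending), `vectors` (columns matching `values`),
#'   `homo_index` and `degenerate`.
#' @export
solve_orbitals <- function(H, params, mode = c("max", "min")) {
  mode <- match.arg(mode)
  H <- as.matrix(H)
  if (!all(is.finite(H))) abort("Hamiltonian must be finite")
  if (nrow(H) != ncol(H) ||
      max(abs(H - t(H))) > 1e-10 * max(1, max(abs(H)))) {
    abort("Hamiltonian must be symmetric")
  }
  n <- nrow(H)
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)
  values <- es$values[ord]
  vectors <- es$vectors[, ord, drop = FALSE]
  occ <- max(1L, floor(n / 2))
  homo <- values[occ]
  sub <- which(abs(values - homo) < params$degeneracy_tol)
  degenerate <- length(sub) > 1L
  l <- rowMeans(vectors[, sub, drop = FALSE]^2)
  l <- l / sum(l)
  L <- if (n >= 2L) localization_index(l) else NULL
  list(
    reference = electronic_reference(homo, mode = mode, l_frac = l, L = L),
    values = values, vectors = vectors,
    homo_index = occ, degenerate = degenerate
  )
}

# zig-zag backbone of n carbon sites in the xy plane, bond length r0
backbone_geometry <- function(n, r0) {
  j <- seq_len(n) - 1L
  cbind(x = j * r0 * sin(pi / 3),
        y = (j %% 2) * r0 * cos(pi / 3),
        z = rep(0, n))
}

#' Generate a synthetic labeled dataset
#'
#' Samples molecules from the configured backbone/substituent library, builds
#' their tight-binding Hamiltonians, diagonalizes exactly and emits records
#' with geometry, HOMO energy target (mode `"max"`), localization fractions
#' and index L. Deterministic for a fixed seed. At default settings the L
#' distribution spans both regimes: at least 5% of records with L >= 0.8 and
#' at least 20% with L < 0.4.
#'
#' @param config A [generator_config()].
#' @param params A [tb_params()].
#' @return An `orb_dataset` with `n_molecules` records, all tagged `train`
#'   (see [assign_splits()]).
#' @export
generate_dataset <- function(config = generator_config(),
                             params = tb_params()) {
  lib_unknown <- setdiff(unique(config$substituent_library$symbol),
                         names(params$onsite_table))
  if (length(lib_unknown) > 0) {
    abort(sprintf("substituent symbols not in onsite_table: %s",
                  paste(lib_unknown, collapse = ", ")))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(config$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  systems <- vector("list", config$n_molecules)
  refs <- vector("list", config$n_molecules)
  skipped <- 0L
  for (i in seq_len(config$n_molecules)) {
    nb <- sample_one(config$backbone_lengths)
    kind <- switch(config$backbone_kind,
                   mixed = sample_one(c("saturated", "conjugated")),
                   config$backbone_kind)
    coords <- backbone_geometry(nb, config$backbone_bond[[kind]])
    elements <- rep("C", nb)
    # substituent placement: one or two sites, >= min_site_separation apart
    n_sub <- sample_one(1:2)
    sites <- sample_one(seq_len(nb))
    if (n_sub == 2L) {
      ok <- which(abs(seq_len(nb) - sites) >= config$min_site_separation)
      if (length(ok) == 0L) {
        skipped <- skipped + 1L
      } else {
        sites <- c(sites, sample_one(ok))
      }
    }
    for (k in seq_along(sites)) {
      row <- config$substituent_library[
        sample_one(seq_len(nrow(config$substituent_library))), ]
      side <- if (k %% 2 == 1) 1 else -1
      pos <- coords[sites[k], ] + c(0, 0, side * row$attach_dist)
      coords <- rbind(coords, pos)
      elements <- c(elements, row$symbol)
    }
    coords <- coords +
      matrix(rnorm(length(coords), sd = config$geometry_noise_sigma),
             ncol = 3L)
    sys <- atomic_system(elements, coords,
                         system_id = sprintf("tb_%05d", i))
    hf <- if (kind == "saturated") config$saturated_hopping_factor else 1.0
    H <- build_hamiltonian(sys, params, hopping_factor = hf)
    sol <- solve_orbitals(H, params, mode = "max")
    systems[[i]] <- sys
    refs[[i]] <- sol$reference
  }
  if (skipped > 0L) {
    warn(sprintf(
      "%d second substituent(s) skipped: no site %d+ backbone atoms away",
      skipped, config$min_site_separation))
  }
  orb_dataset(systems, refs,
              provenance = sprintf("tight-binding generator, seed %d",
                                   config$seed))
}

# sample() with surprise-free single-element behaviour
sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Assign train/val/test split tags
#'
#' Random partition by fractions, deterministic for a fixed seed.
#'
#' @param dataset An `orb_dataset`.
#' @param fractions Named numeric vector over train/val/test, summing to 1.
#' @param seed RNG seed.
#' @return The dataset with its `split` column reassigned.
#' @export
assign_splits <- function(dataset, fractions = c(train = 0.8, val = 0.1,
                                                 test = 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 ||
      !setequal(names(fractions), c("train", "val", "test"))) {
    abort("fractions must be named train/val/test and sum to 1")
  }
  n <- nrow(dataset)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  perm <- sample.int(n)
  n_train <- round(fractions[["train"]] * n)
  n_val <- round(fractions[["val"]] * n)
  tags <- rep("test", n)
  tags[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0 && n_train < n) {
    tags[perm[(n_train + 1):min(n, n_train + n_val)]] <- "val"
  }
  dataset$split <- tags
  dataset
}

#' Compose a non-interacting supersystem
#'
#' Concatenates the records of `dataset` along +x with gaps of `separation`
#' between fragment bounding boxes and distinct fragment labels, so fragments
#' neither couple in the tight-binding Hamiltonian (cutoff `2 * r0`) nor see
#' each other in any descriptor with cutoff below `separation / 2`. The
#' supersystem target is the max (mode `"max"`) or min (mode `"min"`) over
#' subsystem targets; localization fractions are the winning fragment's on
#' its atoms and exactly zero elsewhere, with targets tied within 1e-9
#' averaged across the tied fragments.
#'
#' @param dataset An `orb_dataset` of the subsystems (all same mode).
#' @param separation Gap between consecutive fragments in Angstrom.
#' @param descriptor_cutoff Optional descriptor cutoff radius; when given,
#'   `separation > 2 * descriptor_cutoff` is enforced.
#' @param system_id Identifier for the composed record.
#' @return A one-row `orb_dataset`.
#' @export
compose_noninteracting <- function(dataset, separation,
                                   descriptor_cutoff = NULL,
                                   system_id = NULL) {
  validate_orb_dataset(dataset)
  if (nrow(dataset) < 1L) abort("need at least one subsystem")
  if (separation <= 0) abort("separation must be positive")
  if (!is.null(descriptor_cutoff) && separation <= 2 * descriptor_cutoff) {
    abort(sprintf(
      "separation %.3g must exceed twice the descriptor cutoff (2 x %.3g)",
      separation, descriptor_cutoff))
  }
  k <- nrow(dataset)
  mode <- dataset$mode[[1]]
  coords <- list()
  offset <- 0
  for (m in seq_len(k)) {
    xyz <- dataset$coords[[m]]
    shift <- offset - min(xyz[, 1])
    xyz[, 1] <- xyz[, 1] + shift
    coords[[m]] <- xyz
    offset <- max(xyz[, 1]) + separation
  }
  elements <- unlist(dataset$elements)
  fragment <- rep(seq_len(k) - 1L, times = map_int(dataset$elements, length))
  targets <- dataset$target_energy
  best <- if (mode == "max") max(targets) else min(targets)
  winners <- which(abs(targets - best) <= 1e-9)
  n_tot <- length(elements)
  if (all(!map_lgl(dataset$l_frac[winners], is.null))) {
    l <- numeric(n_tot)
    starts <- cumsum(c(0L, map_int(dataset$elements, length)))
    for (m in winners) {
      idx <- (starts[m] + 1L):starts[m + 1L]
      l[idx] <- dataset$l_frac[[m]] / length(winners)
    }
    L <- if (n_tot >= 2L) localization_index(l) else NULL
  } else {
    l <- NULL
    L <- NULL
  }
  sys <- atomic_system(
    elements, do.call(rbind, coords),
    system_id = system_id %||%
      paste0("super[", paste(dataset$system_id, collapse = "+"), "]"),
    fragment = fragment)
  orb_dataset(list(sys),
              list(electronic_reference(best, mode = mode, l_frac = l,
                                        L = L)),
              provenance = "compose_noninteracting")
}

#' Water and carbon-dioxide ionization-energy fixtures
#'
#' The two monomers of the classic non-interacting supersystem argument:
#' water (r_OH = 0.96 Angstrom, angle 104.5 degrees, IE 12.6 eV) and linear
#' CO2 (r_CO = 1.16 Angstrom, IE 13.8 eV), both mode `"min"`. The attached
#' localization fractions are synthetic stand-ins concentrating the ionized
#' orbital on oxygen (water lone pair; CO2 pi_g), for exercising
#' weight-supervised heads on the toy problem.
#'
#' @return A two-record `orb_dataset` (water first).
#' @export
toy_monomer_fixtures <- function() {
  ang <- 104.5 * pi / 180
  water <- atomic_system(
    c("O", "H", "H"),
    rbind(c(0, 0, 0),
          c(0.96, 0, 0),
          c(0.96 * cos(ang), 0.96 * sin(ang), 0)),
    system_id = "water")
  co2 <- atomic_system(
    c("C", "O", "O"),
    rbind(c(0, 0, 0), c(1.16, 0, 0), c(-1.16, 0, 0)),
    system_id = "co2")
  refs <- list(
    electronic_reference(12.6, mode = "min", l_frac = c(0.8, 0.1, 0.1),
                         L = localization_index(c(0.8, 0.1, 0.1))),
    electronic_reference(13.8, mode = "min", l_frac = c(0.1, 0.45, 0.45),
                         L = localization_index(c(0.1, 0.45, 0.45)))
  )
  orb_dataset(list(water, co2), refs, provenance = "toy monomer fixtures")
}
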