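#' Orbital vector in an atomic basis
#'
#' A normalized molecular orbital expressed as coefficients over atom-centered
#' basis functions, with a map from basis function to atom and an optional
#' overlap matrix (identity when absent, i.e. an orthogonal basis).
#'
#' @param coefficients Numeric length-M coefficient vector `c`.
#' @param basis_to_atom Integer length-M vector mapping each basis function to
#'   its atom (1-based); atoms `1..N` must all be covered.
#' @param overlap Optional M x M symmetric overlap matrix `S`; identity when
#'   `NULL`.
#' @return An object of class `orbital_vector`.
#' @details The orbital must satisfy the normalization `t(c) S c = 1` within
#'   1e-8; construction aborts otherwise.
#' @export
orbital_vector <- function(coefficients, basis_to_atom, overlap = NULL) {
  coefficients <- as.numeric(coefficients)
  m <- length(coefficients)
  basis_to_atom <- as.integer(basis_to_atom)
  if (length(basis_to_atom) != m) {
    abort("basis_to_atom must map every basis function")
  }
  n_atoms <- max(basis_to_atom)
  if (!setequal(unique(basis_to_atom), seq_len(n_atoms))) {
    abort("basis_to_atom must cover atoms 1..N")
  }
  if (!is.null(overlap)) {
    overlap <- as.matrix(overlap)
    if (!isTRUE(all.equal(overlap, t(overlap), tolerance = 1e-10))) {
      abort("overlap matrix must be symmetric")
    }
    norm2 <- drop(crossprod(coefficients, overlap %*% coefficients))
  } else {
    norm2 <- sum(coefficients^2)
  }
  if (abs(norm2 - 1) > 1e-8) {
    abort(sprintf("orbital is not normalized: c'Sc = %.10f", norm2))
  }
  structure(list(coefficients = coefficients,
                 basis_to_atom = basis_to_atom,
                 overlap = overlap, n_atoms = n_atoms),
            class = "orbital_vector")
}

#' Mulliken localization fractions of an orbital
#'
#' The fraction of a normalized orbital residing on each atom,
#' `l_i = sum_{mu in i} sum_nu c_mu c_nu S_munu`, which reduces to
#' `l_i = sum_{mu in i} c_mu^2` in an orthogonal basis. The fractions sum to
#' one; with a non-identity overlap individual Mulliken contributions can be
#' slightly negative and are returned unclipped (see
#' [clip_fractions_for_training()] for the training-label variant).
#'
#' @param orbital An [orbital_vector()].
#' @return Numeric length-N vector `l` with `sum(l) == 1` within 1e-8.
#' @export
#' @examples
#' localization_fraction(orbital_vector(c(1, 0, 0), 1:3))        # one-hot
#' localization_fraction(orbital_vector(rep(1 / sqrt(2), 2), 1:2))
localization_fraction <- function(orbital) {
  if (!inherits(orbital, "orbital_vector")) {
    abort("localization_fraction expects an orbital_vector")
  }
  cc <- orbital$coefficients
  if (is.null(orbital$overlap)) {
    per_basis <- cc^2
  } else {
    per_basis <- cc * drop(orbital$overlap %*% cc)
  }
  l <- as.numeric(rowsum(per_basis, orbital$basis_to_atom,
                         reorder = TRUE))
  if (abs(sum(l) - 1) > 1e-8) {
    abort("localization fractions do not sum to 1; orbital not normalized?")
  }
  l
}

#' Orbital localization index
#'
#' A scalar summary `L` of how concentrated the localization fractions are:
#' `L = (N * sum(l_i^2) - 1) / (N - 1)`, a normalized inverse participation
#' ratio. `L = 1` when the orbital sits entirely on one atom, `L = 0` when it
#' is spread uniformly over all `N` atoms, and `L` increases whenever mass
#' moves from a low-fraction atom to the dominant one.
#'
#' @param l Numeric vector of localization fractions (non-negative up to
#'   -1e-8, summing to 1 within 1e-8, length N >= 2).
#' @return Scalar `L` in \[0, 1\].
#' @export
#' @examples
#' localization_index(c(1, 0, 0, 0))        # 1
#' localization_index(rep(0.25, 4))         # 0
#' localization_index(c(0.7, 0.1, 0.1, 0.1))
localization_index <- function(l) {
  l <- as.numeric(l)
  n <- length(l)
  if (n < 2L) {
    abort("localization index is undefined for a single atom (N = 1)")
  }
  if (any(l < -1e-8)) abort("localization fractions must be >= 0")
  if (abs(sum(l) - 1) > 1e-8) {
    abort("localization fractions must sum to 1")
  }
  (n * sum(l^2) - 1) / (n - 1)
}

#' Stratify a dataset by localization index
#'
#' Partitions record indices into a localized stratum (`L >= localized_cut`),
#' a delocalized stratum (`L < delocalized_cut`) and the middle band; the
#' lower boundary is strict, the upper inclusive.
#'
#' @param dataset An `orb_dataset` whose records all carry `L`.
#' @param localized_cut Localized threshold, default 0.8.
#' @param delocalized_cut Delocalized threshold, default 0.4.
#' @return A list with integer index vectors `localized`, `delocalized` and
#'   `middle`; disjoint and jointly exhaustive.
#' @export
stratify_by_L <- function(dataset, localized_cut = 0.8,
                          delocalized_cut = 0.4) {
  L <- dataset$L
  if (any(is.na(L))) {
    abort("every record must carry a localization index L")
  }
  list(
    localized = which(L >= localized_cut),
    delocalized = which(L < delocalized_cut),
    middle = which(L >= delocalized_cut & L < localized_cut)
  )
}

#' Clip Mulliken fractions into a valid probability vector
#'
#' Mulliken populations can be slightly negative with non-identity overlap.
#' For use as weight-network training labels (the softmax codomain) negatives
#' are clipped to zero and the vector renormalized; the number of clipped
#' entries is reported via a message when positive.
#'
#' @param l Numeric fraction vector.
#' @param quiet Suppress the clipping message.
#' @return A non-negative vector summing to 1.
#' @export
clip_fractions_for_training <- function(l, quiet = FALSE) {
  neg <- sum(l < 0)
  if (neg > 0 && !quiet) {
    inform(sprintf("clipped %d negative Mulliken contribution(s)", neg))
  }
  l <- pmax(l, 0)
  s <- sum(l)
  if (s <= 0) abort("all fractions clipped to zero; invalid labels")
  l / s
}
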