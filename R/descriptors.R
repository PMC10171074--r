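# Reference per-atom environment representation: element-resolved radial
# symmetry functions with a smooth cosine cutoff. Minimal but sufficient for
# pooling comparisons, which are representation-agnostic; external per-atom
# representations plug in through the adapter registry.

#' Radial descriptor configuration
#'
#' `K` Gaussian radial centers evenly spaced in `[0.5, cutoff]`, one channel
#' block per element symbol. The width of center k is
#' `eta = 1 / (2 * dmu^2)` with `dmu` the center spacing, so neighboring
#' Gaussians overlap smoothly.
#'
#' @param element_channels Ordered character vector of element symbols the
#'   descriptor resolves (deduplicated, non-empty).
#' @param cutoff_radius Cutoff radius in Angstrom (default 5).
#' @param n_centers Number of radial centers K (default 16).
#' @return A `descriptor_config` object with fields `centers`, `eta`,
#'   `cutoff_radius`, `element_channels` and a `config_hash`.
#' @export
descriptor_config <- function(element_channels, cutoff_radius = 5.0,
                              n_centers = 16L) {
  element_channels <- unique(as.character(element_channels))
  if (length(element_channels) == 0) {
    abort("element_channels must be non-empty")
  }
  if (n_centers < 1L) abort("need at least one radial center")
  centers <- seq(0.5, cutoff_radius, length.out = max(n_centers, 2L))
  if (n_centers == 1L) centers <- centers[1]
  if (cutoff_radius <= max(centers) - 1e-12 && n_centers > 1L) {
    # centers reach exactly the cutoff; f_c vanishes there so this is fine
  }
  dmu <- if (n_centers > 1L) centers[2] - centers[1] else cutoff_radius / 2
  structure(list(
    cutoff_radius = cutoff_radius,
    n_centers = as.integer(n_centers),
    centers = centers[seq_len(n_centers)],
    eta = 1 / (2 * dmu^2),
    element_channels = element_channels,
    config_hash = paste0("radial-", n_centers, "-",
                         format(cutoff_radius), "-",
                         paste(element_channels, collapse = "."))
  ), class = "descriptor_config")
}

#' Cosine cutoff function
#'
#' `f_c(r) = 0.5 * (cos(pi * r / r_cut) + 1)` up to the cutoff, 0 beyond it;
#' both the function and its first derivative vanish at the cutoff.
#'
#' @param r Distances in Angstrom.
#' @param r_cut Cutoff radius.
#' @return Values in \[0, 1\].
#' @export
cutoff_fn <- function(r, r_cut) {
  ifelse(r <= r_cut, 0.5 * (cos(pi * r / r_cut) + 1), 0)
}

#' Featurize a system with the radial descriptor
#'
#' Entry for atom i and channel (Z, k):
#' `sum over neighbors j of element Z of
#' exp(-eta_k * (r_ij - mu_k)^2) * f_c(r_ij)`.
#' Rows are permutation-equivariant with the atom order and invariant under
#' global rotations and translations (distances only).
#'
#' @param system An [atomic_system()]; every element must appear in
#'   `config$element_channels`.
#' @param config A [descriptor_config()] or the name of a registered adapter.
#' @return A `descriptor_matrix`: list with `values` (N x D matrix,
#'   `D = K * n_channels`, finite and non-negative) and `config_hash`.
#' @export
featurize <- function(system, config) {
  if (is.character(config)) {
    fn <- get_descriptor_adapter(config)
    return(fn(system))
  }
  unknown <- setdiff(unique(system$elements), config$element_channels)
  if (length(unknown) > 0) {
    abort(sprintf("elements not in descriptor channels: %s",
                  paste(unknown, collapse = ", ")))
  }
  n <- n_atoms(system)
  K <- config$n_centers
  nc <- length(config$element_channels)
  vals <- matrix(0, nrow = n, ncol = K * nc)
  if (n > 1L) {
    d <- as.matrix(stats::dist(system$coords))
    fc <- cutoff_fn(d, config$cutoff_radius)
    diag(fc) <- 0
    for (ci in seq_len(nc)) {
      z <- config$element_channels[ci]
      is_z <- system$elements == z
      if (!any(is_z)) next
      fcz <- fc[, is_z, drop = FALSE]
      dz <- d[, is_z, drop = FALSE]
      for (k in seq_len(K)) {
        g <- exp(-config$eta * (dz - config$centers[k])^2) * fcz
        vals[, (ci - 1L) * K + k] <- rowSums(g)
      }
    }
  }
  structure(list(values = vals, config_hash = config$config_hash),
            class = "descriptor_matrix")
}

#' Check that fragments are outside each other's descriptor range
#'
#' `TRUE` iff every atom's descriptor row equals the row it would have in its
#' isolated fragment, within 1e-10 — i.e. the fragments sit beyond the
#' cutoff, the premise that lets intensive pooling extrapolate to
#' non-interacting supersystems.
#'
#' @param system An [atomic_system()] with at least two distinct fragment
#'   labels.
#' @param config A [descriptor_config()].
#' @return Logical scalar.
#' @export
locality_check <- function(system, config) {
  labels <- unique(system$fragment)
  if (length(labels) < 2L) {
    abort("locality_check needs a system with >= 2 fragments")
  }
  full <- featurize(system, config)$values
  for (lab in labels) {
    idx <- which(system$fragment == lab)
    sub <- atomic_system(system$elements[idx],
                         system$coords[idx, , drop = FALSE],
                         system_id = "fragment", fragment = rep(0L,
                                                                length(idx)))
    iso <- featurize(sub, config)$values
    if (max(abs(full[idx, , drop = FALSE] - iso)) > 1e-10) return(FALSE)
  }
  TRUE
}

# adapter registry: external per-atom representations by name
descriptor_registry <- new.env(parent = emptyenv())

#' Register a descriptor adapter
#'
#' Any callable mapping an [atomic_system()] to a `descriptor_matrix`-shaped
#' list (`values`: N x D matrix, `config_hash`: string) can stand in for the
#' reference descriptor, provided it is permutation-equivariant.
#'
#' @param name Adapter name.
#' @param fn Function of one argument (the system).
#' @return `name`, invisibly.
#' @export
register_descriptor_adapter <- function(name, fn) {
  if (!is.function(fn)) abort("adapter must be a function")
  assign(name, fn, envir = descriptor_registry)
  invisible(name)
}

get_descriptor_adapter <- function(name) {
  if (!exists(name, envir = descriptor_registry)) {
    abort(sprintf("no descriptor adapter registered under '%s'", name))
  }
  get(name, envir = descriptor_registry)
}
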