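#' Atomic system
#'
#' A single molecule or non-interacting supersystem: element symbols, Cartesian
#' coordinates in Angstrom, an identifier and optional per-atom fragment labels
#' marking non-interacting subsystems (all zero for a monomer).
#'
#' @param elements Character vector of element symbols (length N >= 1).
#' @param coords Numeric N x 3 matrix of Cartesian positions, Angstrom.
#' @param system_id Opaque identifier string.
#' @param fragment Optional integer vector of per-atom fragment labels
#'   (default all 0). Atoms in different fragments never interact.
#' @return An object of class `atomic_system`.
#' @export
#' @examples
#' atomic_system(c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'               system_id = "water")
atomic_system <- function(elements, coords, system_id = "system",
                          fragment = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) abort("an atomic system needs at least one atom")
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (nrow(coords) != n) {
    abort(sprintf("coords has %d rows but there are %d elements",
                  nrow(coords), n))
  }
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  if (is.null(fragment)) fragment <- integer(n)
  fragment <- as.integer(fragment)
  if (length(fragment) != n) {
    abort("fragment labels must have one entry per atom")
  }
  structure(
    list(elements = elements, coords = coords,
         system_id = as.character(system_id)[1], fragment = fragment),
    class = "atomic_system"
  )
}

#' @export
print.atomic_system <- function(x, ...) {
  comp <- paste(sprintf("%s%d", names(table(x$elements)), table(x$elements)),
                collapse = "")
  cat(sprintf("<atomic_system> %s: %d atoms [%s], %d fragment(s)\n",
              x$system_id, length(x$elements), comp,
              length(unique(x$fragment))))
  invisible(x)
}

n_atoms <- function(system) length(system$elements)

#' Reference electronic data for one system
#'
#' Bundles the scalar target (eV), optional Mulliken localization fractions
#' `l_i` of the frontier orbital, the optional localization index `L`, and the
#' pooling mode: `"max"` for HOMO energies (the property tracks the highest
#' per-atom contribution), `"min"` for ionization or LUMO energies.
#'
#' @param target_energy Scalar reference value in eV.
#' @param mode `"max"` or `"min"`.
#' @param l_frac Optional numeric vector of per-atom localization fractions;
#'   must be non-negative and sum to 1 within 1e-8.
#' @param L Optional localization index in \[0, 1\].
#' @return An object of class `electronic_reference`.
#' @export
electronic_reference <- function(target_energy, mode = c("max", "min"),
                                 l_frac = NULL, L = NULL) {
  mode <- match.arg(mode)
  target_energy <- as.numeric(target_energy)[1]
  if (!is.finite(target_energy)) abort("target_energy must be finite")
  if (!is.null(l_frac)) {
    l_frac <- as.numeric(l_frac)
    if (any(l_frac < -1e-8)) {
      abort("localization fractions must be non-negative")
    }
    if (abs(sum(l_frac) - 1) > 1e-8) {
      abort(sprintf("localization fractions sum to %.10f, not 1", sum(l_frac)))
    }
  }
  if (!is.null(L)) {
    L <- as.numeric(L)[1]
    if (L < -1e-9 || L > 1 + 1e-9) {
      abort(sprintf("localization index %.3g outside [0, 1]", L))
    }
  }
  structure(list(target_energy = target_energy, mode = mode,
                 l_frac = l_frac, L = L),
            class = "electronic_reference")
}

#' Labeled dataset of atomic systems
#'
#' An `orb_dataset` is a tibble with one row per labeled system. Geometry
#' fields are list-columns so the whole dataset pipes through dplyr verbs.
#' All records share one `mode`; `split` tags partition records into
#' train/val/test.
#'
#' @param systems List of [atomic_system()] objects.
#' @param references List of [electronic_reference()] objects (same length).
#' @param split Character vector of `"train"`, `"val"` or `"test"` tags
#'   (recycled if length 1).
#' @param provenance Free-text origin note, stored as an attribute.
#' @return A tibble of class `orb_dataset` with columns `system_id`,
#'   `elements`, `coords`, `fragment` (list-columns), `target_energy`, `mode`,
#'   `l_frac` (list-column, `NULL` entries allowed), `L` (`NA` when absent)
#'   and `split`.
#' @export
orb_dataset <- function(systems, references, split = "train",
                        provenance = "constructed in R") {
  if (length(systems) != length(references)) {
    abort("systems and references must have the same length")
  }
  nrec <- length(systems)
  split <- rep_len(as.character(split), max(nrec, 1L))
  if (nrec > 0 && !all(split %in% c("train", "val", "test"))) {
    abort("split tags must be 'train', 'val' or 'test'")
  }
  modes <- map_chr(references, "mode")
  if (nrec > 0 && length(unique(modes)) > 1L) {
    abort("all records in a dataset must share the same mode")
  }
  out <- tibble(
    system_id = map_chr(systems, "system_id"),
    elements = map(systems, "elements"),
    coords = map(systems, "coords"),
    fragment = map(systems, "fragment"),
    target_energy = map_dbl(references, "target_energy"),
    mode = if (nrec > 0) modes else character(),
    l_frac = map(references, "l_frac"),
    L = map_dbl(references, ~ .x$L %||% NA_real_),
    split = if (nrec > 0) split else character()
  )
  new_orb_dataset(out, provenance = provenance)
}

new_orb_dataset <- function(tbl, provenance = NULL) {
  structure(tbl,
            provenance = provenance %||% attr(tbl, "provenance") %||% "",
            class = c("orb_dataset", class(tibble())))
}

#' Coerce a tibble to an orb_dataset
#'
#' Validates the column schema and per-record invariants, then stamps the
#' `orb_dataset` class.
#'
#' @param tbl A data frame with the [orb_dataset()] columns.
#' @param provenance Optional provenance note.
#' @return An `orb_dataset`.
#' @export
as_orb_dataset <- function(tbl, provenance = NULL) {
  needed <- c("system_id", "elements", "coords", "fragment",
              "target_energy", "mode", "l_frac", "L", "split")
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    abort(paste("missing dataset columns:", paste(missing, collapse = ", ")))
  }
  out <- new_orb_dataset(as_tibble(tbl), provenance = provenance)
  validate_orb_dataset(out)
  out
}

#' Validate an orb_dataset
#'
#' Checks the structural invariants: shared mode, finite coordinates, matching
#' per-atom lengths, localization fractions on the simplex, L in \[0, 1\],
#' split tags recognized.
#'
#' @param dataset An `orb_dataset`.
#' @return The dataset, invisibly; aborts on violation.
#' @export
validate_orb_dataset <- function(dataset) {
  if (nrow(dataset) == 0) return(invisible(dataset))
  if (length(unique(dataset$mode)) > 1L) {
    abort("all records must share the same mode")
  }
  if (!all(dataset$mode %in% c("max", "min"))) {
    abort("mode must be 'max' or 'min'")
  }
  if (!all(dataset$split %in% c("train", "val", "test"))) {
    abort("split tags must be 'train', 'val' or 'test'")
  }
  for (i in seq_len(nrow(dataset))) {
    n <- length(dataset$elements[[i]])
    if (n < 1) abort(sprintf("record %d has no atoms", i))
    if (nrow(dataset$coords[[i]]) != n || !all(is.finite(dataset$coords[[i]]))) {
      abort(sprintf("record %d has invalid coordinates", i))
    }
    if (length(dataset$fragment[[i]]) != n) {
      abort(sprintf("record %d has mismatched fragment labels", i))
    }
    l <- dataset$l_frac[[i]]
    if (!is.null(l)) {
      if (length(l) != n) {
        abort(sprintf("record %d: l_frac has %d entries for %d atoms",
                      i, length(l), n))
      }
      if (abs(sum(l) - 1) > 1e-8 || any(l < -1e-8)) {
        abort(sprintf("record %d: l_frac is not a probability vector", i))
      }
    }
    L <- dataset$L[[i]]
    if (!is.na(L) && (L < -1e-9 || L > 1 + 1e-9)) {
      abort(sprintf("record %d: L = %.3g outside [0, 1]", i, L))
    }
  }
  invisible(dataset)
}

#' Extract one record as an atomic_system
#'
#' @param dataset An `orb_dataset`.
#' @param i Record index.
#' @return An [atomic_system()].
#' @export
record_system <- function(dataset, i) {
  atomic_system(dataset$elements[[i]], dataset$coords[[i]],
                system_id = dataset$system_id[[i]],
                fragment = dataset$fragment[[i]])
}

#' Long per-atom view of a dataset
#'
#' Unnests the geometry list-columns into one row per atom, convenient for
#' dplyr/ggplot work on per-atom quantities.
#'
#' @param dataset An `orb_dataset`.
#' @return A tibble with columns `system_id`, `atom` (0-based), `element`,
#'   `x`, `y`, `z`, `fragment` and `l_frac` (`NA` when absent).
#' @export
atoms_table <- function(dataset) {
  purrr::map_dfr(seq_len(nrow(dataset)), function(i) {
    n <- length(dataset$elements[[i]])
    l <- dataset$l_frac[[i]]
    tibble(
      system_id = dataset$system_id[[i]],
      atom = seq_len(n) - 1L,
      element = dataset$elements[[i]],
      x = dataset$coords[[i]][, 1],
      y = dataset$coords[[i]][, 2],
      z = dataset$coords[[i]][, 3],
      fragment = dataset$fragment[[i]],
      l_frac = if (is.null(l)) rep(NA_real_, n) else l
    )
  })
}

# keep the orb_dataset class through dplyr row operations where possible
#' @export
`[.orb_dataset` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("system_id", "coords") %in% names(out))) {
    return(new_orb_dataset(out, provenance = attr(x, "provenance")))
  }
  out
}

#' @export
print.orb_dataset <- function(x, ...) {
  cat(sprintf("<orb_dataset> %d record(s), mode = %s\n", nrow(x),
              if (nrow(x)) x$mode[[1]] else "?"))
  NextMethod()
}
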