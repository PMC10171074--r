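# Extended-XYZ dialect: frame = count line, key=value comment line with a
# Properties= column descriptor, then one row per atom. Per-atom columns are
# species, x, y, z, optionally fragment, l_frac and owa_weight. Per-structure
# keys: target_energy (required), mode, optional L and system_id. Energies eV,
# coordinates Angstrom.

#' Read a labeled dataset from an extended-XYZ file
#'
#' Parses the dialect written by [write_extxyz()]: each frame carries the
#' per-structure keys `target_energy` (required), `mode`, optionally `L` and
#' `system_id`, and per-atom columns `species x y z` plus optional `fragment`,
#' `l_frac` and `owa_weight` as declared by the `Properties=` descriptor.
#'
#' @param path Path to an extended-XYZ file.
#' @return An `orb_dataset` in file order; if any frame carries `owa_weight`,
#'   an extra `owa_weight` list-column is attached.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  # drop trailing blank lines
  while (length(lines) > 0 && grepl("^\\s*$", lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  systems <- list()
  refs <- list()
  weights <- list()
  has_weights <- FALSE
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L) {
      abort(sprintf("frame %d: malformed atom count line '%s'",
                    frame, lines[pos]))
    }
    if (pos + 1L + n > length(lines) + 1L && pos + n + 1L > length(lines)) {
      # need comment line + n atom rows
    }
    if (pos + n + 1L > length(lines)) {
      abort(sprintf("frame %d: truncated (expected %d atom rows)", frame, n))
    }
    keys <- parse_comment_line(lines[pos + 1L], frame)
    cols <- parse_properties(keys[["Properties"]], frame)
    atom_rows <- lines[(pos + 2L):(pos + 1L + n)]
    atoms <- parse_atom_rows(atom_rows, cols, frame)
    if (is.null(keys[["target_energy"]])) {
      abort(sprintf("frame %d: missing required key 'target_energy'", frame))
    }
    target <- suppressWarnings(as.numeric(keys[["target_energy"]]))
    if (is.na(target)) {
      abort(sprintf("frame %d: non-numeric target_energy", frame))
    }
    mode <- keys[["mode"]] %||% "max"
    if (!mode %in% c("max", "min")) {
      abort(sprintf("frame %d: unknown mode '%s'", frame, mode))
    }
    l <- atoms$l_frac
    if (!is.null(l) && abs(sum(l) - 1) > 1e-6) {
      abort(sprintf("frame %d: l_frac sums to %.8f, not 1", frame, sum(l)))
    }
    Lval <- if (!is.null(keys[["L"]])) as.numeric(keys[["L"]]) else NULL
    systems[[frame]] <- atomic_system(
      atoms$species, atoms$xyz,
      system_id = keys[["system_id"]] %||% sprintf("frame_%04d", frame),
      fragment = atoms$fragment %||% integer(n)
    )
    refs[[frame]] <- electronic_reference(target, mode = mode,
                                          l_frac = l, L = Lval)
    weights[[frame]] <- atoms$owa_weight
    if (!is.null(atoms$owa_weight)) has_weights <- TRUE
    pos <- pos + 2L + n
  }
  out <- orb_dataset(systems, refs, provenance = sprintf("read from %s", path))
  if (has_weights) out$owa_weight <- weights
  out
}

parse_comment_line <- function(line, frame) {
  tokens <- strsplit(trimws(line), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    abort(sprintf("frame %d: empty comment line", frame))
  }
  kv <- regmatches(tokens, regexec("^([^=]+)=(.*)$", tokens))
  bad <- which(map_int(kv, length) != 3L)
  if (length(bad) > 0) {
    abort(sprintf("frame %d: malformed key=value token '%s'",
                  frame, tokens[bad[1]]))
  }
  vals <- map_chr(kv, 3)
  # strip optional quotes
  vals <- gsub('^"|"$', "", vals)
  setNames(as.list(vals), map_chr(kv, 2))
}

parse_properties <- function(prop, frame) {
  if (is.null(prop)) {
    return(c(species = "S", pos = "R3"))  # bare-xyz fallback
  }
  parts <- strsplit(prop, ":")[[1]]
  if (length(parts) %% 3 != 0) {
    abort(sprintf("frame %d: malformed Properties descriptor '%s'",
                  frame, prop))
  }
  idx <- seq(1, length(parts), by = 3)
  tibble(name = parts[idx], type = parts[idx + 1],
         width = as.integer(parts[idx + 2]))
}

parse_atom_rows <- function(rows, cols, frame) {
  mat <- strsplit(trimws(rows), "\\s+")
  widths <- if (is.data.frame(cols)) sum(cols$width) else 4L
  nf <- unique(map_int(mat, length))
  if (length(nf) != 1L || nf != widths) {
    abort(sprintf("frame %d: atom rows have %s fields, expected %d",
                  frame, paste(nf, collapse = "/"), widths))
  }
  m <- do.call(rbind, mat)
  out <- list()
  col0 <- 0L
  if (!is.data.frame(cols)) {
    cols <- tibble(name = c("species", "pos"), type = c("S", "R"),
                   width = c(1L, 3L))
  }
  for (j in seq_len(nrow(cols))) {
    w <- cols$width[j]
    block <- m[, (col0 + 1L):(col0 + w), drop = FALSE]
    nm <- cols$name[j]
    if (nm == "species") {
      out$species <- block[, 1]
    } else if (nm == "pos") {
      xyz <- matrix(as.numeric(block), ncol = 3L)
      if (any(is.na(xyz))) {
        abort(sprintf("frame %d: non-numeric coordinates", frame))
      }
      out$xyz <- xyz
    } else if (nm == "fragment") {
      out$fragment <- as.integer(block[, 1])
    } else if (nm %in% c("l_frac", "owa_weight")) {
      v <- as.numeric(block[, 1])
      if (any(is.na(v))) {
        abort(sprintf("frame %d: non-numeric %s column", frame, nm))
      }
      out[[nm]] <- v
    }
    col0 <- col0 + w
  }
  if (is.null(out$species) || is.null(out$xyz)) {
    abort(sprintf("frame %d: Properties must declare species and pos", frame))
  }
  out
}

#' Write a labeled dataset to an extended-XYZ file
#'
#' Emits frames that [read_extxyz()] parses back identically: coordinates
#' round-trip within 1e-8 Angstrom and scalars within 1e-10. Output is
#' byte-stable for a given dataset (fixed float formatting). A `fragment`
#' column is written whenever any label is nonzero, `l_frac` whenever
#' fractions are present, and `owa_weight` when the dataset carries that
#' list-column (see [export_pseudoorbitals()]).
#'
#' @param dataset An `orb_dataset` (may be empty, producing an empty file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(dataset, path) {
  validate_orb_dataset(dataset)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort(sprintf("cannot write %s", path)),
                  warning = function(w) abort(sprintf("cannot write %s", path)))
  on.exit(close(con))
  for (i in seq_len(nrow(dataset))) {
    n <- length(dataset$elements[[i]])
    frag <- dataset$fragment[[i]]
    l <- dataset$l_frac[[i]]
    w <- if ("owa_weight" %in% names(dataset)) dataset$owa_weight[[i]] else NULL
    props <- "species:S:1:pos:R:3"
    if (any(frag != 0L)) props <- paste0(props, ":fragment:I:1")
    if (!is.null(l)) props <- paste0(props, ":l_frac:R:1")
    if (!is.null(w)) props <- paste0(props, ":owa_weight:R:1")
    keys <- c(
      sprintf("Properties=%s", props),
      sprintf("target_energy=%.12e", dataset$target_energy[[i]]),
      sprintf("mode=%s", dataset$mode[[i]]),
      if (!is.na(dataset$L[[i]])) sprintf("L=%.12e", dataset$L[[i]]),
      sprintf("system_id=%s", dataset$system_id[[i]])
    )
    writeLines(as.character(n), con)
    writeLines(paste(keys, collapse = " "), con)
    xyz <- dataset$coords[[i]]
    rows <- sprintf("%-3s %16.10f %16.10f %16.10f",
                    dataset$elements[[i]], xyz[, 1], xyz[, 2], xyz[, 3])
    if (any(frag != 0L)) rows <- paste(rows, sprintf("%d", frag))
    if (!is.null(l)) rows <- paste(rows, sprintf("%.12e", l))
    if (!is.null(w)) rows <- paste(rows, sprintf("%.12e", w))
    writeLines(rows, con)
  }
  invisible(path)
}
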