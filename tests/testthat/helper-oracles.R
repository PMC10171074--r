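# Independent oracles and fixture builders shared across the suite.

# characteristic-polynomial eigenvalue oracle: Faddeev-LeVerrier coefficients
# from traces of matrix powers (no call to eigen()), roots via polyroot()
charpoly_eigenvalues <- function(H) {
  n <- nrow(H)
  # center the spectrum: the monomial-basis characteristic polynomial is
  # badly conditioned when eigenvalues sit far from zero
  mu <- sum(diag(H)) / n
  H <- H - mu * diag(n)
  # p(x) = x^n + c1 x^(n-1) + ... + cn, via Newton's identities on power sums
  p <- vapply(seq_len(n), function(k) {
    M <- diag(n)
    for (i in seq_len(k)) M <- M %*% H
    sum(diag(M))
  }, numeric(1))
  cc <- numeric(n)
  for (k in seq_len(n)) {
    s <- p[k]
    if (k > 1) for (i in seq_len(k - 1)) s <- s + cc[i] * p[k - i]
    cc[k] <- -s / k
  }
  coefs <- c(rev(cc), 1) # ascending powers for polyroot
  roots <- Re(polyroot(coefs))
  # Newton-polish each root on the characteristic polynomial (Horner);
  # polyroot alone is only ~1e-8 accurate at degree 8
  horner <- function(x) {
    v <- 0; d <- 0
    for (a in rev(coefs)) {
      d <- d * x + v
      v <- v * x + a
    }
    c(v, d)
  }
  for (i in seq_along(roots)) {
    for (it in 1:3) {
      vd <- horner(roots[i])
      if (abs(vd[2]) > 1e-12) roots[i] <- roots[i] - vd[1] / vd[2]
    }
  }
  sort(roots) + mu
}

# O(M^2) brute-force Mulliken accumulation, independent of the vectorized path
brute_mulliken <- function(coefficients, basis_to_atom, overlap = NULL) {
  m <- length(coefficients)
  n <- max(basis_to_atom)
  if (is.null(overlap)) overlap <- diag(m)
  l <- numeric(n)
  for (mu in seq_len(m)) {
    for (nu in seq_len(m)) {
      l[basis_to_atom[mu]] <- l[basis_to_atom[mu]] +
        coefficients[mu] * coefficients[nu] * overlap[mu, nu]
    }
  }
  l
}

# random symmetric positive-definite overlap with unit diagonal
random_overlap <- function(m) {
  A <- matrix(rnorm(m * m, sd = 0.3), m, m)
  S <- diag(m) + (A + t(A)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0.1) S <- S + (0.1 - min(ev)) * diag(m)
  S
}

# random S-normalized coefficient vector
random_normalized_orbital <- function(m, S = NULL) {
  cc <- rnorm(m)
  norm2 <- if (is.null(S)) sum(cc^2) else drop(crossprod(cc, S %*% cc))
  cc / sqrt(norm2)
}

# random small dataset for extxyz round trips
random_dataset <- function(n_records = 3, with_l = TRUE, mode = "max",
                           with_fragments = FALSE) {
  systems <- list()
  refs <- list()
  for (i in seq_len(n_records)) {
    n <- sample(2:6, 1)
    elems <- sample(c("C", "O", "H", "X07"), n, replace = TRUE)
    frag <- if (with_fragments) sample(0:1, n, replace = TRUE) else NULL
    systems[[i]] <- atomic_system(elems, matrix(rnorm(n * 3, sd = 2), n, 3),
                                  system_id = sprintf("rnd_%03d", i),
                                  fragment = frag)
    l <- if (with_l) {
      v <- runif(n)
      v / sum(v)
    } else NULL
    refs[[i]] <- electronic_reference(rnorm(1, -6), mode = mode, l_frac = l,
                                      L = if (!is.null(l) && n >= 2) {
                                        localization_index(l)
                                      } else NULL)
  }
  orb_dataset(systems, refs,
              split = sample(c("train", "val", "test"), n_records,
                             replace = TRUE))
}

# small generated dataset with splits, cached per session for speed
tiny_dataset <- local({
  cache <- NULL
  function(n = 120, seed = 5) {
    if (is.null(cache)) {
      ds <- suppressWarnings(
        generate_dataset(generator_config(n_molecules = n, seed = seed),
                         tb_params()))
      cache <<- assign_splits(ds, c(train = 0.7, val = 0.15, test = 0.15),
                              seed = seed)
    }
    cache
  }
})

tiny_model_config <- function(head, dataset, mode = NULL, ...) {
  desc <- descriptor_config(sort(unique(unlist(dataset$elements))),
                            cutoff_radius = 5, n_centers = 6)
  model_config(desc, pooling_head(head, mode %||% dataset$mode[[1]]),
               energy_net_layers = c(16L, 16L),
               weight_net_layers = c(16L, 16L),
               learning_rate = 3e-3, seed = 11L, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stub prediction models for evaluation-module tests (S3 methods must live
# in the global env so dispatch from package internals can find them)
make_stub_model <- function(dataset, predictions, weights = NULL,
                            head = "avg") {
  structure(list(
    lookup = stats::setNames(predictions, dataset$system_id),
    wlookup = if (!is.null(weights)) {
      stats::setNames(weights, dataset$system_id)
    },
    config = list(pooling = list(name = head))
  ), class = "stub_model")
}

assign("predict.stub_model", function(object, system, l_frac = NULL, ...) {
  list(energy = unname(object$lookup[[system$system_id]]),
       weights = if (!is.null(object$wlookup)) {
         object$wlookup[[system$system_id]]
       })
}, envir = globalenv())

map_dbl_ <- function(x, f) vapply(x, f, numeric(1))
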