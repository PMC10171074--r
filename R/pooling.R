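#' Pooling head specification
#'
#' Names one of the seven aggregation rules that map per-atom scalars (and
#' optional weights) to a single molecular scalar, together with the mode:
#' `"max"` for properties tracking the highest per-atom contribution (HOMO
#' energies), `"min"` for the lowest (ionization energies, LUMO). The softmax
#' sign is derived from the mode: +1 for max, -1 for min.
#'
#' @param name One of `"sum"`, `"avg"`, `"max"`, `"softmax"`, `"wa"`, `"owa"`,
#'   `"coeff"`.
#' @param mode `"max"` or `"min"`.
#' @param temperature Inverse-temperature scale of the softmax weights
#'   (default 1, i.e. weights `exp(+/- eps)` with `eps` in eV).
#' @return An object of class `pooling_head`.
#' @export
pooling_head <- function(name = c("sum", "avg", "max", "softmax", "wa",
                                  "owa", "coeff"),
                         mode = c("max", "min"), temperature = 1) {
  name <- match.arg(name)
  mode <- match.arg(mode)
  structure(list(name = name, mode = mode,
                 softmax_sign = if (mode == "max") 1 else -1,
                 temperature = as.numeric(temperature)[1]),
            class = "pooling_head")
}

#' @export
print.pooling_head <- function(x, ...) {
  cat(sprintf("<pooling_head> %s (mode = %s)\n", x$name, x$mode))
  invisible(x)
}

check_eps <- function(eps) {
  eps <- as.numeric(eps)
  if (length(eps) < 1L) abort("pooling needs at least one per-atom value")
  if (!all(is.finite(eps))) abort("per-atom values must be finite")
  eps
}

#' Sum pooling
#'
#' `f(eps) = sum_i eps_i`. Extensive: replicating a system k times scales the
#' output by k, which is exactly the failure mode for intensive targets.
#'
#' @param eps Numeric vector of per-atom scalars.
#' @return Scalar sum.
#' @export
pool_sum <- function(eps) sum(check_eps(eps))

#' Average pooling
#'
#' `f(eps) = mean(eps)`. Intensive under replication, but mixes fragments: on
#' a non-interacting water + CO2 supersystem it returns the average of the two
#' monomer values instead of the lower ionization energy.
#'
#' @inheritParams pool_sum
#' @return Scalar mean.
#' @export
pool_avg <- function(eps) mean(check_eps(eps))

#' Max/min pooling
#'
#' `f(eps) = max(eps)` in max mode, `min(eps)` in min mode: the property is
#' carried by a single atom.
#'
#' @inheritParams pool_sum
#' @param mode `"max"` or `"min"`.
#' @return Scalar extremum.
#' @export
pool_max <- function(eps, mode = c("max", "min")) {
  mode <- match.arg(mode)
  eps <- check_eps(eps)
  if (mode == "max") max(eps) else min(eps)
}

#' Softmax pooling
#'
#' Smooth interpolation between average and max/min pooling:
#' `f(eps) = sum_i w_i eps_i` with `w_i = exp(s * t * eps_i) / sum_j
#' exp(s * t * eps_j)`, `s = +1` (max mode) or `-1` (min mode) and `t` the
#' inverse temperature. For identical per-atom values it reduces to average
#' pooling; rescaling `eps` upward drives it toward max/min pooling. Computed
#' with max-subtraction so large inputs cannot overflow.
#'
#' @inheritParams pool_max
#' @param temperature Inverse-temperature scale (default 1).
#' @return Scalar softmax-weighted average; exactly intensive under
#'   replication.
#' @export
pool_softmax <- function(eps, mode = c("max", "min"), temperature = 1) {
  mode <- match.arg(mode)
  eps <- check_eps(eps)
  w <- softmax_weights(eps, mode, temperature)
  sum(w * eps)
}

#' Softmax weights
#'
#' The weight vector used by [pool_softmax()]; exposed so softmax weights can
#' be compared against localization fractions.
#'
#' @inheritParams pool_softmax
#' @return Simplex vector of length `length(eps)`.
#' @export
softmax_weights <- function(eps, mode = c("max", "min"), temperature = 1) {
  mode <- match.arg(mode)
  s <- if (mode == "max") 1 else -1
  z <- s * temperature * check_eps(eps)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Weighted-average pooling
#'
#' `f(eps, w) = sum_i w_i eps_i` for a weight vector on the simplex. This one
#' rule serves WA pooling (learned weights), OWA pooling (learned weights
#' supervised by localization fractions) and coefficient pooling
#' (`w = l_i`, the exact Mulliken fractions).
#'
#' @inheritParams pool_sum
#' @param weights Numeric weights, non-negative and summing to 1 within 1e-8.
#' @return Scalar weighted average, bounded by `range(eps)`.
#' @export
pool_weighted_average <- function(eps, weights) {
  eps <- check_eps(eps)
  weights <- as.numeric(weights)
  if (length(weights) != length(eps)) {
    abort("weights and eps must have the same length")
  }
  if (any(weights < -1e-8) || abs(sum(weights) - 1) > 1e-8) {
    abort("weights must lie on the probability simplex")
  }
  sum(weights * eps)
}

#' Apply a pooling head
#'
#' Dispatches to the named rule. `wa`/`owa` require `weights`; `coeff`
#' requires the reference localization fractions as `weights`.
#'
#' @param head A [pooling_head()].
#' @param eps Per-atom scalars.
#' @param weights Optional simplex weights (required for `wa`, `owa`,
#'   `coeff`).
#' @return Pooled scalar.
#' @export
apply_pooling <- function(head, eps, weights = NULL) {
  switch(head$name,
    sum = pool_sum(eps),
    avg = pool_avg(eps),
    max = pool_max(eps, head$mode),
    softmax = pool_softmax(eps, head$mode, head$temperature),
    wa = ,
    owa = ,
    coeff = {
      if (is.null(weights)) {
        abort(sprintf("'%s' pooling requires a weight vector", head$name))
      }
      pool_weighted_average(eps, weights)
    }
  )
}
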