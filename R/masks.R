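# k-space undersampling mask generators. All masks are stored DC-centred
# (low frequencies at the grid centre) and always include the DC element.

new_sampling_mask <- function(flags, scheme, requested_rate, seed = NA_integer_) {
  structure(
    list(
      flags = flags,
      scheme = scheme,
      requested_rate = requested_rate,
      achieved_rate = sum(flags) / length(flags),
      seed = seed
    ),
    class = "sampling_mask"
  )
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %s  %dx%d  requested %.3f  achieved %.4f\n",
              x$scheme, nrow(x$flags), ncol(x$flags),
              x$requested_rate, x$achieved_rate))
  invisible(x)
}

is_sampling_mask <- function(x) inherits(x, "sampling_mask")

dc_index <- function(n) as.integer(n / 2 + 1)

# Weighted sampling without replacement (Efraimidis-Spirakis keys), with
# lexicographic tie-break so identical seeds give bit-identical masks.
weighted_pick <- function(candidates, weights, k) {
  u <- stats::runif(length(candidates))
  keys <- u^(1 / weights)
  ord <- order(keys, candidates, decreasing = TRUE)
  candidates[ord[seq_len(k)]]
}

#' Cartesian (phase-encoding line) undersampling mask
#'
#' Selects `round(rate * n)` full rows of k-space. A central block of
#' `max(1, round(0.04 * n))` lines around DC is always sampled; the remaining
#' lines are drawn without replacement with probability decaying as the cube
#' of the distance from the centre, emulating the variable-density Cartesian
#' patterns used in compressed-sensing MRI.
#'
#' @param n side length in pixels (power of two).
#' @param rate requested sampling rate in (0, 1].
#' @param seed integer seed; identical seeds give bit-identical masks.
#' @return A `sampling_mask` with `scheme = "cartesian"`. The achieved rate is
#'   line-quantised, so it differs from `rate` by at most `1/n`.
#' @export
make_cartesian_mask <- function(n, rate, seed = 0L) {
  check_mask_args(n, rate)
  n_lines <- max(1L, round(rate * n))
  centre <- dc_index(n)
  n_centre <- max(1L, round(0.04 * n))
  half <- (n_centre - 1L) %/% 2L
  centre_lines <- (centre - half):(centre - half + n_centre - 1L)
  if (length(centre_lines) > n_lines)
    stop("infeasible rate: central line block alone exceeds the line budget",
         call. = FALSE)
  rest <- setdiff(seq_len(n), centre_lines)
  d <- abs(rest - centre) / (n / 2)
  w <- pmax(1 - d, 0)^3 + 1e-3
  with_local_seed(seed, {
    extra <- weighted_pick(rest, w, n_lines - length(centre_lines))
  })
  flags <- matrix(FALSE, n, n)
  flags[sort(c(centre_lines, extra)), ] <- TRUE
  new_sampling_mask(flags, "cartesian", rate, seed)
}

#' Radial (golden-angle spoke) undersampling mask
#'
#' Rasterises diametric spokes through the DC centre at golden-angle
#' increments, accumulating spokes until `round(rate * n^2)` k-space points
#' are covered; the last spoke is trimmed from its outer ends so the point
#' budget is met exactly. Deterministic: no randomness is involved.
#'
#' @inheritParams make_cartesian_mask
#' @return A `sampling_mask` with `scheme = "radial"`; `achieved_rate` is
#'   within `0.5/n^2` of `rate`.
#' @export
make_radial_mask <- function(n, rate) {
  check_mask_args(n, rate)
  budget <- max(1L, round(rate * n * n))
  centre <- dc_index(n)
  flags <- matrix(FALSE, n, n)
  golden <- pi * (3 - sqrt(5))    # ~2.39996 rad, equidistributed mod pi
  taken <- 0L
  spoke <- 0L
  tvals <- seq(-n / sqrt(2), n / sqrt(2), by = 0.5)
  while (taken < budget) {
    theta <- spoke * golden
    i <- round(centre + tvals * cos(theta))
    j <- round(centre + tvals * sin(theta))
    keep <- i >= 1 & i <= n & j >= 1 & j <= n
    idx <- cbind(i[keep], j[keep])
    new <- idx[!flags[idx], , drop = FALSE]
    if (nrow(new) > 0) {
      new <- unique(new)
      if (taken + nrow(new) > budget) {
        r2 <- (new[, 1] - centre)^2 + (new[, 2] - centre)^2
        new <- new[order(r2, new[, 1], new[, 2]), , drop = FALSE]
        new <- new[seq_len(budget - taken), , drop = FALSE]
      }
      flags[new] <- TRUE
      taken <- taken + nrow(new)
    }
    spoke <- spoke + 1L
    if (spoke > 200000L)
      stop("radial mask failed to reach the requested rate", call. = FALSE)
  }
  flags[centre, centre] <- TRUE
  new_sampling_mask(flags, "radial", rate)
}

#' Variable-density random undersampling mask
#'
#' Samples exactly `round(rate * n^2)` individual k-space points: a fully
#' sampled central disc of radius `0.04 * n`, plus points drawn without
#' replacement with a radially decaying polynomial density (decay exponent 3).
#' The exact-count construction means requested rates are met deterministically
#' rather than in expectation.
#'
#' @inheritParams make_cartesian_mask
#' @return A `sampling_mask` with `scheme = "variable_density"`.
#' @export
make_variable_density_mask <- function(n, rate, seed = 0L) {
  check_mask_args(n, rate)
  budget <- max(1L, round(rate * n * n))
  centre <- dc_index(n)
  ii <- rep(seq_len(n), times = n)
  jj <- rep(seq_len(n), each = n)
  r <- sqrt((ii - centre)^2 + (jj - centre)^2)
  disc <- which(r <= 0.04 * n)
  if (length(disc) > budget)
    stop("infeasible rate: fully sampled central disc exceeds the point budget",
         call. = FALSE)
  rest <- which(r > 0.04 * n)
  w <- pmax(1 - r[rest] / max(r), 0)^3 + 1e-4
  with_local_seed(seed, {
    extra <- weighted_pick(rest, w, budget - length(disc))
  })
  flags <- matrix(FALSE, n, n)
  flags[c(disc, extra)] <- TRUE
  new_sampling_mask(flags, "variable_density", rate, seed)
}

check_mask_args <- function(n, rate) {
  if (!is_pow2(n))
    stop("`n` must be a power of two", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0 || rate > 1)
    stop("`rate` must lie in (0, 1]", call. = FALSE)
  invisible(TRUE)
}

# Run `code` under a local RNG state seeded with `seed`.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
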