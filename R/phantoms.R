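# Seeded ellipse phantoms: reference/target image pairs with controlled
# structural similarity. The reference plays the role of a previously acquired
# high-resolution scan of the same anatomy; the target is the image actually
# undersampled and reconstructed. Perturbing ellipse geometry and contrast
# between the two (plus smooth texture added to the target only) emulates the
# "similar but not identical" relationship between two scans of one patient.

#' Configuration for a reference/target phantom pair
#'
#' @param n side length in pixels (power of two).
#' @param n_ellipses number of interior structures in addition to the skull
#'   ring.
#' @param deformation relative jitter of ellipse centres/axes between the
#'   reference and the target, in `[0, 0.5]`.
#' @param contrast_shift relative intensity perturbation between the two, in
#'   `[0, 0.5]`.
#' @param texture_amp amplitude of the smooth random texture added to the
#'   target only, in `[0, 0.5]`.
#' @param seed integer seed controlling the whole pair.
#' @return A `phantom_pair_config` list.
#' @export
phantom_pair_config <- function(n = 128L, n_ellipses = 8L, deformation = 0.05,
                                contrast_shift = 0.1, texture_amp = 0.05,
                                seed = 1L) {
  if (!is_pow2(n)) stop("`n` must be a power of two", call. = FALSE)
  for (v in c(deformation, contrast_shift, texture_amp))
    if (v < 0 || v > 0.5)
      stop("perturbation fractions must lie in [0, 0.5]", call. = FALSE)
  structure(list(n = as.integer(n), n_ellipses = as.integer(n_ellipses),
                 deformation = deformation, contrast_shift = contrast_shift,
                 texture_amp = texture_amp, seed = as.integer(seed)),
            class = "phantom_pair_config")
}

# rasterise one ellipse: centre (cx, cy), semi-axes (ax, ay), rotation phi,
# on the unit square [-1, 1]^2
ellipse_mask <- function(n, cx, cy, ax, ay, phi) {
  u <- seq(-1, 1, length.out = n)
  X <- matrix(u, n, n) - cx
  Y <- matrix(u, n, n, byrow = TRUE) - cy
  Xr <- X * cos(phi) + Y * sin(phi)
  Yr <- -X * sin(phi) + Y * cos(phi)
  (Xr / ax)^2 + (Yr / ay)^2 <= 1
}

# smooth a field with a small Gaussian in Fourier space (periodic blur)
gaussian_blur <- function(img, sigma_px = 1) {
  n <- nrow(img)
  f <- seq(0, n - 1); f[f > n / 2] <- f[f > n / 2] - n
  w <- exp(-2 * pi^2 * sigma_px^2 * (f / n)^2)
  W <- outer(w, w)
  Re(stats::fft(stats::fft(img) * W, inverse = TRUE)) / n^2
}

render_phantom <- function(n, ellipses, outer_e) {
  img <- matrix(0, n, n)
  ring <- ellipse_mask(n, outer_e$cx, outer_e$cy, outer_e$ax, outer_e$ay, 0)
  inner <- ellipse_mask(n, outer_e$cx, outer_e$cy,
                        outer_e$ax * 0.92, outer_e$ay * 0.92, 0)
  img[ring] <- 1                      # skull ring
  img[inner] <- 0.25                  # background tissue
  for (e in ellipses) {
    m <- ellipse_mask(n, e$cx, e$cy, e$ax, e$ay, e$phi) & inner
    img[m] <- img[m] + e$val
  }
  img <- gaussian_blur(img, sigma_px = max(1, n / 128))
  img[!ring] <- 0                     # background exactly zero
  img <- pmax(img, 0)
  if (max(img) > 0) img <- img / max(img)
  img
}

#' Generate a reference/target phantom pair
#'
#' Builds a piecewise-smooth head phantom (skull ring plus `n_ellipses`
#' interior ellipses with random geometry and signed contrast), then derives
#' the target by jittering every ellipse's centre and axes by up to
#' `deformation` (relative), its intensity by up to `contrast_shift`, and
#' adding a smooth random texture of amplitude `texture_amp` inside the head.
#' The reference is the unperturbed phantom. Both are normalised to `[0, 1]`
#' and are bit-identical across runs for a fixed seed.
#'
#' @param cfg a [phantom_pair_config()].
#' @return A list with elements `reference` and `target` (numeric matrices).
#' @export
generate_pair <- function(cfg = phantom_pair_config()) {
  stopifnot(inherits(cfg, "phantom_pair_config"))
  n <- cfg$n
  with_local_seed(cfg$seed, {
    outer_e <- list(cx = 0, cy = 0, ax = 0.82, ay = 0.9)
    ellipses <- vector("list", cfg$n_ellipses)
    for (i in seq_len(cfg$n_ellipses)) {
      for (try in 1:100) {
        e <- list(cx = stats::runif(1, -0.45, 0.45),
                  cy = stats::runif(1, -0.5, 0.5),
                  ax = stats::runif(1, 0.06, 0.3),
                  ay = stats::runif(1, 0.06, 0.3),
                  phi = stats::runif(1, 0, pi),
                  val = sample(c(-1, 1), 1) * stats::runif(1, 0.15, 0.5))
        if (abs(e$cx) + e$ax < 0.95 && abs(e$cy) + e$ay < 0.95) break
        if (try == 100) stop("could not place ellipse inside the grid",
                             call. = FALSE)
      }
      ellipses[[i]] <- e
    }
    reference <- render_phantom(n, ellipses, outer_e)

    jit <- function(x, frac, lo = -Inf, hi = Inf) {
      pmin(pmax(x * (1 + stats::runif(1, -frac, frac)), lo), hi)
    }
    perturbed <- lapply(ellipses, function(e) {
      for (try in 1:100) {
        e2 <- e
        e2$cx <- e$cx + stats::runif(1, -cfg$deformation, cfg$deformation) * 0.5
        e2$cy <- e$cy + stats::runif(1, -cfg$deformation, cfg$deformation) * 0.5
        e2$ax <- jit(e$ax, cfg$deformation, lo = 0.02)
        e2$ay <- jit(e$ay, cfg$deformation, lo = 0.02)
        e2$val <- e$val * (1 + stats::runif(1, -cfg$contrast_shift,
                                            cfg$contrast_shift))
        if (abs(e2$cx) + e2$ax < 0.98 && abs(e2$cy) + e2$ay < 0.98) return(e2)
      }
      e
    })
    target <- render_phantom(n, perturbed, outer_e)
    if (cfg$texture_amp > 0) {
      tex <- gaussian_blur(matrix(stats::rnorm(n * n), n, n),
                           sigma_px = n / 32)
      tex <- tex / max(abs(tex))
      support <- target > 0
      target[support] <- target[support] + cfg$texture_amp * tex[support]
      target <- pmax(target, 0)
      if (max(target) > 0) target <- target / max(target)
    }
    list(reference = reference, target = target)
  })
}

#' Deterministic family of phantom pairs
#'
#' Pairs with seeds `base_seed, base_seed + 1, ...`, used for averaged
#' comparative experiments.
#'
#' @param n side length.
#' @param count number of pairs, `>= 1`.
#' @param base_seed seed of the first pair.
#' @param ... further arguments passed to [phantom_pair_config()].
#' @return List of `count` reference/target pairs.
#' @export
pair_suite <- function(n = 128L, count = 3L, base_seed = 1L, ...) {
  stopifnot(count >= 1)
  lapply(seq_len(count) - 1L, function(i) {
    generate_pair(phantom_pair_config(n = n, seed = base_seed + i, ...))
  })
}
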