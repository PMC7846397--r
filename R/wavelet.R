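# Orthonormal multilevel Haar transform and the l1 proximal machinery used by
# the ADMM sparse-code update. Coefficients are kept in the classic packed
# square layout (approximation band in the top-left corner), which keeps the
# whole coefficient set a plain n x n matrix: elementwise arithmetic, norms
# and soft thresholding then need no special casing.

new_wavelet_coeffs <- function(mat, wavelet, level) {
  structure(mat, wavelet = wavelet, level = level, class = "wavelet_coeffs")
}

#' @export
print.wavelet_coeffs <- function(x, ...) {
  cat(sprintf("<wavelet_coeffs> %s, level %d, %dx%d\n",
              attr(x, "wavelet"), attr(x, "level"), nrow(x), ncol(x)))
  invisible(x)
}

# one orthonormal Haar analysis step on an m x m block, m even
haar_step <- function(b) {
  m <- nrow(b)
  o <- seq(1, m, by = 2); e <- seq(2, m, by = 2)
  lo <- (b[o, , drop = FALSE] + b[e, , drop = FALSE]) / sqrt(2)
  hi <- (b[o, , drop = FALSE] - b[e, , drop = FALSE]) / sqrt(2)
  # columns
  ll <- (lo[, o, drop = FALSE] + lo[, e, drop = FALSE]) / sqrt(2)
  lh <- (lo[, o, drop = FALSE] - lo[, e, drop = FALSE]) / sqrt(2)
  hl <- (hi[, o, drop = FALSE] + hi[, e, drop = FALSE]) / sqrt(2)
  hh <- (hi[, o, drop = FALSE] - hi[, e, drop = FALSE]) / sqrt(2)
  rbind(cbind(ll, lh), cbind(hl, hh))
}

haar_step_inv <- function(b) {
  m <- nrow(b); h <- m / 2
  ll <- b[1:h, 1:h, drop = FALSE];         lh <- b[1:h, (h + 1):m, drop = FALSE]
  hl <- b[(h + 1):m, 1:h, drop = FALSE];   hh <- b[(h + 1):m, (h + 1):m, drop = FALSE]
  lo <- matrix(0, h, m); hi <- matrix(0, h, m)
  o <- seq(1, m, by = 2); e <- seq(2, m, by = 2)
  lo[, o] <- (ll + lh) / sqrt(2); lo[, e] <- (ll - lh) / sqrt(2)
  hi[, o] <- (hl + hh) / sqrt(2); hi[, e] <- (hl - hh) / sqrt(2)
  out <- matrix(0, m, m)
  out[o, ] <- (lo + hi) / sqrt(2)
  out[e, ] <- (lo - hi) / sqrt(2)
  out
}

#' Multilevel orthonormal 2-D Haar decomposition
#'
#' Linear, energy-preserving wavelet analysis on a power-of-two grid. Being
#' orthonormal, the synthesis [idwt()] is both the exact inverse and the exact
#' adjoint, which is what the gradient of the ADMM proximity term requires.
#'
#' @param img square numeric matrix with power-of-two side length.
#' @param wavelet wavelet family; only `"haar"` is implemented.
#' @param level decomposition depth, at most `log2(n)`.
#' @return A `wavelet_coeffs` object: an `n x n` matrix in packed layout with
#'   the level-`level` approximation band in the top-left corner.
#' @export
dwt <- function(img, wavelet = "haar", level = 6L) {
  assert_image(img)
  n <- nrow(img)
  if (!is_pow2(n)) stop("side length must be a power of two", call. = FALSE)
  if (!identical(wavelet, "haar"))
    stop("only the Haar wavelet is implemented", call. = FALSE)
  level <- as.integer(level)
  if (level < 1L || level > log2(n))
    stop("`level` must be between 1 and log2(n)", call. = FALSE)
  out <- img
  m <- n
  for (l in seq_len(level)) {
    out[1:m, 1:m] <- haar_step(out[1:m, 1:m, drop = FALSE])
    m <- m / 2
  }
  new_wavelet_coeffs(out, wavelet, level)
}

#' Inverse multilevel Haar transform
#'
#' Exact inverse (and adjoint) of [dwt()].
#'
#' @param coeffs a `wavelet_coeffs` object, or a plain matrix together with
#'   `level`.
#' @param level decomposition depth; taken from `coeffs` when available.
#' @return Numeric matrix of the original size.
#' @export
idwt <- function(coeffs, level = attr(coeffs, "level")) {
  if (is.null(level)) stop("decomposition level unknown", call. = FALSE)
  mat <- unclass(coeffs)
  attributes(mat) <- list(dim = dim(mat))
  n <- nrow(mat)
  if (!is.matrix(mat) || n != ncol(mat) || !is_pow2(n))
    stop("malformed coefficient set", call. = FALSE)
  m <- n / 2^(level - 1)
  for (l in seq_len(level)) {
    mat[1:m, 1:m] <- haar_step_inv(mat[1:m, 1:m, drop = FALSE])
    m <- m * 2
  }
  mat
}

#' Soft thresholding
#'
#' The elementwise shrinkage operator: values with magnitude below `kappa`
#' are set to zero and the rest are moved toward zero by `kappa`. It is the
#' proximal operator of the scaled l1 norm.
#'
#' @param b numeric scalar, vector, matrix or `wavelet_coeffs`.
#' @param kappa nonnegative threshold.
#' @return Object of the same shape (and class) as `b`.
#' @export
soft_threshold <- function(b, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa < 0)
    stop("`kappa` must be a nonnegative scalar", call. = FALSE)
  out <- sign(b) * pmax(abs(b) - kappa, 0)
  attributes(out) <- attributes(b)
  out
}

#' Proximal operator of the l1-penalised quadratic
#'
#' Exact minimiser of `lam * ||a||_1 + (rho/2) * ||a - v||_2^2`, i.e. soft
#' thresholding of `v` at `lam / rho`. This is the closed-form ADMM update of
#' the wavelet code.
#'
#' @param v coefficient set (any numeric shape).
#' @param lam l1 regularisation weight, `>= 0`.
#' @param rho ADMM penalty parameter, `> 0`.
#' @return Same shape as `v`.
#' @export
prox_l1 <- function(v, lam, rho) {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0)
    stop("`rho` must be a positive scalar", call. = FALSE)
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0)
    stop("`lam` must be a nonnegative scalar", call. = FALSE)
  soft_threshold(v, lam / rho)
}
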