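#' @useDynLib rwsdip, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal validators ----------------------------------------------------

assert_image <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop("`", arg, "` must be a square matrix", call. = FALSE)
  if (!all(is.finite(img)))
    stop("`", arg, "` contains non-finite values", call. = FALSE)
  invisible(img)
}

is_pow2 <- function(n) n >= 1 && bitwAnd(n, n - 1L) == 0L

# ---- DC-centred orthonormal Fourier operators -------------------------------

#' Shift the zero-frequency component to the grid centre
#'
#' For even side lengths `fftshift()` and its inverse coincide; both are
#' provided for readability at call sites.
#'
#' @param x matrix (real, complex or logical).
#' @return Matrix with quadrants swapped so DC sits at `(n/2 + 1, n/2 + 1)`.
#' @export
fftshift <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  x[c(seq_len(n1 - s1) + s1, seq_len(s1)),
    c(seq_len(n2 - s2) + s2, seq_len(s2)), drop = FALSE]
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  x[c(seq_len(n1 - s1) + s1, seq_len(s1)),
    c(seq_len(n2 - s2) + s2, seq_len(s2)), drop = FALSE]
}

#' Orthonormal 2-D discrete Fourier transform, DC-centred
#'
#' Computes the unitary DFT of a square image: the raw transform is divided by
#' the side length `n` (so `1/sqrt(n^2)`), which makes [inverse_fourier()] the
#' exact adjoint and preserves energy (Parseval). The output is shifted so the
#' DC coefficient sits at the grid centre, matching how sampling masks are
#' stored.
#'
#' @param img square numeric (or complex) matrix.
#' @return Complex matrix of the same size, DC-centred.
#' @seealso [inverse_fourier()], [undersample()]
#' @export
fourier <- function(img) {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop("`img` must be a square matrix", call. = FALSE)
  if (!all(is.finite(img)))
    stop("`img` contains non-finite values", call. = FALSE)
  fftshift(stats::fft(img) / nrow(img))
}

#' Inverse of the orthonormal DC-centred Fourier transform
#'
#' Exact inverse of [fourier()]. The result is complex in general; callers
#' wanting an image take the magnitude (the convention used throughout for
#' display and metrics).
#'
#' @param k square complex matrix in DC-centred layout.
#' @return Complex matrix of the same size.
#' @export
inverse_fourier <- function(k) {
  if (!is.matrix(k) || nrow(k) != ncol(k))
    stop("`k` must be a square matrix", call. = FALSE)
  stats::fft(ifftshift(k), inverse = TRUE) / nrow(k)
}
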