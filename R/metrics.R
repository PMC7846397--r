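# Image quality metrics: relative l2 error, PSNR and SSIM.

#' Relative l2 reconstruction error
#'
#' `||est - truth||_2 / ||truth||_2`. Dimensionless; multiply by 100 for the
#' percentage convention used in result tables.
#'
#' @param est,truth same-size numeric matrices; `truth` must not be all zero.
#' @return Nonnegative scalar.
#' @export
rel_err <- function(est, truth) {
  check_metric_args(est, truth)
  denom <- sqrt(sum(truth^2))
  if (denom == 0) stop("`truth` has zero norm; RelErr undefined", call. = FALSE)
  sqrt(sum((est - truth)^2)) / denom
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(MAX^2 / MSE)` where `MAX` is the largest value of the ground
#' truth and MSE the mean squared error. Identical images give `Inf`.
#'
#' @inheritParams rel_err
#' @return Scalar in dB (`Inf` for a perfect match).
#' @export
psnr <- function(est, truth) {
  check_metric_args(est, truth)
  mse <- mean((est - truth)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(truth)^2 / mse)
}

#' Structural similarity index
#'
#' Global-statistics SSIM with stabilising constants `c1 = 0.01` and
#' `c2 = 0.03`: a single comparison of the two images' means, variances and
#' cross-covariance. Symmetric in its arguments and equal to 1 only for a
#' perfect match. A sliding-window variant (11x11 Gaussian, sigma 1.5, the
#' common practice) is available with `windowed = TRUE`; the global form is
#' the default.
#'
#' @inheritParams rel_err
#' @param c1,c2 stabilising constants.
#' @param windowed if `TRUE`, compute mean SSIM over a Gaussian sliding window
#'   instead of the single global statistic.
#' @return Scalar `<= 1`.
#' @export
ssim <- function(est, truth, c1 = 0.01, c2 = 0.03, windowed = FALSE) {
  check_metric_args(est, truth)
  if (windowed) return(ssim_windowed(est, truth, c1, c2))
  n <- length(truth)
  mx <- mean(truth); my <- mean(est)
  vx <- sum((truth - mx)^2) / n
  vy <- sum((est - my)^2) / n
  cxy <- sum((truth - mx) * (est - my)) / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

ssim_windowed <- function(est, truth, c1, c2, win = 11L, sigma = 1.5) {
  g <- stats::dnorm(seq(-(win %/% 2), win %/% 2), sd = sigma)
  g <- g / sum(g)
  blur <- function(x) {
    # separable Gaussian filter with edge truncation (renormalised weights)
    ones <- matrix(1, nrow(x), ncol(x))
    conv1 <- function(m, k, dim) {
      out <- matrix(0, nrow(m), ncol(m))
      half <- length(k) %/% 2
      for (s in seq_along(k)) {
        off <- s - half - 1L
        if (dim == 1L) {
          src <- pmin(pmax(seq_len(nrow(m)) + off, 1L), nrow(m))
          out <- out + k[s] * m[src, , drop = FALSE]
        } else {
          src <- pmin(pmax(seq_len(ncol(m)) + off, 1L), ncol(m))
          out <- out + k[s] * m[, src, drop = FALSE]
        }
      }
      out
    }
    conv1(conv1(x, g, 1L), g, 2L)
  }
  mx <- blur(truth); my <- blur(est)
  vx <- blur(truth^2) - mx^2
  vy <- blur(est^2) - my^2
  cxy <- blur(truth * est) - mx * my
  map <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(map)
}

check_metric_args <- function(est, truth) {
  if (!is.matrix(est) || !is.matrix(truth) || !all(dim(est) == dim(truth)))
    stop("`est` and `truth` must be same-size matrices", call. = FALSE)
  if (!all(is.finite(est)) || !all(is.finite(truth)))
    stop("non-finite values in metric inputs", call. = FALSE)
  invisible(TRUE)
}

#' Score a reconstruction against ground truth
#'
#' Convenience wrapper returning the three standard metrics at once.
#'
#' @inheritParams rel_err
#' @return A list with `relerr`, `psnr` (dB) and `ssim`.
#' @export
metric_report <- function(est, truth) {
  list(relerr = rel_err(est, truth),
       psnr = psnr(est, truth),
       ssim = ssim(est, truth))
}
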