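# Simulated acquisition, zero-filling baseline and the k-space data-correction
# step that re-inserts every acquired Fourier sample into a reconstruction.

new_kspace_measurement <- function(values, mask) {
  structure(list(values = values, mask = mask), class = "kspace_measurement")
}

#' @export
print.kspace_measurement <- function(x, ...) {
  cat(sprintf("<kspace_measurement> %dx%d, %s mask, rate %.4f\n",
              nrow(x$values), ncol(x$values),
              x$mask$scheme, x$mask$achieved_rate))
  invisible(x)
}

#' Simulate an undersampled k-space acquisition
#'
#' Computes the DC-centred orthonormal Fourier transform of `img` and keeps
#' only the samples selected by `mask`; everything else is exactly zero. This
#' is the undersampled Fourier operator applied to the target image — the
#' measurement vector that drives all reconstruction methods.
#'
#' @param img square numeric matrix (the fully sampled target image).
#' @param mask a [make_cartesian_mask()]-style `sampling_mask` of the same size.
#' @return A `kspace_measurement` (complex matrix plus its mask).
#' @export
undersample <- function(img, mask) {
  assert_image(img)
  stopifnot(is_sampling_mask(mask))
  if (!all(dim(img) == dim(mask$flags)))
    stop("image and mask sizes disagree", call. = FALSE)
  k <- fourier(img)
  k[!mask$flags] <- 0 + 0i
  new_kspace_measurement(k, mask)
}

#' Zero-filling reconstruction
#'
#' The baseline reconstruction: inverse Fourier transform of the measured
#' k-space with all unacquired samples left at zero, returned as a magnitude
#' image.
#'
#' @param y a `kspace_measurement`.
#' @return Numeric matrix (magnitude image).
#' @export
zero_fill <- function(y) {
  stopifnot(inherits(y, "kspace_measurement"))
  Mod(inverse_fourier(y$values))
}

#' k-space data correction
#'
#' Replaces the reconstruction's Fourier samples by the acquired measurements
#' wherever the mask is true, leaving the network's prediction only on the
#' unmeasured locations, and inverse-transforms the corrected k-space. All
#' acquired data are therefore preserved exactly and reconstruction error is
#' confined to unmeasured k-space.
#'
#' The returned image is the magnitude of the complex inverse (the display
#' convention), but it carries the corrected complex k-space as attribute
#' `"kspace"` and the complex image as `"complex"`. Correcting an
#' already-corrected image reuses that complex channel, which makes the
#' operation exactly idempotent and keeps the k-space projection property
#' (`F(result)` equals `y` on the mask) at machine precision.
#'
#' @param recon square numeric matrix (a reconstruction), or the output of a
#'   previous `data_correction()` call.
#' @param y the acquired `kspace_measurement`.
#' @return Magnitude image with attributes `kspace` (complex corrected
#'   k-space) and `complex` (complex corrected image).
#' @export
data_correction <- function(recon, y) {
  stopifnot(inherits(y, "kspace_measurement"))
  k_rec <- attr(recon, "kspace")
  if (is.null(k_rec)) {
    assert_image(recon)
    if (!all(dim(recon) == dim(y$values)))
      stop("reconstruction and measurement sizes disagree", call. = FALSE)
    k_rec <- fourier(recon)
  }
  y_cor <- k_rec
  y_cor[y$mask$flags] <- y$values[y$mask$flags]
  img_c <- inverse_fourier(y_cor)
  out <- Mod(img_c)
  attr(out, "kspace") <- y_cor
  attr(out, "complex") <- img_c
  out
}
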