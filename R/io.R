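# File interchange: PNG images, HDF5 masks / k-space, YAML configuration.
# All formats are optional conveniences; every internal computation runs on
# plain double matrices.

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package `", pkg, "` is required for this I/O helper", call. = FALSE)
}

#' Read / write images as 16-bit greyscale PNG
#'
#' Intensities are clipped to `[0, 1]`; PNG rows run top-to-bottom, matrix
#' rows likewise, so the round trip is transposition-free.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path file path.
#' @return `read_image_png()` returns a numeric matrix in `[0, 1]`.
#' @export
write_image_png <- function(img, path) {
  need_pkg("png")
  png::writePNG(pmin(pmax(img, 0), 1), path, dpi = NULL)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  need_pkg("png")
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

#' Store a sampling mask in HDF5
#'
#' Dataset `flags` (uint8) plus attributes `scheme`, `requested_rate`,
#' `achieved_rate` and `seed`.
#'
#' @param mask a `sampling_mask`.
#' @param path HDF5 file path (overwritten).
#' @return `read_mask_h5()` returns the `sampling_mask`.
#' @export
write_mask_h5 <- function(mask, path) {
  need_pkg("rhdf5")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(storage.mode_uint8(mask$flags), path, "flags")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(mask$scheme, fid, "scheme")
  rhdf5::h5writeAttribute(mask$requested_rate, fid, "requested_rate")
  rhdf5::h5writeAttribute(mask$achieved_rate, fid, "achieved_rate")
  rhdf5::h5writeAttribute(as.integer(mask$seed), fid, "seed")
  invisible(path)
}

storage.mode_uint8 <- function(flags) {
  m <- matrix(as.integer(flags), nrow(flags), ncol(flags))
  storage.mode(m) <- "integer"
  m
}

#' @rdname write_mask_h5
#' @export
read_mask_h5 <- function(path) {
  need_pkg("rhdf5")
  flags <- rhdf5::h5read(path, "flags") != 0L
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  att <- function(name) rhdf5::h5readAttributes(fid, "/")[[name]]
  m <- new_sampling_mask(flags, as.character(att("scheme")),
                         as.numeric(att("requested_rate")),
                         as.integer(att("seed")))
  m
}

#' Store k-space measurements in HDF5
#'
#' Complex values as paired float64 datasets `real` / `imag`, the mask flags
#' alongside, and the mask metadata as attributes.
#'
#' @param y a `kspace_measurement`.
#' @param path HDF5 file path (overwritten).
#' @return `read_kspace_h5()` returns the `kspace_measurement`.
#' @export
write_kspace_h5 <- function(y, path) {
  need_pkg("rhdf5")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(y$values), path, "real")
  rhdf5::h5write(Im(y$values), path, "imag")
  rhdf5::h5write(storage.mode_uint8(y$mask$flags), path, "flags")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(y$mask$scheme, fid, "scheme")
  rhdf5::h5writeAttribute(y$mask$requested_rate, fid, "requested_rate")
  rhdf5::h5writeAttribute(as.integer(y$mask$seed), fid, "seed")
  invisible(path)
}

#' @rdname write_kspace_h5
#' @export
read_kspace_h5 <- function(path) {
  need_pkg("rhdf5")
  re <- rhdf5::h5read(path, "real")
  im <- rhdf5::h5read(path, "imag")
  flags <- rhdf5::h5read(path, "flags") != 0L
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  att <- rhdf5::h5readAttributes(fid, "/")
  mask <- new_sampling_mask(flags, as.character(att$scheme),
                            as.numeric(att$requested_rate),
                            as.integer(att$seed))
  new_kspace_measurement(matrix(complex(real = re, imaginary = im),
                                nrow(re), ncol(re)), mask)
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the training-setting names: `learning_rate`, `L`,
#' `n_d`, `n_u`, `n_s`, `k_d`, `k_u`, `k_s`, `MaxIt`, `SubIt`,
#' `wavelet_function`, `decomposition_level`, `rho`, `lambda`, `seed`.
#' Missing keys fall back to the defaults of [admm_config()].
#'
#' @param path YAML file path.
#' @return An [admm_config()].
#' @export
read_config_yaml <- function(path) {
  need_pkg("yaml")
  raw <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  spec <- network_spec(
    depth_L = pick("L", 6L),
    n_d = pick("n_d", c(32L, 32L, 64L, 128L, 128L, 128L)),
    n_u = pick("n_u", pick("n_d", c(32L, 32L, 64L, 128L, 128L, 128L))),
    n_s = pick("n_s", rep(16L, pick("L", 6L))),
    k_d = pick("k_d", 3L), k_u = pick("k_u", 3L), k_s = pick("k_s", 1L))
  admm_config(
    max_it = pick("MaxIt", 50L), sub_it = pick("SubIt", 100L),
    rho = pick("rho", 0.05), lam = pick("lambda", 1e-4),
    learning_rate = pick("learning_rate", 0.01),
    wavelet_name = tolower(pick("wavelet_function", "haar")),
    wavelet_level = pick("decomposition_level", 6L),
    net_spec = spec, seed = pick("seed", 0L))
}

#' Serialise wavelet coefficients to HDF5
#'
#' Stores the packed coefficient matrix as dataset `coeffs` with `wavelet`
#' and `level` attributes; intended for debugging dumps of ADMM state.
#'
#' @param coeffs a `wavelet_coeffs` object.
#' @param path HDF5 file path (overwritten).
#' @return `read_coeffs_h5()` returns the `wavelet_coeffs`.
#' @export
write_coeffs_h5 <- function(coeffs, path) {
  need_pkg("rhdf5")
  stopifnot(inherits(coeffs, "wavelet_coeffs"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  mat <- unclass(coeffs)
  attributes(mat) <- list(dim = dim(mat))
  rhdf5::h5write(mat, path, "coeffs")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(attr(coeffs, "wavelet"), fid, "wavelet")
  rhdf5::h5writeAttribute(as.integer(attr(coeffs, "level")), fid, "level")
  invisible(path)
}

#' @rdname write_coeffs_h5
#' @export
read_coeffs_h5 <- function(path) {
  need_pkg("rhdf5")
  mat <- rhdf5::h5read(path, "coeffs")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  att <- rhdf5::h5readAttributes(fid, "/")
  new_wavelet_coeffs(mat, as.character(att$wavelet), as.integer(att$level))
}
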