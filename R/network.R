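# The untrained hourglass encoder-decoder with skip connections.
#
# Topology (depth L, input side N divisible by 2^L):
#   encoder block i: conv k_d stride-2 -> BN -> LeakyReLU,
#                    conv k_d stride-1 -> BN -> LeakyReLU     (n_d[i] filters)
#   skip branch i:   1x1 conv -> BN -> LeakyReLU              (n_s[i] filters,
#                    fed from the encoder feature entering block i)
#   decoder block i: bilinear 2x upsample of the deeper feature, channel
#                    concatenation with skip i, conv k_u stride-1 -> BN ->
#                    LeakyReLU                                 (n_u[i] filters)
#   head:            1x1 conv to one channel -> sigmoid, so outputs live in
#                    [0, 1].
#
# Normalisation always uses the statistics of the current (single) input, so a
# forward pass is a pure, deterministic function of parameters and input.

#' Hourglass network specification
#'
#' Per-depth filter counts and kernel sizes for the encoder (`n_d`, `k_d`),
#' decoder (`n_u`, `k_u`) and skip branches (`n_s`, `k_s`). The defaults are
#' the configuration used for 256 x 256 brain scans; [desk_network_spec()]
#' gives a CPU-sized variant.
#'
#' @param depth_L network depth; the input side must be divisible by
#'   `2^depth_L`.
#' @param n_d,n_u,n_s integer vectors of length `depth_L`.
#' @param k_d,k_u,k_s kernel sizes, scalar or per-depth vectors.
#' @param leaky_slope negative slope of the LeakyReLU.
#' @return A `network_spec` list.
#' @export
network_spec <- function(depth_L = 6L,
                         n_d = c(32L, 32L, 64L, 128L, 128L, 128L),
                         n_u = n_d,
                         n_s = rep(16L, depth_L),
                         k_d = 3L, k_u = 3L, k_s = 1L,
                         leaky_slope = 0.1) {
  L <- as.integer(depth_L)
  rep_len_int <- function(x) as.integer(rep_len(x, L))
  spec <- list(depth_L = L, n_d = rep_len_int(n_d), n_u = rep_len_int(n_u),
               n_s = rep_len_int(n_s), k_d = rep_len_int(k_d),
               k_u = rep_len_int(k_u), k_s = rep_len_int(k_s),
               leaky_slope = leaky_slope)
  for (f in c("n_d", "n_u", "n_s", "k_d", "k_u", "k_s"))
    if (length(spec[[f]]) != L)
      stop("`", f, "` must have length depth_L", call. = FALSE)
  if (any(spec$k_d %% 2 == 0) || any(spec$k_u %% 2 == 0) ||
      any(spec$k_s %% 2 == 0))
    stop("kernel sizes must be odd", call. = FALSE)
  structure(spec, class = "network_spec")
}

#' CPU-sized hourglass specification
#'
#' Depth 4 with halved filter counts relative to the full-scale configuration;
#' used by the `"desk"` experiment preset.
#'
#' @return A `network_spec`.
#' @export
desk_network_spec <- function() {
  network_spec(depth_L = 4L, n_d = c(16L, 16L, 32L, 64L), n_s = rep(8L, 4L))
}

enc_in_channels <- function(spec, i) if (i == 1L) 1L else spec$n_d[i - 1L]
dec_in_channels <- function(spec, i) {
  deeper <- if (i == spec$depth_L) spec$n_d[spec$depth_L] else spec$n_u[i + 1L]
  deeper + spec$n_s[i]
}

conv_layer_init <- function(c_out, c_in, k) {
  fan_in <- c_in * k * k
  bound <- 1 / sqrt(fan_in)
  list(w = matrix(stats::runif(c_out * fan_in, -bound, bound), c_out, fan_in),
       b = stats::runif(c_out, -bound, bound),
       gamma = rep(1, c_out),
       beta = rep(0, c_out))
}

#' Build (randomly initialise) the network parameters
#'
#' No pre-training is involved anywhere: the parameters are drawn from a
#' scaled uniform distribution (bound `1/sqrt(fan_in)`), and two builds with
#' the same spec and seed are identical.
#'
#' @param spec a [network_spec()].
#' @param seed integer initialisation seed.
#' @return A `network_params` list (one entry of conv weights/bias and BN
#'   gain/shift per layer).
#' @export
build_network <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "network_spec"))
  L <- spec$depth_L
  with_local_seed(seed, {
    params <- list(
      enc1 = lapply(seq_len(L), function(i)
        conv_layer_init(spec$n_d[i], enc_in_channels(spec, i), spec$k_d[i])),
      enc2 = lapply(seq_len(L), function(i)
        conv_layer_init(spec$n_d[i], spec$n_d[i], spec$k_d[i])),
      skip = lapply(seq_len(L), function(i)
        conv_layer_init(spec$n_s[i], enc_in_channels(spec, i), spec$k_s[i])),
      dec = lapply(seq_len(L), function(i)
        conv_layer_init(spec$n_u[i], dec_in_channels(spec, i), spec$k_u[i])),
      head = conv_layer_init(1L, spec$n_u[1], 1L)[c("w", "b")]
    )
    structure(list(layers = params, spec = spec, init_seed = as.integer(seed)),
              class = "network_params")
  })
}

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

# conv -> BN -> LeakyReLU with cached intermediates for the backward pass
cbl_fwd <- function(x, layer, k, stride, slope) {
  z <- .conv_fwd(x, layer$w, layer$b, k, stride)
  bn <- .bn_fwd(z, layer$gamma, layer$beta, 1e-5)
  a <- .lrelu_fwd(bn$y, slope)
  list(out = a, x = x, z = z, bn_y = bn$y, mu = bn$mu, istd = bn$istd)
}

cbl_bwd <- function(cache, layer, k, stride, slope, dout) {
  d_bn <- .lrelu_bwd(cache$bn_y, dout, slope)
  bb <- .bn_bwd(cache$z, layer$gamma, cache$mu, cache$istd, d_bn)
  cb <- .conv_bwd(cache$x, layer$w, k, stride, bb$dx)
  list(dx = cb$dx,
       grads = list(w = cb$dw, b = cb$db, dgamma = bb$dgamma,
                    dbeta = bb$dbeta))
}

#' Forward pass of the hourglass network
#'
#' Deterministic given parameters and input; normalisation statistics are
#' those of the current input. Use `with_cache = TRUE` to retain the
#' intermediates needed by [net_backward()].
#'
#' @param params a `network_params` from [build_network()].
#' @param input_img square numeric matrix with side divisible by
#'   `2^depth_L`.
#' @param with_cache keep intermediates for backpropagation.
#' @return The output image (matrix in `[0, 1]`); with `with_cache = TRUE`, a
#'   list `(out, cache)`.
#' @export
net_forward <- function(params, input_img, with_cache = FALSE) {
  stopifnot(inherits(params, "network_params"))
  spec <- params$spec
  L <- spec$depth_L
  n <- nrow(input_img)
  if (!is.matrix(input_img) || n != ncol(input_img))
    stop("input must be a square matrix", call. = FALSE)
  if (n %% (2^L) != 0)
    stop("input side must be divisible by 2^depth_L", call. = FALSE)
  slope <- spec$leaky_slope
  lay <- params$layers

  e <- vector("list", L + 1L)   # e[[i+1]] = feature entering encoder block i+1
  e[[1]] <- as_cube(input_img)
  cache_e1 <- cache_e2 <- cache_s <- cache_d <- vector("list", L)
  for (i in seq_len(L)) {
    c1 <- cbl_fwd(e[[i]], lay$enc1[[i]], spec$k_d[i], 2L, slope)
    c2 <- cbl_fwd(c1$out, lay$enc2[[i]], spec$k_d[i], 1L, slope)
    cache_e1[[i]] <- c1; cache_e2[[i]] <- c2
    e[[i + 1]] <- c2$out
  }
  s <- vector("list", L)
  for (i in seq_len(L)) {
    cs <- cbl_fwd(e[[i]], lay$skip[[i]], spec$k_s[i], 1L, slope)
    cache_s[[i]] <- cs
    s[[i]] <- cs$out
  }
  d <- e[[L + 1]]
  for (i in rev(seq_len(L))) {
    u <- .up_fwd(d)
    cat_in <- array(c(u, s[[i]]), dim = c(dim(u)[1], dim(u)[2],
                                          dim(u)[3] + dim(s[[i]])[3]))
    cd <- cbl_fwd(cat_in, lay$dec[[i]], spec$k_u[i], 1L, slope)
    cache_d[[i]] <- c(cd, list(n_up = dim(u)[3]))
    d <- cd$out
  }
  z <- .conv_fwd(d, lay$head$w, lay$head$b, 1L, 1L)
  out <- 1 / (1 + exp(-z[, , 1]))
  if (!with_cache) return(out)
  list(out = out,
       cache = list(e1 = cache_e1, e2 = cache_e2, s = cache_s, d = cache_d,
                    head_x = d, out = out))
}

#' Backpropagation through the hourglass network
#'
#' Given the gradient of a scalar loss with respect to the network output,
#' returns the gradient with respect to every parameter (same structure as
#' `params$layers`).
#'
#' @param params a `network_params`.
#' @param cache the cache from `net_forward(..., with_cache = TRUE)`.
#' @param dout matrix: d(loss)/d(output image).
#' @return Nested list of gradients.
#' @export
net_backward <- function(params, cache, dout) {
  spec <- params$spec
  L <- spec$depth_L
  slope <- spec$leaky_slope
  lay <- params$layers
  g <- list(enc1 = vector("list", L), enc2 = vector("list", L),
            skip = vector("list", L), dec = vector("list", L))

  s_out <- cache$out
  dz <- as_cube(dout * s_out * (1 - s_out))
  hb <- .conv_bwd(cache$head_x, lay$head$w, 1L, 1L, dz)
  g$head <- list(w = hb$dw, b = hb$db)
  dd <- hb$dx

  de <- vector("list", L + 1L)        # gradient wrt e[[i]]
  ds <- vector("list", L)
  for (i in seq_len(L)) {             # decoder blocks, reverse of forward
    cd <- cache$d[[i]]
    bk <- cbl_bwd(cd, lay$dec[[i]], spec$k_u[i], 1L, slope, dd)
    g$dec[[i]] <- bk$grads
    n_up <- cd$n_up
    dcat <- bk$dx
    du <- dcat[, , seq_len(n_up), drop = FALSE]
    ds[[i]] <- dcat[, , n_up + seq_len(dim(dcat)[3] - n_up), drop = FALSE]
    dd <- .up_bwd(du)
  }
  de[[L + 1]] <- dd

  for (i in seq_len(L)) {             # skip branches feed e[[i]]
    bk <- cbl_bwd(cache$s[[i]], lay$skip[[i]], spec$k_s[i], 1L, slope, ds[[i]])
    g$skip[[i]] <- bk$grads
    de[[i]] <- if (is.null(de[[i]])) bk$dx else de[[i]] + bk$dx
  }
  for (i in rev(seq_len(L))) {        # encoder blocks
    bk2 <- cbl_bwd(cache$e2[[i]], lay$enc2[[i]], spec$k_d[i], 1L, slope,
                   de[[i + 1]])
    g$enc2[[i]] <- bk2$grads
    bk1 <- cbl_bwd(cache$e1[[i]], lay$enc1[[i]], spec$k_d[i], 2L, slope,
                   bk2$dx)
    g$enc1[[i]] <- bk1$grads
    de[[i]] <- if (is.null(de[[i]])) bk1$dx else de[[i]] + bk1$dx
  }
  g
}

#' Seeded noise input for the deep-image-prior baseline
#'
#' Uniform noise in `[0, 0.1]`, drawn once and held fixed across all training
#' iterations.
#'
#' @param n side length.
#' @param seed integer seed.
#' @return `n x n` numeric matrix.
#' @export
make_noise_input <- function(n, seed = 0L) {
  with_local_seed(seed, matrix(stats::runif(n * n, 0, 0.1), n, n))
}

# ---- parameter flattening and Adam ------------------------------------------

# fixed traversal order of all tensors in `params$layers`
param_tensors <- function(layers) {
  out <- list()
  for (grp in c("enc1", "enc2", "skip", "dec"))
    for (i in seq_along(layers[[grp]]))
      for (f in c("w", "b", "gamma", "beta"))
        out[[length(out) + 1L]] <- list(grp = grp, i = i, f = f)
  for (f in c("w", "b"))
    out[[length(out) + 1L]] <- list(grp = "head", i = NA_integer_, f = f)
  out
}

get_tensor <- function(layers, t) {
  if (identical(t$grp, "head")) layers$head[[t$f]] else layers[[t$grp]][[t$i]][[t$f]]
}

set_tensor <- function(layers, t, value) {
  if (identical(t$grp, "head")) layers$head[[t$f]] <- value
  else layers[[t$grp]][[t$i]][[t$f]] <- value
  layers
}

flatten_params <- function(params) {
  unlist(lapply(param_tensors(params$layers),
                function(t) as.numeric(get_tensor(params$layers, t))))
}

unflatten_params <- function(params, theta) {
  pos <- 0L
  for (t in param_tensors(params$layers)) {
    cur <- get_tensor(params$layers, t)
    len <- length(cur)
    new <- theta[pos + seq_len(len)]
    if (is.matrix(cur)) dim(new) <- dim(cur)
    params$layers <- set_tensor(params$layers, t, new)
    pos <- pos + len
  }
  params
}

flatten_grads <- function(params, grads) {
  unlist(lapply(param_tensors(params$layers), function(t) {
    f <- if (t$f %in% c("gamma", "beta")) paste0("d", t$f) else t$f
    g <- if (identical(t$grp, "head")) grads$head[[f]] else grads[[t$grp]][[t$i]][[f]]
    as.numeric(g)
  }))
}

adam_init <- function(n_par) {
  list(m = numeric(n_par), v = numeric(n_par), t = 0L)
}

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}
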