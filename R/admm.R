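# Reconstruction engines: the reference-driven wavelet-sparsity constrained
# deep image prior trained by ADMM, and the traditional noise-input DIP
# baseline. Per scan, the ADMM loop alternates
#   theta: sub_it Adam steps on  ||y - F_u f(theta|ref)||^2
#                                + (rho/2) ||alpha - Psi f - mu||^2
#   alpha: soft thresholding of  Psi f(theta|ref) + mu   at  lam/rho
#   mu:    dual ascent           mu + alpha - Psi f(theta|ref)
# followed by one k-space data-correction pass on the network output.

#' ADMM / training configuration
#'
#' Defaults are the full-scale settings used for 256 x 256 scans: 50 outer
#' ADMM iterations of 100 inner gradient steps, learning rate 0.01, penalty
#' `rho = 0.05`, regularisation `lam = 1e-4`, Haar wavelet at decomposition
#' level 6. [desk_admm_config()] scales this down for CPU-only runs.
#'
#' @param max_it outer ADMM iterations.
#' @param sub_it inner gradient steps per theta update.
#' @param rho ADMM penalty parameter (`> 0`).
#' @param lam l1 regularisation weight (`>= 0`).
#' @param learning_rate Adam step size.
#' @param wavelet_name,wavelet_level sparsifying transform settings.
#' @param net_spec a [network_spec()].
#' @param seed seed for network initialisation (and the noise input of the
#'   DIP baseline).
#' @return An `admm_config` list.
#' @export
admm_config <- function(max_it = 50L, sub_it = 100L, rho = 0.05, lam = 1e-4,
                        learning_rate = 0.01, wavelet_name = "haar",
                        wavelet_level = 6L, net_spec = network_spec(),
                        seed = 0L) {
  stopifnot(max_it >= 1, sub_it >= 1, rho > 0, lam >= 0, learning_rate > 0)
  structure(list(max_it = as.integer(max_it), sub_it = as.integer(sub_it),
                 rho = rho, lam = lam, learning_rate = learning_rate,
                 wavelet_name = wavelet_name,
                 wavelet_level = as.integer(wavelet_level),
                 net_spec = net_spec, seed = as.integer(seed)),
            class = "admm_config")
}

#' Scaled-down configuration for CPU runs
#'
#' Depth-4 network with halved filters, 10 outer x 50 inner iterations,
#' intended for 128 x 128 images. All outputs produced under this preset are
#' labelled `scale = "desk"`.
#'
#' @param ... overrides passed to [admm_config()].
#' @return An `admm_config`.
#' @export
desk_admm_config <- function(...) {
  admm_config(max_it = 10L, sub_it = 50L, net_spec = desk_network_spec(), ...)
}

# ---- loss and gradient ------------------------------------------------------

# squared l2 data-fidelity of a real image against masked measurements
fidelity_loss <- function(f, y) {
  k <- fourier(f)
  k[!y$mask$flags] <- 0 + 0i
  r <- k - y$values
  list(value = sum(Mod(r)^2), residual = r)
}

# gradient of the fidelity term wrt the (real) network output
fidelity_grad <- function(residual) 2 * Re(inverse_fourier(residual))

# Eq-style inner objective: fidelity plus the proximity penalty
theta_objective <- function(f, y, alpha, mu, cfg) {
  fid <- fidelity_loss(f, y)
  g <- NULL
  prox <- 0
  if (!is.null(alpha)) {
    psif <- dwt(f, cfg$wavelet_name, cfg$wavelet_level)
    g <- unclass(alpha) - unclass(psif) - unclass(mu)
    prox <- cfg$rho / 2 * sum(g^2)
  }
  list(value = fid$value + prox, residual = fid$residual, gap = g)
}

# full augmented-Lagrangian objective (includes the l1 term)
admm_objective <- function(f, y, alpha, mu, cfg) {
  theta_objective(f, y, alpha, mu, cfg)$value + cfg$lam * sum(abs(alpha))
}

new_admm_state <- function(params, alpha, mu, opt) {
  structure(list(params = params, alpha = alpha, mu = mu, k = 0L, opt = opt),
            class = "admm_state")
}

#' Initialise the ADMM state
#'
#' Builds the network (seeded), sets the sparse code to the wavelet transform
#' of the initial network output (so the proximity penalty starts at zero) and
#' the multiplier to zero.
#'
#' @param ref reference image (network input).
#' @param cfg an [admm_config()].
#' @return An `admm_state` with elements `params`, `alpha`, `mu`, `k`, `opt`.
#' @export
admm_init <- function(ref, cfg) {
  params <- build_network(cfg$net_spec, cfg$seed)
  f0 <- net_forward(params, ref)
  alpha0 <- dwt(f0, cfg$wavelet_name, cfg$wavelet_level)
  mu0 <- alpha0
  mu0[] <- 0
  new_admm_state(params, alpha0, mu0, adam_init(length(flatten_params(params))))
}

#' Network (theta) update
#'
#' Runs `cfg$sub_it` Adam steps on the data-fidelity plus proximity objective,
#' holding `alpha` and `mu` fixed. Optimizer state persists across outer
#' iterations. As a divergence guard the best parameters seen during the inner
#' loop are restored if the final objective exceeds them, so the objective
#' never ends above its starting value; a non-finite loss raises an error
#' naming the inner iteration.
#'
#' @param state an `admm_state`; with `state$alpha = NULL` the proximity term
#'   vanishes and the update is the plain DIP iteration.
#' @param y acquired `kspace_measurement`.
#' @param ref network input image.
#' @param cfg an [admm_config()].
#' @param n_steps number of gradient steps (defaults to `cfg$sub_it`).
#' @return The updated `admm_state`.
#' @export
theta_update <- function(state, y, ref, cfg, n_steps = cfg$sub_it) {
  params <- state$params
  theta <- flatten_params(params)
  opt <- state$opt
  best_val <- Inf
  best_theta <- NULL
  for (s in seq_len(n_steps)) {
    fc <- net_forward(params, ref, with_cache = TRUE)
    obj <- theta_objective(fc$out, y, state$alpha, state$mu, cfg)
    if (!is.finite(obj$value))
      stop("divergence: non-finite objective at inner iteration ", s,
           call. = FALSE)
    if (obj$value < best_val) {
      best_val <- obj$value
      best_theta <- theta
    }
    dfout <- fidelity_grad(obj$residual)
    if (!is.null(obj$gap))
      dfout <- dfout - cfg$rho * idwt(obj$gap, level = cfg$wavelet_level)
    grads <- net_backward(params, fc$cache, dfout)
    gvec <- flatten_grads(params, grads)
    st <- adam_step(theta, gvec, opt, cfg$learning_rate)
    theta <- st$theta
    opt <- st$state
    params <- unflatten_params(params, theta)
  }
  f_end <- net_forward(params, ref)
  end_val <- theta_objective(f_end, y, state$alpha, state$mu, cfg)$value
  if (!is.finite(end_val))
    stop("divergence: non-finite objective after the inner loop", call. = FALSE)
  if (end_val > best_val)
    params <- unflatten_params(params, best_theta)
  state$params <- params
  state$opt <- opt
  state
}

#' Sparse-code (alpha) update
#'
#' Closed-form minimiser of the l1-penalised quadratic subproblem: soft
#' thresholding of `Psi f(theta|ref) + mu` at `lam / rho`.
#'
#' @inheritParams theta_update
#' @return The updated `admm_state`.
#' @export
alpha_update <- function(state, ref, cfg) {
  f <- net_forward(state$params, ref)
  psif <- dwt(f, cfg$wavelet_name, cfg$wavelet_level)
  state$alpha <- prox_l1(psif + unclass(state$mu), cfg$lam, cfg$rho)
  state
}

#' Multiplier (mu) update
#'
#' Dual ascent on the splitting constraint `alpha = Psi f(theta|ref)`:
#' `mu <- mu + Psi f(theta|ref) - alpha`. This is the update implied by the
#' augmented-Lagrangian penalty `(rho/2) ||alpha - Psi f - mu||^2` together
#' with the thresholding step `S_{lam/rho}(Psi f + mu)` (scaled-dual ADMM
#' with multiplier `-rho * mu`); the opposite sign turns the dual iteration
#' into a positive feedback loop whose residual doubles every cycle instead
#' of vanishing.
#'
#' @inheritParams theta_update
#' @return The updated `admm_state`.
#' @export
mu_update <- function(state, ref, cfg) {
  f <- net_forward(state$params, ref)
  psif <- dwt(f, cfg$wavelet_name, cfg$wavelet_level)
  state$mu <- state$mu + unclass(psif) - unclass(state$alpha)
  state
}

history_row <- function(k, objective, f, truth) {
  if (is.null(truth))
    data.frame(k = k, objective = objective, relerr = NA_real_,
               psnr = NA_real_, ssim = NA_real_)
  else
    data.frame(k = k, objective = objective, relerr = rel_err(f, truth),
               psnr = psnr(f, truth), ssim = ssim(f, truth))
}

new_recon_report <- function(method, pre, final, history) {
  structure(list(method = method, recon_pre_correction = pre,
                 recon_final = final, history = history),
            class = "recon_report")
}

#' @export
print.recon_report <- function(x, ...) {
  cat(sprintf("<recon_report> %s, %d iterations recorded\n",
              x$method, nrow(x$history)))
  if (!all(is.na(x$history$relerr))) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final-iteration RelErr %.4f, PSNR %.2f dB, SSIM %.4f\n",
                last$relerr, last$psnr, last$ssim))
  }
  invisible(x)
}

#' Reference-driven wavelet-sparsity DIP reconstruction
#'
#' Trains the untrained network per scan by the ADMM loop (theta, alpha, mu
#' updates), takes the trained network's output as the reconstruction, and
#' applies the k-space data-correction step. When the ground truth is
#' supplied, per-iteration RelErr/PSNR/SSIM of the current network output are
#' recorded alongside the augmented-Lagrangian objective.
#'
#' @param y acquired `kspace_measurement`.
#' @param ref high-resolution reference image of the same size (the network
#'   input).
#' @param cfg an [admm_config()].
#' @param truth optional ground-truth target image for history metrics.
#' @param verbose emit a timestamped per-iteration progress line.
#' @return A `recon_report`: `recon_pre_correction`, `recon_final` (after
#'   data correction; carries the corrected complex k-space as attributes) and
#'   a `history` data frame with one row per ADMM iteration.
#' @export
rws_dip_reconstruct <- function(y, ref, cfg = admm_config(), truth = NULL,
                                verbose = FALSE) {
  assert_image(ref)
  if (!all(dim(ref) == dim(y$values)))
    stop("reference and measurement sizes disagree", call. = FALSE)
  state <- admm_init(ref, cfg)
  history <- vector("list", cfg$max_it)
  for (k in seq_len(cfg$max_it)) {
    state <- theta_update(state, y, ref, cfg)
    state <- alpha_update(state, ref, cfg)
    state <- mu_update(state, ref, cfg)
    state$k <- k
    f <- net_forward(state$params, ref)
    obj <- admm_objective(f, y, state$alpha, state$mu, cfg)
    history[[k]] <- history_row(k, obj, f, truth)
    if (verbose)
      message(format(Sys.time(), "%H:%M:%S"),
              sprintf(" admm iteration %d/%d  objective %.6g%s", k, cfg$max_it,
                      obj, if (is.null(truth)) "" else
                        sprintf("  relerr %.4f", history[[k]]$relerr)))
  }
  pre <- net_forward(state$params, ref)
  final <- data_correction(pre, y)
  new_recon_report("rws_dip", pre, final, do.call(rbind, history))
}

#' Traditional deep-image-prior baseline
#'
#' Fixed seeded noise input, plain gradient iterations on the data-fidelity
#' loss alone, run for `max_it * sub_it` steps so both methods see the same
#' gradient-step budget. The same data-correction step is applied afterwards
#' for a fair comparison. History is recorded every `sub_it` steps.
#'
#' @inheritParams rws_dip_reconstruct
#' @return A `recon_report` with `method = "dip"`.
#' @export
dip_reconstruct <- function(y, cfg = admm_config(), truth = NULL,
                            verbose = FALSE) {
  n <- nrow(y$values)
  if (n %% (2^cfg$net_spec$depth_L) != 0)
    stop("image side must be divisible by 2^depth_L", call. = FALSE)
  z <- make_noise_input(n, cfg$seed)
  params <- build_network(cfg$net_spec, cfg$seed + 1L)
  state <- new_admm_state(params, NULL, NULL,
                          adam_init(length(flatten_params(params))))
  history <- vector("list", cfg$max_it)
  for (k in seq_len(cfg$max_it)) {
    state <- theta_update(state, y, z, cfg)
    state$k <- k
    f <- net_forward(state$params, z)
    obj <- fidelity_loss(f, y)$value
    history[[k]] <- history_row(k, obj, f, truth)
    if (verbose)
      message(format(Sys.time(), "%H:%M:%S"),
              sprintf(" dip step block %d/%d  loss %.6g", k, cfg$max_it, obj))
  }
  pre <- net_forward(state$params, z)
  final <- data_correction(pre, y)
  new_recon_report("dip", pre, final, do.call(rbind, history))
}
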