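# ADMM mechanics on a 16x16 fixture: a tiny network keeps every update cheap
# while exercising exactly the same code paths as full-scale runs.

fixture <- function(seed = 1L) {
  pair <- generate_pair(phantom_pair_config(n = 16L, n_ellipses = 3L,
                                            seed = seed))
  mask <- make_variable_density_mask(16L, 0.5, seed)
  cfg <- admm_config(max_it = 2L, sub_it = 10L, rho = 0.05, lam = 1e-3,
                     wavelet_level = 3L,
                     net_spec = network_spec(depth_L = 2L, n_d = c(4L, 6L),
                                             n_s = c(3L, 3L)),
                     seed = seed)
  list(pair = pair, y = undersample(pair$target, mask), cfg = cfg)
}

test_that("alpha update equals hand-computed soft thresholding", {
  fx <- fixture()
  st <- admm_init(fx$pair$reference, fx$cfg)
  # make mu nontrivial
  st$mu[] <- seq(-0.1, 0.1, length.out = 256)
  st2 <- alpha_update(st, fx$pair$reference, fx$cfg)

  f <- net_forward(st$params, fx$pair$reference)
  arg <- unclass(dwt(f, "haar", 3L)) + unclass(st$mu)
  kappa <- fx$cfg$lam / fx$cfg$rho
  want <- sign(arg) * pmax(abs(arg) - kappa, 0)   # branch table, by hand
  expect_lt(max(abs(unclass(st2$alpha) - want)), 1e-12)

  # lam = 0: no shrinkage at all
  cfg0 <- fx$cfg; cfg0$lam <- 0
  st0 <- alpha_update(st, fx$pair$reference, cfg0)
  expect_lt(max(abs(unclass(st0$alpha) - arg)), 1e-12)

  # the update minimises the subproblem objective locally
  obj <- function(a) fx$cfg$lam * sum(abs(a)) +
    fx$cfg$rho / 2 * sum((a - arg)^2)
  set.seed(3)
  base <- obj(unclass(st2$alpha))
  for (i in 1:20)
    expect_gte(obj(unclass(st2$alpha) + rnorm(256, sd = 0.01)), base)

  # shrinkage in l1
  expect_lte(sum(abs(unclass(st2$alpha))), sum(abs(arg)))
})

test_that("mu update is the exact dual ascent step", {
  fx <- fixture(2L)
  st <- admm_init(fx$pair$reference, fx$cfg)
  st <- alpha_update(st, fx$pair$reference, fx$cfg)
  mu_prev <- unclass(st$mu)
  st2 <- mu_update(st, fx$pair$reference, fx$cfg)

  psif <- unclass(dwt(net_forward(st$params, fx$pair$reference), "haar", 3L))
  want <- mu_prev + psif - unclass(st$alpha)
  expect_lt(max(abs(unclass(st2$mu) - want)), 1e-12)

  # alpha == Psi f leaves mu unchanged
  st$alpha <- dwt(net_forward(st$params, fx$pair$reference), "haar", 3L)
  st3 <- mu_update(st, fx$pair$reference, fx$cfg)
  expect_lt(max(abs(unclass(st3$mu) - mu_prev)), 1e-12)

  # a constant constraint violation c walks into mu with opposite sign
  st$mu[] <- 0
  st$alpha <- st$alpha + 0.3
  st4 <- mu_update(st, fx$pair$reference, fx$cfg)
  expect_lt(max(abs(unclass(st4$mu) + 0.3)), 1e-12)
})

test_that("theta gradient (fidelity + proximity) matches finite differences", {
  fx <- fixture(3L)
  st <- admm_init(fx$pair$reference, fx$cfg)
  st$mu[] <- rnorm(256, sd = 0.01)
  cfg <- fx$cfg

  pars <- st$params
  theta <- rwsdip:::flatten_params(pars)
  loss_of <- function(th) {
    f <- net_forward(rwsdip:::unflatten_params(pars, th), fx$pair$reference)
    rwsdip:::theta_objective(f, fx$y, st$alpha, st$mu, cfg)$value
  }
  fc <- net_forward(pars, fx$pair$reference, with_cache = TRUE)
  obj <- rwsdip:::theta_objective(fc$out, fx$y, st$alpha, st$mu, cfg)
  dfout <- rwsdip:::fidelity_grad(obj$residual) -
    cfg$rho * idwt(obj$gap, level = cfg$wavelet_level)
  g <- rwsdip:::flatten_grads(pars, net_backward(pars, fc$cache, dfout))

  set.seed(13)
  for (i in sample(length(theta), 5)) {
    e <- 1e-5
    tp <- theta; tp[i] <- tp[i] + e
    tm <- theta; tm[i] <- tm[i] - e
    fd <- (loss_of(tp) - loss_of(tm)) / (2 * e)
    expect_lt(abs(fd - g[i]) / max(abs(fd), 1e-6), 1e-3)
  }
})

test_that("theta update descends and never ends above its starting objective", {
  fx <- fixture(4L)
  st <- admm_init(fx$pair$reference, fx$cfg)
  before <- rwsdip:::theta_objective(
    net_forward(st$params, fx$pair$reference), fx$y, st$alpha, st$mu, fx$cfg)$value
  st2 <- theta_update(st, fx$y, fx$pair$reference, fx$cfg, n_steps = 30L)
  after <- rwsdip:::theta_objective(
    net_forward(st2$params, fx$pair$reference), fx$y, st$alpha, st$mu, fx$cfg)$value
  expect_lte(after, before * 1.05)
  expect_lt(after, before)   # 30 Adam steps should actually make progress
})

test_that("with a vanishing penalty the update reduces to the DIP iteration", {
  fx <- fixture(5L)
  # DIP path: no alpha/mu at all
  pars <- build_network(fx$cfg$net_spec, 7L)
  opt <- rwsdip:::adam_init(length(rwsdip:::flatten_params(pars)))
  st_dip <- rwsdip:::new_admm_state(pars, NULL, NULL, opt)
  st_dip <- theta_update(st_dip, fx$y, fx$pair$reference, fx$cfg, n_steps = 5L)

  # RWS path with rho -> 0 and alpha = mu = 0
  cfg0 <- fx$cfg; cfg0$rho <- 1e-20; cfg0$lam <- 0
  zero <- dwt(matrix(0, 16, 16), "haar", 3L)
  st_rws <- rwsdip:::new_admm_state(build_network(fx$cfg$net_spec, 7L),
                                    zero, zero, opt)
  st_rws <- theta_update(st_rws, fx$y, fx$pair$reference, cfg0, n_steps = 5L)

  expect_lt(max(abs(rwsdip:::flatten_params(st_rws$params) -
                    rwsdip:::flatten_params(st_dip$params))), 1e-8)
})

test_that("full reconstructions are seeded, consistent and reported correctly", {
  fx <- fixture(6L)
  rep1 <- rws_dip_reconstruct(fx$y, fx$pair$reference, fx$cfg,
                              truth = fx$pair$target)
  rep2 <- rws_dip_reconstruct(fx$y, fx$pair$reference, fx$cfg,
                              truth = fx$pair$target)
  expect_identical(rep1$recon_final, rep2$recon_final)   # bit-reproducible
  expect_identical(nrow(rep1$history), fx$cfg$max_it)
  expect_true(all(is.finite(rep1$history$objective)))

  # final image keeps every acquired k-space sample
  k <- attr(rep1$recon_final, "kspace")
  flags <- fx$y$mask$flags
  expect_lt(max(Mod(k[flags] - fx$y$values[flags])), 1e-10)

  # full-mask acquisition: the measurement determines the answer exactly
  y_full <- undersample(fx$pair$target, make_cartesian_mask(16L, 1.0, 0L))
  rep_full <- rws_dip_reconstruct(y_full, fx$pair$reference, fx$cfg)
  expect_lt(max(abs(rep_full$recon_final - fx$pair$target)), 1e-8)

  # DIP baseline: deterministic, same history contract
  d1 <- dip_reconstruct(fx$y, fx$cfg, truth = fx$pair$target)
  d2 <- dip_reconstruct(fx$y, fx$cfg, truth = fx$pair$target)
  expect_identical(d1$recon_final, d2$recon_final)
  expect_identical(nrow(d1$history), fx$cfg$max_it)
})

test_that("ADMM drives the splitting constraint toward feasibility", {
  pair <- generate_pair(phantom_pair_config(n = 32L, seed = 8L))
  y <- undersample(pair$target, make_cartesian_mask(32L, 0.4, 2L))
  cfg <- admm_config(max_it = 4L, sub_it = 40L, wavelet_level = 4L,
                     net_spec = network_spec(depth_L = 2L, n_d = c(8L, 16L),
                                             n_s = c(4L, 4L)),
                     seed = 2L)
  gaps <- numeric(cfg$max_it)
  st <- admm_init(pair$reference, cfg)
  for (k in seq_len(cfg$max_it)) {
    st <- theta_update(st, y, pair$reference, cfg)
    st <- alpha_update(st, pair$reference, cfg)
    st <- mu_update(st, pair$reference, cfg)
    psif <- unclass(dwt(net_forward(st$params, pair$reference), "haar", 4L))
    gaps[k] <- sqrt(sum((unclass(st$alpha) - psif)^2))
  }
  expect_lt(gaps[cfg$max_it], gaps[1])
})
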