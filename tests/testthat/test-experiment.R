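# Tiny configurations keep the runner tests fast; the scientifically meaningful
# desk-scale comparison lives in the acceptance suite.

tiny_overrides <- function() {
  list(max_it = 1L, sub_it = 2L, wavelet_level = 3L,
       net_spec = network_spec(depth_L = 2L, n_d = c(4L, 4L), n_s = c(2L, 2L)))
}

test_that("a zero-fill-only plan completes without building a network", {
  out <- withr::local_tempdir()
  plan <- experiment_plan(methods = "zero_fill", rates = c(0.2, 0.3),
                          repeats = 2L, scale = "desk", output_dir = out)
  res <- run_experiment(plan)
  expect_identical(nrow(res$runs), 4L)
  expect_identical(nrow(res$summary), 2L)
  expect_true(all(c("relerr_pct", "psnr_db", "ssim") %in% names(res$summary)))
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_identical(sum(grepl("^run_.*json$", list.files(out))), 4L)
})

test_that("experiments are reproducible from their manifest", {
  plan <- experiment_plan(methods = c("zero_fill", "rws_dip"), rates = 0.3,
                          repeats = 1L, scale = "desk", base_seed = 4L)
  r1 <- run_experiment(plan, cfg_overrides = tiny_overrides())
  r2 <- run_experiment(plan, cfg_overrides = tiny_overrides())
  expect_identical(r1$summary, r2$summary)
  expect_true(all(r1$summary$scale == "desk"))
})

test_that("plan validation rejects unknown methods and schemes upfront", {
  expect_error(experiment_plan(methods = "magic"), "unknown method")
  expect_error(experiment_plan(mask_schemes = "spiral"), "unknown mask scheme")
  expect_error(run_experiment(experiment_plan(),
                              cfg_overrides = list(nonsense = 1)),
               "unknown config override")
})

test_that("parameter sweeps produce one curve point per value and rate", {
  plan <- experiment_plan(methods = "rws_dip", rates = c(0.2, 0.3),
                          repeats = 1L, scale = "desk", base_seed = 2L)
  curve <- sweep_parameters("rho", c(0.01, 0.05), plan,
                            cfg_overrides = tiny_overrides())
  expect_identical(nrow(curve), 4L)   # 2 values x 2 rates
  expect_identical(curve$value, rep(c(0.01, 0.05), each = 2))

  # a one-point sweep degenerates to the plain experiment result
  one <- sweep_parameters("lam", 1e-4, plan, cfg_overrides = tiny_overrides())
  direct <- run_experiment(plan, cfg_overrides = c(list(lam = 1e-4),
                                                   tiny_overrides()))
  expect_equal(one$psnr_db, direct$summary$psnr_db, tolerance = 1e-12)
})

test_that("configuration files round-trip the training settings", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("learning_rate: 0.02", "L: 2", "n_d: [4, 6]", "n_s: [2, 2]",
               "MaxIt: 3", "SubIt: 7", "wavelet_function: Haar",
               "decomposition_level: 4", "rho: 0.07", "lambda: 0.001",
               "seed: 11"), path)
  cfg <- read_config_yaml(path)
  expect_identical(cfg$max_it, 3L)
  expect_identical(cfg$sub_it, 7L)
  expect_equal(cfg$rho, 0.07)
  expect_equal(cfg$lam, 0.001)
  expect_equal(cfg$learning_rate, 0.02)
  expect_identical(cfg$wavelet_name, "haar")
  expect_identical(cfg$net_spec$depth_L, 2L)
  expect_identical(cfg$net_spec$n_d, c(4L, 6L))
})

test_that("mask and k-space HDF5 round trips preserve data and metadata", {
  skip_if_not_installed("rhdf5")
  m <- make_variable_density_mask(32, 0.3, 9L)
  path <- withr::local_tempfile(fileext = ".h5")
  write_mask_h5(m, path)
  m2 <- read_mask_h5(path)
  expect_identical(m2$flags, m$flags)
  expect_identical(m2$scheme, m$scheme)
  expect_equal(m2$achieved_rate, m$achieved_rate)

  y <- undersample(random_image(32, 4), m)
  path2 <- withr::local_tempfile(fileext = ".h5")
  write_kspace_h5(y, path2)
  y2 <- read_kspace_h5(path2)
  expect_equal(y2$values, y$values, tolerance = 1e-15)
  expect_identical(y2$mask$flags, m$flags)

  w <- dwt(random_image(32, 5), level = 4L)
  path3 <- withr::local_tempfile(fileext = ".h5")
  write_coeffs_h5(w, path3)
  w2 <- read_coeffs_h5(path3)
  expect_equal(unclass(w2)[seq_along(w)], unclass(w)[seq_along(w)],
               tolerance = 1e-15)
  expect_identical(attr(w2, "level"), attr(w, "level"))
})
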