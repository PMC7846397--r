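test_that("fourier is the unitary DC-centred DFT", {
  x <- random_image(16, 1)

  # matches a naive DFT oracle on a tiny grid
  expect_lt(max(Mod(fourier(x) - dft_oracle(x))), 1e-10)

  # constant image -> energy concentrated at the DC element
  cimg <- matrix(0.7, 16, 16)
  k <- fourier(cimg)
  expect_equal(Mod(k[9, 9]), 0.7 * 16, tolerance = 1e-12)
  k[9, 9] <- 0
  expect_lt(max(Mod(k)), 1e-12)

  # unitarity and Parseval
  expect_lt(max(Mod(inverse_fourier(fourier(x)) - x)), 1e-10)
  expect_lt(max(Mod(fourier(inverse_fourier(fourier(x))) - fourier(x))), 1e-10)
  expect_lt(abs(sum(Mod(fourier(x))^2) - sum(x^2)) / sum(x^2), 1e-8)

  # DC-only grid inverts to a constant image
  k0 <- matrix(0 + 0i, 16, 16); k0[9, 9] <- 3.2
  expect_lt(max(Mod(inverse_fourier(k0) - 3.2 / 16)), 1e-12)

  expect_error(fourier(matrix(1, 4, 8)), "square")
  expect_error(fourier(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})

test_that("mask generators meet their rate contracts and sample DC", {
  for (n in c(64L, 128L, 256L)) {
    dc <- n / 2 + 1
    for (seed in 1:4) {
      mc <- make_cartesian_mask(n, 0.3, seed)
      expect_lte(abs(mc$achieved_rate - 0.3), 1 / n)
      expect_identical(mc$achieved_rate, sum(mc$flags) / n^2)
      expect_true(mc$flags[dc, dc])
      # full rows only
      expect_true(all(rowSums(mc$flags) %in% c(0L, n)))

      mv <- make_variable_density_mask(n, 0.15, seed)
      expect_lte(abs(mv$achieved_rate - 0.15), 0.005)
      expect_true(mv$flags[dc, dc])
    }
    mr <- make_radial_mask(n, 0.2)
    expect_lte(abs(mr$achieved_rate - 0.2), 0.005)
    expect_gte(mr$achieved_rate, 0.2 - 0.5 / n^2)
    expect_true(mr$flags[dc, dc])
  }

  # spot check at the largest supported scan size
  m512c <- make_cartesian_mask(512L, 0.1, 1L)
  expect_lte(abs(m512c$achieved_rate - 0.1), 1 / 512)
  m512v <- make_variable_density_mask(512L, 0.15, 1L)
  expect_lte(abs(m512v$achieved_rate - 0.15), 0.005)
  m512r <- make_radial_mask(512L, 0.1)
  expect_lte(abs(m512r$achieved_rate - 0.1), 0.005)
})

test_that("mask construction details match their definitions", {
  # cartesian: exact line count, rate-1 saturation, determinism
  mc <- make_cartesian_mask(256, 0.25, 0)
  expect_identical(sum(rowSums(mc$flags) > 0), 64L)
  expect_identical(mc$achieved_rate, 0.25)
  expect_identical(make_cartesian_mask(128, 0.3, 7)$flags,
                   make_cartesian_mask(128, 0.3, 7)$flags)
  expect_true(all(make_cartesian_mask(256, 1.0, 3)$flags))
  expect_error(make_cartesian_mask(256, 0.004, 1), "infeasible")

  # central 4% line block always present
  m <- make_cartesian_mask(256, 0.1, 5)
  expect_true(all(m$flags[124:133, ]))

  # radial: deterministic, saturates at rate 1
  expect_identical(make_radial_mask(128, 0.2)$flags,
                   make_radial_mask(128, 0.2)$flags)
  expect_true(all(make_radial_mask(64, 1.0)$flags))

  # variable density: exact count, central disc, determinism
  mv <- make_variable_density_mask(256, 0.15, 7)
  expect_identical(sum(mv$flags), 9830L)
  ii <- rep(1:256, times = 256); jj <- rep(1:256, each = 256)
  disc <- sqrt((ii - 129)^2 + (jj - 129)^2) <= 0.04 * 256
  expect_true(all(mv$flags[disc]))
  expect_identical(make_variable_density_mask(64, 0.2, 3)$flags,
                   make_variable_density_mask(64, 0.2, 3)$flags)
  expect_true(all(make_variable_density_mask(64, 1.0, 1)$flags))
})

test_that("undersample and zero_fill implement the masked acquisition", {
  x <- random_image(32, 2)
  mask_full <- make_cartesian_mask(32, 1.0, 0)
  y_full <- undersample(x, mask_full)
  expect_lt(max(Mod(y_full$values - fourier(x))), 1e-12)
  expect_lt(max(abs(zero_fill(y_full) - x)), 1e-10)

  m <- make_variable_density_mask(32, 0.4, 1)
  y <- undersample(x, m)
  expect_true(all(y$values[!m$flags] == 0))
  expect_lte(sum(Mod(y$values)^2), sum(Mod(fourier(x))^2))
  zf <- zero_fill(y)
  expect_true(is.matrix(zf) && all(dim(zf) == 32) && is.numeric(zf))

  expect_error(undersample(random_image(16), m), "disagree")
})

test_that("data correction preserves acquired samples and is idempotent", {
  x <- random_image(32, 3)
  m <- make_cartesian_mask(32, 0.4, 2)
  y <- undersample(x, m)
  recon <- random_image(32, 4)   # arbitrary network output

  cor1 <- data_correction(recon, y)
  # projection: F(result) equals y on every acquired location (complex channel)
  k1 <- attr(cor1, "kspace")
  expect_lt(sqrt(sum(Mod(k1[m$flags] - y$values[m$flags])^2)), 1e-8)
  expect_lt(max(Mod(fourier(attr(cor1, "complex")) - k1)), 1e-10)

  # idempotence
  cor2 <- data_correction(cor1, y)
  expect_lt(max(abs(cor2 - cor1)), 1e-10)
  expect_lt(max(Mod(attr(cor2, "kspace") - k1)), 1e-10)

  # full mask: ground truth comes back regardless of the reconstruction
  y_full <- undersample(x, make_cartesian_mask(32, 1.0, 0))
  expect_lt(max(abs(data_correction(recon, y_full) - x)), 1e-8)

  # zero reconstruction reduces to zero filling
  expect_lt(max(abs(data_correction(matrix(0, 32, 32), y) - zero_fill(y))),
            1e-12)

  # unacquired samples keep the reconstruction's spectrum
  kr <- fourier(recon)
  expect_lt(max(Mod(k1[!m$flags] - kr[!m$flags])), 1e-12)
})
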