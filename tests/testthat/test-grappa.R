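test_that("in-plane GRAPPA reconstructs held-out calibration lines", {
  cs <- fx("calib0"); pr <- fx("proto0")
  kern <- train_inplane_kernel(cs, lambda = 1e-6)
  ks <- cs$calib[, pr$ky_idx, , 1]
  full <- inplane_fill(ks, kern, pr$ky_idx, pr$n)
  miss <- setdiff(seq_len(pr$n), pr$ky_idx)
  expect_lt(nrmse(full[, miss, ], cs$calib[, miss, , 1]), 1e-3)
  # acquired lines are untouched
  expect_identical(full[, pr$ky_idx, ], ks)
})

test_that("ridge behaves: weights vanish as lambda grows, residual is monotone", {
  cs <- fx("calib0")
  k_inf <- train_inplane_kernel(cs, lambda = 1e8)
  expect_lt(max(Mod(k_inf$W)), 1e-5)
  res <- sapply(c(1e-6, 1e-3, 1e0), function(l)
    train_inplane_kernel(cs, lambda = l)$relres)
  expect_true(all(diff(res) >= -1e-12))
  # shift-operator residual is also non-decreasing in lambda
  res2 <- sapply(c(5e-4, 5e-3, 5e-2), function(l)
    train_shift_operator(cs, "ky", lambda = l)$relres)
  expect_true(all(diff(res2) >= -1e-12))
})

test_that("single-coil in-plane fit is a documented degraded mode", {
  cs1 <- array(fx("calib0")$calib[, , 1, , drop = FALSE],
               c(64, 64, 1, 4))
  k1 <- train_inplane_kernel(cs1)
  expect_s3_class(k1, "grappa_kernel")
  expect_gt(k1$relres, 0.05)   # single coil cannot unalias R = 2
})

test_that("split-slice kernels separate slices with low leakage", {
  cs <- fx("calib0"); pr <- fx("proto0")
  sk <- train_slice_kernels(cs, pr)
  for (g in 1:2) expect_lt(max(sk$groups[[g]]$leak), 0.05)

  # unaliased zero-field frame matches the single-band reference
  f0 <- acquire_frame(fx("phantom0")$img[, , c(1, 3)], fx("coils"),
                      c(0, 0, 0), pr, "physics", sigma = 0)
  gh <- ghost_params_from_nav(f0$nav, f0$nav_polarity)
  f0 <- nyquist_correct(f0, gh)
  ks <- sms_unalias(f0$data, sk, pr, 1)
  kern <- train_inplane_kernel(cs)
  for (s in 1:2) {
    img <- coil_combine(smsb0:::ifft2c(
      inplane_fill(ks[, , , s], kern, pr$ky_idx, pr$n)))
    expect_lt(nrmse(img, cs$sb_ref[, , c(1, 3)[s]]), 0.03)
  }
})

test_that("kernels trained with CAIPI on fail on CAIPI-off data", {
  pr <- fx("proto0")
  pr_off <- sms_protocol(sigma = 0, sigma_calib = 0, caipi = FALSE)
  cs <- fx("calib0")
  sk_on <- train_slice_kernels(cs, pr)

  # collapse the calibration slices without the CAIPI phase and measure how
  # much of slice 3 leaks through slice 1's kernel
  D1 <- cs$calib[, pr$ky_idx, , 1]
  D2_off <- cs$calib[, pr$ky_idx, , 3]
  A2_off <- smsb0:::shift_columns(D2_off, sk_on$taps$dx, sk_on$taps$dy)
  leak_off <- sqrt(sum(Mod(A2_off %*% sk_on$groups[[1]]$W[[1]])^2) /
                     sum(Mod(D1)^2))
  cp <- smsb0:::caipi_phase(pr)
  D2_on <- D2_off * rep(cp, each = pr$n)
  A2_on <- smsb0:::shift_columns(D2_on, sk_on$taps$dx, sk_on$taps$dy)
  leak_on <- sqrt(sum(Mod(A2_on %*% sk_on$groups[[1]]$W[[1]])^2) /
                    sum(Mod(D1)^2))
  expect_gt(leak_off, 2 * leak_on)
})

test_that("MB = 1 unaliasing is a passthrough", {
  pr1 <- sms_protocol(mb = 1, sigma = 0, sigma_calib = 0)
  sk <- train_slice_kernels(fx("calib0"), pr1)
  x <- array(complex(real = rnorm(64 * 32 * 8),
                     imaginary = rnorm(64 * 32 * 8)), c(64, 32, 8))
  out <- sms_unalias(x, sk, pr1, 1)
  expect_identical(out[, , , 1], x)
})

test_that("the shift operator advances calibration lines", {
  op <- fx("ops0")$shift_ky
  expect_lt(op$relres, 0.10)
  L <- fx("calib0")$calib[, , , 1]
  expect_lt(nrmse(apply_shift_operator(op, L, 1), smsb0:::roll2(L, 0L, -1L)),
            0.10)
})

test_that("fractional powers form an exact semigroup with identity at zero", {
  op <- fx("ops0")$shift_ky
  C <- op$n_coils
  I3 <- array(diag(C), c(C, C, op$n))
  expect_lt(max(abs(fractional_shift(op, 0)$mats - I3)), 1e-8)
  expect_lt(max(abs(fractional_shift(op, 1)$mats - op$M)), 1e-8)

  L <- fx("calib0")$calib[, , , 2]
  for (ab in list(c(0.25, 0.5), c(-0.25, -0.5), c(0.25, -0.5),
                  c(-0.25, 0.5))) {
    two <- apply_shift_operator(op, apply_shift_operator(op, L, ab[1]), ab[2])
    one <- apply_shift_operator(op, L, sum(ab))
    expect_lt(nrmse(two, one), 0.01)
  }
  half2 <- apply_shift_operator(op, apply_shift_operator(op, L, 0.5), 0.5)
  expect_lt(nrmse(half2, apply_shift_operator(op, L, 1)), 0.01)
  # inverse composition
  back <- apply_shift_operator(op, apply_shift_operator(op, L, 0.5), -0.5)
  expect_lt(nrmse(back, L), 0.01)
})

test_that("fractional powers respect the validity range and degeneracy check", {
  op <- fx("ops0")$shift_ky
  expect_error(fractional_shift(op, 1.6), "validity")
  op_bad <- op
  op_bad$lam[1, 30] <- 0 + 0i
  expect_error(fractional_shift(op_bad, 0.5), "lambda")
})

test_that("the operator approximates off-grid sampling for single-coil data", {
  # y-compact object: one thin bar, for which the coil-free one-step ratio is
  # nearly ky-independent and the operator model is near-exact
  n <- 64
  x <- fov_grid <- ((seq_len(n) - 1) - n / 2) / n
  X <- matrix(x, n, n); Y <- t(X)
  bar <- exp(-(X^2 / (2 * 0.15^2))) * exp(-((Y - 0.1)^2 / (2 * 0.02^2))) *
    exp(1i * 0.3 * Y)
  K1 <- smsb0:::fft2c(array(bar, c(n, n, 1)))
  op1 <- train_shift_operator(array(K1, c(n, n, 1, 1)), "ky", lambda = 1e-6)
  for (d in c(0.25, 0.5, -0.5)) {
    shifted <- apply_shift_operator(op1, array(K1, c(n, n, 1)), d)
    # independent oracle: exact off-grid sample of the continuous transform
    # via the image-domain modulation
    oracle <- smsb0:::fft2c(array(
      bar * matrix(exp(-2i * pi * d * x), n, n, byrow = TRUE), c(n, n, 1)))
    expect_lt(nrmse(shifted, oracle), 0.05)
  }
})

test_that("kx-axis operators are supported through transposition", {
  cs <- fx("calib0")
  opx <- train_shift_operator(cs, "kx", lambda = 5e-4)
  expect_lt(opx$relres, 0.12)
})
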