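test_that("ghost parameters are recovered from the navigators", {
  f <- inject_frame(0, 0, 0)
  gh <- ghost_params_from_nav(f$nav, f$nav_polarity)
  expect_equal(gh$theta0, 0.1, tolerance = 1e-3)
  expect_equal(gh$theta1, 0.05, tolerance = 1e-3)

  # zero injected ghost -> zero estimate
  pr0 <- sms_protocol(sigma = 0, sigma_calib = 0, ghost_theta0 = 0,
                      ghost_theta1 = 0)
  f0 <- acquire_frame(fx("phantom0")$img[, , c(1, 3)], fx("coils"),
                      c(0, 0, 0), pr0, "physics", sigma = 0)
  gh0 <- ghost_params_from_nav(f0$nav, f0$nav_polarity)
  expect_equal(abs(gh0$theta0), 0, tolerance = 1e-9)
  expect_equal(abs(gh0$theta1), 0, tolerance = 1e-9)

  # swapped polarity labels flip the sign
  ghs <- ghost_params_from_nav(f$nav, -f$nav_polarity)
  expect_equal(ghs$theta0, -gh$theta0, tolerance = 1e-9)
  expect_equal(ghs$theta1, -gh$theta1, tolerance = 1e-9)

  expect_error(ghost_params_from_nav(array(0i, c(64, 3, 8))), "zero")
  expect_error(ghost_params_from_nav(f$nav, c(1, 1, 1)), "polarity")
})

test_that("nyquist correction is an involution and suppresses the ghost", {
  f <- inject_frame(0, 0, 0)
  gh <- list(theta0 = 0.1, theta1 = 0.05)
  fc <- nyquist_correct(f, gh)
  fb <- nyquist_correct(fc, list(theta0 = -0.1, theta1 = -0.05))
  expect_lt(nrmse(fb$data, f$data), 1e-12)

  id <- nyquist_correct(f, list(theta0 = 0, theta1 = 0))
  expect_lt(nrmse(id$data, f$data), 1e-12)

  # ghost-band energy drops by >= 10x after correction with the truth.
  # Measured on a fully sampled single-band acquisition, where the even/odd
  # alternation puts the replica exactly at FOV/2 along phase-encode.
  pr1 <- sms_protocol(mb = 1, r_inplane = 1, sigma = 0, sigma_calib = 0)
  f1 <- acquire_frame(fx("phantom0")$img[, , 1, drop = FALSE], fx("coils"),
                      c(0, 0, 0), pr1, "physics", sigma = 0)
  f1c <- nyquist_correct(f1, gh)
  recon1 <- function(fr) coil_combine(smsb0:::ifft2c(fr$data))
  sup <- fx("phantom0")$support[, , 1]
  g_un <- ghost_energy(recon1(f1), sup)
  g_co <- ghost_energy(recon1(f1c), sup)
  expect_gt(g_un / g_co, 10)
})

test_that("phi0 and dkx are recovered from navigator projections", {
  ref <- fx("navref0")
  # identity
  est0 <- estimate_phi0_dkx(ref, ref)
  expect_equal(unname(est0), c(0, 0), tolerance = 1e-12)
  # constructed global phase
  estp <- estimate_phi0_dkx(ref * exp(1i * pi / 4), ref)
  expect_equal(estp[["phi0"]], pi / 4, tolerance = 1e-9)
  expect_equal(estp[["dkx"]], 0, tolerance = 1e-9)
  # injected translate-mode perturbation
  f <- inject_frame(0.3, 0.25, 0)
  est <- estimate_phi0_dkx(nav_proj(f), ref)
  expect_equal(est[["phi0"]], 0.3, tolerance = 0.01)
  expect_equal(est[["dkx"]], 0.25, tolerance = 0.01)

  expect_error(estimate_phi0_dkx(ref, ref * 0), "support")
})

test_that("the operator search recovers dky with the right sign and gate", {
  op <- fx("ops0")$shift_ky
  ref <- fx("navref0")
  f4 <- inject_frame(0, 0, 0.4)
  d4 <- estimate_dky(nav_proj(f4), ref, op)
  expect_lt(abs(as.numeric(d4) - 0.4), 0.02)

  fm <- inject_frame(0, 0, -0.3)
  dm <- estimate_dky(nav_proj(fm), ref, op)
  expect_lt(dm, 0)
  expect_lt(abs(as.numeric(dm) + 0.3), 0.02)

  # identical navigators give an exact zero (significance gate)
  d0 <- estimate_dky(ref, ref, op)
  expect_identical(as.numeric(d0), 0)
})

test_that("full-frame correction restores translate-mode corruption", {
  op <- fx("ops0")$shift_ky
  f0 <- inject_frame(0, 0, 0)
  tru <- list(phi0 = 0.3, dkx = 0.25, dky = 0.4)
  ft <- inject_frame(tru$phi0, tru$dkx, tru$dky)

  # identity correction is bit-identical
  fi <- correct_frame(ft, list(phi0 = 0, dkx = 0, dky = 0), op)
  expect_identical(fi$data, ft$data)

  fc <- correct_frame(ft, tru, op)
  expect_lt(nrmse(fc$data, f0$data), 0.02)

  # correcting with the negated estimate recovers the input
  fb <- correct_frame(fc, list(phi0 = -tru$phi0, dkx = -tru$dkx,
                               dky = -tru$dky), op)
  expect_lt(nrmse(fb$data, ft$data), 0.01)

  expect_error(correct_frame(ft, list(phi0 = NA, dkx = 0, dky = 0), op),
               "finite")
  expect_error(correct_frame(ft, list(phi0 = 0, dkx = 0, dky = 0.4)),
               "operator")
})

test_that("session estimation is quiet at rest and local for spikes", {
  ph0 <- fx("phantom0"); pr <- fx("proto0")
  tl0 <- make_field_timeline(4, c(0, 0, 0), "smooth", seed = 1)
  ev <- make_task_events(2, 1, seed = 1)
  ses0 <- acquire_session(ph0, fx("coils"), tl0, ev, pr, "physics", seed = 3)
  ops <- train_recon_operators(ses0$calibration, pr)
  est0 <- estimate_session(ses0, ops)
  expect_true(all(abs(est0$phi0) < 1e-9))
  expect_true(all(est0$dky == 0))

  tl <- tl0
  tl$c0 <- c(0, 0, 10, 0); tl$cx <- c(0, 0, 12, 0); tl$cy <- c(0, 0, -10, 0)
  ses <- acquire_session(ph0, fx("coils"), tl, ev, pr, "physics", seed = 3)
  est <- estimate_session(ses, ops)
  spike <- est$frame == 3
  expect_true(all(abs(est$dky[spike]) > 0.05))
  expect_true(all(abs(est$dky[!spike]) < 0.05))

  p <- write_estimates(est, tempfile(fileext = ".csv"))
  tab <- utils::read.csv(p)
  expect_true(all(c("frame", "group", "phi0", "dkx", "dky", "objective")
                  %in% names(tab)))
})

test_that("physics-mode estimates track the net translation with unit slope", {
  op <- fx("ops0")$shift_ky
  ref_f <- inject_frame(0, 0, 0, mode = "physics")
  ref <- nav_proj(ref_f)
  dk_in <- seq(-0.3, 0.3, by = 0.1)
  dk_out <- sapply(dk_in, function(d) {
    f <- inject_frame(0, 0, d, mode = "physics")
    estimate_frame_perturbation(nav_proj(f), ref, op)$dky
  })
  slope <- stats::coef(stats::lm(dk_out ~ dk_in))[2]
  expect_gt(slope, 0.85)
  expect_lt(slope, 1.15)
})
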