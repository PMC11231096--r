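test_that("phantom generation is deterministic and honours its contracts", {
  p1 <- make_phantom(64, 4, seed = 1)
  p2 <- make_phantom(64, 4, seed = 1)
  expect_identical(p1$img, p2$img)
  expect_identical(p1$masks, p2$masks)

  p3 <- make_phantom(64, 4, seed = 2)
  expect_false(isTRUE(all.equal(p1$img, p3$img)))
  expect_identical(names(p1$masks), names(p3$masks))

  expect_gte(length(p1$masks), 4L)
  for (m in p1$masks) expect_true(all(p1$support[m]))
  expect_true(all(p1$activation[!p1$support] == 0))
  expect_equal(max(p1$activation), 0.02)
  # two disjoint activation regions driven by different regressors
  expect_gt(sum(p1$act_label == 1L), 0)
  expect_gt(sum(p1$act_label == 2L), 0)
  expect_equal(sum(p1$act_label == 1L & p1$act_label == 2L), 0)

  expect_error(make_phantom(63, 4), "even")
  expect_error(make_phantom(16, 4), "even|32")
})

test_that("coil maps are normalised, smooth and need at least two coils", {
  cm <- make_coil_maps(8, 64, seed = 1)
  rss <- coil_rss(cm)
  x <- ((seq_len(64) - 1) - 32) / 64
  disc <- outer(x^2, x^2, `+`) <= 0.35^2
  expect_gte(min(rss[disc]), 0.5)
  expect_lte(max(rss[disc]), 2.0)

  cm2 <- make_coil_maps(2, 64, seed = 1)
  expect_equal(dim(cm2$maps)[3], 2L)
  expect_error(make_coil_maps(1, 64, seed = 1), "coil")
})

test_that("field timelines respect amplitudes, models and the zero reference", {
  te <- 0.0254
  z <- make_field_timeline(10, c(0, 0, 0), "smooth", seed = 1)
  expect_true(all(z$c0 == 0 & z$cx == 0 & z$cy == 0))

  sm <- make_field_timeline(100, c(10, 15, 15), "smooth", seed = 1)
  expect_equal(as.numeric(sm[1, c("c0", "cx", "cy")]), c(0, 0, 0))
  expect_lte(max(abs(sm$cy)) * te, 15 * te + 1e-12)
  expect_lte(max(abs(sm$cy)) * te, 0.382)   # 15 Hz/FOV at TE = 25.4 ms
  expect_lte(max(abs(sm$c0)), 10)

  sp <- make_field_timeline(100, c(10, 15, 15), "spikes", seed = 1)
  zero_frames <- sp$c0 == 0 & sp$cx == 0 & sp$cy == 0
  expect_gte(mean(zero_frames), 0.8)

  st <- make_field_timeline(50, c(10, 15, 15), "step", seed = 1)
  expect_lte(max(abs(st$cx)), 15)
  expect_equal(as.numeric(st[1, c("c0", "cx", "cy")]), c(0, 0, 0))

  expect_error(make_field_timeline(100, c(-1, 0, 0), "smooth"), "negative")
  expect_error(make_field_timeline(1, c(1, 1, 1), "smooth"), "frames")
})

test_that("field state <-> k-space shift mapping round-trips exactly", {
  te <- 0.0254
  for (st in list(c(0, 0, 0), c(10, -15, 7.3), c(-3.2, 0.5, -14))) {
    sh <- field_to_shift(st, te)
    expect_equal(unname(shift_to_field(sh, te)), st, tolerance = 1e-12)
  }
  expect_equal(unname(field_to_shift(c(10, 15, 15), te)),
               c(2 * pi * 10 * te, 15 * te, 15 * te))
})

test_that("task event lists honour the trial timing ranges for any seed", {
  ev1 <- make_task_events(20, 1.0, seed = 1)
  expect_equal(nrow(ev1), 20L)
  expect_true(all(ev1$responded))
  expect_equal(sum(is.na(ev1$outcome_onset)), 0L)

  ev0 <- make_task_events(20, 0.0, seed = 1)
  expect_false(any(ev0$responded))
  expect_true(all(is.na(ev0$response_onset)))

  for (seed in 1:120) {
    ev <- make_task_events(8, 0.8, seed = seed)
    gap_go <- ev$gocue_onset - ev$offer_onset
    expect_true(all(gap_go >= 3 & gap_go <= 4))
    resp <- ev$responded
    if (any(resp)) {
      d_out <- ev$outcome_onset[resp] - ev$response_onset[resp]
      expect_true(all(d_out >= 3.5 & d_out <= 4.5))
    }
    ev_all <- stats::na.omit(as.numeric(t(
      ev[, c("offer_onset", "gocue_onset", "response_onset",
             "outcome_onset")])))
    expect_true(all(diff(ev_all) > 0))
    # intertrial gap: next offer at least 3.5 s after the trial's last event
    last_evt <- ifelse(resp, ev$outcome_onset, ev$gocue_onset + 1)
    iti <- ev$offer_onset[-1] - last_evt[-nrow(ev)]
    expect_true(all(iti >= 3.5 - 1e-9 & iti <= 4.5 + 1e-9))
  }
})

test_that("BOLD modulation peaks where the convolution oracle says", {
  ph <- make_phantom(64, 2, seed = 1)
  tr <- 1.282
  hrf <- hrf_params(peak = 3)
  ev <- tibble::tibble(trial = 1L, offer_onset = 10, gocue_onset = 13.5,
                       responded = FALSE, response_onset = NA_real_,
                       outcome_onset = NA_real_)
  class(ev) <- c("event_list", class(ev))
  n_frames <- 30

  # before the first offer the object is the static phantom
  o1 <- object_at_frame(ph, ev, hrf, t = 3, tr = tr, n_frames = n_frames)
  expect_equal(o1, ph$img, tolerance = 1e-12)

  # a zero activation map is frame-independent
  ph0 <- make_phantom(64, 2, seed = 1, activation_amp = 0)
  for (t in c(1, 12, 25)) {
    expect_identical(object_at_frame(ph0, ev, hrf, t, tr, n_frames), ph0$img)
  }

  # independent oracle: direct numerical convolution of the boxcar with the
  # HRF kernel on a fine grid
  dt <- 0.02
  grid <- seq(0, n_frames * tr, by = dt)
  stim <- as.numeric(grid >= 10 & grid < 10.1)
  ker <- hrf_kernel(seq(0, hrf$duration, by = dt), hrf)
  conv <- stats::convolve(stim, rev(ker), type = "open")[seq_along(grid)]
  t_peak <- grid[which.max(conv)]
  frame_peak_oracle <- which.min(abs((seq_len(n_frames) - 1) * tr - t_peak))

  mods <- sapply(seq_len(n_frames), function(t) {
    ob <- object_at_frame(ph, ev, hrf, t, tr, n_frames)
    max(Mod(ob) / pmax(Mod(ph$img), 1e-9))
  })
  expect_equal(which.max(mods), frame_peak_oracle, tolerance = 1)
  # modulation factor bounded by the activation amplitude
  expect_lte(max(mods), 1 + ph$activation_amp + 1e-9)

  expect_error(object_at_frame(ph, ev, hrf, 31, tr, 30), "range")
})

test_that("event files use the 3-column onset/duration/amplitude format", {
  ev <- make_task_events(5, 0.8, seed = 3)
  dir <- tempfile()
  paths <- write_event_files(ev, dir)
  expect_setequal(basename(paths),
                  c("offer.txt", "action_onset.txt", "motor_response.txt",
                    "outcome.txt"))
  tab <- utils::read.table(file.path(dir, "offer.txt"))
  expect_equal(ncol(tab), 3L)
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab[[2]] == 0.1) && all(tab[[3]] == 1))
  expect_equal(tab[[1]], ev$offer_onset)
})
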