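test_that("the design matrix follows the task structure", {
  tr <- 1.282
  # no events: task columns all zero
  ev0 <- tibble::tibble(trial = integer(0), offer_onset = numeric(0),
                        gocue_onset = numeric(0), responded = logical(0),
                        response_onset = numeric(0),
                        outcome_onset = numeric(0))
  X0 <- build_design(ev0, 50, tr)
  expect_equal(colnames(X0), c("intercept", "offer", "action_onset",
                               "motor_response", "outcome"))
  expect_true(all(X0[, -1] == 0))
  expect_true(all(X0[, 1] == 1))

  # single offer at t = 0: the offer column peaks at the frame nearest the
  # HRF peak, computed with an independent numeric convolution
  ev1 <- tibble::tibble(trial = 1L, offer_onset = 0, gocue_onset = 3.5,
                        responded = FALSE, response_onset = NA_real_,
                        outcome_onset = NA_real_)
  hrf <- hrf_params(peak = 3)
  X1 <- build_design(ev1, 30, tr, hrf)
  dt <- 0.01
  grid <- seq(0, 40, by = dt)
  stim <- as.numeric(grid >= 0 & grid < 0.1)
  ker <- hrf_kernel(seq(0, hrf$duration, by = dt), hrf)
  conv <- stats::convolve(stim, rev(ker), type = "open")[seq_along(grid)]
  oracle_frame <- which.min(abs((seq_len(30) - 1) * tr -
                                  grid[which.max(conv)]))
  expect_equal(which.max(X1[, "offer"]), oracle_frame)

  # motor_response differs from action_onset iff no-response trials exist
  ev_all <- make_task_events(6, 1.0, seed = 2)
  Xa <- build_design(ev_all, 80, tr)
  expect_equal(Xa[, "action_onset"], Xa[, "motor_response"])
  ev_mix <- make_task_events(6, 0.5, seed = 2)
  Xm <- build_design(ev_mix, 80, tr)
  expect_gt(max(abs(Xm[, "action_onset"] - Xm[, "motor_response"])), 0.1)

  expect_warning(build_design(ev_all, 10, tr), "truncated")
})

test_that("temporal filtering passes task frequencies and removes drift", {
  tr <- 1.282
  n_frames <- 200
  mk <- function(signal) {
    arr <- array(10, c(8, 8, 1, n_frames))
    arr[4, 4, 1, ] <- 10 + signal
    structure(list(data = arr, tr = tr, voxel_mm = 1.875, arm = "x",
                   provenance = list()), class = "recon_series")
  }
  t_s <- (seq_len(n_frames) - 1) * tr
  att_db <- function(period) {
    s <- sin(2 * pi * t_s / period)
    out <- preprocess_series(mk(s), highpass_s = 100, fwhm_mm = 0)
    resid <- out$data[4, 4, 1, ] - mean(out$data[4, 4, 1, ])
    -20 * log10(stats::sd(resid) / stats::sd(s))
  }
  expect_lt(att_db(20), 1)     # task band untouched
  expect_gt(att_db(400), 6)    # slow drift removed

  # constant series unchanged up to the mean-recentering convention
  out_c <- preprocess_series(mk(rep(0, n_frames)), 100, fwhm_mm = 0)
  expect_equal(out_c$data, mk(rep(0, n_frames))$data, tolerance = 1e-10)

  expect_error(preprocess_series(mk(rep(0, n_frames)), highpass_s = 2 * tr),
               "cutoff")
})

test_that("spatial smoothing realises the requested FWHM", {
  n <- 64
  arr <- array(0, c(n, n, 1, 1))
  arr[n / 2, n / 2, 1, 1] <- 1
  series <- structure(list(data = arr, tr = 1.282, voxel_mm = 1.875,
                           arm = "x", provenance = list()),
                      class = "recon_series")
  out <- preprocess_series(series, highpass_s = 1e9, fwhm_mm = 3)
  prof <- out$data[, n / 2, 1, 1]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation of the half-maximum crossings
  lo <- min(above); hi <- max(above)
  f_lo <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  f_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_vox <- f_hi - f_lo
  expect_equal(fwhm_vox * 1.875, 3, tolerance = 0.05)
})

test_that("GLM recovers known effects and whitens AR(1) noise", {
  set.seed(6)
  ev <- make_task_events(20, 0.8, seed = 3)
  tr <- 1.282
  n_frames <- 400
  X <- build_design(ev, n_frames, tr)
  beta_true <- c(100, 2, 1.5, 1, 0.8)
  V <- 600
  # AR(1) noise with phi = 0.4
  phi <- 0.4
  E <- matrix(rnorm(n_frames * V, sd = 0.25), n_frames, V)
  for (t in 2:n_frames) E[t, ] <- phi * E[t - 1, ] + E[t, ]
  Y <- matrix(X %*% beta_true, n_frames, V) + E
  fit <- fit_glm(Y, X)

  # beta recovery bias < 2% at high SNR
  for (j in 2:5) {
    expect_lt(abs(mean(fit$beta[, j]) - beta_true[j]) / beta_true[j], 0.02)
  }
  expect_equal(mean(fit$rho), phi, tolerance = 0.12)

  # whitened residual lag-1 autocorrelation < 0.1
  X1 <- X[-n_frames, ]; X2 <- X[-1, ]
  Y1 <- Y[-n_frames, ]; Y2 <- Y[-1, ]
  lag1 <- sapply(seq_len(V), function(v) {
    r <- (Y2[, v] - fit$rho[v] * Y1[, v]) -
      (X2 - fit$rho[v] * X1) %*% fit$beta[v, ]
    sum(r[-1] * r[-length(r)]) / sum(r^2)
  })
  expect_lt(abs(mean(lag1)), 0.1)

  # rank-deficient design is rejected
  Xbad <- cbind(X, offer2 = X[, "offer"])
  expect_error(fit_glm(Y, Xbad), "rank-deficient")
})

test_that("null voxels keep the nominal z > 3.1 false-positive rate", {
  set.seed(7)
  ev <- make_task_events(8, 0.8, seed = 4)
  n_frames <- 150
  X <- build_design(ev, n_frames, 1.282)
  V <- 12000
  Y <- matrix(rnorm(n_frames * V), n_frames, V) + 50
  fit <- fit_glm(Y, X)
  z <- as.vector(fit$z[, c("offer", "motor_response")])
  fpr <- mean(z > 3.1)
  nominal <- stats::pnorm(3.1, lower.tail = FALSE)
  expect_gt(fpr, 0.5 * nominal)
  expect_lt(fpr, 2 * nominal)
})

test_that("cluster thresholding finds exactly the constructed blobs", {
  z0 <- array(0, c(16, 16, 4))
  expect_equal(nrow(cluster_threshold(z0)), 0L)

  z1 <- z0
  z1[4:8, 4:9, 2] <- 4          # 5 x 6 x 1 = 30 voxels
  z1[12:15, 12:15, 3] <- 3.5    # 16 voxels
  z1[1, 1, 1] <- 5              # singleton, dropped by min_extent
  cls <- cluster_threshold(z1, z_thr = 3.1, min_extent = 10)
  expect_equal(nrow(cls), 2L)
  expect_equal(sort(cls$size), c(16L, 30L))
  expect_equal(max(cls$peak_z), 4)   # the dropped singleton held the max z

  # threshold above the map maximum yields nothing
  z2 <- z0; z2[5, 5, 1] <- 3.0
  expect_equal(nrow(cluster_threshold(z2, z_thr = 3.1)), 0L)

  # extent calibration returns a positive integer
  k <- cluster_extent_null(c(16, 16, 2), z_thr = 2.5, n_sim = 30, seed = 1)
  expect_gte(k, 1L)
})

test_that("second level scales like sqrt(S) and caps degenerate voxels", {
  set.seed(8)
  d <- c(6, 6, 1)
  mu <- array(0.5, d)
  mk_maps <- function(S) lapply(seq_len(S), function(i)
    mu + array(rnorm(prod(d), sd = 1), d))
  zf <- sapply(c(4, 8, 16), function(S) {
    z <- replicate(40, stats::median(second_level(mk_maps(S))))
    mean(z)
  })
  # group z grows roughly like sqrt(S)
  expect_equal(zf[2] / zf[1], sqrt(2), tolerance = 0.25)
  expect_equal(zf[3] / zf[2], sqrt(2), tolerance = 0.25)

  # sign flip symmetry
  maps <- mk_maps(6)
  z1 <- second_level(maps)
  z2 <- second_level(lapply(maps, function(m) -m))
  expect_equal(as.vector(z2), -as.vector(z1), tolerance = 1e-10)

  # identical sessions: capped and flagged
  same <- lapply(1:5, function(i) mu)
  zc <- second_level(same, z_cap = 40)
  expect_true(all(zc == 40))
  expect_true(all(attr(zc, "capped")))

  expect_error(second_level(mk_maps(2)), "3 sessions")
})

test_that("split-half reliability separates signal from noise", {
  set.seed(9)
  d <- c(8, 8, 2)
  masks <- list(roi1 = array(c(rep(TRUE, 32), rep(FALSE, 96)), d),
                roi2 = array(c(rep(FALSE, 96), rep(TRUE, 32)), d))
  # identical halves: r = 1, bias = 0
  base <- array(rnorm(prod(d)), d)
  same_maps <- lapply(1:8, function(i) base)
  rel1 <- split_half_reliability(same_maps, masks, n_folds = 10, seed = 1)
  expect_true(all(abs(rel1$r - 1) < 1e-9))
  expect_true(all(rel1$bias < 1e-9))

  # independent pure noise: mean r near zero
  noise_maps <- lapply(1:12, function(i) array(rnorm(prod(d)), d))
  rel0 <- split_half_reliability(noise_maps, masks, n_folds = 10, seed = 2)
  expect_lt(abs(mean(rel0$r)), 0.2)

  expect_error(split_half_reliability(noise_maps[1:3], masks), "4 sessions")

  g <- glance(rel0)
  expect_equal(g$n_folds, 10L)
  cmp <- reliability_compare(rel1, rel0)
  expect_true(all(cmp$delta_r > 0.5))
})
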