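# SMS-EPI acquisition engine.
#
# Physics mode applies the per-line phase accrual of a spatially linear
# off-resonance field Df(x, y) = c0 + cx*x + cy*y (Hz, x/y in FOV units):
# line m acquired at time t_m sees the object modulated by
# exp(i*2*pi*Df(r)*t_m). Translate mode replaces the field effect by the
# idealised model the estimator assumes: a global phase phi0 = 2*pi*c0*TE and
# an exact k-space translation (dkx, dky) = (cx, cy)*TE of the whole frame
# (navigators included).

# Simulate the EPI readout of one slice-group constituent slice.
# obj: (n, n) complex; coils: (n, n, C); returns list(data (n, n_lines, C),
# nav (n, 3, C)) *before* CAIPI phase, collapse and noise.
acquire_slice_lines <- function(obj, coils, field, protocol, mode) {
  n <- protocol$n; C <- dim(coils)[3]
  x <- fov_grid(n); y <- fov_grid(n)
  c0 <- field[1]; cx <- field[2]; cy <- field[3]

  if (mode == "translate") {
    sh <- field_to_shift(field, protocol$te)
    ramp <- exp(1i * sh[1]) *
      outer(exp(2i * pi * sh[2] * x), exp(2i * pi * sh[3] * y))
    obj <- obj * ramp
    c0 <- cx <- cy <- 0
  }

  A <- array(0i, c(n, C, n))                      # (x, coil, y)
  for (c_ in seq_len(C)) A[, c_, ] <- obj * coils[, , c_]
  B <- matrix(A, n * C, n)                        # rows x*coil, cols y

  one_set <- function(kys, times, pol) {
    L <- length(kys)
    # y-direction weights: encoding plus field phase at each line's time
    W <- exp(-2i * pi * outer(y, kys)) *
      exp(2i * pi * cy * outer(y, times))
    G <- B %*% W                                  # (n*C, L)
    G <- aperm(array(G, c(n, C, L)), c(1, 3, 2))  # (x, line, coil)
    # x-space phases: constant + readout-linear field terms and ghost phase
    sc <- k_grid(n)                               # centred sample index
    P <- exp(2i * pi * (rep(c0 * times, each = n) +
                          cx * outer(x, times))) *
      exp(0.5i * outer(protocol$ghost_theta0 + protocol$ghost_theta1 * sc,
                       pol))
    G <- G * as.vector(P)                         # recycles over coils
    fft1c(G) / sqrt(n)                            # k-space lines
  }

  list(
    data = one_set(protocol$ky, protocol$line_times, protocol$polarity),
    nav = one_set(rep(0, 3), protocol$nav_times, protocol$nav_polarity)
  )
}

# CAIPI phase of the second slice of a group: exp(i*pi*m) per acquired line m.
caipi_phase <- function(protocol) {
  if (!protocol$caipi || protocol$mb < 2) return(rep(1 + 0i, protocol$n_lines))
  exp(1i * pi * (seq_len(protocol$n_lines) - 1L))
}

#' Acquire one SMS-EPI frame
#'
#' Simulates the collapsed, in-plane-undersampled multi-coil k-space of one
#' slice group at one time-point, together with its three non-phase-encoded
#' navigator lines.
#'
#' @param object complex array (n, n, mb): the slices of the group.
#' @param coils a `coil_maps` object (or a bare complex array).
#' @param field numeric `(c0, cx, cy)` in Hz (per FOV).
#' @param protocol an [sms_protocol()].
#' @param mode "physics" (per-line phase accrual) or "translate" (exact
#'   k-space translation, the estimator's idealised model).
#' @param sigma complex noise SD (defaults to `protocol$sigma`).
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @param frame,group metadata stored on the frame.
#' @return class `kspace_frame`.
#' @export
acquire_frame <- function(object, coils, field = c(0, 0, 0), protocol,
                          mode = c("physics", "translate"),
                          sigma = protocol$sigma, seed = NULL,
                          frame = 1L, group = 1L) {
  mode <- match.arg(mode)
  if (inherits(coils, "coil_maps")) coils <- coils$maps
  if (length(dim(object)) == 2L) object <- array(object, c(dim(object), 1L))
  if (dim(object)[3] != protocol$mb)
    stop("object must supply exactly mb slices")
  if (!is.null(seed)) set.seed(seed)

  n <- protocol$n; C <- dim(coils)[3]
  data <- array(0i, c(n, protocol$n_lines, C))
  nav <- array(0i, c(n, 3L, C))
  cp <- caipi_phase(protocol)
  for (s in seq_len(protocol$mb)) {
    part <- acquire_slice_lines(object[, , s], coils, field, protocol, mode)
    if (s == 2L) part$data <- part$data * rep(cp, each = n)
    data <- data + part$data
    nav <- nav + part$nav      # navigators carry no CAIPI phase (ky = 0)
  }
  if (sigma > 0) {
    data <- data + cnoise(length(data), sigma)
    nav <- nav + cnoise(length(nav), sigma)
  }
  structure(list(
    data = data, nav = nav,
    ky = protocol$ky, ky_idx = protocol$ky_idx,
    line_times = protocol$line_times, nav_times = protocol$nav_times,
    polarity = protocol$polarity, nav_polarity = protocol$nav_polarity,
    frame = frame, group = group, mode = mode,
    n = n, mb = protocol$mb, r_inplane = protocol$r_inplane,
    caipi = protocol$caipi, te = protocol$te
  ), class = "kspace_frame")
}

#' Acquire calibration and reference data
#'
#' Produces the fully sampled, zero-field multi-coil calibration k-space per
#' slice, reference navigators per slice group, and a single-band EPI
#' reference image per slice (R-undersampled, ghost-corrected, GRAPPA-filled
#' and RSS-combined) - the fidelity reference that frame reconstructions are
#' compared against.
#'
#' @param phantom an `sms_phantom`.
#' @param coils a `coil_maps`.
#' @param protocol an [sms_protocol()].
#' @param sigma noise SD of the calibration acquisitions
#'   (defaults to `protocol$sigma_calib`).
#' @param seed optional seed.
#' @return class `calibration_set`: `calib` (n, n, C, n_slices) k-space,
#'   `nav_ref` list per group, `sb_frames` single-band frames, `sb_ref`
#'   (n, n, n_slices) magnitude images, `sb_coil` per-coil images.
#' @export
acquire_calibration <- function(phantom, coils, protocol,
                                sigma = protocol$sigma_calib, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maps <- if (inherits(coils, "coil_maps")) coils$maps else coils
  n <- protocol$n; C <- dim(maps)[3]; S <- phantom$n_slices

  calib <- array(0i, c(n, n, C, S))
  for (s in seq_len(S)) {
    A <- array(0i, c(n, n, C))
    for (c_ in seq_len(C)) A[, , c_] <- phantom$img[, , s] * maps[, , c_]
    calib[, , , s] <- fft2c(A)
  }
  if (sigma > 0) calib <- calib + cnoise(length(calib), sigma)

  # reference navigators per slice group (zero field)
  nav_ref <- lapply(seq_len(n_groups(protocol)), function(g) {
    obj <- phantom$img[, , slice_group(protocol, g), drop = FALSE]
    acquire_frame(obj, maps, c(0, 0, 0), protocol, mode = "physics",
                  sigma = sigma, frame = 0L, group = g)$nav
  })

  # single-band EPI reference: one frame per slice with MB = 1
  proto1 <- protocol
  proto1$mb <- 1L
  sb_frames <- lapply(seq_len(S), function(s) {
    acquire_frame(phantom$img[, , s, drop = FALSE], maps, c(0, 0, 0), proto1,
                  mode = "physics", sigma = sigma, frame = 0L, group = s)
  })

  cs <- structure(list(
    calib = calib, nav_ref = nav_ref, sb_frames = sb_frames,
    sb_ref = NULL, sb_coil = NULL, protocol = protocol
  ), class = "calibration_set")

  # reconstruct the single-band reference with the in-plane kernel
  kern <- train_inplane_kernel(cs, lambda = 1e-4)
  sb_ref <- array(0, c(n, n, S))
  sb_coil <- array(0i, c(n, n, C, S))
  for (s in seq_len(S)) {
    fr <- sb_frames[[s]]
    gp <- ghost_params_from_nav(fr$nav, fr$nav_polarity)
    fr <- nyquist_correct(fr, gp)
    full <- inplane_fill(fr$data, kern, fr$ky_idx, n)
    imgs <- ifft2c(full)
    sb_coil[, , , s] <- imgs
    sb_ref[, , s] <- coil_combine(imgs)
  }
  cs$sb_ref <- sb_ref
  cs$sb_coil <- sb_coil
  cs
}

#' Acquire a full functional session
#'
#' Frame t of slice-group g images the BOLD-modulated object under the
#' field state of frame t; navigators are simulated with the same field state
#' (they sense the perturbation).
#'
#' @param phantom an `sms_phantom`.
#' @param coils a `coil_maps`.
#' @param timeline a `field_timeline` (frame 1 must be the zero reference).
#' @param events an `event_list` (task events driving the BOLD signal).
#' @param protocol an [sms_protocol()].
#' @param mode "physics" or "translate" (see [acquire_frame()]).
#' @param hrf HRF parameters.
#' @param seed session seed (all noise draws derive from it).
#' @return class `sms_session`.
#' @export
acquire_session <- function(phantom, coils, timeline, events, protocol,
                            mode = c("physics", "translate"),
                            hrf = hrf_params(), seed = 1) {
  mode <- match.arg(mode)
  n_frames <- nrow(timeline)
  if (!all(abs(as.numeric(timeline[1, c("c0", "cx", "cy")])) < 1e-12))
    stop("timeline frame 1 must be the zero reference state")
  set.seed(seed)
  maps <- if (inherits(coils, "coil_maps")) coils$maps else coils

  x_off <- regressor_timecourse(events$offer_onset, n_frames, protocol$tr, hrf)
  x_mot <- regressor_timecourse(events$gocue_onset[events$responded],
                                n_frames, protocol$tr, hrf)

  calibration <- acquire_calibration(phantom, coils, protocol)

  ngr <- n_groups(protocol)
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    obj_t <- modulate_object(phantom, x_off[t], x_mot[t])
    st <- as.numeric(timeline[t, c("c0", "cx", "cy")])
    frames[[t]] <- lapply(seq_len(ngr), function(g) {
      acquire_frame(obj_t[, , slice_group(protocol, g), drop = FALSE],
                    maps, st, protocol, mode = mode,
                    frame = t, group = g)
    })
  }

  structure(list(
    frames = frames, calibration = calibration, protocol = protocol,
    truth = list(timeline = timeline, phantom = phantom, events = events,
                 mode = mode, seed = seed, hrf = hrf,
                 x_offer = x_off, x_motor = x_mot),
    n_frames = n_frames
  ), class = "sms_session")
}

#' @export
print.sms_session <- function(x, ...) {
  cat(sprintf("SMS-EPI session: %d frames x %d slice groups (%s mode)\n",
              x$n_frames, n_groups(x$protocol), x$truth$mode))
  invisible(x)
}

#' Persist / restore a session
#'
#' Sessions are stored as a versioned R-native serialized container holding
#' the frames, calibration set, protocol and simulation ground truth.
#'
#' @param session an `sms_session`.
#' @param path output file path.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "sms_session"))
  saveRDS(list(format = "smsb0-session", version = 1L, session = session),
          path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "smsb0-session"))
    stop("not an smsb0 session container: ", path)
  obj$session
}
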