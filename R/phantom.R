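#' Digital brain-like phantom for SMS-EPI simulation
#'
#' Builds a piecewise-smooth, ellipse-based multi-slice complex phantom with
#' named tissue masks (used as ROIs downstream), a fractional BOLD activation
#' map split between a posterior "visual/offer" region and an anterior
#' "motor" region, and smooth per-slice variation so that slice supports
#' differ (which makes slice-leakage measurable).
#'
#' @param n grid size (even, >= 32); the image is `n x n` per slice.
#' @param n_slices number of slices.
#' @param seed integer seed; the phantom is bit-reproducible for a fixed seed.
#' @param activation_amp peak fractional BOLD amplitude (default 0.02 = 2%).
#' @return An object of class `sms_phantom`: complex image array
#'   `img` (n, n, n_slices), named logical `masks`, `activation` amplitude
#'   array, integer `act_label` array (0 none, 1 offer, 2 motor_response).
#' @export
make_phantom <- function(n = 64, n_slices = 4, seed = 1, activation_amp = 0.02) {
  if (n %% 2 != 0 || n < 32) stop("grid size must be even and >= 32")
  if (n_slices < 1) stop("need at least one slice")
  set.seed(seed)

  x <- fov_grid(n); y <- fov_grid(n)
  X <- matrix(x, n, n); Y <- matrix(y, n, n, byrow = TRUE)

  img <- array(0i, c(n, n, n_slices))
  support <- array(FALSE, c(n, n, n_slices))

  for (s in seq_len(n_slices)) {
    # per-slice ellipse geometry (deterministic in s) so supports differ
    rx <- 0.36 * (1 + 0.10 * cos(2 * pi * (s - 1) / n_slices + 0.7))
    ry <- 0.42 * (1 - 0.08 * sin(2 * pi * (s - 1) / n_slices + 0.3))
    ell <- (X / rx)^2 + (Y / ry)^2
    sup <- ell <= 1

    mag <- matrix(0, n, n)
    mag[sup] <- 0.9
    # smooth random texture: sum of seeded Gaussian bumps
    for (k in seq_len(20)) {
      cx <- stats::runif(1, -0.3, 0.3); cy <- stats::runif(1, -0.35, 0.35)
      wd <- stats::runif(1, 0.05, 0.15); am <- stats::runif(1, -0.18, 0.18)
      mag <- mag + am * exp(-(((X - cx)^2 + (Y - cy)^2) / (2 * wd^2)))
    }
    # ventricle-like dark inclusions
    vent <- (((X - 0.06) / 0.06)^2 + ((Y - 0.04) / 0.10)^2 <= 1) |
            (((X + 0.06) / 0.06)^2 + ((Y - 0.04) / 0.10)^2 <= 1)
    mag[vent] <- mag[vent] * 0.35
    mag[!sup] <- 0
    mag[sup] <- pmax(mag[sup], 0.25)

    # smooth low-order phase
    ph <- stats::runif(1, -0.4, 0.4) + stats::runif(1, -0.8, 0.8) * X +
      stats::runif(1, -0.8, 0.8) * Y + stats::runif(1, -1.5, 1.5) * X * Y
    img[, , s] <- mag * exp(1i * ph)
    support[, , s] <- sup
  }

  # ROI set: angular sectors of the object shell plus a deep central region.
  r2 <- X^2 + Y^2
  theta <- atan2(Y, X)
  deep2d <- r2 <= 0.12^2
  sector_names <- c("occipital", "parietal_l", "parietal_r", "temporal_l",
                    "temporal_r", "frontal_l", "frontal_r")
  edges <- seq(-pi, pi, length.out = length(sector_names) + 1)
  masks <- stats::setNames(
    vector("list", length(sector_names) + 1), c(sector_names, "deep"))
  for (i in seq_along(sector_names)) {
    sec2d <- theta >= edges[i] & theta < edges[i + 1] & !deep2d
    m <- array(FALSE, c(n, n, n_slices))
    for (s in seq_len(n_slices)) m[, , s] <- sec2d & support[, , s]
    masks[[i]] <- m
  }
  md <- array(FALSE, c(n, n, n_slices))
  for (s in seq_len(n_slices)) md[, , s] <- deep2d & support[, , s]
  masks[["deep"]] <- md

  # Activation: two disjoint Gaussian blobs, posterior (offer) and
  # anterior-left (motor_response), present on all slices, peak = amp.
  act <- array(0, c(n, n, n_slices))
  lab <- array(0L, c(n, n, n_slices))
  blob <- function(cx, cy, wd) exp(-(((X - cx)^2 + (Y - cy)^2) / (2 * wd^2)))
  b_off <- blob(-0.22, 0.0, 0.06)   # posterior (low x = "back of head")
  b_mot <- blob(0.20, -0.12, 0.05)  # anterior-left
  for (s in seq_len(n_slices)) {
    a <- activation_amp * b_off
    a[b_off < 0.3] <- 0
    m <- activation_amp * b_mot
    m[b_mot < 0.3] <- 0
    a[!support[, , s]] <- 0; m[!support[, , s]] <- 0
    lab_s <- matrix(0L, n, n)
    lab_s[a > 0] <- 1L
    lab_s[m > 0] <- 2L
    act[, , s] <- pmax(a, m)
    lab[, , s] <- lab_s
  }
  if (max(act) > 0) act <- act * (activation_amp / max(act))

  structure(list(
    n = n, n_slices = n_slices, img = img, support = support,
    masks = masks, activation = act, act_label = lab,
    act_regressors = c("offer", "motor_response"),
    activation_amp = activation_amp, seed = seed
  ), class = "sms_phantom")
}

#' Smooth complex coil sensitivity maps
#'
#' Coils are modelled as broad Gaussian lobes placed on a ring around the
#' object with smooth low-order phase, then normalised so that the
#' root-sum-of-squares over the object region is 1 on average.
#'
#' @param n_coils number of receive channels (>= 2; parallel imaging below
#'   needs coil encoding).
#' @param n grid size.
#' @param seed integer seed.
#' @return class `coil_maps`: complex array (n, n, n_coils).
#' @export
make_coil_maps <- function(n_coils = 8, n = 64, seed = 1) {
  if (n_coils < 2) stop("parallel imaging requires at least 2 coils")
  set.seed(seed + 1000L)
  x <- fov_grid(n)
  X <- matrix(x, n, n); Y <- matrix(x, n, n, byrow = TRUE)
  maps <- array(0i, c(n, n, n_coils))
  for (c_ in seq_len(n_coils)) {
    ang <- 2 * pi * (c_ - 1) / n_coils + stats::runif(1, -0.15, 0.15)
    cx <- 0.55 * cos(ang); cy <- 0.55 * sin(ang)
    wd <- stats::runif(1, 0.28, 0.38)
    mag <- exp(-(((X - cx)^2 + (Y - cy)^2) / (2 * wd^2)))
    ph <- stats::runif(1, -pi, pi) + stats::runif(1, -2.5, 2.5) * X +
      stats::runif(1, -2.5, 2.5) * Y + stats::runif(1, -2.5, 2.5) * X * Y
    maps[, , c_] <- mag * exp(1i * ph)
  }
  rss <- sqrt(apply(Mod(maps)^2, c(1, 2), sum))
  disc <- (X^2 + Y^2) <= 0.35^2
  maps <- maps / mean(rss[disc])
  structure(list(maps = maps, n = n, n_coils = n_coils, seed = seed),
            class = "coil_maps")
}

#' Root-sum-of-squares of coil maps
#' @param coils a `coil_maps` object.
#' @return matrix (n, n).
#' @export
coil_rss <- function(coils) {
  sqrt(apply(Mod(coils$maps)^2, c(1, 2), sum))
}

#' Dynamic field-perturbation timeline
#'
#' One spatially-linear field state per frame: a constant term `c0` (Hz) and
#' linear coefficients `cx`, `cy` (Hz per FOV along readout / phase-encode).
#' Frame 1 is the reference and is always (0, 0, 0). Models: "smooth"
#' (low-pass filtered noise, body-motion-like drift), "step" (piecewise
#' constant posture changes), "spikes" (mostly zero with isolated excursions,
#' e.g. discrete responses or licking).
#'
#' @param n_frames number of frames T (>= 2).
#' @param amp named or positional numeric of length 3: maximum |c0|, |cx|,
#'   |cy| in Hz (per FOV for the linear terms). Must be non-negative.
#' @param model one of "smooth", "step", "spikes".
#' @param seed integer seed.
#' @return class `field_timeline`: tibble with columns frame, c0, cx, cy.
#' @export
make_field_timeline <- function(n_frames, amp = c(c0 = 10, cx = 15, cy = 15),
                                model = c("smooth", "step", "spikes"),
                                seed = 1) {
  model <- match.arg(model)
  if (n_frames < 2) stop("need at least 2 frames")
  amp <- rep_len(as.numeric(amp), 3)
  if (any(amp < 0)) stop("amplitudes must be non-negative")
  set.seed(seed + 2000L)

  # spike positions are shared across the three coefficients (a discrete
  # body-motion event perturbs all field terms at once)
  spike_pos <- if (model == "spikes") {
    n_spk <- max(1L, round(0.1 * n_frames))
    cand <- seq(3L, n_frames, by = 2L)
    sample(cand, min(n_spk, length(cand)))
  } else integer(0)

  one <- function(a) {
    if (a == 0) return(rep(0, n_frames))
    v <- switch(model,
      smooth = {
        z <- stats::rnorm(n_frames + 24)
        k <- stats::dnorm(seq(-3, 3, length.out = 13))
        z <- stats::filter(z, k / sum(k), sides = 2)
        z <- as.numeric(z[13:(12 + n_frames)])
        z - z[1]
      },
      step = {
        n_seg <- 4L
        bounds <- sort(sample(2:(n_frames - 1), n_seg - 1))
        lev <- c(0, stats::runif(n_seg - 1, -1, 1))
        rep(lev, diff(c(1L, bounds, n_frames + 1L)))
      },
      spikes = {
        v <- rep(0, n_frames)
        v[spike_pos] <- stats::runif(length(spike_pos), -1, 1)
        v
      })
    m <- max(abs(v))
    if (m > 0) v <- v * (a / m)
    v[1] <- 0
    v
  }

  tl <- tibble::tibble(frame = seq_len(n_frames),
                       c0 = one(amp[1]), cx = one(amp[2]), cy = one(amp[3]))
  class(tl) <- c("field_timeline", class(tl))
  attr(tl, "model") <- model
  attr(tl, "amp") <- amp
  tl
}

#' Convert a field state to its k-space translation equivalent
#'
#' A spatially linear off-resonance (c0, cx, cy) acting until the echo time
#' is equivalent to a global phase `phi0 = 2*pi*c0*TE` plus a net k-space
#' translation `(dkx, dky) = (cx*TE, cy*TE)` in grid units.
#'
#' @param state numeric of length 3 `(c0, cx, cy)` in Hz (per FOV).
#' @param te echo time in seconds.
#' @return numeric `(phi0, dkx, dky)` (radians, grid units).
#' @export
field_to_shift <- function(state, te) {
  state <- as.numeric(state)
  c(phi0 = 2 * pi * state[1] * te, dkx = state[2] * te, dky = state[3] * te)
}

#' Inverse of [field_to_shift()]
#' @param shift numeric `(phi0, dkx, dky)`.
#' @param te echo time in seconds.
#' @return numeric `(c0, cx, cy)`.
#' @export
shift_to_field <- function(shift, te) {
  shift <- as.numeric(shift)
  c(c0 = shift[1] / (2 * pi * te), cx = shift[2] / te, cy = shift[3] / te)
}

#' Decision-task event list
#'
#' Emulates the trial structure of a decision-making task: an offer appears,
#' the go-cue follows after 3-4 s, the animal may respond within 1 s of the
#' go-cue, a reward outcome follows a responded trial after 3.5-4.5 s, and
#' trials are separated by a 3.5-4.5 s intertrial interval.
#'
#' @param n_trials number of trials (>= 1).
#' @param p_respond probability of a response on each trial, in `[0, 1]`.
#' @param seed integer seed.
#' @param t_start time of the first offer (s).
#' @return class `event_list`: tibble with per-trial onsets (s): offer_onset,
#'   gocue_onset, responded, response_onset, outcome_onset (NA when the trial
#'   was not responded).
#' @export
make_task_events <- function(n_trials, p_respond = 0.8, seed = 1,
                             t_start = 4) {
  if (n_trials < 1) stop("need at least one trial")
  if (p_respond < 0 || p_respond > 1) stop("p_respond must be in [0, 1]")
  set.seed(seed + 3000L)
  offer <- gocue <- resp_on <- outc <- numeric(n_trials)
  # with 0 < p < 1 the task must contain both trial types, otherwise the
  # motor_response regressor is indistinguishable from action_onset
  responded <- stats::runif(n_trials) < p_respond
  if (p_respond > 0 && p_respond < 1 && n_trials >= 2) {
    if (all(responded)) responded[sample(n_trials, 1)] <- FALSE
    if (!any(responded)) responded[sample(n_trials, 1)] <- TRUE
  }
  t <- t_start
  for (i in seq_len(n_trials)) {
    offer[i] <- t
    gocue[i] <- offer[i] + stats::runif(1, 3, 4)
    if (responded[i]) {
      resp_on[i] <- gocue[i] + stats::runif(1, 0.2, 1.0)
      outc[i] <- resp_on[i] + stats::runif(1, 3.5, 4.5)
      t <- outc[i] + stats::runif(1, 3.5, 4.5)
    } else {
      resp_on[i] <- NA_real_
      outc[i] <- NA_real_
      t <- gocue[i] + 1.0 + stats::runif(1, 3.5, 4.5)
    }
  }
  ev <- tibble::tibble(trial = seq_len(n_trials), offer_onset = offer,
                       gocue_onset = gocue, responded = responded,
                       response_onset = resp_on, outcome_onset = outc)
  class(ev) <- c("event_list", class(ev))
  ev
}

#' Monkey-calibrated double-gamma HRF parameters
#'
#' The response peak defaults to 3 s (faster than the canonical human HRF);
#' shape is a configuration knob since no standard parameter set exists for
#' macaque cortex.
#'
#' @param peak time-to-peak of the positive lobe (s).
#' @param upeak time-to-peak of the undershoot (s).
#' @param ratio positive-to-undershoot amplitude ratio.
#' @param duration kernel length (s).
#' @export
hrf_params <- function(peak = 3, upeak = 7.5, ratio = 6, duration = 24) {
  list(peak = peak, upeak = upeak, ratio = ratio, duration = duration,
       a1 = 6, a2 = 12)
}

#' Evaluate the double-gamma HRF kernel
#' @param t time points (s).
#' @param hrf parameters from [hrf_params()].
#' @return kernel values, normalised to unit peak.
#' @export
hrf_kernel <- function(t, hrf = hrf_params()) {
  r1 <- (hrf$a1 - 1) / hrf$peak
  r2 <- (hrf$a2 - 1) / hrf$upeak
  h <- stats::dgamma(t, shape = hrf$a1, rate = r1) -
    stats::dgamma(t, shape = hrf$a2, rate = r2) / hrf$ratio
  h / max(h)
}

# Convolved regressor time course sampled at frame times.
# onsets: event onset times (s); boxcar of `dur` seconds, unit amplitude.
regressor_timecourse <- function(onsets, n_frames, tr, hrf = hrf_params(),
                                 dur = 0.1, dt = 0.02) {
  onsets <- onsets[!is.na(onsets)]
  t_end <- n_frames * tr
  grid <- seq(0, t_end + hrf$duration, by = dt)
  stim <- numeric(length(grid))
  for (o in onsets) {
    if (o > t_end) next
    idx <- which(grid >= o & grid < o + dur)
    stim[idx] <- stim[idx] + 1
  }
  ker <- hrf_kernel(seq(0, hrf$duration, by = dt), hrf)
  conv <- stats::convolve(stim, rev(ker), type = "open")[seq_along(grid)]
  conv <- conv / (dur / dt)  # unit-amplitude response per isolated event
  ft <- (seq_len(n_frames) - 1) * tr
  stats::approx(grid, conv, xout = ft, rule = 2)$y
}

#' Ground-truth object at a given frame
#'
#' Applies the BOLD modulation to the static phantom: voxels in the offer
#' region follow the convolved offer regressor, voxels in the motor region
#' follow the convolved motor_response regressor; all other voxels are
#' frame-independent.
#'
#' @param phantom an `sms_phantom`.
#' @param events an `event_list`.
#' @param hrf HRF parameters ([hrf_params()]).
#' @param t frame index (1-based).
#' @param tr repetition time (s).
#' @param n_frames total frames (for regressor construction; defaults to `t`).
#' @return complex array (n, n, n_slices).
#' @export
object_at_frame <- function(phantom, events, hrf = hrf_params(), t, tr,
                            n_frames = t) {
  if (t < 1 || t > n_frames) stop("frame index out of range")
  xo <- regressor_timecourse(events$offer_onset, n_frames, tr, hrf)
  xm <- regressor_timecourse(
    events$gocue_onset[events$responded], n_frames, tr, hrf)
  modulate_object(phantom, xo[t], xm[t])
}

# Fast path used by the acquisition loop: regressor values already known.
modulate_object <- function(phantom, x_offer, x_motor) {
  mod <- 1 + phantom$activation *
    ((phantom$act_label == 1L) * x_offer + (phantom$act_label == 2L) * x_motor)
  phantom$img * mod
}

#' Write event files in 3-column (onset, duration, amplitude) text format
#'
#' One file per regressor: offer, action_onset, motor_response, outcome.
#'
#' @param events an `event_list`.
#' @param dir output directory (created if missing).
#' @param duration event duration written to the files (s).
#' @return invisibly, the paths written.
#' @export
write_event_files <- function(events, dir, duration = 0.1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sets <- list(
    offer = events$offer_onset,
    action_onset = events$gocue_onset,
    motor_response = events$gocue_onset[events$responded],
    outcome = events$outcome_onset[events$responded]
  )
  paths <- character(0)
  for (nm in names(sets)) {
    on <- sets[[nm]][!is.na(sets[[nm]])]
    p <- file.path(dir, paste0(nm, ".txt"))
    utils::write.table(
      data.frame(onset = on, duration = duration, amplitude = 1),
      p, row.names = FALSE, col.names = FALSE, sep = "\t")
    paths <- c(paths, p)
  }
  invisible(paths)
}
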